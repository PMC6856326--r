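#' Bundled reference proteins for homology-seeded mining
#'
#' Loads the packaged exemplar set used to seed cluster discovery: one
#' protein per role among lasso cyclase (C), leader peptidase (B), RiPP
#' recognition element (E) and ABC transporter. These are constructed
#' stand-in sequences of realistic length and composition (the file is
#' labelled `synthetic`), generated once with a fixed seed; they anchor the
#' self-consistent synthetic-genome validation loop and can be replaced by a
#' curated FASTA (e.g. real cyclase accessions) via `path`.
#'
#' @param path Optional FASTA of reference proteins; headers must carry a
#'   `role=` tag (`cyclase`, `peptidase`, `RRE` or `transporter`).
#' @return data.frame with columns `id`, `role`, `sequence`.
#' @export
read_reference_proteins <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_proteins_synthetic.fasta",
                        package = "lassokit", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  role <- sub(".*role=([A-Za-z]+).*", "\\1", hdr)
  id <- vapply(strsplit(hdr, "\\s+"), `[[`, "", 1L)
  data.frame(id = id, role = role, sequence = as.character(aa),
             row.names = NULL)
}

.as_proteome <- function(proteome) {
  if (is.data.frame(proteome)) {
    stopifnot(all(c("id", "sequence") %in% names(proteome)))
    return(proteome)
  }
  if (methods::is(proteome, "AAStringSet"))
    return(data.frame(id = names(proteome), sequence = as.character(proteome)))
  if (is.character(proteome)) {
    ids <- names(proteome)
    if (is.null(ids)) ids <- paste0("protein_", seq_along(proteome))
    return(data.frame(id = ids, sequence = unname(proteome)))
  }
  stop("unsupported proteome representation", call. = FALSE)
}

#' Find seed hits by local similarity to reference proteins
#'
#' Aligns every protein of a proteome against each reference exemplar with
#' [smith_waterman()] and reports proteins whose normalized score (alignment
#' score divided by the reference's self-score) reaches `threshold`, labelled
#' with the reference's role. This is the homology-seeded entry point of
#' cluster mining: the default scans for lasso-cyclase homologues only.
#'
#' @param proteome data.frame with `id` and `sequence` columns, an
#'   `AAStringSet`, or a (named) character vector.
#' @param references Reference set from [read_reference_proteins()].
#' @param threshold Minimum normalized score (default 0.3).
#' @param roles Which reference roles to search with (default `"cyclase"`).
#' @return data.frame `id`, `role`, `ref_id`, `score`, `normalized_score`,
#'   `percent_identity`, sorted by normalized score, best first.
#' @export
find_seed_hits <- function(proteome, references = read_reference_proteins(),
                           threshold = 0.3, roles = "cyclase") {
  proteome <- .as_proteome(proteome)
  refs <- references[references$role %in% roles, , drop = FALSE]
  if (!nrow(refs)) stop("reference set contains no exemplar for the requested roles",
                        call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(proteome))) {
    for (j in seq_len(nrow(refs))) {
      al <- smith_waterman(refs$sequence[j], proteome$sequence[i])
      if (al$normalized_score >= threshold)
        out[[length(out) + 1L]] <- data.frame(
          id = proteome$id[i], role = refs$role[j], ref_id = refs$id[j],
          score = al$score, normalized_score = al$normalized_score,
          percent_identity = al$percent_identity)
    }
  }
  if (!length(out))
    return(data.frame(id = character(), role = character(), ref_id = character(),
                      score = numeric(), normalized_score = numeric(),
                      percent_identity = numeric()))
  out <- do.call(rbind, out)
  out <- out[order(-out$normalized_score, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.role_call <- function(sequence, references, threshold) {
  best_role <- "other"; best <- 0
  for (j in seq_len(nrow(references))) {
    al <- smith_waterman(references$sequence[j], sequence)
    if (al$normalized_score >= threshold && al$normalized_score > best) {
      best <- al$normalized_score
      best_role <- references$role[j]
    }
  }
  list(role = best_role, normalized_score = best)
}

#' Assemble a cluster candidate around a seed hit
#'
#' Gathers annotated genes around a cyclase seed hit (within `window_genes`
#' genes and `window_bp` bp of the seed, whichever is smaller), assigns each
#' neighbor a role by local similarity to the reference exemplars, and
#' summarizes the neighborhood: completeness requires the peptidase (B),
#' cyclase (C) and RRE (E); transporters are counted but optional, and the
#' maximum intergenic gap is reported with a flag for gaps over
#' `gap_flag_bp` (clusters lacking substantial intergenic regions are likely
#' single transcription units).
#'
#' @param hit One row of [find_seed_hits()] output (or a list with `id`).
#' @param annotations data.frame of gene annotations: `id`, `contig`,
#'   `start`, `end`, `strand`, `sequence` (protein). Coordinates are 1-based
#'   inclusive. The seed `id` must appear here with coordinates.
#' @param references Reference exemplars for role assignment.
#' @param threshold Normalized-score threshold for role calls.
#' @param window_genes,window_bp Neighborhood window (default 8 genes, 10 kb).
#' @param gap_flag_bp Gap size flagged as a substantial intergenic region.
#' @return An object of class `cluster_candidate`: list with `contig`,
#'   `span`, `members` (data.frame with assigned `role` and
#'   `normalized_score`), `max_intergenic_gap`, `substantial_gap`,
#'   `transporter_count`, `has_B`/`has_C`/`has_E`, `complete`.
#' @export
assemble_cluster <- function(hit, annotations,
                             references = read_reference_proteins(),
                             threshold = 0.3, window_genes = 8,
                             window_bp = 10000, gap_flag_bp = 500) {
  id <- if (is.data.frame(hit)) hit$id[[1]] else hit$id
  ann <- annotations
  stopifnot(all(c("id", "contig", "start", "end", "strand", "sequence") %in% names(ann)))
  k <- match(id, ann$id)
  if (is.na(k) || is.na(ann$start[k]))
    stop("seed hit '", id, "' has no coordinates in the annotation; ",
         "use proteome-only mode (find_seed_hits) instead", call. = FALSE)
  ann <- ann[ann$contig == ann$contig[k], , drop = FALSE]
  ann <- ann[order(ann$start), , drop = FALSE]
  k <- match(id, ann$id)
  idx <- seq_len(nrow(ann))
  near_genes <- abs(idx - k) <= window_genes
  seed_mid <- (ann$start[k] + ann$end[k]) / 2
  near_bp <- pmax(ann$start, ann$start[k]) - pmin(ann$end, ann$end[k]) <= window_bp
  members <- ann[near_genes & near_bp, , drop = FALSE]
  calls <- lapply(members$sequence, .role_call, references = references,
                  threshold = threshold)
  members$role <- vapply(calls, `[[`, "", "role")
  members$normalized_score <- vapply(calls, `[[`, 0, "normalized_score")
  gaps <- if (nrow(members) > 1L)
    members$start[-1L] - members$end[-nrow(members)] - 1L else integer()
  has <- function(role) any(members$role == role)
  structure(list(
    contig = members$contig[1L],
    span = c(min(members$start), max(members$end)),
    seed_id = id,
    members = members[, c("id", "contig", "start", "end", "strand", "role",
                          "normalized_score")],
    max_intergenic_gap = if (length(gaps)) max(gaps) else 0L,
    substantial_gap = length(gaps) && max(gaps) > gap_flag_bp,
    transporter_count = sum(members$role == "transporter"),
    has_B = has("peptidase"), has_C = has("cyclase"), has_E = has("RRE"),
    complete = has("peptidase") && has("cyclase") && has("RRE")),
    class = "cluster_candidate")
}

#' @export
print.cluster_candidate <- function(x, ...) {
  cat(sprintf("cluster candidate on %s:%d-%d (seed %s)\n", x$contig,
              x$span[1], x$span[2], x$seed_id))
  cat(sprintf("  complete (B+C+E): %s; transporters: %d; max intergenic gap: %d bp\n",
              x$complete, x$transporter_count, x$max_intergenic_gap))
  print.data.frame(x$members, row.names = FALSE)
  invisible(x)
}

#' Find short precursor-like ORFs in a genomic span
#'
#' Enumerates every open reading frame on both strands whose start codon is
#' ATG, GTG or TTG (bacterial genetic code), whose encoded protein is
#' `min_aa`-`max_aa` residues, and which lies within the requested span.
#' Each ORF is scored with [scan_motif()]; motif-positive ORFs are candidate
#' precursor (A) genes.
#'
#' @param dna Contig DNA (character or `DNAString`), A/C/G/T only.
#' @param span Optional `c(start, end)` (1-based inclusive) restricting the
#'   search; `margin` widens it on both sides.
#' @param margin Extra bp added around `span` (default 500).
#' @param min_aa,max_aa Protein length window (default 25-70).
#' @param starts Accepted start codons.
#' @param motif A [leader_motif] for scoring.
#' @return data.frame: `start`, `end`, `strand`, `length_aa`, `protein`,
#'   `motif_score`, `motif_positive`. Coordinates are forward-strand 1-based
#'   inclusive and include the stop codon.
#' @export
find_precursor_orfs <- function(dna, span = NULL, margin = 500L,
                                min_aa = 25L, max_aa = 70L,
                                starts = c("ATG", "GTG", "TTG"),
                                motif = leader_motif()) {
  dna <- toupper(as.character(dna))
  chars <- strsplit(dna, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("non-ACGT characters at positions ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  L <- nchar(dna)
  if (is.null(span)) span <- c(1L, L)
  lo <- max(1L, span[1] - margin); hi <- min(L, span[2] + margin)
  sub <- substr(dna, lo, hi)
  stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    out <- list()
    for (frame in 0:2) {
      npos <- seq(1L + frame, n - 2L, by = 3L)
      codons <- substring(s, npos, npos + 2L)
      stop_idx <- which(codons %in% stops)
      start_idx <- which(codons %in% starts)
      for (si in start_idx) {
        nxt <- stop_idx[stop_idx > si]
        if (!length(nxt)) next
        aa_len <- nxt[1] - si
        if (aa_len < min_aa || aa_len > max_aa) next
        orf_nt <- substr(s, npos[si], npos[nxt[1]] + 2L)
        prot <- as.character(Biostrings::translate(
          Biostrings::DNAString(substr(orf_nt, 1L, nchar(orf_nt) - 3L)),
          no.init.codon = TRUE))
        substr(prot, 1L, 1L) <- "M"  # alternative starts encode fMet
        out[[length(out) + 1L]] <- data.frame(
          s1 = npos[si], s2 = npos[nxt[1]] + 2L, strand = strand,
          length_aa = aa_len, protein = prot)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  fwd <- scan_strand(sub, "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  rev <- scan_strand(rc, "-")
  nsub <- nchar(sub)
  if (!is.null(rev)) {
    tmp <- nsub - rev$s2 + 1L
    rev$s2 <- nsub - rev$s1 + 1L
    rev$s1 <- tmp
  }
  orfs <- rbind(fwd, rev)
  if (is.null(orfs))
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      length_aa = integer(), protein = character(),
                      motif_score = integer(), motif_positive = logical()))
  orfs$start <- orfs$s1 + lo - 1L
  orfs$end <- orfs$s2 + lo - 1L
  score <- vapply(orfs$protein, function(p) {
    if (nchar(p) < motif$length) return(0L)
    hits <- scan_motif(p, motif)
    if (nrow(hits)) hits$score[1] else 0L
  }, 0L, USE.NAMES = FALSE)
  out <- data.frame(start = orfs$start, end = orfs$end, strand = orfs$strand,
                    length_aa = orfs$length_aa, protein = orfs$protein,
                    motif_score = score, motif_positive = score >= 4L)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genome annotation from GFF3 + FASTA
#'
#' Imports gene/CDS features with [rtracklayer::import()] and the genome with
#' [Biostrings::readDNAStringSet()], translates each CDS (strand-aware), and
#' returns the annotation table [mine_genome()] consumes.
#'
#' @param gff Path to a GFF3 file with CDS features.
#' @param fasta Path to the matching genome FASTA.
#' @return List with `dna` (named character, one element per contig) and
#'   `annotations` (data.frame `id`, `contig`, `start`, `end`, `strand`,
#'   `sequence`).
#' @export
read_genome_annotation <- function(gff, fasta) {
  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type == "CDS"]
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[[`, "", 1L)
  ids <- if (!is.null(gr$ID)) gr$ID else paste0("gene_", seq_along(gr))
  prot <- vapply(seq_along(gr), function(i) {
    contig <- as.character(GenomicRanges::seqnames(gr[i]))
    nt <- Biostrings::subseq(genome[[contig]], GenomicRanges::start(gr[i]),
                             GenomicRanges::end(gr[i]))
    if (as.character(GenomicRanges::strand(gr[i])) == "-")
      nt <- Biostrings::reverseComplement(nt)
    nt <- Biostrings::subseq(nt, 1L, length(nt) - 3L)  # drop stop codon
    p <- as.character(Biostrings::translate(nt, no.init.codon = TRUE))
    substr(p, 1L, 1L) <- "M"
    p
  }, "")
  list(dna = stats::setNames(as.character(genome), names(genome)),
       annotations = data.frame(
         id = ids,
         contig = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         sequence = prot))
}

#' Mine a genome for lasso peptide gene clusters
#'
#' Runs the full mining chain: cyclase seed search over the annotated
#' proteins ([find_seed_hits()]), neighborhood assembly and role assignment
#' around each seed ([assemble_cluster()]), and short-ORF precursor discovery
#' over each cluster span ([find_precursor_orfs()]). Overlapping candidates
#' from multiple seeds in one neighborhood are deduplicated (best seed kept).
#'
#' @param x Either a list with `dna` and `annotations` (as returned by
#'   [read_genome_annotation()] or [gen_cluster_genome()]), or a GFF3 path
#'   (then supply `fasta`).
#' @param fasta Genome FASTA path when `x` is a GFF3 path.
#' @param references,threshold,window_genes,window_bp Passed to the
#'   underlying steps.
#' @param ... Passed to [find_precursor_orfs()].
#' @return List of `cluster_candidate` objects, each with a `precursors`
#'   data.frame of motif-positive ORFs found in its span.
#' @export
mine_genome <- function(x, fasta = NULL,
                        references = read_reference_proteins(),
                        threshold = 0.3, window_genes = 8, window_bp = 10000,
                        ...) {
  if (is.character(x) && length(x) == 1L) {
    if (is.null(fasta)) stop("supply 'fasta' alongside a GFF3 path", call. = FALSE)
    x <- read_genome_annotation(x, fasta)
  }
  ann <- x$annotations
  hits <- find_seed_hits(ann, references, threshold, roles = "cyclase")
  clusters <- list()
  for (i in seq_len(nrow(hits))) {
    cc <- assemble_cluster(hits[i, ], ann, references, threshold,
                           window_genes, window_bp)
    dup <- any(vapply(clusters, function(z)
      z$contig == cc$contig && z$span[1] <= cc$span[2] && cc$span[1] <= z$span[2],
      NA))
    if (!dup) clusters[[length(clusters) + 1L]] <- cc
  }
  for (i in seq_along(clusters)) {
    contig <- clusters[[i]]$contig
    orfs <- find_precursor_orfs(x$dna[[contig]], span = clusters[[i]]$span, ...)
    clusters[[i]]$precursors <- orfs[orfs$motif_positive, , drop = FALSE]
  }
  clusters
}
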