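# Seeded synthetic-data generators: genomes with planted lasso BGCs,
# motif-obeying precursors, and deconvoluted lasso MS/MS peak lists. Every
# artifact carries its ground truth so recovery tests never re-derive it.

.AA20 <- names(.RESIDUE_MASSES)

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation specification
#'
#' Bundles the parameters of the synthetic-data generators. A fixed seed
#' gives byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param gc_content Target GC fraction of generated DNA (default 0.72,
#'   Streptomyces-like).
#' @param layout Ordered gene roles of the planted cluster; letters from
#'   C (cyclase), E (RRE), B (peptidase), A (precursor), D/F (transporters).
#'   Default is the lee-type order `c("C","E","B","A","D","F")`.
#' @param intergenic_bp Range of intergenic spacer lengths within the
#'   cluster (default 20-120 bp: compact, minimal intergenic gaps).
#' @param flank_bp Flanking DNA on each side of the gene region.
#' @param decoy_genes Number of unrelated random protein genes planted
#'   outside the cluster (default 2).
#' @param precursor_template Optional precursor sequence used as mutation
#'   template instead of de novo generation.
#' @param mutation_rate Per-position substitution probability applied to
#'   planted proteins (and to `precursor_template` if given).
#' @param core_length Range of de novo core lengths (default 14-24).
#' @param ring_positions Positions from which the planted ring residue is
#'   drawn (default 7-9).
#' @param precursor_strand Strand on which the precursor gene is planted.
#' @param dropout Per-ion drop probability for spectra; scalar or named
#'   vector `c(a=,b=,y=)`; in \[0, 1\].
#' @param noise_peaks Number of uniform random noise peaks added.
#' @param noise_range m/z range of noise peaks.
#' @param noise_meanlog,noise_sdlog Log-normal noise intensity parameters.
#' @param intensity_floor True-ion intensities are drawn uniformly above
#'   this fraction of the maximum.
#' @param jitter_sd Gaussian mass jitter applied to true ions (Da; default
#'   0.002, matching sub-0.002 Da instrument deviations).
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, gc_content = 0.72,
                            layout = c("C", "E", "B", "A", "D", "F"),
                            intergenic_bp = c(20L, 120L), flank_bp = 300L,
                            decoy_genes = 2L, precursor_template = NULL,
                            mutation_rate = 0, core_length = c(14L, 24L),
                            ring_positions = 7:9, precursor_strand = "+",
                            dropout = 0, noise_peaks = 0L,
                            noise_range = c(100, 2000),
                            noise_meanlog = log(50), noise_sdlog = 1,
                            intensity_floor = 0.2, jitter_sd = 0.002) {
  stopifnot(gc_content > 0, gc_content < 1, all(dropout >= 0), all(dropout <= 1),
            mutation_rate >= 0, mutation_rate <= 1, jitter_sd >= 0,
            precursor_strand %in% c("+", "-"))
  structure(as.list(environment()), class = "simulation_spec")
}

.mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  r <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(r)) < rate)
  hit <- hit[hit > 1L]  # keep the initiator Met
  for (i in hit) r[i] <- sample(setdiff(.AA20, r[i]), 1L)
  paste(r, collapse = "")
}

.gen_precursor_impl <- function(spec) {
  motif <- leader_motif()
  if (!is.null(spec$precursor_template)) {
    seq <- .mutate_protein(toupper(spec$precursor_template), spec$mutation_rate)
    cands <- enumerate_core_candidates(seq, spec$ring_positions)
    top <- cands[1L, ]
    ring <- top$ring_candidates[[1]]
    return(list(id = paste0("synthetic_precursor_seed", spec$seed),
                sequence = seq, leader = top$leader, core = top$core,
                cleavage_site = top$cleavage_site,
                ring_pos = if (length(ring) == 1L) unname(ring) else NA_integer_))
  }
  no_y <- setdiff(.AA20, "Y")
  prefix_len <- sample(4:8, 1L)
  prefix <- c("M", sample(no_y, prefix_len - 1L, replace = TRUE))
  win <- sample(no_y, motif$length, replace = TRUE)
  win[1] <- "Y"; win[4] <- "P"; win[6] <- sample(c("L", "V"), 1L)
  win[10] <- "G"; win[16] <- "T"
  leader <- c(prefix, win)
  core_len <- sample(spec$core_length[1]:spec$core_length[2], 1L)
  core <- sample(.AA20, core_len, replace = TRUE)
  ring_pos <- sample(spec$ring_positions, 1L)
  core[ring_pos] <- sample(c("D", "E"), 1L)
  list(id = paste0("synthetic_precursor_seed", spec$seed),
       sequence = paste(c(leader, core), collapse = ""),
       leader = paste(leader, collapse = ""), core = paste(core, collapse = ""),
       cleavage_site = length(leader), ring_pos = ring_pos)
}

#' Generate a synthetic precursor peptide with ground truth
#'
#' De novo mode builds a leader (initiator Met, a short random prefix, then
#' one instance of the conserved leader motif) followed by a random core of
#' length 14-24 with an Asp/Glu planted at a ring position drawn from 7-9.
#' Template mode mutates `spec$precursor_template` at the configured rate
#' (rate 0 reproduces the template exactly). Output is deterministic per
#' seed.
#'
#' @param spec A [simulation_spec()].
#' @return List: `id`, `sequence`, `leader`, `core`, `cleavage_site`,
#'   `ring_pos` (the planted ground truth; `NA` ring in template mode when
#'   several ring candidates remain).
#' @examples
#' gen_precursor(simulation_spec(seed = 7))$core
#' @export
gen_precursor <- function(spec = simulation_spec()) {
  .with_seed(spec$seed, .gen_precursor_impl(spec))
}

.random_dna_impl <- function(n, gc)
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")

#' Random DNA with a target GC content
#'
#' @param n Length in bp.
#' @param gc_content GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return A character DNA string.
#' @export
random_dna <- function(n, gc_content = 0.72, seed = 1L) {
  stopifnot(gc_content > 0, gc_content < 1)
  .with_seed(seed, .random_dna_impl(n, gc_content))
}

# GC-biased back-translation: synonymous codons weighted by
# gc^(#GC) * (1-gc)^(3-#GC); stop codon drawn with the same weighting.
.back_translate <- function(protein, gc) {
  code <- Biostrings::GENETIC_CODE
  r <- strsplit(protein, "")[[1]]
  pick <- function(codons) {
    g <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")), 0L)
    w <- gc^g * (1 - gc)^(3 - g)
    sample(codons, 1L, prob = w)
  }
  body <- vapply(seq_along(r), function(i) {
    if (i == 1L && r[i] == "M") return("ATG")
    pick(names(code)[code == r[i]])
  }, "")
  paste(c(body, pick(c("TAA", "TAG", "TGA"))), collapse = "")
}

#' Generate a synthetic genome with a planted lasso BGC
#'
#' Back-translates the bundled reference proteins (optionally mutated at a
#' seeded rate) and a generated precursor with GC-biased codon choice,
#' concatenates them in the requested gene order with short intergenic
#' spacers, and plants unrelated decoy genes outside the cluster behind
#' larger gaps. The result is a single contig plus its annotation and the
#' full ground truth.
#'
#' @param spec A [simulation_spec()]. `spec$layout` must contain a cyclase
#'   (`"C"`), otherwise the truth is unmineable and an error is raised.
#' @return List with `dna` (named character, one contig), `annotations`
#'   (data.frame `id`, `contig`, `start`, `end`, `strand`, `sequence`),
#'   and `truth` (list: `layout`, `roles` per gene id, `cluster_span`,
#'   `transporter_count`, `precursor` ground truth, `seed`).
#' @export
gen_cluster_genome <- function(spec = simulation_spec()) {
  if (!"C" %in% spec$layout)
    stop("layout must contain a cyclase ('C'); a cluster without one cannot be mined",
         call. = FALSE)
  .with_seed(spec$seed, {
    refs <- read_reference_proteins()
    role_of <- c(C = "cyclase", E = "RRE", B = "peptidase", A = "precursor",
                 D = "transporter", F = "transporter")
    bad <- setdiff(spec$layout, names(role_of))
    if (length(bad)) stop("unknown layout role: ", bad[1], call. = FALSE)
    prec <- .gen_precursor_impl(spec)
    gene_protein <- function(code) {
      if (code == "A") return(prec$sequence)
      role <- role_of[[code]]
      .mutate_protein(refs$sequence[refs$role == role][1L], spec$mutation_rate)
    }
    genes <- data.frame(code = spec$layout,
                        id = paste0("gene", seq_along(spec$layout), "_", spec$layout))
    genes$protein <- vapply(genes$code, gene_protein, "")
    genes$strand <- ifelse(genes$code == "A", spec$precursor_strand, "+")
    # decoy genes flank the cluster behind substantial gaps
    n_decoy <- spec$decoy_genes
    decoys <- if (n_decoy > 0) data.frame(
      code = "X", id = paste0("decoy", seq_len(n_decoy)),
      protein = vapply(seq_len(n_decoy), function(i)
        paste(c("M", sample(.AA20, sample(80:150, 1L), replace = TRUE)),
              collapse = ""), ""),
      strand = "+") else NULL
    n_before <- if (n_decoy > 0) ceiling(n_decoy / 2) else 0L
    order_df <- rbind(if (n_before > 0) decoys[seq_len(n_before), ],
                      genes,
                      if (n_decoy > n_before) decoys[(n_before + 1):n_decoy, ])
    parts <- character(); ann <- list(); pos <- 0L
    emit <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
    emit(.random_dna_impl(spec$flank_bp, spec$gc_content))
    for (i in seq_len(nrow(order_df))) {
      is_decoy <- order_df$code[i] == "X"
      prev_decoy <- i > 1L && order_df$code[i - 1L] == "X"
      if (i > 1L) {
        gap <- if (is_decoy || prev_decoy) 1500L else
          sample(spec$intergenic_bp[1]:spec$intergenic_bp[2], 1L)
        emit(.random_dna_impl(gap, spec$gc_content))
      }
      nt <- .back_translate(order_df$protein[i], spec$gc_content)
      if (order_df$strand[i] == "-")
        nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
      start <- pos + 1L
      emit(nt)
      ann[[length(ann) + 1L]] <- data.frame(
        id = order_df$id[i], contig = "contig_1", start = start, end = pos,
        strand = order_df$strand[i], sequence = order_df$protein[i])
    }
    emit(.random_dna_impl(spec$flank_bp, spec$gc_content))
    ann <- do.call(rbind, ann)
    cluster_ids <- genes$id
    span <- c(min(ann$start[ann$id %in% cluster_ids]),
              max(ann$end[ann$id %in% cluster_ids]))
    list(dna = c(contig_1 = paste(parts, collapse = "")),
         annotations = ann,
         truth = list(layout = spec$layout,
                      roles = stats::setNames(
                        c(unname(role_of[genes$code]),
                          if (n_decoy > 0) rep("other", n_decoy)),
                        c(genes$id, if (n_decoy > 0) decoys$id)),
                      cluster_span = span,
                      transporter_count = sum(spec$layout %in% c("D", "F")),
                      precursor = prec, seed = spec$seed))
  })
}

#' Write a synthetic genome as FASTA + GFF3 + truth JSON
#'
#' @param genome Result of [gen_cluster_genome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_cluster_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genome.gff3")
  truth <- file.path(dir, "truth.json")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$dna), fa)
  ann <- genome$annotations
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig,
    ranges = IRanges::IRanges(ann$start, ann$end),
    strand = ann$strand, type = "CDS", ID = ann$id, phase = 0L)
  rtracklayer::export(gr, gff, format = "gff3")
  jsonlite::write_json(genome$truth, truth, auto_unbox = TRUE, digits = NA)
  c(fasta = fa, gff = gff, truth = truth)
}

#' Generate a synthetic deconvoluted lasso MS/MS peak list
#'
#' Emits the observable theoretical ions of the lasso ion table for
#' (`core`, `ring_pos`) with Gaussian mass jitter, drops each ion with the
#' configured probability, never emits ring-internal ions, and adds uniform
#' noise peaks with log-normal intensities. The ground truth records every
#' true ion and whether it survived dropout.
#'
#' @param core Core residue string.
#' @param ring_pos Planted ring position.
#' @param spec A [simulation_spec()]; uses `dropout` (scalar or named
#'   `c(a=,b=,y=)`), `noise_peaks`, `noise_range`, `noise_meanlog`,
#'   `noise_sdlog`, `intensity_floor`, `jitter_sd`, `seed`.
#' @param tolerance Tolerance contract recorded on the returned peak list.
#' @param protect_diagnostic If `TRUE`, the ring-diagnostic ions (a/b at
#'   index r + 1 and y at index n - r) are exempt from dropout, so dropout
#'   only thins the non-diagnostic evidence.
#' @return List: `peaks` (a [peak_list]), `truth` (data.frame `series`,
#'   `index`, `theoretical`, `observed`, `kept`), `core`, `ring_pos`.
#' @examples
#' sim <- gen_spectrum("LYGVRNDEEINWHFDYWT", 8, simulation_spec(seed = 3))
#' infer_ring("LYGVRNDEEINWHFDYWT", sim$peaks)$ring_pos
#' @export
gen_spectrum <- function(core, ring_pos, spec = simulation_spec(),
                         tolerance = "0.01da", protect_diagnostic = FALSE) {
  tab <- lasso_ion_table(core, ring_pos)
  obs <- as.data.frame(tab)[tab$observable, , drop = FALSE]
  n <- nchar(core)
  diagnostic <- (obs$series %in% c("a", "b") & obs$index == ring_pos + 1L) |
    (obs$series == "y" & obs$index == n - ring_pos)
  .with_seed(spec$seed, {
    drop_p <- if (length(spec$dropout) == 1L)
      rep(spec$dropout, nrow(obs)) else unname(spec$dropout[obs$series])
    if (protect_diagnostic) drop_p[diagnostic] <- 0
    kept <- stats::runif(nrow(obs)) >= drop_p
    observed <- obs$mz + stats::rnorm(nrow(obs), 0, spec$jitter_sd)
    intensity <- stats::runif(nrow(obs), spec$intensity_floor, 1) * 1000
    noise_mz <- if (spec$noise_peaks > 0)
      stats::runif(spec$noise_peaks, spec$noise_range[1], spec$noise_range[2])
    else numeric()
    noise_int <- if (spec$noise_peaks > 0)
      stats::rlnorm(spec$noise_peaks, spec$noise_meanlog, spec$noise_sdlog)
    else numeric()
    peaks <- peak_list(c(observed[kept], noise_mz),
                       c(intensity[kept], noise_int), tolerance,
                       source_id = sprintf("synthetic_%s_r%d_seed%d", core,
                                           ring_pos, spec$seed))
    list(peaks = peaks,
         truth = data.frame(series = obs$series, index = obs$index,
                            theoretical = obs$mz, observed = observed,
                            kept = kept),
         core = core, ring_pos = ring_pos)
  })
}

#' Write a peak list as MGF
#'
#' @param x A [peak_list].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(x, path) {
  stopifnot(inherits(x, "peak_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("BEGIN IONS",
               paste0("TITLE=", if (is.na(x$source_id)) "peaklist" else x$source_id),
               "CHARGE=1+",
               sprintf("%.6f %.4f", x$mz, x$intensity),
               "END IONS"), con)
  invisible(path)
}
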