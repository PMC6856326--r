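#' Conserved lasso leader motif
#'
#' The 17-position leader template Y-x-x-P-x-\[LV\]-x-x-x-G-x-x-x-x-x-T-x
#' shared by actinobacterial lasso precursors: four anchor residues
#' (Tyr1, Pro4, Gly10, Thr16) and a tolerated Leu/Val at position 6. Thr at
#' position 16 is the penultimate residue of the leader, so cleavage after
#' position 17 leaves a leader ending in Thr-x.
#'
#' @param tolerated_6 Character vector of residues tolerated at motif
#'   position 6 (default `c("L", "V")`).
#' @return An object of class `leader_motif`.
#' @examples
#' leader_motif()
#' @export
leader_motif <- function(tolerated_6 = c("L", "V")) {
  structure(list(
    length = 17L,
    anchors = c(`1` = "Y", `4` = "P", `10` = "G", `16` = "T"),
    tolerated = list(`6` = toupper(tolerated_6))
  ), class = "leader_motif")
}

#' @export
print.leader_motif <- function(x, ...) {
  tmpl <- rep("x", x$length)
  tmpl[as.integer(names(x$anchors))] <- x$anchors
  tmpl[6] <- paste0("[", paste(x$tolerated[["6"]], collapse = ""), "]")
  cat("leader motif:", paste(tmpl, collapse = ""), "\n")
  invisible(x)
}

#' Scan a precursor for leader-motif matches
#'
#' Slides the 17-position leader motif along the precursor and reports every
#' window in which all four anchor positions (Y1, P4, G10, T16) match. The
#' score counts matched positions among the anchors plus the tolerated
#' position 6, so a window with the canonical Leu/Val at position 6 scores 5
#' and one without scores 4.
#'
#' @param precursor Precursor residue string (or a list with a `sequence`
#'   element).
#' @param motif A [leader_motif].
#' @return data.frame with columns `start` (1-based window start), `window`
#'   (the 17-residue match) and `score`, ordered score-descending then
#'   leftmost-first. Zero rows when nothing matches.
#' @examples
#' scan_motif("MEHDEKTPYETPAVYGLGAFAEETGLYGVRNDEEINWHFDYWT")
#' @export
scan_motif <- function(precursor, motif = leader_motif()) {
  seq <- if (is.list(precursor)) precursor$sequence else precursor
  r <- .residue_vector(seq)
  L <- length(r)
  out <- data.frame(start = integer(), window = character(), score = integer())
  if (L < motif$length) return(out)
  anchor_pos <- as.integer(names(motif$anchors))
  for (s in seq_len(L - motif$length + 1L)) {
    win <- r[s:(s + motif$length - 1L)]
    if (!all(win[anchor_pos] == motif$anchors)) next
    score <- length(anchor_pos) + as.integer(win[6] %in% motif$tolerated[["6"]])
    out <- rbind(out, data.frame(start = s, window = paste(win, collapse = ""),
                                 score = score))
  }
  out[order(-out$score, out$start), , drop = FALSE]
}

#' Enumerate leader/core split candidates for a precursor
#'
#' Two complementary rules generate candidates:
#' \describe{
#'   \item{motif-cleavage}{cleave after position 17 of each leader-motif
#'     match (one residue past the conserved Thr), the rule consistent with
#'     experimentally confirmed cores;}
#'   \item{gly-start}{cleave before each Gly in the C-terminal half of the
#'     precursor, the classic assumption that mature cores start with Gly.}
#' }
#' Candidates are ranked motif-cleavage first, then by motif score, then by
#' compliance with the typical core-length window. Each candidate carries the
#' Asp/Glu ring-closure candidates at the configured core positions.
#'
#' @param precursor Precursor residue string.
#' @param ring_positions Core positions searched for a ring-closing Asp/Glu
#'   (default 7:9).
#' @param core_window Typical core length range, a soft constraint: violation
#'   demotes a candidate's rank but does not remove it (default `c(14, 24)`).
#' @param motif A [leader_motif].
#' @return data.frame with one row per candidate: `rank`, `leader`, `core`,
#'   `cleavage_site` (number of leader residues), `rule`, `motif_score`,
#'   `core_in_window`, and list-column `ring_candidates` (named integer
#'   vector, names = residue letters).
#' @examples
#' cands <- enumerate_core_candidates("MEHDEKTPYETPAVYGLGAFAEETGLYGVRNDEEINWHFDYWT")
#' cands$core[1]  # "LYGVRNDEEINWHFDYWT"
#' @export
enumerate_core_candidates <- function(precursor, ring_positions = 7:9,
                                      core_window = c(14L, 24L),
                                      motif = leader_motif()) {
  seq <- if (is.list(precursor)) precursor$sequence else precursor
  r <- .residue_vector(seq)
  L <- length(r)
  if (L < motif$length + 5L)
    stop(sprintf("precursor too short (%d aa); need at least %d",
                 L, motif$length + 5L), call. = FALSE)
  rows <- list()
  add <- function(cleave, rule, score) {
    if (cleave < 1L || cleave >= L) return()
    core <- r[(cleave + 1L):L]
    ring <- ring_positions[ring_positions <= length(core)]
    ring <- ring[core[ring] %in% c("D", "E")]
    ring <- stats::setNames(as.integer(ring), core[ring])
    rows[[length(rows) + 1L]] <<- list(
      leader = paste(r[1:cleave], collapse = ""),
      core = paste(core, collapse = ""),
      cleavage_site = cleave,
      rule = rule,
      motif_score = score,
      core_in_window = length(core) >= core_window[1] && length(core) <= core_window[2],
      ring_candidates = ring)
  }
  hits <- scan_motif(seq, motif)
  for (i in seq_len(nrow(hits)))
    add(hits$start[i] + motif$length - 1L, "motif-cleavage", hits$score[i])
  # Gly-start rule over the C-terminal half only
  gly <- which(r == "G")
  gly <- gly[gly > floor(L / 2) & gly > 1L]
  for (p in gly) add(p - 1L, "gly-start", 0L)
  if (!length(rows)) {
    return(data.frame(rank = integer(), leader = character(), core = character(),
                      cleavage_site = integer(), rule = character(),
                      motif_score = integer(), core_in_window = logical(),
                      ring_candidates = I(list())))
  }
  out <- data.frame(
    leader = vapply(rows, `[[`, "", "leader"),
    core = vapply(rows, `[[`, "", "core"),
    cleavage_site = vapply(rows, `[[`, 0L, "cleavage_site"),
    rule = vapply(rows, `[[`, "", "rule"),
    motif_score = vapply(rows, `[[`, 0L, "motif_score"),
    core_in_window = vapply(rows, `[[`, NA, "core_in_window"))
  out$ring_candidates <- I(lapply(rows, `[[`, "ring_candidates"))
  o <- order(out$rule != "motif-cleavage", -out$motif_score,
             !out$core_in_window, out$cleavage_site)
  out <- out[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Predict cyclized products for a core candidate
#'
#' For each candidate ring-closing Asp/Glu, builds the corresponding
#' [lasso_peptide] and computes its cyclized monoisotopic mass and singly and
#' doubly protonated m/z.
#'
#' @param candidate Either a single-row data.frame from
#'   [enumerate_core_candidates()] or a core residue string.
#' @param ring_positions Used when `candidate` is a bare string: core
#'   positions searched for Asp/Glu (default 7:9).
#' @return data.frame with columns `core`, `ring_pos`, `residue`,
#'   `cyclized_mass`, `mz_1`, `mz_2`, sorted by ring position. Zero rows (with
#'   a warning) when no candidate ring residue exists.
#' @examples
#' predict_products("GFGSKPLDSFGLNFF")  # ring at Asp8, 1613.7879 Da
#' @export
predict_products <- function(candidate, ring_positions = 7:9) {
  if (is.data.frame(candidate)) {
    stopifnot(nrow(candidate) == 1L)
    core <- candidate$core[[1]]
    ring <- candidate$ring_candidates[[1]]
  } else {
    core <- candidate
    r <- .residue_vector(core)
    ring <- ring_positions[ring_positions <= length(r)]
    ring <- ring[r[ring] %in% c("D", "E")]
    ring <- stats::setNames(as.integer(ring), r[ring])
  }
  if (!length(ring)) {
    warning(sprintf("no Asp/Glu ring candidate in core '%s'", core), call. = FALSE)
    return(data.frame(core = character(), ring_pos = integer(),
                      residue = character(), cyclized_mass = numeric(),
                      mz_1 = numeric(), mz_2 = numeric()))
  }
  ring <- sort(ring)
  m <- cyclized_mass(core)
  data.frame(core = core, ring_pos = as.integer(ring), residue = names(ring),
             cyclized_mass = m, mz_1 = mz(m, 1), mz_2 = mz(m, 2))
}
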