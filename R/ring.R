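#' Match observed peaks to theoretical ions
#'
#' Greedy nearest-first matching within the peak list's tolerance: candidate
#' (ion, peak) pairs are taken in order of increasing absolute mass error,
#' and each peak matches at most one ion and vice versa.
#'
#' @param table An `ion_table` from [linear_ion_table()] or
#'   [lasso_ion_table()].
#' @param peaks A [peak_list].
#' @param tolerance Optional override of the peak list's tolerance.
#' @return data.frame with one row per matched ion: `series`, `index`, `mz`
#'   (theoretical), `ring_corrected`, `observable`, `peak_mz`, `intensity`,
#'   `delta` (signed, observed minus theoretical). Zero rows when nothing
#'   matches.
#' @examples
#' tab <- lasso_ion_table("LYGVRNDEEINWHFDYWT", 8)
#' match_peaks(tab, peak_list(c(1058.4921, 1030.4958)))
#' @export
match_peaks <- function(table, peaks, tolerance = NULL) {
  stopifnot(inherits(table, "ion_table"), inherits(peaks, "peak_list"))
  tol <- if (is.null(tolerance)) peaks$tolerance else .parse_tolerance(tolerance)
  empty <- data.frame(series = character(), index = integer(), mz = numeric(),
                      ring_corrected = logical(), observable = logical(),
                      peak_mz = numeric(), intensity = numeric(), delta = numeric())
  if (!length(peaks$mz) || !nrow(table)) return(empty)
  tab <- as.data.frame(table)
  tol_da <- .tol_da(tol, tab$mz)
  cand <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    d <- peaks$mz - tab$mz[i]
    j <- which(abs(d) <= tol_da[i])
    if (!length(j)) return(NULL)
    data.frame(ion = i, peak = j, delta = d[j])
  }))
  if (is.null(cand)) return(empty)
  cand <- cand[order(abs(cand$delta), cand$ion), , drop = FALSE]
  used_ion <- logical(nrow(tab)); used_peak <- logical(length(peaks$mz))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_ion[cand$ion[i]] && !used_peak[cand$peak[i]]) {
      keep[i] <- TRUE
      used_ion[cand$ion[i]] <- TRUE
      used_peak[cand$peak[i]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- cbind(tab[cand$ion, c("series", "index", "mz", "ring_corrected", "observable")],
               peak_mz = peaks$mz[cand$peak],
               intensity = peaks$intensity[cand$peak],
               delta = cand$delta)
  out <- out[order(out$series, out$index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer the ring-closing residue from a fragmentation spectrum
#'
#' The macrolactam blocks fragmentation inside the ring, so the observable
#' ion series of a lasso peptide start abruptly: the first a/b ion appears at
#' index r + 1 and the largest y ion at index n - r. For each candidate ring
#' position r this function builds the lasso ion table, matches the peaks,
#' and scores the candidate as
#' (number of matched observable ions) - `penalty` x (number of matched
#' should-be-unobservable ions). A candidate is *consistent* when its first
#' matched a/b index equals r + 1 and its largest matched y index equals
#' n - r. The verdict is `"called"` only when exactly one candidate is
#' consistent and no other candidate strictly outscores it; ties and
#' conflicting evidence give `"ambiguous"`, and an empty match set gives
#' `"no-call"` - the scorer never guesses.
#'
#' @param core Core residue string.
#' @param peaks A [peak_list] of deconvoluted fragment masses.
#' @param candidates Candidate ring positions (default: Asp/Glu among core
#'   positions 7-9). All must carry Asp or Glu.
#' @param tolerance Optional override of the peak list's tolerance.
#' @param penalty Weight of matched should-be-unobservable ions (default 1).
#' @return An object of class `ring_call`: list with `verdict`
#'   (`"called"`/`"ambiguous"`/`"no-call"`), `ring_pos` (NA unless called),
#'   `core`, and an `evidence` data.frame with one row per candidate
#'   (`ring_pos`, `residue`, `matched_observable`, `matched_unobservable`,
#'   `first_ab_index`, `max_y_index`, `consistent`, `score`).
#' @examples
#' tab <- lasso_ion_table("LYGVRNDEEINWHFDYWT", 8)
#' pk <- peak_list(tab$mz[tab$observable])
#' infer_ring("LYGVRNDEEINWHFDYWT", pk)$ring_pos  # 8 (Glu8)
#' @export
infer_ring <- function(core, peaks, candidates = NULL, tolerance = NULL,
                       penalty = 1) {
  r <- .residue_vector(core)
  n <- length(r)
  if (is.null(candidates)) {
    candidates <- intersect(7:9, seq_len(n))
    candidates <- candidates[r[candidates] %in% c("D", "E")]
  }
  candidates <- as.integer(candidates)
  if (!length(candidates)) stop("no candidate ring positions", call. = FALSE)
  bad <- candidates[!r[candidates] %in% c("D", "E")]
  if (length(bad))
    stop(sprintf("candidate position %d is '%s', not Asp/Glu", bad[1], r[bad[1]]),
         call. = FALSE)
  ev <- do.call(rbind, lapply(sort(candidates), function(rp) {
    tab <- lasso_ion_table(core, rp)
    m <- match_peaks(tab, peaks, tolerance)
    ab <- m$series %in% c("a", "b")
    first_ab <- if (any(ab)) min(m$index[ab]) else NA_integer_
    max_y <- if (any(m$series == "y")) max(m$index[m$series == "y"]) else NA_integer_
    n_obs <- sum(m$observable)
    n_unobs <- sum(!m$observable)
    consistent <- !is.na(first_ab) && !is.na(max_y) &&
      first_ab == rp + 1L && max_y == n - rp
    data.frame(ring_pos = rp, residue = r[rp], matched_observable = n_obs,
               matched_unobservable = n_unobs, first_ab_index = first_ab,
               max_y_index = max_y, consistent = consistent,
               score = n_obs - penalty * n_unobs)
  }))
  verdict <- "ambiguous"; called <- NA_integer_
  if (sum(ev$matched_observable) + sum(ev$matched_unobservable) == 0) {
    verdict <- "no-call"
  } else {
    ok <- which(ev$consistent)
    if (length(ok) > 1L) {
      best <- ok[ev$score[ok] == max(ev$score[ok])]
      ok <- if (length(best) == 1L) best else integer()
    }
    if (length(ok) == 1L && !any(ev$score[-ok] > ev$score[ok])) {
      verdict <- "called"
      called <- ev$ring_pos[ok]
    }
  }
  structure(list(verdict = verdict, ring_pos = called, core = core, n = n,
                 evidence = ev),
            class = "ring_call")
}

#' @export
print.ring_call <- function(x, ...) {
  cat(sprintf("ring localization for core %s (n = %d)\n", x$core, x$n))
  if (x$verdict == "called") {
    res <- x$evidence$residue[x$evidence$ring_pos == x$ring_pos]
    cat(sprintf("  verdict: called %s%d\n", res, x$ring_pos))
  } else cat(sprintf("  verdict: %s\n", x$verdict))
  print.data.frame(x$evidence, row.names = FALSE)
  invisible(x)
}

#' Annotate a spectrum against a lasso ion table
#'
#' Produces the full expected-ion table for a given core and ring position
#' with detection flags, the observed m/z and signed error for each detected
#' ion, plus a coverage summary of the C-terminal tail and the list of
#' unmatched peaks.
#'
#' @param core Core residue string.
#' @param ring_pos Ring-closing position.
#' @param peaks A [peak_list].
#' @param tolerance Optional override of the peak list's tolerance.
#' @return A list of class `spectrum_annotation`: `table` (the ion table with
#'   `detected`, `peak_mz`, `delta` columns), `tail_sites_covered` /
#'   `tail_sites` (cleavage sites C-terminal of the ring with at least one
#'   detected ion, out of n - r), and `unmatched_peaks` (data.frame of peaks
#'   not assigned to any ion).
#' @export
annotate_spectrum <- function(core, ring_pos, peaks, tolerance = NULL) {
  tab <- lasso_ion_table(core, ring_pos)
  m <- match_peaks(tab, peaks, tolerance)
  out <- as.data.frame(tab)
  key <- paste(out$series, out$index)
  mk <- paste(m$series, m$index)
  hit <- match(key, mk)
  out$detected <- !is.na(hit)
  out$peak_mz <- m$peak_mz[hit]
  out$delta <- m$delta[hit]
  n <- nchar(core)
  # tail cleavage sites: between residues k and k+1 for k = r .. n-1; site k
  # is covered by a/b index k or y index n-k
  sites <- ring_pos:(n - 1L)
  covered <- vapply(sites, function(k) {
    any(out$detected & ((out$series %in% c("a", "b") & out$index == k) |
                          (out$series == "y" & out$index == n - k)))
  }, NA)
  unmatched <- setdiff(seq_along(peaks$mz), which(peaks$mz %in% m$peak_mz))
  structure(list(
    table = out,
    core = core, ring_pos = ring_pos,
    tail_sites_covered = sum(covered), tail_sites = length(sites),
    unmatched_peaks = data.frame(mz = peaks$mz[unmatched],
                                 intensity = peaks$intensity[unmatched])),
    class = "spectrum_annotation")
}

#' @export
print.spectrum_annotation <- function(x, ...) {
  cat(sprintf("spectrum annotation: core %s, ring %d\n", x$core, x$ring_pos))
  cat(sprintf("  tail coverage: %d/%d cleavage sites; %d detected ions; %d unmatched peaks\n",
              x$tail_sites_covered, x$tail_sites, sum(x$table$detected),
              nrow(x$unmatched_peaks)))
  invisible(x)
}
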