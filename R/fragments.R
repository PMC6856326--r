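.ion_table <- function(df, peptide, ring_pos = NA_integer_) {
  k <- mass_constants()
  structure(df, class = c("ion_table", "data.frame"),
            peptide = peptide, ring_pos = ring_pos,
            conventions = list(charge_carrier = k[["hydrogen"]],
                               water = k[["water"]], CO = k[["CO"]]))
}

#' Theoretical a/b/y ions for a linear peptide
#'
#' Singly charged fragment m/z under the hydrogen-atom charge-carrier
#' convention of the classic fragment-ion calculators:
#' \eqn{b_k = \sum_{1..k} + 1.007825}, \eqn{a_k = b_k - 27.994915},
#' \eqn{y_j = \sum_{n-j+1..n} + 18.010565 + 1.007825}.
#'
#' @param seq Residue string, length >= 2.
#' @return An `ion_table`: data.frame with columns `series` (a/b/y), `index`
#'   (1-based), `mz`, `ring_corrected` (all `FALSE`), `observable` (all
#'   `TRUE`); 3(n-1) rows for an n-residue peptide. The charge-carrier and
#'   water constants used are recorded in the `conventions` attribute.
#' @examples
#' linear_ion_table("GG")  # b1 = 58.029, y1 = 76.040
#' @export
linear_ion_table <- function(seq) {
  r <- .residue_vector(seq)
  n <- length(r)
  if (n < 2L) stop("need at least 2 residues", call. = FALSE)
  k <- mass_constants()
  rm <- .RESIDUE_MASSES[r]
  b <- cumsum(rm)[-n] + k[["hydrogen"]]
  a <- b - k[["CO"]]
  y <- cumsum(rev(rm))[-n] + k[["water"]] + k[["hydrogen"]]
  idx <- seq_len(n - 1L)
  df <- data.frame(
    series = rep(c("a", "b", "y"), each = n - 1L),
    index = rep(idx, 3L),
    mz = c(a, b, y),
    ring_corrected = FALSE,
    observable = TRUE)
  .ion_table(df, paste(r, collapse = ""))
}

#' Theoretical a/b/y ions for a lasso (macrolactam) peptide
#'
#' Starts from the linear table and applies the lasso topology for a ring
#' closed at position `r` of an n-residue core:
#' \itemize{
#'   \item a/b ions with index >= r contain the intact macrolactam, so one
#'     water (18.010565 Da) is subtracted and `ring_corrected` is set;
#'   \item backbone cleavages inside the ring cannot release a fragment, so
#'     a/b ions with index < r and y ions with index > n - r are flagged
#'     unobservable;
#'   \item a_r/b_r (the bare macrolactam with no tail residue) are also
#'     flagged unobservable by default, matching the observed absence of
#'     these species.
#' }
#' Unobservable ions are retained with their theoretical m/z: the ring
#' localization scorer uses them as negative evidence.
#'
#' @param p A [lasso_peptide], or a core residue string (then `ring_pos` is
#'   required).
#' @param ring_pos Ring position when `p` is a string.
#' @param bare_ring_observable If `TRUE`, treat a_r/b_r as observable.
#' @return An `ion_table` (see [linear_ion_table()]).
#' @examples
#' tab <- lasso_ion_table(lasso_peptide("LYGVRNDEEINWHFDYWT", 8))
#' subset(tab, series == "b" & index == 9)$mz  # 1058.491
#' @export
lasso_ion_table <- function(p, ring_pos = NULL, bare_ring_observable = FALSE) {
  if (!inherits(p, "lasso_peptide")) {
    if (is.null(ring_pos)) stop("'ring_pos' required when 'p' is a string", call. = FALSE)
    p <- lasso_peptide(p, ring_pos)
  }
  tab <- linear_ion_table(p$core)
  n <- nchar(p$core)
  r <- p$ring_pos
  ab <- tab$series %in% c("a", "b")
  corr <- ab & tab$index >= r
  tab$mz[corr] <- tab$mz[corr] - mass_constants()[["water"]]
  tab$ring_corrected <- corr
  tab$observable <- ifelse(ab, tab$index >= r + 1L, tab$index <= n - r)
  if (bare_ring_observable) tab$observable[ab & tab$index == r] <- TRUE
  .ion_table(as.data.frame(tab), p$core, r)
}

#' @export
print.ion_table <- function(x, ...) {
  pep <- attr(x, "peptide")
  r <- attr(x, "ring_pos")
  if (is.na(r)) cat(sprintf("ion table for linear peptide %s\n", pep))
  else cat(sprintf("ion table for lasso peptide %s, ring at %d\n", pep, r))
  print.data.frame(x, ...)
  invisible(x)
}
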