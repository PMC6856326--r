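.parse_tolerance <- function(tol) {
  if (is.list(tol) && all(c("value", "unit") %in% names(tol))) return(tol)
  if (is.numeric(tol)) {
    if (tol <= 0) stop("tolerance must be > 0", call. = FALSE)
    return(list(value = tol, unit = "da"))
  }
  if (is.character(tol)) {
    m <- regmatches(tol, regexec("^\\s*([0-9.eE+-]+)\\s*(da|ppm)\\s*$",
                                 tolower(tol)))[[1]]
    if (length(m) == 3L) {
      v <- as.numeric(m[2])
      if (!is.na(v) && v > 0) return(list(value = v, unit = m[3]))
    }
  }
  stop("tolerance must be a positive number (Da) or a string like '0.01da' or '5ppm'",
       call. = FALSE)
}

.tol_da <- function(tol, at_mz) {
  if (tol$unit == "ppm") tol$value * 1e-6 * at_mz else rep(tol$value, length(at_mz))
}

#' Construct a deconvoluted peak list
#'
#' Holds a deconvoluted MS/MS peak list (neutral singly-protonated m/z plus
#' intensity) together with its mass-tolerance contract. Peaks are sorted by
#' m/z on construction.
#'
#' @param mz Numeric vector of positive m/z values (deconvoluted,
#'   singly-protonated masses).
#' @param intensity Numeric intensities (default all 1).
#' @param tolerance Matching tolerance: a number (Da) or a string such as
#'   `"0.01da"` or `"5ppm"` (default `"0.01da"`).
#' @param source_id Optional identifier recorded as metadata.
#' @return An object of class `peak_list`.
#' @examples
#' peak_list(c(1058.4921, 1030.4958), tolerance = "0.01da")
#' @export
peak_list <- function(mz, intensity = rep(1, length(mz)), tolerance = "0.01da",
                      source_id = NA_character_) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(mz))
    stop("'intensity' must have the same length as 'mz'", call. = FALSE)
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("all m/z values must be positive and finite", call. = FALSE)
  o <- order(mz)
  structure(list(mz = mz[o], intensity = intensity[o],
                 tolerance = .parse_tolerance(tolerance), source_id = source_id),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("peak list: %d peaks, tolerance %g %s%s\n", length(x$mz),
              x$tolerance$value, x$tolerance$unit,
              if (is.na(x$source_id)) "" else paste0(" [", x$source_id, "]")))
  invisible(x)
}

#' Read a peak list from MGF or two-column text
#'
#' Accepts a standard MGF file (`BEGIN IONS`/`END IONS`; `PEPMASS` is parsed
#' but unused) or plain two-column whitespace/tab-separated text
#' (m/z, intensity; a missing second column defaults to intensity 1).
#' Input is expected to be deconvoluted to neutral singly-protonated masses:
#' an MGF block declaring a charge above 1 is rejected.
#'
#' @param path File path.
#' @param tolerance Tolerance contract for the resulting [peak_list].
#' @return A [peak_list] (for an MGF with several blocks, the first block; use
#'   `all_blocks = TRUE` for a list of all of them).
#' @param all_blocks Return every MGF block as a list of peak lists.
#' @export
read_peak_list <- function(path, tolerance = "0.01da", all_blocks = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (any(lines == "BEGIN IONS")) {
    starts <- which(lines == "BEGIN IONS")
    ends <- which(lines == "END IONS")
    if (length(starts) != length(ends) || any(ends < starts))
      stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
    blocks <- lapply(seq_along(starts), function(i) {
      body <- lines[(starts[i] + 1L):(ends[i] - 1L)]
      hdr <- body[grepl("=", body, fixed = TRUE)]
      ch <- hdr[startsWith(hdr, "CHARGE=")]
      if (length(ch)) {
        z <- suppressWarnings(as.integer(gsub("[^0-9]", "", ch[1])))
        if (!is.na(z) && z > 1L)
          stop("peak list declares charge ", z,
               "+: raw multiply-charged spectra are not supported; ",
               "deconvolute to singly-protonated masses first", call. = FALSE)
      }
      ttl <- hdr[startsWith(hdr, "TITLE=")]
      id <- if (length(ttl)) sub("^TITLE=", "", ttl[1]) else basename(path)
      body <- body[!grepl("=", body, fixed = TRUE)]
      fields <- strsplit(body, "[ \t]+")
      mzv <- vapply(fields, function(f) as.numeric(f[1]), 0)
      int <- vapply(fields, function(f)
        if (length(f) > 1L) as.numeric(f[2]) else 1, 0)
      peak_list(mzv, int, tolerance, source_id = id)
    })
    if (all_blocks) return(blocks)
    return(blocks[[1L]])
  }
  fields <- strsplit(lines, "[ \t]+")
  mzv <- vapply(fields, function(f) as.numeric(f[1]), 0)
  int <- vapply(fields, function(f) if (length(f) > 1L) as.numeric(f[2]) else 1, 0)
  peak_list(mzv, int, tolerance, source_id = basename(path))
}
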