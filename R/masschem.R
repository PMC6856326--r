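#' @useDynLib lassokit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
NULL

# Monoisotopic residue masses (Da) for the 20 standard amino acids, computed
# from elemental formulas with IUPAC monoisotopic atomic masses
# (H 1.0078250319, C 12, N 14.0030740052, O 15.9949146221, S 31.97207069).
.RESIDUE_MASSES <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic mass constants
#'
#' Constants used throughout the mass arithmetic, in Da:
#' `water` (H2O, lost upon macrolactam formation), `proton` (charge carrier
#' for precursor charge states), `hydrogen` (hydrogen atom; the fragment-ion
#' charge-carrier convention of the classic fragment-ion calculators), and
#' `CO` (carbonyl, the b-to-a ion difference).
#'
#' @return Named numeric vector of constants (Da).
#' @examples
#' mass_constants()["water"]
#' @export
mass_constants <- function() {
  c(water = 18.010565, proton = 1.007276, hydrogen = 1.007825, CO = 27.994915)
}

#' Monoisotopic residue mass table
#'
#' @return Named numeric vector mapping one-letter residue codes of the 20
#'   standard amino acids to their monoisotopic residue masses (Da).
#' @examples
#' residue_masses()["G"]  # glycine residue, 57.02146 Da
#' @export
residue_masses <- function() .RESIDUE_MASSES

# Split a peptide string into validated residue letters; errors name the
# offending character and its position.
.residue_vector <- function(seq) {
  if (length(seq) != 1L || !is.character(seq) || is.na(seq) || !nzchar(seq))
    stop("'seq' must be a single non-empty residue string", call. = FALSE)
  r <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!r %in% names(.RESIDUE_MASSES))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d of '%s'",
                 r[bad[1]], bad[1], seq), call. = FALSE)
  r
}

#' Monoisotopic mass of a linear peptide
#'
#' Sum of residue masses plus one water (the terminal H and OH).
#'
#' @param seq Residue string (one-letter codes, standard 20 amino acids).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' linear_peptide_mass("G")   # 75.03203
#' linear_peptide_mass("GG")  # 132.05349
#' @export
linear_peptide_mass <- function(seq) {
  r <- .residue_vector(seq)
  sum(.RESIDUE_MASSES[r]) + mass_constants()[["water"]]
}

#' Construct a lasso peptide
#'
#' A lasso peptide is a core sequence whose N-terminal amine is bonded to the
#' side-chain carboxylate of an Asp or Glu at `ring_pos`, closing the
#' macrolactam with loss of one water.
#'
#' @param core Core residue string of length n.
#' @param ring_pos 1-based position of the ring-closing Asp/Glu (2 <= r <= n).
#' @param provenance `"predicted"` or `"confirmed"`.
#' @return An object of class `lasso_peptide`.
#' @examples
#' lasso_peptide("LYGVRNDEEINWHFDYWT", 8)
#' @export
lasso_peptide <- function(core, ring_pos, provenance = c("predicted", "confirmed")) {
  provenance <- match.arg(provenance)
  r <- .residue_vector(core)
  n <- length(r)
  ring_pos <- as.integer(ring_pos)
  if (is.na(ring_pos) || ring_pos < 2L || ring_pos > n)
    stop("'ring_pos' must satisfy 2 <= ring_pos <= nchar(core)", call. = FALSE)
  if (!r[ring_pos] %in% c("D", "E"))
    stop(sprintf("residue at ring position %d is '%s'; must be Asp (D) or Glu (E)",
                 ring_pos, r[ring_pos]), call. = FALSE)
  structure(list(core = paste(r, collapse = ""), ring_pos = ring_pos,
                 provenance = provenance),
            class = "lasso_peptide")
}

#' @export
print.lasso_peptide <- function(x, ...) {
  cat(sprintf("lasso peptide (%s): %s\n", x$provenance, x$core))
  cat(sprintf("  macrolactam: N-terminal %s to side chain of %s%d\n",
              substr(x$core, 1, 1), substr(x$core, x$ring_pos, x$ring_pos),
              x$ring_pos))
  cat(sprintf("  cyclized monoisotopic mass: %.4f Da\n", cyclized_mass(x)))
  invisible(x)
}

#' Monoisotopic mass of a cyclized (macrolactam) peptide
#'
#' Ring closure between the N-terminal amine and an Asp/Glu side-chain
#' carboxylate releases one water, so the cyclized mass is the linear peptide
#' mass minus 18.010565 Da (equivalently the bare sum of residue masses). The
#' intact mass does not depend on which residue closes the ring.
#'
#' @param x A [lasso_peptide] or a core residue string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' cyclized_mass("GLLQRSGNDRLILSKN")    # 1764.9958
#' cyclized_mass("LYGVRNDEEINWHFDYWT")  # 2338.0443
#' @export
cyclized_mass <- function(x) {
  seq <- if (inherits(x, "lasso_peptide")) x$core else x
  linear_peptide_mass(seq) - mass_constants()[["water"]]
}

#' m/z of a protonated species
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param z Positive integer charge (number of protons).
#' @return m/z of \eqn{[M + zH]^{z+}}.
#' @examples
#' mz(2338.0440, 2)  # 1170.0293
#' @export
mz <- function(neutral_mass, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop("'z' must be a positive integer", call. = FALSE)
  (neutral_mass + z * mass_constants()[["proton"]]) / z
}

#' Neutral mass from an observed m/z
#'
#' Inverse of [mz()]; round-trips to well below 1e-9 Da.
#'
#' @param x Observed m/z.
#' @param z Positive integer charge.
#' @return Neutral monoisotopic mass (Da).
#' @examples
#' neutral_from_mz(1170.0293, 2)  # 2338.0440
#' @export
neutral_from_mz <- function(x, z) {
  z <- as.integer(z)
  if (any(is.na(z)) || any(z < 1L)) stop("'z' must be a positive integer", call. = FALSE)
  x * z - z * mass_constants()[["proton"]]
}
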