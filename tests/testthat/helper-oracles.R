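# Independent oracles used by the property and equivalence tests. These are
# deliberately naive (exhaustive recursion, union-find) and share no code
# with the package implementation.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive global alignment score between full sequences a and b under the
# affine model (gap run of length L costs go + L * ge): enumerates every
# monotone alignment path recursively, no DP.
oracle_global_score <- function(a, b, sub = blosum62, go = 10, ge = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[A[i], B[j]] + rec(i + 1L, j + 1L, "m"))
    if (i <= n)
      best <- max(best, -(ge + if (last != "u") go else 0) + rec(i + 1L, j, "u"))
    if (j <= m)
      best <- max(best, -(ge + if (last != "l") go else 0) + rec(i, j + 1L, "l"))
    best
  }
  rec(1L, 1L, "m")
}

# Brute-force local alignment score: best exhaustive global score over all
# non-empty substring pairs, floored at 0 (the empty alignment).
oracle_local_score <- function(a, b, sub = blosum62, go = 10, ge = 0.5) {
  n <- nchar(a); m <- nchar(b)
  best <- 0
  for (i1 in 1:n) for (i2 in i1:n) for (j1 in 1:m) for (j2 in j1:m) {
    s <- oracle_global_score(substr(a, i1, i2), substr(b, j1, j2), sub, go, ge)
    if (s > best) best <- s
  }
  best
}

# Union-find connected components over an edge list; returns the canonical
# component label (smallest member id) for every id.
oracle_components <- function(ids, edges_a, edges_b) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, "")
  label <- vapply(split(ids, roots), min, "")
  stats::setNames(unname(label[roots]), ids)
}

random_peptide <- function(n, alphabet = names(residue_masses()))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# The three precursor peptides of S. leeuwenhoekii C34
LP1_PRECURSOR <- "MKKAYEAPTLVRLGSFRRKTGLLQRSGNDRLILSKN"
LP2_PRECURSOR <- "MEHDEKTPYETPAVYGLGAFAEETGLYGVRNDEEINWHFDYWT"
LP3_PRECURSOR <- "MTELQPEAYEAPSLIEVGEFSEDTLGFGSKPLDSFGLNFF"
LEEPEPTIN_CORE <- "LYGVRNDEEINWHFDYWT"
CHAXAPEPTIN_CORE <- "GFGSKPLDSFGLNFF"
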