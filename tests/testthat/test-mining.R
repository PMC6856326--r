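test_that("local alignment is exact against exhaustive enumeration", {
  set.seed(101)
  aa <- names(residue_masses())
  for (i in 1:30) {
    a <- random_peptide(sample(2:6, 1), aa)
    b <- random_peptide(sample(2:6, 1), aa)
    expect_equal(smith_waterman(a, b)$score, oracle_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("local alignment basics: self-identity, symmetry, lower bound", {
  al <- smith_waterman("MKTAYIAKQR", "MKTAYIAKQR")
  expect_equal(al$percent_identity, 100)
  expect_equal(al$normalized_score, 1.0)
  set.seed(3)
  for (i in 1:10) {
    a <- random_peptide(8); b <- random_peptide(12)
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
  # at least the best single-residue match
  best_single <- max(outer(strsplit("ACDEFG", "")[[1]], strsplit("GFEDCA", "")[[1]],
                           Vectorize(function(x, y) blosum62[x, y])))
  expect_gte(smith_waterman("ACDEFG", "GFEDCA")$score, best_single)
  expect_error(smith_waterman("ACDO", "ACD"), "unknown residue 'O' at position 4")
})

test_that("local alignment agrees with Biostrings on positive-scoring pairs", {
  set.seed(202)
  refs <- read_reference_proteins()
  a <- substr(refs$sequence[1], 1, 120)
  b <- substr(refs$sequence[4], 1, 150)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62, gapOpening = 10, gapExtension = 0.5,
    type = "local")
  expect_equal(smith_waterman(a, b)$score, Biostrings::score(pa))
})

test_that("seed search labels hits by reference role and normalized score", {
  refs <- read_reference_proteins()
  cyclase <- refs$sequence[refs$role == "cyclase"]
  proteome <- data.frame(id = c("p1", "p2"),
                         sequence = c(cyclase, random_peptide(60)))
  hits <- find_seed_hits(proteome, refs)
  expect_equal(hits$id, "p1")
  expect_equal(hits$role, "cyclase")
  expect_equal(hits$normalized_score, 1.0, tolerance = 1e-9)
  # a heavily mutated cyclase still clears the default threshold
  set.seed(8)
  r <- strsplit(cyclase, "")[[1]]
  idx <- sample(seq_along(r), round(0.4 * length(r)))
  aa <- names(residue_masses())
  for (k in idx) r[k] <- sample(setdiff(aa, r[k]), 1)
  mut <- paste(r, collapse = "")
  hits2 <- find_seed_hits(data.frame(id = "mut", sequence = mut), refs)
  expect_equal(hits2$id, "mut")
  # unrelated short peptides yield nothing
  none <- find_seed_hits(data.frame(id = letters[1:3],
                                    sequence = replicate(3, random_peptide(20))),
                         refs)
  expect_equal(nrow(none), 0L)
})

test_that("cluster assembly recovers planted architectures", {
  lee <- gen_cluster_genome(simulation_spec(seed = 21))
  cl <- mine_genome(lee)
  expect_length(cl, 1L)
  cc <- cl[[1]]
  expect_true(cc$complete && cc$has_B && cc$has_C && cc$has_E)
  expect_equal(cc$transporter_count, 2L)
  expect_lte(cc$max_intergenic_gap, 1500L)
  # chaxapeptin-like architecture: no transporter genes at all
  cxp <- gen_cluster_genome(simulation_spec(seed = 22, layout = c("C", "E", "B", "A"),
                                            decoy_genes = 0))
  cl2 <- mine_genome(cxp)
  expect_length(cl2, 1L)
  expect_true(cl2[[1]]$complete)
  expect_equal(cl2[[1]]$transporter_count, 0L)
  expect_false(cl2[[1]]$substantial_gap)
})

test_that("cluster assembly is invariant to annotation row order and needs coordinates", {
  g <- gen_cluster_genome(simulation_spec(seed = 23))
  hit <- find_seed_hits(g$annotations)[1, ]
  cc1 <- assemble_cluster(hit, g$annotations)
  set.seed(1)
  cc2 <- assemble_cluster(hit, g$annotations[sample(nrow(g$annotations)), ])
  expect_identical(cc1$members, cc2$members)
  ann <- g$annotations
  ann$start[ann$id == hit$id] <- NA
  expect_error(assemble_cluster(hit, ann), "proteome-only")
  # a lone cyclase with no B/E in the window is incomplete
  lone <- data.frame(id = "c1", contig = "x", start = 1, end = 1800,
                     strand = "+", sequence = read_reference_proteins()$sequence[1])
  cc3 <- assemble_cluster(list(id = "c1"), lone)
  expect_false(cc3$complete)
  expect_equal(cc3$transporter_count, 0L)
})

test_that("precursor ORFs are recovered on either strand", {
  for (strand in c("+", "-")) {
    g <- gen_cluster_genome(simulation_spec(seed = 31, precursor_strand = strand))
    orfs <- find_precursor_orfs(g$dna[[1]], span = g$truth$cluster_span)
    hit <- orfs[orfs$protein == g$truth$precursor$sequence, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$strand, strand)
    expect_true(hit$motif_positive)
  }
})

test_that("ORF finding mirrors under reverse complement", {
  g <- gen_cluster_genome(simulation_spec(seed = 33))
  dna <- g$dna[[1]]
  L <- nchar(dna)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  f <- find_precursor_orfs(dna)
  r <- find_precursor_orfs(rc)
  expect_equal(nrow(f), nrow(r))
  mirrored <- data.frame(start = L - r$end + 1L, end = L - r$start + 1L,
                         strand = ifelse(r$strand == "+", "-", "+"),
                         protein = r$protein)
  key <- function(d) sort(paste(d$start, d$end, d$strand, d$protein))
  expect_identical(key(f), key(mirrored))
})

test_that("ORF finder validates input and handles empty spans", {
  expect_error(find_precursor_orfs("ACGTNACGT"), "non-ACGT")
  expect_equal(nrow(find_precursor_orfs(strrep("C", 400), margin = 0)), 0L)
})

test_that("mining a genome written as GFF3 + FASTA matches in-memory mining", {
  g <- gen_cluster_genome(simulation_spec(seed = 35))
  d <- tempfile()
  paths <- write_cluster_genome(g, d)
  back <- read_genome_annotation(paths["gff"], paths["fasta"])
  expect_identical(unname(back$dna), unname(g$dna))
  m <- match(g$annotations$id, back$annotations$id)
  expect_identical(back$annotations$sequence[m], g$annotations$sequence)
  cl <- mine_genome(paths[["gff"]], fasta = paths[["fasta"]])
  expect_length(cl, 1L)
  expect_true(cl[[1]]$complete)
  expect_true(g$truth$precursor$sequence %in% cl[[1]]$precursors$protein)
})
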