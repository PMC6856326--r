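test_that("generators are deterministic per seed and leave the RNG alone", {
  spec <- simulation_spec(seed = 12, noise_peaks = 5, dropout = 0.2)
  expect_identical(gen_precursor(spec), gen_precursor(spec))
  expect_identical(gen_spectrum("LYGVRNDEEINWHFDYWT", 8, spec),
                   gen_spectrum("LYGVRNDEEINWHFDYWT", 8, spec))
  expect_identical(gen_cluster_genome(spec), gen_cluster_genome(spec))
  set.seed(555); before <- stats::runif(1)
  set.seed(555); invisible(gen_precursor(spec)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("generated precursors are self-consistent with core prediction", {
  for (seed in 1:10) {
    truth <- gen_precursor(simulation_spec(seed = seed))
    cands <- enumerate_core_candidates(truth$sequence)
    expect_equal(cands$core[1], truth$core, info = paste("seed", seed))
    expect_equal(cands$leader[1], truth$leader)
    expect_true(truth$ring_pos %in% 7:9)
    ring_res <- substr(truth$core, truth$ring_pos, truth$ring_pos)
    expect_true(ring_res %in% c("D", "E"))
  }
})

test_that("template mode with zero mutation reproduces the template", {
  spec <- simulation_spec(seed = 1, precursor_template = LP2_PRECURSOR,
                          mutation_rate = 0)
  truth <- gen_precursor(spec)
  expect_identical(truth$sequence, LP2_PRECURSOR)
  expect_identical(truth$core, LEEPEPTIN_CORE)
})

test_that("random DNA hits its target GC content at scale", {
  dna <- random_dna(100000, gc_content = 0.72, seed = 6)
  gc <- sum(strsplit(dna, "")[[1]] %in% c("G", "C")) / nchar(dna)
  expect_gt(gc, 0.70)
  expect_lt(gc, 0.74)
})

test_that("a noiseless spectrum equals the observable table and round-trips", {
  spec <- simulation_spec(seed = 5, dropout = 0, noise_peaks = 0, jitter_sd = 0)
  sim <- gen_spectrum("LYGVRNDEEINWHFDYWT", 8, spec)
  tab <- lasso_ion_table("LYGVRNDEEINWHFDYWT", 8)
  expect_equal(sort(sim$peaks$mz), sort(tab$mz[tab$observable]), tolerance = 1e-9)
  expect_equal(infer_ring("LYGVRNDEEINWHFDYWT", sim$peaks)$ring_pos, 8L)
})

test_that("default jitter stays well inside the matching tolerance", {
  for (seed in 1:30) {
    sim <- gen_spectrum(LEEPEPTIN_CORE, 8,
                        simulation_spec(seed = seed, jitter_sd = 0.002))
    tab <- lasso_ion_table(LEEPEPTIN_CORE, 8)
    m <- match_peaks(tab, sim$peaks)
    expect_equal(nrow(m), sum(tab$observable), info = paste("seed", seed))
  }
})

test_that("removing the whole a/b series never yields a wrong call", {
  for (seed in 1:10) {
    spec <- simulation_spec(seed = seed, dropout = c(a = 1, b = 1, y = 0))
    truth <- gen_precursor(spec)
    sim <- gen_spectrum(truth$core, truth$ring_pos, spec)
    call <- infer_ring(truth$core, sim$peaks)
    expect_true(call$verdict %in% c("ambiguous", "no-call"))
  }
})

test_that("ring-internal ions are never emitted", {
  sim <- gen_spectrum(LEEPEPTIN_CORE, 8,
                      simulation_spec(seed = 3, noise_peaks = 0, jitter_sd = 0))
  tab <- lasso_ion_table(LEEPEPTIN_CORE, 8)
  unobservable <- tab$mz[!tab$observable]
  expect_false(any(sim$peaks$mz %in% unobservable))
})

test_that("a layout without a cyclase is rejected", {
  expect_error(gen_cluster_genome(simulation_spec(layout = c("E", "B", "A"))),
               "cyclase")
})

test_that("genome ground truth matches the annotation", {
  g <- gen_cluster_genome(simulation_spec(seed = 44))
  ann <- g$annotations
  expect_identical(sort(names(g$truth$roles)), sort(ann$id))
  # every annotated gene's protein is encoded at its coordinates
  for (i in seq_len(nrow(ann))) {
    nt <- substr(g$dna[[1]], ann$start[i], ann$end[i])
    if (ann$strand[i] == "-")
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(nt, 1, nchar(nt) - 3)), no.init.codon = TRUE))
    substr(prot, 1, 1) <- "M"
    expect_identical(prot, ann$sequence[i])
  }
  expect_equal(g$truth$transporter_count, 2L)
})
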