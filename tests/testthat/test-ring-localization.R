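leepeptin_observable_peaks <- function(tolerance = "0.01da") {
  tab <- lasso_ion_table(LEEPEPTIN_CORE, 8)
  peak_list(tab$mz[tab$observable], tolerance = tolerance)
}

test_that("peak matching reports signed deltas within tolerance", {
  tab <- lasso_ion_table(LEEPEPTIN_CORE, 8)
  pk <- peak_list(c(1058.4921, 1030.4958), tolerance = 0.01)
  m <- match_peaks(tab, pk)
  b9 <- m[m$series == "b" & m$index == 9, ]
  a9 <- m[m$series == "a" & m$index == 9, ]
  expect_equal(nrow(m), 2L)
  expect_equal(b9$delta, 1058.4921 - b9$mz, tolerance = 1e-9)
  expect_gt(b9$delta, 0)
  expect_lt(abs(b9$delta - 0.0011), 5e-4)
  expect_lt(abs(a9$delta), 5e-4)
  expect_equal(nrow(match_peaks(tab, peak_list(numeric(0) + 1))), 0L)
})

test_that("each peak matches at most one ion and vice versa", {
  tab <- lasso_ion_table(LEEPEPTIN_CORE, 8)
  # duplicate the same peak: only one can be assigned
  pk <- peak_list(c(1058.4910, 1058.4912), tolerance = 0.01)
  m <- match_peaks(tab, pk)
  expect_equal(sum(m$series == "b" & m$index == 9), 1L)
  expect_false(any(duplicated(paste(m$series, m$index))))
})

test_that("ring localization reproduces the Glu8 call for leepeptin", {
  call <- infer_ring(LEEPEPTIN_CORE, leepeptin_observable_peaks())
  expect_equal(call$verdict, "called")
  expect_equal(call$ring_pos, 8L)
  ev <- call$evidence
  expect_equal(ev$ring_pos, c(7L, 8L, 9L))
  expect_equal(ev$residue, c("D", "E", "E"))
  r8 <- ev[ev$ring_pos == 8, ]
  expect_equal(r8$first_ab_index, 9L)   # first a/b beyond the ring
  expect_equal(r8$max_y_index, 10L)     # 10 C-terminal residues covered
  expect_true(r8$consistent)
  expect_false(any(ev$consistent[ev$ring_pos != 8]))
})

test_that("no peaks gives no-call; candidates must be acidic", {
  call <- infer_ring(LEEPEPTIN_CORE, peak_list(1000, tolerance = 0.01))
  expect_equal(call$verdict, "no-call")
  expect_true(is.na(call$ring_pos))
  expect_error(infer_ring(LEEPEPTIN_CORE, peak_list(1000), candidates = c(3, 8)),
               "not Asp/Glu")
  expect_error(infer_ring(strrep("A", 15), peak_list(1000)), "no candidate")
})

test_that("a planted ring position round-trips through the ion table", {
  core <- "GVAARSEDAVLKWFNQ"  # Glu7 and Asp8 both candidates
  tab <- lasso_ion_table(core, 7)
  pk <- peak_list(tab$mz[tab$observable])
  call <- infer_ring(core, pk)
  expect_equal(call$verdict, "called")
  expect_equal(call$ring_pos, 7L)
})

test_that("the score ignores intensity scaling", {
  sim <- gen_spectrum(LEEPEPTIN_CORE, 8,
                      simulation_spec(seed = 4, dropout = 0.2, noise_peaks = 10))
  pk1 <- sim$peaks
  pk2 <- peak_list(pk1$mz, pk1$intensity * 1000, tolerance = "0.01da")
  e1 <- infer_ring(LEEPEPTIN_CORE, pk1)$evidence
  e2 <- infer_ring(LEEPEPTIN_CORE, pk2)$evidence
  expect_identical(e1$score, e2$score)
})

test_that("tightening the tolerance can only shrink the match set", {
  sim <- gen_spectrum(LEEPEPTIN_CORE, 8, simulation_spec(seed = 9, jitter_sd = 0.004))
  tab <- lasso_ion_table(LEEPEPTIN_CORE, 8)
  loose <- match_peaks(tab, sim$peaks, tolerance = 0.01)
  tight <- match_peaks(tab, sim$peaks, tolerance = 0.002)
  expect_lte(nrow(tight), nrow(loose))
  expect_true(all(paste(tight$series, tight$index) %in%
                    paste(loose$series, loose$index)))
})

test_that("dropout of non-diagnostic ions never produces a wrong call", {
  wrong <- 0L; called <- 0L
  for (seed in 1:40) {
    spec <- simulation_spec(seed = seed, dropout = 0.3)
    truth <- gen_precursor(spec)
    sim <- gen_spectrum(truth$core, truth$ring_pos, spec,
                        protect_diagnostic = TRUE)
    call <- infer_ring(truth$core, sim$peaks)
    if (call$verdict == "called") {
      called <- called + 1L
      if (call$ring_pos != truth$ring_pos) wrong <- wrong + 1L
    }
  }
  expect_equal(wrong, 0L)
  expect_equal(called, 40L)  # diagnostics survive, so every case is called
})

test_that("spectrum annotation reports tail coverage and unmatched peaks", {
  ann <- annotate_spectrum(LEEPEPTIN_CORE, 8, leepeptin_observable_peaks())
  expect_equal(ann$tail_sites_covered, 10L)
  expect_equal(ann$tail_sites, 10L)
  expect_equal(nrow(ann$unmatched_peaks), 0L)
  none <- annotate_spectrum(LEEPEPTIN_CORE, 8, peak_list(5000))
  expect_false(any(none$table$detected))
  sim <- gen_spectrum(LEEPEPTIN_CORE, 8,
                      simulation_spec(seed = 2, noise_peaks = 8,
                                      noise_range = c(2500, 3000)))
  noisy <- annotate_spectrum(LEEPEPTIN_CORE, 8, sim$peaks)
  expect_equal(nrow(noisy$unmatched_peaks), 8L)
})

test_that("peak lists validate, sort, and parse tolerances", {
  pk <- peak_list(c(300, 100, 200), c(1, 2, 3), tolerance = "5ppm")
  expect_equal(pk$mz, c(100, 200, 300))
  expect_equal(pk$intensity, c(2, 3, 1))
  expect_equal(pk$tolerance$unit, "ppm")
  expect_error(peak_list(c(-1, 10)), "positive")
  expect_error(peak_list(10, tolerance = "fast"), "tolerance")
})

test_that("MGF round-trips and multiply-charged input is rejected", {
  sim <- gen_spectrum(LEEPEPTIN_CORE, 8, simulation_spec(seed = 1, noise_peaks = 3))
  f <- tempfile(fileext = ".mgf")
  write_mgf(sim$peaks, f)
  back <- read_peak_list(f)
  expect_equal(back$mz, sim$peaks$mz, tolerance = 1e-5)
  expect_equal(back$intensity, sim$peaks$intensity, tolerance = 1e-3)
  f2 <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=raw", "CHARGE=2+", "500.1 10", "END IONS"), f2)
  expect_error(read_peak_list(f2), "deconvolute")
  # plain two-column text
  f3 <- tempfile(fileext = ".txt")
  writeLines(c("100.5\t10", "200.25 20"), f3)
  pk <- read_peak_list(f3)
  expect_equal(pk$mz, c(100.5, 200.25))
})
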