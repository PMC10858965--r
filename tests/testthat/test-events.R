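test_that("noiseless single steps are recovered exactly", {
  x <- c(rep(0, 40), rep(8, 40))
  bp <- detect_change_points(x)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$index, 40)
  expect_equal(bp$amplitude, 8)
  expect_equal(bp$sign, 1)
  # flat trace: no breakpoints
  expect_equal(nrow(detect_change_points(rep(3, 100))), 0)
  # all-masked stream gives an empty result
  expect_equal(nrow(detect_change_points(rep(NA_real_, 50))), 0)
})

test_that("a close step pair at SNR 5 matches the exhaustive two-break oracle", {
  set.seed(100)
  ok <- vapply(1:40, function(i) {
    x <- c(rnorm(120, 0, 1), rnorm(10, 5, 1), rnorm(120, 0, 1))
    bp <- detect_change_points(x)
    oracle <- brute_force_two_breaks(x)
    nrow(bp) == 2 && all(abs(bp$index - oracle) <= 1)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("null false-positive rate stays at or below 5 percent per trace", {
  set.seed(42)
  fp <- vapply(1:100, function(i) {
    nrow(detect_change_points(rnorm(1000, 50, 10))) > 0
  }, logical(1))
  expect_lte(mean(fp), 0.05)
})

test_that("segmentation is idempotent on its own reconstruction", {
  set.seed(7)
  x <- c(rnorm(60, 0, 1), rnorm(40, 6, 1), rnorm(80, 2, 1))
  bp <- detect_change_points(x)
  # rebuild the piecewise-constant fit and re-detect
  bounds <- c(0, bp$index, length(x))
  recon <- unlist(lapply(seq_len(length(bounds) - 1), function(j) {
    seg <- x[(bounds[j] + 1):bounds[j + 1]]
    rep(mean(seg), length(seg))
  }))
  bp2 <- detect_change_points(recon)
  expect_equal(bp2$index, bp$index)
})

test_that("synapsis detection fires on high-FRET steps only", {
  e <- c(rep(0.05, 30), rep(0.6, 30))
  tm <- seq_along(e)
  syn <- detect_synapsis(e, time = tm)
  expect_equal(nrow(syn), 1)
  expect_equal(syn$start_time, 31)
  expect_gt(syn$mean_e35_post, 0.3)
  # constant low trace: nothing
  expect_equal(nrow(detect_synapsis(rep(0.05, 60), time = tm)), 0)
  # a step that stays below the high-FRET threshold is not synapsis
  expect_equal(nrow(detect_synapsis(c(rep(0.02, 30), rep(0.2, 30)), time = tm)), 0)
})

test_that("colocalization rules: two-frame minimum and two-frame gap merge", {
  tm <- seq_len(40)
  base <- rep(0, 40)
  # single 1-frame spike: no event
  x <- base; x[10] <- 100
  expect_equal(nrow(detect_colocalization(x, tm, intensity_threshold = 50)), 0)
  # two 5-frame runs separated by one below-threshold frame: merged, 11 frames
  x <- base; x[c(10:14, 16:20)] <- 100
  ev <- detect_colocalization(x, tm, intensity_threshold = 50)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_frames, 11)
  # two runs separated by two frames stay separate events
  x <- base; x[c(10:14, 17:21)] <- 100
  expect_equal(nrow(detect_colocalization(x, tm, intensity_threshold = 50)), 2)
  # one clean 10-frame run
  x <- base; x[11:20] <- 100
  ev <- detect_colocalization(x, tm, intensity_threshold = 50,
                              fret = rep(0.4, 40))
  expect_equal(ev$n_frames, 10)
  expect_equal(ev$mean_fret, 0.4)
  expect_error(detect_colocalization(x, tm, intensity_threshold = 0), "threshold")
})

test_that("raising the colocalization threshold never adds events", {
  set.seed(11)
  x <- pmax(rnorm(500, 20, 15), 0)
  x[sample(500, 60)] <- x[sample(500, 60)] + 120
  counts <- vapply(c(30, 60, 90, 120, 150), function(th) {
    nrow(detect_colocalization(x, intensity_threshold = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("DNA spots qualify by the two-step photobleach intensity rule", {
  two_step <- c(rep(200, 50), rep(100, 50), rep(0, 50))
  one_unit <- rep(100, 150)
  res <- qualify_dna_spot(list(two_step, one_unit, rep(0, 150)))
  expect_equal(res$single_step, 100)
  expect_equal(res$qualified, c(TRUE, FALSE, FALSE))
  # no steps anywhere: qualification disabled with a warning
  expect_warning(res2 <- qualify_dna_spot(list(rep(5, 100))), "disabled")
  expect_true(all(res2$qualified))
})

test_that("stoichiometry is the stream normalized by the mean step size", {
  tm <- seq_len(60)
  x <- c(rep(0, 20), rep(100, 40))
  s <- estimate_stoichiometry(x, tm)
  expect_true(s$defined)
  expect_equal(s$normalization_step, 100)
  expect_equal(unique(s$stoichiometry[30:60]), 1)
  # two successive up-steps of equal size: plateaus at 1 then 2
  x2 <- c(rep(0, 20), rep(100, 20), rep(200, 20))
  s2 <- estimate_stoichiometry(x2, tm)
  expect_equal(s2$stoichiometry[c(30, 50)], c(1, 2))
  # steps A and 1.5A: normalization 1.25A, plateaus 0.8 and 2
  x3 <- c(rep(0, 20), rep(100, 20), rep(250, 20))
  s3 <- estimate_stoichiometry(x3, tm)
  expect_equal(s3$normalization_step, 125)
  expect_equal(s3$stoichiometry[c(30, 50)], c(0.8, 2))
  # flat stream: undefined, excluded from statistics
  s4 <- estimate_stoichiometry(rep(0, 60), tm)
  expect_false(s4$defined)
})

test_that("colocalization boundaries match truth to one frame at zero noise", {
  sch <- scheme_two_color_binding(60)
  ph <- clean_photophysics()
  lg <- rbind(ligase_row(1L, "end", 1L, 10, 20),
              ligase_row(2L, "hover", NA_integer_, 30.05, 40.05))
  truth <- make_truth_set(make_truth(lg, duration = 60), scheme = sch)
  ts <- render_trajectories(truth, ph, sch, seed = 1, assay = "two_color_binding")
  st <- demultiplex(ts$molecules[[1]], sch)
  corr <- correct_intensities(st, ph$crosstalk)
  ev <- detect_colocalization(corr$values[, "I5"], st$times[, "I5"],
                              intensity_threshold = 50)
  expect_equal(nrow(ev), 2)
  period <- st$period
  expect_lte(abs(ev$start_time[1] - 10), period)
  expect_lte(abs(ev$end_time[1] - 20), period)
  expect_lte(abs(ev$start_time[2] - 30.05), period)
  expect_lte(abs(ev$end_time[2] - 40.05), period)
})
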