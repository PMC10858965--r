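test_that("demultiplexing maps cycle positions to labeled streams", {
  sch <- scheme_two_color_sr(120)      # 2 frame/s alternating, 120 s
  raw <- matrix(1, sch$n_frames, 6, dimnames = list(NULL, c("I3", "I35", "I37", "I5", "I57", "I7")))
  st <- demultiplex(raw, sch)
  expect_equal(nrow(st$values), 120)
  expect_equal(st$period, 1)
  expect_setequal(colnames(st$values), c("I3", "I35", "I5"))

  sch3 <- scheme_three_color(60)       # 5 frame/s, 5-frame cycle
  raw3 <- matrix(1, sch3$n_frames, 6, dimnames = dimnames(raw))
  st3 <- demultiplex(raw3, sch3)
  expect_equal(nrow(st3$values), 60)   # each channel once per second
  expect_equal(ncol(st3$values), 6)

  # a single full cycle gives one sample per channel without error
  st1 <- demultiplex(raw3[1:5, , drop = FALSE], sch3)
  expect_equal(nrow(st1$values), 1)

  # trailing partial cycle dropped with a warning
  expect_warning(demultiplex(raw3[1:7, , drop = FALSE], sch3), "partial cycle")
})

test_that("FRET efficiency formulas satisfy their arithmetic identities", {
  expect_equal(fret_two_color(100, 100), 0.5)
  expect_equal(fret_two_color(100, 0), 0)
  expect_equal(fret_two_color(300, 100), 0.25)
  expect_true(is.na(fret_two_color(0, 0)))

  ef <- fret_three_color(1, 1, 1, 1, 1)
  expect_equal(unlist(ef), c(E35 = 1/3, E37 = 1/3, E57 = 1/2))
  ef2 <- fret_three_color(200, 100, 0, 300, 100)
  expect_equal(ef2$E37, 0)
  expect_equal(ef2$E35, fret_two_color(200, 100))
  ef3 <- fret_three_color(200, 100, 100, 300, 100)
  expect_equal(unlist(ef3), c(E35 = 0.25, E37 = 0.25, E57 = 0.25))
  # E35 + E37 <= 1 for non-negative inputs
  set.seed(1)
  x <- matrix(runif(500, 0, 100), ncol = 5)
  ef4 <- fret_three_color(x[, 1], x[, 2], x[, 3], x[, 4], x[, 5])
  expect_true(all(ef4$E35 + ef4$E37 <= 1 + 1e-12))
})

test_that("identity correction parameters leave streams unchanged", {
  sch <- scheme_three_color(20)
  raw <- matrix(rnorm(sch$n_frames * 6, 100, 5), sch$n_frames, 6,
                dimnames = list(NULL, c("I3", "I35", "I37", "I5", "I57", "I7")))
  st <- demultiplex(raw, sch)
  ident <- crosstalk_params(beta = c(b35 = 0, b37 = 0, b57 = 0),
                            delta = c(d35 = 0, d37 = 0, d57 = 0))
  corr <- correct_intensities(st, ident)
  expect_equal(corr$values, st$values)
  expect_error(correct_intensities(st, list(matrix = matrix(0, 6, 6),
                                            gamma = c(g3 = 1, g5 = 1))),
               "singular")
})

test_that("corrections exactly invert the rendering crosstalk at zero noise", {
  sch <- scheme_three_color(20)
  ct <- crosstalk_params(beta = c(b35 = 0.12, b37 = 0.05, b57 = 0.09),
                         delta = c(d35 = 0.06, d37 = 0.03, d57 = 0.05),
                         gamma = c(g3 = 1.3, g5 = 0.8))
  ph <- clean_photophysics(crosstalk = ct)
  # events aligned to cycle boundaries so every cycle is state-constant
  lg <- rbind(ligase_row(1L, "end", 1L, 3, 9),
              ligase_row(2L, "end", 2L, 5, 12),
              ligase_row(3L, "hover", NA_integer_, 14, 17))
  truth <- make_truth_set(make_truth(lg, duration = 20), scheme = sch)
  ts <- render_trajectories(truth, ph, sch, seed = 1)
  st <- demultiplex(ts$molecules[[1]], sch)
  corr <- correct_intensities(st, ct)
  lv <- ph$fret_levels
  # cycle 1 (t in [0,1)): bare DNA
  expect_equal(unname(corr$values[1, c("I3", "I35", "I5", "I7")]),
               c(100 * (1 - lv[["e35_baseline"]]), 100 * lv[["e35_baseline"]], 100, 0))
  # cycle 4 (t in [3,4)): ligase on the Cy3B end
  expect_equal(unname(corr$values[4, "I37"]), 100 * lv[["e37_bound"]])
  expect_equal(unname(corr$values[4, "I7"]), 100)
  # cycle 6: both ends engaged, two ligases
  expect_equal(unname(corr$values[6, "I57"]), 100 * lv[["e57_bound"]])
  expect_equal(unname(corr$values[6, "I7"]), 200)
  # cycle 15: hover only: Cy7 present, no FRET
  expect_equal(unname(corr$values[15, c("I37", "I57", "I7")]),
               c(0, 0, 100))
  # matrix-route correction agrees with the coefficient route
  corr2 <- correct_intensities(st, list(matrix = crosstalk_matrix(ct),
                                        gamma = ct$gamma))
  expect_equal(corr2$values, corr$values, tolerance = 1e-10)
})

test_that("efficiencies are invariant under common intensity rescaling", {
  sch <- scheme_three_color(20)
  ph <- clean_photophysics()
  lg <- ligase_row(1L, "end", 1L, 3, 9)
  truth <- make_truth_set(make_truth(lg, duration = 20), scheme = sch)
  ts <- render_trajectories(truth, ph, sch, seed = 1)
  st <- demultiplex(ts$molecules[[1]], sch)
  c1 <- correct_intensities(st, ph$crosstalk)
  st2 <- st
  st2$values <- st$values * 7.5
  c2 <- correct_intensities(st2, ph$crosstalk)
  expect_equal(c2$efficiencies$E35, c1$efficiencies$E35, tolerance = 1e-12)
  expect_equal(c2$efficiencies$E37, c1$efficiencies$E37, tolerance = 1e-12)
  expect_equal(c2$values, c1$values * 7.5, tolerance = 1e-12)
})

test_that("donor-only molecules show no corrected acceptor signal", {
  sch <- scheme_two_color_sr(30)
  ph <- photophysics_model(noise_sd = 4, labeling_efficiency = 1,
                           bleach_rates = c(cy3b = 0, cy5 = 0, cy7 = 0),
                           fret_levels = c(e35_baseline = 0, e35_synapsed = 0.7,
                                           e37_bound = 0.45, e57_bound = 0.45,
                                           e35_ligase = 0.45))
  truth <- make_truth_set(make_truth(no_ligases(), duration = 30), scheme = sch)
  ts <- render_trajectories(truth, ph, sch, seed = 2, assay = "two_color_sr")
  st <- demultiplex(ts$molecules[[1]], sch)
  corr <- correct_intensities(st, ph$crosstalk)
  # with no transfer, corrected I35 is pure noise around zero
  expect_lt(abs(mean(corr$values[, "I35"])), 3 * 4 / sqrt(nrow(corr$values)))
})

test_that("bleach masks invalidate efficiencies after the bleach time", {
  sch <- scheme_three_color(20)
  ph <- clean_photophysics()
  truth <- make_truth_set(make_truth(no_ligases(), duration = 20), scheme = sch)
  ts <- render_trajectories(truth, ph, sch, seed = 1)
  st <- demultiplex(ts$molecules[[1]], sch)
  gt <- ts$truth[[1]]
  gt$bleach_cy3b <- 10
  masks <- masks_from_truth(gt, st)
  corr <- correct_intensities(st, ph$crosstalk, masks = masks)
  expect_true(all(is.na(corr$efficiencies$E35[11:20])))
  expect_true(all(is.finite(corr$efficiencies$E35[1:9])))
})

test_that("crosstalk coefficients are recoverable from control molecules", {
  sch <- scheme_three_color(60)
  ct <- crosstalk_params(beta = c(b35 = 0.10, b37 = 0.04, b57 = 0.08),
                         delta = c(d35 = 0.05, d37 = 0.02, d57 = 0.04))
  ph <- photophysics_model(noise_sd = 2, labeling_efficiency = 1,
                           bleach_rates = c(cy3b = 0, cy5 = 0, cy7 = 0),
                           crosstalk = ct,
                           fret_levels = c(e35_baseline = 0, e35_synapsed = 0,
                                           e37_bound = 0, e57_bound = 0,
                                           e35_ligase = 0))
  # donor-only control: substrate Cy3B only (no Cy5, no ligases)
  ph_d <- ph; ph_d$acceptor_budget <- 0
  truth <- make_truth_set(make_truth(no_ligases(), duration = 60), scheme = sch)
  ts <- render_trajectories(truth, ph_d, sch, seed = 3)
  donor <- demultiplex(ts$molecules[[1]], sch)
  # acceptor-only control: hovering labeled ligases, dark substrate
  ph2 <- ph; ph2$donor_budget <- 0; ph2$acceptor_budget <- 0
  lg <- ligase_row(1L, "hover", NA_integer_, 0, 60)
  truth2 <- make_truth_set(make_truth(lg, duration = 60), scheme = sch)
  ts2 <- render_trajectories(truth2, ph2, sch, seed = 4)
  acceptor <- demultiplex(ts2$molecules[[1]], sch)
  est <- estimate_crosstalk(donor, acceptor)
  expect_equal(unname(est$beta[c("b35", "b37")]), c(0.10, 0.04), tolerance = 0.05)
  expect_equal(unname(est$delta[c("d37", "d57")]), c(0.02, 0.04), tolerance = 0.05)
})
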