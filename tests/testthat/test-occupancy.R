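fake_corrected <- function(E35, E37, E57) {
  list(efficiencies = list(E35 = E35, E37 = E37, E57 = E57))
}

test_that("end-occupancy classification follows the FRET threshold rule", {
  ct <- fake_corrected(E35 = rep(0.05, 3),
                       E37 = c(0.3, 0.0, 0.3),
                       E57 = c(0.0, 0.3, 0.3))
  s <- classify_end_occupancy(list(ct))
  expect_equal(unname(s$fractions), c(0, 200 / 3, 100 / 3))
  expect_equal(sum(s$fractions), 100)
  # all-zero FRET frames: 100% neither
  s0 <- classify_end_occupancy(list(fake_corrected(rep(0, 5), rep(0, 5), rep(0, 5))))
  expect_equal(unname(s0$fractions["neither"]), 100)
  # frames at or above the synapsis mask are excluded
  s1 <- classify_end_occupancy(list(fake_corrected(c(0.05, 0.5), c(0.3, 0.3), c(0, 0))))
  expect_equal(s1$n_frames, 1)
  expect_warning(classify_end_occupancy(list(fake_corrected(0.5, 0.3, 0.3))),
                 "no qualifying frames")
})

test_that("high-FRET colocalization fraction counts events above threshold", {
  ev <- data.frame(mean_fret = c(0, 0.05, 0.2, 0.3, NA))
  f <- colocalization_fret_fraction(ev, 0.1)
  expect_equal(f$percent, 50)
  expect_equal(f$n_events, 4)
  # zero-FRET events give 0%
  expect_equal(colocalization_fret_fraction(data.frame(mean_fret = rep(0, 10)))$percent, 0)
  # threshold above the maximum possible efficiency gives 0%
  expect_equal(colocalization_fret_fraction(ev, 1.5)$percent, 0)
  expect_error(colocalization_fret_fraction(data.frame(mean_fret = NA_real_)),
               "no annotated")
})

stoich_trace <- function(values, period = 1) {
  structure(list(defined = TRUE, stoichiometry = values,
                 time = seq_along(values) * period - period / 2,
                 normalization_step = 1,
                 steps = data.frame(index = 1)), class = "stoichiometry_trace")
}

test_that("alignment re-indexes traces to time-to-synapsis", {
  tr <- stoich_trace(rep(1, 60))
  al <- align_at_synapsis(list(tr), synapsis_times = 30.5, window = c(-10, 5))
  expect_true(all(al$median[al$n > 0] == 1))
  expect_equal(al$n_events, 1)
  # a programmed 2 -> 1 drop at synapsis appears at t = 0
  drop2 <- stoich_trace(c(rep(2, 30), rep(1, 30)))
  al2 <- align_at_synapsis(list(drop2, drop2, drop2), rep(30.5, 3),
                           window = c(-10, 5))
  expect_equal(alignment_window_median(al2, c(-8, -2)), 2)
  expect_equal(alignment_window_median(al2, c(0, 0)), 1)
  expect_equal(alignment_window_median(al2, c(2, 5)), 1)
  # undefined traces and missing synapses are excluded
  undef <- structure(list(defined = FALSE), class = "stoichiometry_trace")
  al3 <- align_at_synapsis(list(drop2, undef), c(30.5, NA), window = c(-5, 5))
  expect_equal(al3$n_events, 1)
  # bins beyond the record are reported with n = 0
  al4 <- align_at_synapsis(list(stoich_trace(rep(1, 20))), 10.5,
                           window = c(-40, 5))
  expect_true(any(al4$n == 0))
  expect_true(all(is.na(al4$median[al4$n == 0])))
})

test_that("presence conditioning excludes Cy7-absent bins from the median", {
  # two molecules: one with a ligase (stoich 2), one empty (stoich 0)
  al <- align_at_synapsis(list(stoich_trace(rep(2, 40)), stoich_trace(rep(0, 40))),
                          c(20.5, 20.5), window = c(-5, 5))
  expect_equal(alignment_window_median(al, c(-5, -1)), 2)
  al_all <- align_at_synapsis(list(stoich_trace(rep(2, 40)), stoich_trace(rep(0, 40))),
                              c(20.5, 20.5), window = c(-5, 5),
                              presence_threshold = -Inf)
  expect_equal(alignment_window_median(al_all, c(-5, -1)), 1)
})

test_that("dissociation-before-synapsis counts down-steps in the window", {
  expect_equal(dissociation_before_synapsis(list(numeric(0), numeric(0)),
                                            c(50, 80))$percent, 0)
  d <- dissociation_before_synapsis(list(45), 50)  # 5 s before the synapsis
  expect_equal(d$percent, 100)
  # a step outside the window does not count
  expect_equal(dissociation_before_synapsis(list(35), 50)$percent, 0)
  # the window is (t - 10, t]: a step at the synapsis instant counts
  expect_equal(dissociation_before_synapsis(list(50), 50)$percent, 100)
  expect_equal(dissociation_before_synapsis(list(40), 50)$percent, 0)
  expect_error(dissociation_before_synapsis(list(), numeric(0)), "no synapsis")
})
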