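test_that("noiseless isotherm points are recovered to machine precision", {
  conc <- 2^(0:11) * 1.25e-9
  curve <- simulate_filter_binding(10e-9, conc, noise_sd = 0, replicates = 1)
  fit <- fit_isotherm(curve, fix_bmax = TRUE, n_boot = 20)
  expect_equal(fit$kd, 10e-9, tolerance = 1e-6)
  fit2 <- fit_isotherm(curve, n_boot = 20)
  expect_equal(fit2$kd, 10e-9, tolerance = 1e-4)
  expect_equal(fit2$bmax, 1, tolerance = 1e-4)
})

test_that("noisy dose series round-trip the generating Kd within 10 percent", {
  conc <- 2^(0:11) * (10e-9 / 8)
  curve <- simulate_filter_binding(10e-9, conc, noise_sd = 0.02,
                                   replicates = 3, seed = 5)
  fit <- fit_isotherm(curve, seed = 5)
  expect_lt(abs(fit$kd - 10e-9) / 10e-9, 0.10)
  expect_true(fit$kd_ci95[1] < fit$kd & fit$kd < fit$kd_ci95[2])
})

test_that("curves without a measurable transition are flagged unreliable", {
  conc <- 2^(0:6) * 1e-9
  flat <- data.frame(concentration = conc, replicate = 1,
                     fraction_bound = rep(0, 7))
  fit <- fit_isotherm(flat)
  expect_false(fit$reliable)
  expect_true(is.na(fit$kd))
  expect_error(fold_change(fit, fit), "unreliable")
  expect_error(fit_isotherm(data.frame(concentration = c(1, 2) * 1e-9,
                                       fraction_bound = c(0.2, 0.4))),
               "at least 5")
})

test_that("Kd fold-changes recover simulated affinity ratios", {
  conc <- 2^(0:11) * 2.5e-9
  wt <- fit_isotherm(simulate_filter_binding(20e-9, conc, 0.02, 3, seed = 1), seed = 1)
  self <- fold_change(wt, wt)
  expect_equal(self$ratio, 1)
  mut10 <- fit_isotherm(simulate_filter_binding(200e-9, conc, 0.02, 3, seed = 2), seed = 2)
  fc10 <- fold_change(mut10, wt)
  expect_lt(abs(fc10$ratio - 10) / 10, 0.2)
  expect_true(fc10$ci95[1] <= 10 & 10 <= fc10$ci95[2])
  mut30 <- fit_isotherm(simulate_filter_binding(600e-9, conc, 0.02, 3, seed = 3), seed = 3)
  fc30 <- fold_change(mut30, wt)
  expect_lt(abs(fc30$ratio - 30) / 30, 0.2)
  expect_true(fc30$ci95[1] <= 30 & 30 <= fc30$ci95[2])
})

test_that("isotherm fitting is scale-equivariant in concentration units", {
  conc <- 2^(0:11) * 1.25e-9
  curve <- simulate_filter_binding(10e-9, conc, noise_sd = 0.01,
                                   replicates = 2, seed = 9)
  fit_M <- fit_isotherm(curve, n_boot = 20, seed = 1)
  curve_nM <- curve
  curve_nM$concentration <- curve$concentration * 1e9
  fit_nM <- fit_isotherm(curve_nM, n_boot = 20, seed = 1)
  expect_equal(fit_nM$kd, fit_M$kd * 1e9, tolerance = 1e-6)
  # fold-change is invariant to a unit change applied to both curves
  curve2 <- simulate_filter_binding(100e-9, conc, noise_sd = 0.01,
                                    replicates = 2, seed = 10)
  f1 <- fold_change(fit_isotherm(curve2, n_boot = 20, seed = 2), fit_M)
  curve2_nM <- curve2; curve2_nM$concentration <- curve2$concentration * 1e9
  f2 <- fold_change(fit_isotherm(curve2_nM, n_boot = 20, seed = 2), fit_nM)
  expect_equal(f1$ratio, f2$ratio, tolerance = 1e-6)
})

test_that("relative adenylation normalizes by Cy5 and the WT 10-min reference", {
  s <- data.frame(variant = c("wt", "wt", "mut", "mut"),
                  time_min = c(2, 10, 2, 10),
                  autorad = c(40, 100, 30, 50),
                  cy5 = c(100, 100, 100, 100))
  out <- relative_adenylation(s)
  expect_equal(out$relative_adenylation, c(0.4, 1.0, 0.3, 0.5))
  # halving autorad at fixed Cy5 halves the relative value
  expect_equal(out$relative_adenylation[4], 0.5)
  # doubling every Cy5 leaves relative values unchanged
  s2 <- s; s2$cy5 <- s2$cy5 * 2
  expect_equal(relative_adenylation(s2)$relative_adenylation,
               out$relative_adenylation)
  # zero-Cy5 entries are flagged, not propagated
  s3 <- s; s3$cy5[3] <- 0
  out3 <- relative_adenylation(s3)
  expect_true(out3$flagged[3])
  expect_true(is.na(out3$relative_adenylation[3]))
  expect_error(relative_adenylation(s[s$variant == "mut", ]), "reference")
})
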