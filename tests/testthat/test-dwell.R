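test_that("single-exponential MLE matches the closed-form sample mean", {
  set.seed(1)
  d <- rexp(10000, 1 / 5)
  fit <- fit_dwell_mixture(d, 1)
  expect_lt(abs(fit$taus - 5) / 5, 0.05)
  expect_equal(fit$taus, mean(d), tolerance = 1e-4)  # uncensored MLE = mean
})

test_that("left truncation is handled in the likelihood normalization", {
  set.seed(2)
  d <- rexp(20000, 1 / 5)
  d <- d[d >= 1]
  fit <- fit_dwell_mixture(d, 1, min_dwell = 1)
  expect_lt(abs(fit$taus - 5) / 5, 0.05)
  # ignoring truncation would overestimate tau by about the bound
  naive <- mean(d)
  expect_gt(naive, 5.5)
})

test_that("right censoring contributes survival terms", {
  set.seed(3)
  true <- rexp(5000, 1 / 5)
  cens_at <- 6
  obs <- pmin(true, cens_at)
  censored <- true > cens_at
  fit <- fit_dwell_mixture(obs, 1, censored = censored)
  expect_lt(abs(fit$taus - 5) / 5, 0.05)
  # treating censored dwells as complete underestimates tau
  naive <- fit_dwell_mixture(obs, 1)
  expect_lt(naive$taus, 4.5)
})

test_that("two-term fit dominates one-term fit on mixture data", {
  m <- kinetic_preset("wt")
  d <- sample_dwells(m, 3000, seed = 4)
  fit1 <- fit_dwell_mixture(d, 1)
  fit2 <- fit_dwell_mixture(d, 2)
  expect_gt(fit2$log_likelihood, fit1$log_likelihood)
  sel <- select_dwell_model(d)
  expect_equal(sel$preferred, 2L)
  expect_lt(sel$p_value, 0.05)
  # the fit is deterministic given the data
  expect_equal(fit_dwell_mixture(d, 2)$taus, fit2$taus)
})

test_that("bootstrap intervals behave on degenerate and regular data", {
  d <- rep(3, 50)
  fit <- fit_dwell_mixture(d, 1)
  fit <- dwell_bootstrap_ci(d, fit, n_boot = 50, seed = 1)
  expect_equal(unname(fit$ci95$taus[1, "lower"]), unname(fit$ci95$taus[1, "upper"]))
  set.seed(5)
  d2 <- rexp(400, 1 / 3)
  fit2 <- fit_dwell_mixture(d2, 1)
  fit2 <- dwell_bootstrap_ci(d2, fit2, n_boot = 200, seed = 2)
  expect_lte(fit2$ci95$taus[1, "lower"], fit2$taus[1])
  expect_gte(fit2$ci95$taus[1, "upper"], fit2$taus[1])
})

test_that("bootstrap interval coverage is close to nominal", {
  hits <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    d <- rexp(500, 1 / 3)
    fit <- fit_dwell_mixture(d, 1)
    fit <- dwell_bootstrap_ci(d, fit, n_boot = 150, seed = i)
    fit$ci95$taus[1, "lower"] <= 3 && 3 <= fit$ci95$taus[1, "upper"]
  }, logical(1))
  expect_gte(mean(hits), 0.91)
  expect_lte(mean(hits), 0.99)
})

test_that("synapsis rate is events over exposure with an exact Poisson CI", {
  expect_equal(synapsis_rate(0, 500)$rate, 0)
  r <- synapsis_rate(10, 1000)
  expect_equal(r$rate, 0.01)
  expect_lt(r$ci95[1], 0.01)
  expect_gt(r$ci95[2], 0.01)
  expect_error(synapsis_rate(3, 0), "exposure")
})

test_that("rate estimator is unbiased on constant-hazard simulations", {
  # hazard 0.02/s, exponential bleaching censors observation at rate 0.01/s,
  # 60 s records; estimate pooled over replicates of 200 molecules
  hazard <- 0.02
  ests <- vapply(1:100, function(r) {
    set.seed(300 + r)
    t_syn <- rexp(300, hazard)
    t_obs <- pmin(rexp(300, 0.01), 60)
    events <- sum(t_syn <= t_obs)
    exposure <- sum(pmin(t_syn, t_obs))
    events / exposure
  }, numeric(1))
  expect_lt(abs(mean(ests) - hazard) / hazard, 0.02)
  # a single run's exact Poisson CI covers the truth
  set.seed(301)
  t_syn <- rexp(500, hazard)
  t_obs <- pmin(rexp(500, 0.01), 60)
  r <- synapsis_rate(sum(t_syn <= t_obs), sum(pmin(t_syn, t_obs)))
  expect_true(r$ci95[1] <= hazard && hazard <= r$ci95[2])
})

test_that("model selection prefers one term on single-exponential data", {
  m <- kinetic_preset("dn-brct")
  d <- sample_dwells(m, 2500, seed = 8, frame_period = 0.1, min_frames = 2)
  sel <- select_dwell_model(d, min_dwell = 0.2)
  expect_equal(sel$preferred, 1L)
  fit <- dwell_bootstrap_ci(d, sel$fit1, n_boot = 100, seed = 3)
  expect_lte(fit$ci95$taus[1, "lower"], fit$taus[1])
  expect_gte(fit$ci95$taus[1, "upper"], fit$taus[1])
})
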