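#' Fit a one-site binding isotherm to a filter-binding dose series
#'
#' Least-squares fit of `f(c) = Bmax * c / (c + Kd)` (free ligand
#' approximated by total protein, which is in large excess over the ~1 nM
#' DNA). Replicates are fit jointly; the Kd confidence interval comes from a
#' nonparametric bootstrap over replicate series.
#'
#' @param curve A `binding_curve` data frame (`concentration`, `replicate`,
#'   `fraction_bound`), e.g. from [simulate_filter_binding()] or read from a
#'   tidy CSV.
#' @param fix_bmax Fix the plateau at 1 instead of fitting it.
#' @param n_boot Bootstrap resamples for the Kd interval (measurements are
#'   resampled within each concentration, preserving the dose design).
#' @param seed Integer seed for the bootstrap.
#' @return A `binding_fit`: `kd` (molar), `bmax`, `kd_ci95`, `residual_sd`,
#'   `reliable` flag (FALSE when the series shows no measurable transition),
#'   `n_points`.
#' @export
fit_isotherm <- function(curve, fix_bmax = FALSE, n_boot = 200, seed = 1) {
  stopifnot(all(c("concentration", "fraction_bound") %in% names(curve)))
  if (is.null(curve$replicate)) curve$replicate <- 1L
  if (length(unique(curve$concentration)) < 5)
    stop("fit_isotherm: need at least 5 concentrations spanning the transition")
  reliable <- !(all(curve$fraction_bound < 0.1) || all(curve$fraction_bound > 0.9))
  if (!reliable) {
    return(structure(list(kd = NA_real_, bmax = NA_real_, kd_ci95 = c(NA, NA),
                          residual_sd = NA_real_, reliable = FALSE,
                          n_points = nrow(curve)), class = "binding_fit"))
  }
  fit1 <- function(dat) {
    # log-parameterized Kd keeps the search positive and scale-free
    mid <- stats::median(dat$concentration)
    if (fix_bmax) {
      f <- minpack.lm::nlsLM(fraction_bound ~ conc / (conc + exp(lkd)),
                             data = list(fraction_bound = dat$fraction_bound,
                                         conc = dat$concentration),
                             start = list(lkd = log(mid)))
      c(kd = exp(stats::coef(f)[["lkd"]]), bmax = 1,
        sd = stats::sigma(f))
    } else {
      f <- minpack.lm::nlsLM(fraction_bound ~ bmax * conc / (conc + exp(lkd)),
                             data = list(fraction_bound = dat$fraction_bound,
                                         conc = dat$concentration),
                             start = list(lkd = log(mid), bmax = 0.9),
                             lower = c(-Inf, 0.05), upper = c(Inf, 1))
      co <- stats::coef(f)
      c(kd = exp(co[["lkd"]]), bmax = co[["bmax"]], sd = stats::sigma(f))
    }
  }
  est <- fit1(curve)
  by_conc <- split(seq_len(nrow(curve)), curve$concentration)
  set.seed(derive_seed(seed, 0L, 4L))
  boots <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(by_conc, function(i) sample(i, length(i), replace = TRUE)))
    boots[b] <- tryCatch(fit1(curve[idx, ])[["kd"]], error = function(e) NA_real_)
  }
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  structure(list(kd = est[["kd"]], bmax = est[["bmax"]],
                 kd_ci95 = as.numeric(ci), kd_boot = boots,
                 residual_sd = est[["sd"]], reliable = TRUE,
                 n_points = nrow(curve)), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$reliable) {
    cat("Binding fit: unreliable (no measurable transition); no Kd reported\n")
    return(invisible(x))
  }
  cat(sprintf("One-site isotherm fit: Kd = %.3g M [%.3g, %.3g], Bmax = %.2f (n = %d)\n",
              x$kd, x$kd_ci95[1], x$kd_ci95[2], x$bmax, x$n_points))
  invisible(x)
}

#' Kd fold-change between a mutant and the wild type
#'
#' Ratio `Kd_mut / Kd_wt` with a bootstrap-ratio confidence interval.
#'
#' @param fit_mut,fit_wt Reliable [fit_isotherm()] results.
#' @return List: `ratio`, `ci95`.
#' @export
fold_change <- function(fit_mut, fit_wt) {
  stopifnot(inherits(fit_mut, "binding_fit"), inherits(fit_wt, "binding_fit"))
  if (!isTRUE(fit_mut$reliable) || !isTRUE(fit_wt$reliable))
    stop("fold_change: unreliable input fit")
  ratio <- fit_mut$kd / fit_wt$kd
  ci <- c(NA_real_, NA_real_)
  if (!is.null(fit_mut$kd_boot) && !is.null(fit_wt$kd_boot)) {
    n <- min(length(fit_mut$kd_boot), length(fit_wt$kd_boot))
    r <- fit_mut$kd_boot[seq_len(n)] / fit_wt$kd_boot[seq_len(n)]
    ci <- as.numeric(stats::quantile(r, c(0.025, 0.975), na.rm = TRUE))
  }
  list(ratio = ratio, ci95 = ci)
}

#' Normalize autoadenylation signals
#'
#' Autoradiogram signal is divided by the Cy5 loading signal per lane, then
#' the whole table is normalized to the wild-type value at the reference
#' timepoint.
#'
#' @param series Data frame with columns `variant`, `time_min`, `autorad`,
#'   `cy5`.
#' @param reference_variant,reference_time Reference entry (defaults:
#'   wild type at 10 min).
#' @return The input with a `relative_adenylation` column; entries with zero
#'   Cy5 signal are NA and flagged in the `flagged` column.
#' @export
relative_adenylation <- function(series, reference_variant = "wt",
                                 reference_time = 10) {
  stopifnot(all(c("variant", "time_min", "autorad", "cy5") %in% names(series)))
  ratio <- ifelse(series$cy5 > 0, series$autorad / series$cy5, NA_real_)
  ref_idx <- which(series$variant == reference_variant &
                     series$time_min == reference_time)
  if (!length(ref_idx) || !is.finite(ratio[ref_idx[1]]) || ratio[ref_idx[1]] <= 0)
    stop("relative_adenylation: reference entry missing or has no Cy5 signal")
  series$relative_adenylation <- ratio / ratio[ref_idx[1]]
  series$flagged <- !is.finite(series$relative_adenylation)
  series
}
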