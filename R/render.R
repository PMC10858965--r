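## Map an exposure-time draw to wall-clock time through the on-frame schedule
## of one laser: bleaching accrues only during frames in which the dye's
## excitation laser is on. `positions` are 1-based cycle positions of the
## laser's frames; exposure starts at the first on-frame at or after t_start.
exposure_to_walltime <- function(x, positions, cycle_len, frame_period, t_start = 0) {
  if (!length(positions)) return(Inf)
  n_full <- floor(x / frame_period)       # whole on-frames survived
  frac <- x / frame_period - n_full
  # enumerate on-frames from the cycle containing t_start
  k0 <- floor(t_start / (cycle_len * frame_period))
  per <- length(positions)
  # index (0-based) of the (n_full+1)-th on-frame whose start >= t_start
  # on-frame j (0-based within laser sequence from cycle k0): time =
  # (k0 + floor(j/per)) * cycle_len * fp + (positions[j %% per + 1] - 1) * fp
  j <- 0L
  # skip on-frames before t_start within the starting cycle
  repeat {
    cyc <- k0 + j %/% per
    pos <- positions[j %% per + 1L]
    t_frame <- (cyc * cycle_len + pos - 1L) * frame_period
    if (t_frame + frame_period > t_start) break
    j <- j + 1L
  }
  j <- j + n_full
  cyc <- k0 + j %/% per
  pos <- positions[j %% per + 1L]
  (cyc * cycle_len + pos - 1L) * frame_period + frac * frame_period
}

## Positions in the cycle at which a given laser fires.
laser_positions <- function(scheme, laser) {
  which(vapply(scheme$cycle, function(fr) fr$laser == laser, logical(1)))
}

## Integrate a piecewise-constant function (breaks, values on segments) over
## frame windows [starts, starts + fp], returning per-frame means.
integrate_step <- function(breaks, seg_values, starts, fp) {
  cum <- c(0, cumsum(seg_values * diff(breaks)))
  Fat <- function(t) {
    t <- pmin(pmax(t, breaks[1]), breaks[length(breaks)])
    j <- findInterval(t, breaks, rightmost.closed = TRUE)
    cum[j] + seg_values[pmin(j, length(seg_values))] * (t - breaks[j])
  }
  (Fat(starts + fp) - Fat(starts)) / fp
}

#' Render observed multi-channel intensity trajectories from ground truth
#'
#' Forward photophysics model: per-frame ideal channel intensities are
#' integrated over each frame interval (sub-frame events produce intermediate
#' levels), donor channels are divided by their gamma factors, the linear
#' crosstalk map is applied, and per-frame noise is added. Unlabeled ligases
#' contribute no ligase-dye signal; bleached dyes emit nothing thereafter,
#' with bleaching accruing only during frames in which the dye's excitation
#' laser is on.
#'
#' @param truth A `ground_truth_set` from [simulate_state_paths()].
#' @param photo A [photophysics_model()].
#' @param scheme The [acquisition_scheme()] used in simulation.
#' @param seed Master integer seed (independent of the simulation seed
#'   stream).
#' @param assay `"three_color"` (substrate Cy3B+Cy5, ligase Cy7),
#'   `"two_color_binding"` (substrate Cy3B at both ends, ligase Cy5) or
#'   `"two_color_sr"` (substrate Cy3B+Cy5, ligase dark).
#' @return A `trajectory_set`: `molecules` (each `list(raw, frame_time)`
#'   where `raw` is frames x channels with NA at unrecorded positions) and
#'   `truth` (the input ledger augmented with per-ligase `labeled` and
#'   `dye_bleach` columns and substrate bleach times), plus the scheme,
#'   photophysics model and assay tag.
#' @export
render_trajectories <- function(truth, photo, scheme, seed,
                                assay = c("three_color", "two_color_binding", "two_color_sr")) {
  assay <- match.arg(assay)
  stopifnot(inherits(truth, "ground_truth_set"), inherits(photo, "photophysics_model"))
  M <- crosstalk_matrix(photo$crosstalk)
  if (abs(det(M)) < 1e-12) stop("render_trajectories: singular crosstalk matrix")
  molecules <- vector("list", length(truth))
  truth_out <- truth
  for (i in seq_along(truth)) {
    set.seed(derive_seed(seed, i, 2L))
    gt <- render_assign_photophysics(truth[[i]], photo, scheme, assay)
    molecules[[i]] <- render_one_molecule(gt, photo, scheme, assay, M)
    truth_out[[i]] <- gt
  }
  structure(list(molecules = molecules, truth = truth_out, scheme = scheme,
                 photo = photo, assay = assay), class = "trajectory_set")
}

## Draw labeling flags and bleach times for one molecule (stage 2 stream).
render_assign_photophysics <- function(gt, photo, scheme, assay) {
  L <- length(scheme$cycle)
  fp <- scheme$frame_period
  model_rates <- photo$bleach_rates
  n <- nrow(gt$ligases)
  gt$ligases$labeled <- stats::runif(n) < photo$labeling_efficiency
  pos532 <- laser_positions(scheme, 532)
  pos641 <- laser_positions(scheme, 641)
  pos730 <- laser_positions(scheme, 730)
  bl <- function(rate, positions, t0 = 0) {
    if (rate <= 0 || !length(positions)) return(Inf)
    exposure_to_walltime(stats::rexp(1, rate), positions, L, fp, t0)
  }
  if (assay == "two_color_binding") {
    gt$bleach_cy3b <- c(bl(model_rates[["cy3b"]], pos532),
                        bl(model_rates[["cy3b"]], pos532))
    gt$bleach_cy5 <- Inf                      # no substrate Cy5
    lig_pos <- pos641
  } else {
    gt$bleach_cy3b <- bl(model_rates[["cy3b"]], pos532)
    gt$bleach_cy5 <- bl(model_rates[["cy5"]], pos641)
    lig_pos <- if (assay == "three_color") pos730 else integer(0)
  }
  gt$ligases$dye_bleach <- rep(Inf, n)
  if (n > 0 && length(lig_pos)) {
    rate_l <- if (assay == "three_color") model_rates[["cy7"]] else model_rates[["cy5"]]
    for (j in seq_len(n)) {
      if (gt$ligases$labeled[j] && rate_l > 0)
        gt$ligases$dye_bleach[j] <- bl(rate_l, lig_pos, gt$ligases$t_on[j])
    }
  }
  gt
}

## Ideal (corrected-units) channel levels for every state segment, then
## frame-integrate, apply gamma + crosstalk, and add noise.
render_one_molecule <- function(gt, photo, scheme, assay, M) {
  fp <- scheme$frame_period
  L <- length(scheme$cycle)
  n_frames <- scheme$n_frames
  duration <- gt$duration
  lv <- photo$fret_levels
  B3 <- photo$donor_budget; B5 <- photo$acceptor_budget; U7 <- photo$cy7_unit
  lg <- gt$ligases

  brk <- c(0, duration, gt$synapsis_time, lg$t_on, lg$t_off, lg$dye_bleach,
           gt$bleach_cy3b, gt$bleach_cy5)
  brk <- sort(unique(pmin(pmax(brk[is.finite(brk)], 0), duration)))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  nseg <- length(mids)
  ideal <- matrix(0, nseg, 6, dimnames = list(NULL, c("I3", "I35", "I37", "I5", "I57", "I7")))

  for (s in seq_len(nseg)) {
    m <- mids[s]
    present <- lg$t_on <= m & lg$t_off > m
    vis <- present & lg$labeled & lg$dye_bleach > m
    synapsed <- !is.na(gt$synapsis_time) && m > gt$synapsis_time
    surv_vis <- synapsed && any(vis & lg$survivor)
    occ1 <- present & lg$kind == "end" & lg$end %in% 1L
    occ2 <- present & lg$kind == "end" & lg$end %in% 2L
    if (assay == "two_color_binding") {
      a1 <- m < gt$bleach_cy3b[1]; a2 <- m < gt$bleach_cy3b[2]
      e1 <- if ((any(occ1 & vis)) || surv_vis) lv[["e35_ligase"]] else 0
      e2 <- if ((any(occ2 & vis)) || surv_vis) lv[["e35_ligase"]] else 0
      ideal[s, "I3"] <- B3 * (a1 * (1 - e1) + a2 * (1 - e2))
      ideal[s, "I35"] <- B3 * (a1 * e1 + a2 * e2)
      ideal[s, "I5"] <- B5 * sum(vis)
    } else {
      a3 <- m < gt$bleach_cy3b; a5 <- m < gt$bleach_cy5
      e35 <- if (a3 && a5) { if (synapsed) lv[["e35_synapsed"]] else lv[["e35_baseline"]] } else 0
      if (assay == "three_color") {
        e37 <- if (a3 && (any(occ1 & vis) || surv_vis)) lv[["e37_bound"]] else 0
        e57 <- if (a5 && (any(occ2 & vis) || surv_vis)) lv[["e57_bound"]] else 0
        ideal[s, "I37"] <- a3 * B3 * e37
        ideal[s, "I57"] <- a5 * B5 * e57
        ideal[s, "I7"] <- U7 * sum(vis)
        ideal[s, "I3"] <- a3 * B3 * (1 - e35 - e37)
        ideal[s, "I5"] <- a5 * B5 * (1 - e57)
      } else {
        ideal[s, "I3"] <- a3 * B3 * (1 - e35)
        ideal[s, "I5"] <- a5 * B5
      }
      ideal[s, "I35"] <- a3 * B3 * e35
    }
  }

  frame_starts <- (seq_len(n_frames) - 1) * fp
  X <- matrix(0, n_frames, 6, dimnames = list(NULL, colnames(ideal)))
  for (ch in colnames(ideal)) {
    if (any(ideal[, ch] != 0))
      X[, ch] <- integrate_step(brk, ideal[, ch], frame_starts, fp)
  }
  # gamma division of donor channels, then crosstalk
  g <- photo$crosstalk$gamma
  X[, "I3"] <- X[, "I3"] / g[["g3"]]
  X[, "I5"] <- X[, "I5"] / g[["g5"]]
  obs <- X %*% t(M)
  colnames(obs) <- colnames(X)
  # record only the channels of each frame's cycle position; add noise there
  rec <- matrix(FALSE, n_frames, 6, dimnames = dimnames(obs))
  for (ch in names(scheme$channels)) {
    p <- scheme$channels[[ch]]$pos
    rows <- seq(p, n_frames, by = L)
    rec[rows, ch] <- TRUE
  }
  if (photo$noise_model == "poisson") {
    idx <- which(rec)
    obs[idx] <- stats::rpois(length(idx), pmax(obs[idx], 0))
  } else if (photo$noise_sd > 0) {
    idx <- which(rec)
    obs[idx] <- obs[idx] + stats::rnorm(length(idx), 0, photo$noise_sd)
  }
  obs[!rec] <- NA_real_
  list(raw = obs, frame_time = frame_starts + fp / 2)
}
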