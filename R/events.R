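#' Penalized seeded binary-segmentation change-point detection
#'
#' Piecewise-constant mean-shift segmentation under a Gaussian cost. Split
#' candidates are evaluated locally on a deterministic collection of seeded
#' (dyadic, half-overlapping) intervals, which keeps short-lived steps
#' detectable inside long records; the strongest candidate in a segment is
#' accepted when its residual-sum-of-squares reduction exceeds
#' `penalty_mult * sigma^2 * log(n)`, and segmentation recurses on both
#' sides. The noise scale `sigma` is estimated robustly from successive
#' differences (`MAD(diff(x)) / sqrt(2)`) unless supplied. The default
#' `penalty_mult` was fixed once by null-trace simulation
#' (`analysis/00_calibration_scan.R`) to keep the per-trace false-positive
#' rate at or below 5% for 1000-frame flat Gaussian traces.
#'
#' Non-finite samples are masked before detection; breakpoint indices refer
#' to the original stream.
#'
#' @param x Numeric stream (length >= 3 after masking; shorter streams return
#'   no breakpoints).
#' @param time Optional per-sample timestamps; breakpoint times are the
#'   timestamp of the first sample after the break.
#' @param penalty_mult Penalty multiplier (unitless).
#' @param sigma Optional known noise standard deviation.
#' @param min_size Minimum segment length in samples.
#' @return A data frame with one row per breakpoint: `index` (last sample of
#'   the left segment), `time`, `sign`, `amplitude` (right-segment mean minus
#'   left-segment mean between neighboring breakpoints).
#' @export
detect_change_points <- function(x, time = NULL, penalty_mult = 3.5,
                                 sigma = NULL, min_size = 2) {
  ok <- is.finite(x)
  xs <- x[ok]
  n <- length(xs)
  empty <- data.frame(index = integer(0), time = numeric(0),
                      sign = numeric(0), amplitude = numeric(0))
  if (n < 2 * min_size) return(empty)
  if (is.null(sigma)) sigma <- stats::mad(diff(xs)) / sqrt(2)
  sigma2 <- max(sigma^2, 1e-12 * max(1, diff(range(xs)))^2, .Machine$double.eps)
  pen <- penalty_mult * sigma2 * log(n)
  cs <- c(0, cumsum(xs))

  # best split within [a, b] by local RSS-reduction
  local_best <- function(a, b) {
    ks <- seq.int(a + min_size - 1L, b - min_size)
    nl <- ks - a + 1
    nr <- b - ks
    ml <- (cs[ks + 1] - cs[a]) / nl
    mr <- (cs[b + 1] - cs[ks + 1]) / nr
    gain <- nl * nr / (nl + nr) * (ml - mr)^2
    j <- which.max(gain)
    c(ks[j], gain[j])
  }

  # seeded intervals within [l, r]: dyadic lengths, half-overlapping starts
  best_split <- function(l, r) {
    len <- r - l + 1L
    best <- c(NA_integer_, -Inf)
    L <- max(2L * min_size, 4L)
    repeat {
      step <- max(1L, L %/% 2L)
      starts <- seq.int(l, max(l, r - L + 1L), by = step)
      for (a in starts) {
        b <- min(a + L - 1L, r)
        if (b - a + 1L < 2L * min_size) next
        cand <- local_best(a, b)
        if (cand[2] > best[2]) best <- cand
      }
      if (L >= len) break
      L <- 2L * L
    }
    if (!is.finite(best[2])) return(NULL)
    list(k = as.integer(best[1]), gain = best[2])
  }

  bps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- seg[1]; r <- seg[2]
    if (r - l + 1 < 2 * min_size) next
    sp <- best_split(l, r)
    if (is.null(sp) || sp$gain <= pen) next
    bps <- c(bps, sp$k)
    stack <- c(stack, list(c(l, sp$k)), list(c(sp$k + 1L, r)))
  }
  if (!length(bps)) return(empty)
  bps <- sort(bps)
  bounds <- c(0L, bps, n)
  seg_means <- vapply(seq_len(length(bounds) - 1L), function(j) {
    (cs[bounds[j + 1] + 1] - cs[bounds[j] + 1]) / (bounds[j + 1] - bounds[j])
  }, numeric(1))
  amp <- diff(seg_means)
  orig_idx <- which(ok)
  idx <- orig_idx[bps]
  tm <- if (!is.null(time)) {
    nxt <- orig_idx[pmin(bps + 1L, n)]
    time[nxt]
  } else rep(NA_real_, length(bps))
  data.frame(index = idx, time = tm, sign = sign(amp), amplitude = amp)
}

#' Detect short-range synapsis events as stepwise FRET increases
#'
#' A synapsis event is an up-going change point in the corrected E35 stream
#' whose post-step segment mean exceeds `threshold` while the pre-step mean
#' lies below it. The synapsis time is the first cycle after the breakpoint.
#'
#' @param e35 Per-cycle corrected E35 values (NA allowed).
#' @param time Per-cycle timestamps (s).
#' @param threshold High-FRET call threshold on the post-step mean.
#' @param penalty_mult,min_size Passed to [detect_change_points()].
#' @return Event data frame (`kind`, `start_time`, `end_time`,
#'   `mean_e35_post`); zero rows when no synapsis is found.
#' @export
detect_synapsis <- function(e35, time = NULL, threshold = 0.3,
                            penalty_mult = 3.5, min_size = 2) {
  bp <- detect_change_points(e35, time = time, penalty_mult = penalty_mult,
                             min_size = min_size)
  empty <- data.frame(kind = character(0), start_time = numeric(0),
                      end_time = numeric(0), mean_e35_post = numeric(0))
  if (!nrow(bp)) return(empty)
  ok <- is.finite(e35)
  xs <- e35[ok]; orig <- which(ok)
  bounds <- c(0L, match(bp$index, orig), length(xs))
  out <- empty
  for (j in seq_len(nrow(bp))) {
    post <- mean(xs[(bounds[j + 1] + 1):bounds[j + 2]])
    pre <- mean(xs[(bounds[j] + 1):bounds[j + 1]])
    if (bp$sign[j] > 0 && post > threshold && pre < threshold) {
      out <- rbind(out, data.frame(kind = "synapsis", start_time = bp$time[j],
                                   end_time = bp$time[j], mean_e35_post = post))
    }
  }
  out
}

#' Detect colocalization events from a directly excited ligase-dye stream
#'
#' Maximal above-threshold runs; runs separated by fewer than
#' `min_gap_frames` below-threshold samples are merged; merged runs shorter
#' than `min_dwell_frames` are discarded. Each event is annotated with its
#' mean FRET efficiency over its frames when a FRET stream is supplied.
#'
#' @param value Directly excited ligase-dye stream (I5 in the two-color
#'   binding assay, I7 in three-color), per cycle.
#' @param time Per-cycle timestamps (s).
#' @param intensity_threshold Counts threshold (> 0).
#' @param min_dwell_frames Minimum event length in samples.
#' @param min_gap_frames Runs closer than this many samples are merged.
#' @param fret Optional per-cycle FRET efficiency stream for annotation.
#' @return Event data frame: `kind`, `start_index`, `end_index`,
#'   `start_time`, `end_time`, `n_frames`, `duration`, `mean_fret`.
#' @export
detect_colocalization <- function(value, time = NULL, intensity_threshold,
                                  min_dwell_frames = 2, min_gap_frames = 2,
                                  fret = NULL) {
  if (intensity_threshold <= 0)
    stop("detect_colocalization: intensity_threshold must be > 0")
  above <- is.finite(value) & value > intensity_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  empty <- data.frame(kind = character(0), start_index = integer(0),
                      end_index = integer(0), start_time = numeric(0),
                      end_time = numeric(0), n_frames = integer(0),
                      duration = numeric(0), mean_fret = numeric(0))
  if (!nrow(runs)) return(empty)
  # merge runs separated by gaps shorter than min_gap_frames
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (j in 2:nrow(runs)) {
    gap <- runs$start[j] - merged$end[nrow(merged)] - 1L
    if (gap < min_gap_frames) merged$end[nrow(merged)] <- runs$end[j]
    else merged <- rbind(merged, runs[j, ])
  }
  merged$n <- merged$end - merged$start + 1L
  merged <- merged[merged$n >= min_dwell_frames, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  period <- if (!is.null(time) && length(time) > 1) stats::median(diff(time)) else NA_real_
  mf <- vapply(seq_len(nrow(merged)), function(j) {
    if (is.null(fret)) return(NA_real_)
    f <- fret[merged$start[j]:merged$end[j]]
    if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE)
  }, numeric(1))
  data.frame(kind = "colocalization",
             start_index = merged$start, end_index = merged$end,
             start_time = if (!is.null(time)) time[merged$start] else NA_real_,
             end_time = if (!is.null(time)) time[merged$end] else NA_real_,
             n_frames = merged$n,
             duration = merged$n * period,
             mean_fret = mf)
}

#' Qualify DNA spots by the two-step photobleach intensity criterion
#'
#' Estimates the single-fluorophore intensity from the down-step amplitudes
#' detected across all donor (I3) streams of a dataset, then qualifies each
#' spot whose initial intensity exceeds `ratio` times that unit (spots with
#' two intact donor fluorophores start near twice the unit).
#'
#' @param i3_streams List of per-molecule I3 streams.
#' @param ratio Qualification multiple of the single-fluorophore unit.
#' @param n_initial Number of leading samples averaged for the initial
#'   intensity.
#' @param penalty_mult Passed to [detect_change_points()].
#' @return List: `qualified` (logical per molecule), `single_step` (counts),
#'   `initial` (per-molecule initial intensities). When no bleach steps are
#'   detected in the whole dataset, qualification is disabled (all `TRUE`)
#'   with a warning.
#' @export
qualify_dna_spot <- function(i3_streams, ratio = 1.5, n_initial = 5,
                             penalty_mult = 3.5) {
  downs <- unlist(lapply(i3_streams, function(x) {
    bp <- detect_change_points(x, penalty_mult = penalty_mult)
    -bp$amplitude[bp$sign < 0]
  }))
  initial <- vapply(i3_streams, function(x) {
    x <- x[is.finite(x)]
    mean(utils::head(x, n_initial))
  }, numeric(1))
  if (!length(downs)) {
    warning("qualify_dna_spot: no photobleach steps detected; qualification disabled")
    return(list(qualified = rep(TRUE, length(i3_streams)),
                single_step = NA_real_, initial = initial))
  }
  unit <- stats::median(downs)
  list(qualified = initial > ratio * unit, single_step = unit, initial = initial)
}

#' Estimate Lig4 stoichiometry from step-normalized Cy7 intensity
#'
#' Detects stepwise changes in the directly excited Cy7 stream and normalizes
#' the stream by the mean absolute step amplitude of that molecule, yielding
#' an estimate of the number of labeled ligases present per cycle.
#'
#' @param i7 Per-cycle direct-excitation Cy7 stream.
#' @param time Per-cycle timestamps.
#' @param penalty_mult,min_size Passed to [detect_change_points()].
#' @return A `stoichiometry_trace`: `defined` flag, `stoichiometry` and
#'   `time` vectors, `normalization_step` (counts) and the detected `steps`.
#'   Molecules with no detected steps are flagged undefined and excluded
#'   from stoichiometry statistics.
#' @export
estimate_stoichiometry <- function(i7, time = NULL, penalty_mult = 3.5,
                                   min_size = 2) {
  steps <- detect_change_points(i7, time = time, penalty_mult = penalty_mult,
                                min_size = min_size)
  if (!nrow(steps)) {
    return(structure(list(defined = FALSE, stoichiometry = NULL, time = time,
                          normalization_step = NA_real_, steps = steps),
                     class = "stoichiometry_trace"))
  }
  unit <- mean(abs(steps$amplitude))
  structure(list(defined = TRUE, stoichiometry = i7 / unit, time = time,
                 normalization_step = unit, steps = steps),
            class = "stoichiometry_trace")
}
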