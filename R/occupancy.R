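#' Classify pre-synapsis frames by Lig4 end occupancy
#'
#' For each qualifying cycle (valid, pre-bleach, and pre-synapsis by the
#' `E35 < presyn_mask` criterion) classifies whether neither, one or both DNA
#' ends show ligase FRET (`E37 > fret_threshold`, `E57 > fret_threshold`),
#' pooling frames across molecules.
#'
#' @param corrected A list of `corrected_trajectory` objects (three-color).
#' @param fret_threshold End-bound call threshold on E37/E57.
#' @param presyn_mask Frames with `E35 <` this value count as pre-synapsis.
#' @return An `occupancy_summary`: `fractions` (percent, named `neither`,
#'   `one`, `both`), `n_frames`, and the thresholds used. Empty input frames
#'   give an empty summary with a warning.
#' @export
classify_end_occupancy <- function(corrected, fret_threshold = 0.25,
                                   presyn_mask = 0.15) {
  counts <- c(neither = 0, one = 0, both = 0)
  for (ct in corrected) {
    ef <- ct$efficiencies
    if (is.null(ef$E37) || is.null(ef$E57))
      stop("classify_end_occupancy: three-color efficiencies required")
    ok <- is.finite(ef$E35) & is.finite(ef$E37) & is.finite(ef$E57) &
      ef$E35 < presyn_mask
    n_bound <- (ef$E37[ok] > fret_threshold) + (ef$E57[ok] > fret_threshold)
    counts <- counts + c(sum(n_bound == 0), sum(n_bound == 1), sum(n_bound == 2))
  }
  n <- sum(counts)
  if (n == 0) {
    warning("classify_end_occupancy: no qualifying frames")
    return(structure(list(fractions = counts * NA_real_, n_frames = 0,
                          fret_threshold = fret_threshold,
                          presyn_mask = presyn_mask),
                     class = "occupancy_summary"))
  }
  structure(list(fractions = 100 * counts / n, n_frames = n,
                 fret_threshold = fret_threshold, presyn_mask = presyn_mask),
            class = "occupancy_summary")
}

#' Fraction of colocalization events showing FRET
#'
#' @param events Event data frame from [detect_colocalization()] (possibly
#'   row-bound across molecules) with a `mean_fret` column.
#' @param threshold Events with mean FRET efficiency above this threshold
#'   count as end-bound.
#' @return List: `percent` high-FRET, `ci95` (exact binomial, percent),
#'   `n_events`.
#' @export
colocalization_fret_fraction <- function(events, threshold = 0.1) {
  f <- events$mean_fret[is.finite(events$mean_fret)]
  if (!length(f)) stop("colocalization_fret_fraction: no annotated events")
  x <- sum(f > threshold)
  ci <- stats::binom.test(x, length(f))$conf.int
  list(percent = 100 * x / length(f), ci95 = 100 * as.numeric(ci),
       n_events = length(f), threshold = threshold)
}

#' Align stoichiometry traces at synapsis
#'
#' Re-indexes per-molecule stoichiometry traces to time-to-synapsis (t = 0 at
#' the detected synapsis), bins one bin per acquisition cycle, and computes
#' the per-bin median over trajectories. Only molecules with a detected
#' synapsis and a defined stoichiometry trace participate.
#'
#' The per-bin median is taken over trajectories with labeled ligase present
#' at that bin (stoichiometry above `presence_threshold`): it summarizes the
#' stoichiometry of complexes with detected Cy7-Lig4, not the (labeling- and
#' occupancy-diluted) average over all molecules. Set
#' `presence_threshold = -Inf` for the unconditional median.
#'
#' @param stoich_list List of `stoichiometry_trace` objects.
#' @param synapsis_times Numeric vector of synapsis times (s), same length.
#' @param window `c(before, after)` extent of the alignment axis in seconds.
#' @param presence_threshold Minimum stoichiometry for a trajectory to count
#'   as Cy7-present in a bin.
#' @return A `synapsis_alignment`: `time` (bin centers, s), `median`, `n`
#'   (present trajectories per bin), `matrix` (trajectories x bins, all
#'   values), `n_events`. Bins with no trajectories are reported as NA.
#' @export
align_at_synapsis <- function(stoich_list, synapsis_times, window = c(-30, 10),
                              presence_threshold = 0.5) {
  stopifnot(length(stoich_list) == length(synapsis_times))
  keep <- vapply(stoich_list, function(s) isTRUE(s$defined), logical(1)) &
    is.finite(synapsis_times)
  stoich_list <- stoich_list[keep]
  synapsis_times <- synapsis_times[keep]
  if (!length(stoich_list)) stop("align_at_synapsis: no usable trajectories")
  period <- stats::median(diff(stoich_list[[1]]$time))
  bins <- seq(floor(window[1] / period), ceiling(window[2] / period))
  mat <- matrix(NA_real_, length(stoich_list), length(bins))
  for (i in seq_along(stoich_list)) {
    s <- stoich_list[[i]]
    rel <- round((s$time - synapsis_times[i]) / period)
    j <- match(rel, bins)
    ok <- !is.na(j)
    mat[i, j[ok]] <- s$stoichiometry[ok]
  }
  present <- !is.na(mat) & mat > presence_threshold
  n <- colSums(present)
  med <- vapply(seq_along(bins), function(j) {
    v <- mat[present[, j], j]
    if (length(v)) stats::median(v) else NA_real_
  }, numeric(1))
  structure(list(time = bins * period, median = med, n = n, matrix = mat,
                 n_events = length(stoich_list),
                 presence_threshold = presence_threshold),
            class = "synapsis_alignment")
}

#' Median aligned stoichiometry over a time window
#'
#' @param alignment A [align_at_synapsis()] result.
#' @param window `c(from, to)` in seconds relative to synapsis (inclusive).
#' @return Median of the pooled per-trajectory Cy7-present values in the
#'   window bins (same presence rule as the per-bin medians).
#' @export
alignment_window_median <- function(alignment, window) {
  j <- which(alignment$time >= window[1] & alignment$time <= window[2])
  vals <- alignment$matrix[, j]
  vals <- vals[is.finite(vals) & vals > alignment$presence_threshold]
  if (!length(vals)) return(NA_real_)
  stats::median(vals)
}

#' Fraction of synapsis events preceded by a ligase dissociation
#'
#' Fraction of synapsis events with at least one Cy7 down-step in the window
#' `(t_syn - window, t_syn]`. With incomplete Cy7 labeling this measured
#' fraction underestimates the true dissociation frequency (dark departures
#' are invisible).
#'
#' @param down_step_times List (one entry per synapsis event) of the
#'   molecule's detected down-step times (s).
#' @param synapsis_times Synapsis times (s), same length.
#' @param window Look-back window in seconds.
#' @return List: `percent`, `ci95` (exact binomial, percent), `n_events`.
#' @export
dissociation_before_synapsis <- function(down_step_times, synapsis_times,
                                         window = 10) {
  stopifnot(length(down_step_times) == length(synapsis_times))
  if (!length(synapsis_times)) stop("dissociation_before_synapsis: no synapsis events")
  hit <- mapply(function(steps, ts) {
    any(steps > ts - window & steps <= ts)
  }, down_step_times, synapsis_times)
  ci <- stats::binom.test(sum(hit), length(hit))$conf.int
  list(percent = 100 * mean(hit), ci95 = 100 * as.numeric(ci),
       n_events = length(hit))
}
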