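#' End-to-end analysis of a two-color Lig4 colocalization/binding experiment
#'
#' Demultiplexes and corrects every molecule, detects colocalization events
#' on the directly excited ligase (I5) stream with the two-frame-minimum /
#' two-frame-gap rules, annotates each event with its mean E35, and collects
#' dwell times with right-censoring flags for events truncated by the record
#' end.
#'
#' @param ts A `trajectory_set` rendered with `assay = "two_color_binding"`.
#' @param intensity_threshold Counts threshold on I5 (default: half the
#'   single-ligase Cy5 emission level).
#' @param min_dwell_frames,min_gap_frames Colocalization rules.
#' @return List: `events` (all molecules, with `molecule` and `fret_valid`
#'   columns), `dwells`, `censored`, `min_dwell` (s), `period` (s).
#' @export
analyze_two_color_binding <- function(ts, intensity_threshold = NULL,
                                      min_dwell_frames = 2, min_gap_frames = 2) {
  stopifnot(inherits(ts, "trajectory_set"), ts$assay == "two_color_binding")
  if (is.null(intensity_threshold))
    intensity_threshold <- 0.5 * ts$photo$acceptor_budget
  all_events <- list()
  for (i in seq_along(ts$molecules)) {
    st <- demultiplex(ts$molecules[[i]], ts$scheme)
    gt <- ts$truth[[i]]
    masks <- masks_from_truth(gt, st)
    corr <- correct_intensities(st, ts$photo$crosstalk, masks = masks)
    ev <- detect_colocalization(corr$values[, "I5"], time = st$times[, "I5"],
                                intensity_threshold = intensity_threshold,
                                min_dwell_frames = min_dwell_frames,
                                min_gap_frames = min_gap_frames,
                                fret = corr$efficiencies$E35)
    if (!nrow(ev)) next
    ev$molecule <- i
    ev$censored <- ev$end_index == nrow(st$values)
    donor_alive <- min(gt$bleach_cy3b)
    ev$fret_valid <- ev$end_time < donor_alive
    all_events[[length(all_events) + 1L]] <- ev
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(kind = character(0), mean_fret = numeric(0),
               duration = numeric(0), censored = logical(0),
               fret_valid = logical(0))
  period <- length(ts$scheme$cycle) * ts$scheme$frame_period
  list(events = events, dwells = events$duration, censored = events$censored,
       min_dwell = min_dwell_frames * period, period = period,
       intensity_threshold = intensity_threshold)
}

#' End-to-end analysis of a three-color synapsis/stoichiometry experiment
#'
#' Per molecule: demultiplex, correct, detect synapsis (stepwise E35
#' increase), estimate Cy7 step-normalized stoichiometry and collect Cy7
#' down-steps. Across molecules: pre-synapsis end-occupancy classification,
#' synapsis-aligned median stoichiometry, the dissociation-before-synapsis
#' statistic, and the synapsis rate over unsynapsed pre-bleach exposure.
#'
#' @param ts A `trajectory_set` rendered with `assay = "three_color"`.
#' @param fret_threshold End-bound call threshold on E37/E57.
#' @param presyn_mask Pre-synapsis criterion on E35.
#' @param synapsis_threshold Post-step mean E35 threshold for a synapsis call.
#' @param dissociation_window Look-back window (s).
#' @param alignment_window `c(before, after)` seconds for the aligned axis.
#' @return List with `occupancy`, `alignment`, `stoich_presyn_median`
#'   (window -10..-5 s), `stoich_t0_median`, `dissociation`, `rate`,
#'   `synapsis_times`, `n_molecules`, plus the thresholds used.
#' @export
analyze_three_color <- function(ts, fret_threshold = 0.25, presyn_mask = 0.15,
                                synapsis_threshold = 0.3,
                                dissociation_window = 10,
                                alignment_window = c(-30, 10)) {
  stopifnot(inherits(ts, "trajectory_set"), ts$assay == "three_color")
  n <- length(ts$molecules)
  corrected <- vector("list", n)
  stoich <- vector("list", n)
  syn_time <- rep(NA_real_, n)
  down_steps <- vector("list", n)
  exposure <- numeric(n)
  for (i in seq_len(n)) {
    st <- demultiplex(ts$molecules[[i]], ts$scheme)
    gt <- ts$truth[[i]]
    masks <- masks_from_truth(gt, st)
    corr <- correct_intensities(st, ts$photo$crosstalk, masks = masks)
    corrected[[i]] <- corr
    tvec <- st$times[, "I35"]
    syn <- detect_synapsis(corr$efficiencies$E35, time = tvec,
                           threshold = synapsis_threshold)
    if (nrow(syn)) syn_time[i] <- syn$start_time[1]
    s7 <- estimate_stoichiometry(corr$values[, "I7"], time = st$times[, "I7"])
    stoich[[i]] <- s7
    down_steps[[i]] <- if (s7$defined) s7$steps$time[s7$steps$sign < 0] else numeric(0)
    exposure[i] <- min(gt$duration, syn_time[i], gt$bleach_cy3b, gt$bleach_cy5,
                       na.rm = TRUE)
  }
  occupancy <- classify_end_occupancy(corrected, fret_threshold, presyn_mask)
  has_syn <- which(is.finite(syn_time))
  alignment <- NULL
  stoich_presyn <- NA_real_
  stoich_t0 <- NA_real_
  dissoc <- NULL
  if (length(has_syn)) {
    usable <- has_syn[vapply(stoich[has_syn], function(s) isTRUE(s$defined), logical(1))]
    if (length(usable)) {
      alignment <- align_at_synapsis(stoich[usable], syn_time[usable],
                                     window = alignment_window)
      stoich_presyn <- alignment_window_median(alignment, c(-10, -5))
      stoich_t0 <- alignment_window_median(alignment, c(0, 0))
      dissoc <- dissociation_before_synapsis(down_steps[usable], syn_time[usable],
                                             window = dissociation_window)
    }
  }
  rate <- synapsis_rate(length(has_syn), sum(exposure))
  list(occupancy = occupancy, alignment = alignment,
       stoich_presyn_median = stoich_presyn, stoich_t0_median = stoich_t0,
       dissociation = dissoc, rate = rate, synapsis_times = syn_time,
       stoichiometry = stoich, n_molecules = n,
       config = list(fret_threshold = fret_threshold, presyn_mask = presyn_mask,
                     synapsis_threshold = synapsis_threshold,
                     dissociation_window = dissociation_window))
}

#' End-to-end analysis of a two-color synapsis-rate experiment
#'
#' @param ts A `trajectory_set` rendered with `assay = "two_color_sr"`.
#' @param synapsis_threshold Post-step mean E35 threshold.
#' @return List: `synapsis_times`, `rate` (with exact Poisson CI).
#' @export
analyze_two_color_sr <- function(ts, synapsis_threshold = 0.3) {
  stopifnot(inherits(ts, "trajectory_set"), ts$assay == "two_color_sr")
  n <- length(ts$molecules)
  syn_time <- rep(NA_real_, n)
  exposure <- numeric(n)
  for (i in seq_len(n)) {
    st <- demultiplex(ts$molecules[[i]], ts$scheme)
    gt <- ts$truth[[i]]
    masks <- masks_from_truth(gt, st)
    corr <- correct_intensities(st, ts$photo$crosstalk, masks = masks)
    syn <- detect_synapsis(corr$efficiencies$E35, time = st$times[, "I35"],
                           threshold = synapsis_threshold)
    if (nrow(syn)) syn_time[i] <- syn$start_time[1]
    exposure[i] <- min(gt$duration, syn_time[i], gt$bleach_cy3b, gt$bleach_cy5,
                       na.rm = TRUE)
  }
  list(synapsis_times = syn_time,
       rate = synapsis_rate(sum(is.finite(syn_time)), sum(exposure)))
}
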