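## Counter-based per-molecule seed split: derived from (master seed, molecule
## index, stage) only, so changing n_molecules never reshuffles earlier
## molecules. All arithmetic stays exact in doubles and below 2^31.
derive_seed <- function(seed, molecule, stage = 0L) {
  a <- (abs(seed) %% 65536) * 1e7 + molecule * 1e3 + stage
  as.integer((1103515245 * (a %% 1e6) + 12345 + floor(a / 1e6) * 2246822519) %% 2147483647)
}

## Draw one dwell-mixture component index (1 = fast, 2 = slow).
draw_component <- function(model) {
  if (stats::runif(1) < model$dwell_fractions[1]) 1L else 2L
}

#' Sample colocalization dwell times from a kinetic model's mixture law
#'
#' Draws i.i.d. dwells from `f1 * Exp(tau1) + f2 * Exp(tau2)`; optionally
#' frame-discretizes them (rounding up to whole sampling periods, as a
#' threshold-run detector would measure them) and applies a minimum-length
#' truncation.
#'
#' @param model A [kinetic_model()].
#' @param n Number of dwells.
#' @param seed Integer seed.
#' @param frame_period Sampling period in seconds for discretization
#'   (`NULL` for exact continuous dwells).
#' @param min_frames Discard dwells shorter than this many sampling periods.
#' @return Numeric vector of dwell times (s); may be shorter than `n` when
#'   truncation removes short dwells.
#' @export
sample_dwells <- function(model, n, seed, frame_period = NULL, min_frames = 2) {
  set.seed(derive_seed(seed, 0L, 7L))
  comp <- 1L + (stats::runif(n) >= model$dwell_fractions[1])
  d <- stats::rexp(n, rate = 1 / model$dwell_taus[comp])
  if (!is.null(frame_period)) {
    d <- ceiling(d / frame_period) * frame_period
    d <- d[d >= min_frames * frame_period]
  }
  d
}

#' Simulate ground-truth state paths for surface-tethered DNA molecules
#'
#' Exact (continuous-time) stochastic simulation of the kinetic model in
#' [kinetic_model()]: end-engaging arrivals per free end with cooperativity,
#' colocalization-only ("hover") arrivals, exponential-mixture dwells
#' (simulated as a two-phase race, which reproduces the mixture law exactly),
#' and short-range synapsis from the poised single-ligase state that follows
#' a two-ligase bridge episode. At synapsis the surviving ligase captures
#' both DNA ends and remains for the rest of the record.
#'
#' @param model A [kinetic_model()].
#' @param scheme An [acquisition_scheme()]; fixes the record duration.
#' @param n_molecules Number of molecules (>= 1).
#' @param seed Master integer seed; per-molecule streams are derived by a
#'   counter-based split.
#' @return An object of class `ground_truth_set`: a list with one
#'   `ground_truth` entry per molecule, each holding `ligases` (data frame:
#'   `ligase`, `kind` ("end"/"hover"), `end` (1, 2 or NA), `component`,
#'   `t_on`, `t_off`, `survivor`), `synapsis_time` (NA if none) and
#'   `duration`. The model and scheme are attached as attributes.
#' @export
simulate_state_paths <- function(model, scheme, n_molecules, seed) {
  stopifnot(inherits(model, "kinetic_model"), inherits(scheme, "acquisition_scheme"))
  if (n_molecules < 1) stop("simulate_state_paths: n_molecules must be >= 1")
  out <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    set.seed(derive_seed(seed, i, 1L))
    out[[i]] <- simulate_one_molecule(model, scheme$total_duration)
    out[[i]]$molecule <- i
  }
  structure(out, class = "ground_truth_set", model = model, scheme = scheme)
}

simulate_one_molecule <- function(model, duration) {
  a <- model$arrival_rate_per_end
  coop <- model$cooperativity_factor
  h <- model$synapsis_hazard
  feb <- model$fraction_end_bound
  r_hover <- 2 * a * (1 - feb) / feb
  dep_rate <- 1 / model$dwell_taus

  cap <- 64L
  lig_kind <- character(cap); lig_end <- integer(cap); lig_comp <- integer(cap)
  lig_on <- numeric(cap); lig_off <- rep(NA_real_, cap); lig_surv <- logical(cap)
  n_lig <- 0L
  grow <- function() {
    cap2 <- cap * 2L
    length(lig_kind) <<- cap2; length(lig_end) <<- cap2; length(lig_comp) <<- cap2
    length(lig_on) <<- cap2; lig_off <<- c(lig_off, rep(NA_real_, cap))
    length(lig_surv) <<- cap2; cap <<- cap2
  }

  end_occ <- c(0L, 0L)          # ligase index occupying each end (0 = free)
  active_hover <- integer(0)    # ligase indices hovering
  poised <- 0L                  # ligase index carrying the synapsis hazard
  synapsed <- FALSE
  synapsis_time <- NA_real_
  t <- 0

  add_ligase <- function(kind, end, t0) {
    if (n_lig == cap) grow()
    n_lig <<- n_lig + 1L
    lig_kind[n_lig] <<- kind; lig_end[n_lig] <<- end
    lig_comp[n_lig] <<- draw_component(model)
    lig_on[n_lig] <<- t0; lig_surv[n_lig] <<- FALSE
    n_lig
  }

  repeat {
    free_ends <- if (synapsed) integer(0) else which(end_occ == 0L)
    n_occ <- sum(end_occ > 0L)
    arr_rates <- if (length(free_ends))
      rep(a * if (n_occ > 0L) coop else 1, length(free_ends)) else numeric(0)
    bound <- if (synapsed) integer(0) else end_occ[end_occ > 0L]
    dep_bound <- if (length(bound)) dep_rate[lig_comp[bound]] else numeric(0)
    if (length(bound) == 2L) dep_bound <- dep_bound * model$bridge_stability
    dep_hover <- if (length(active_hover)) dep_rate[lig_comp[active_hover]] else numeric(0)
    syn_rate <- if (!synapsed && poised > 0L && n_occ == 1L && end_occ[lig_end[poised]] == poised)
      h else 0
    rates <- c(arr_rates, r_hover, dep_bound, dep_hover, syn_rate)
    total <- sum(rates)
    if (total <= 0) break
    t <- t + stats::rexp(1, total)
    if (t >= duration) break
    ev <- sample.int(length(rates), 1L, prob = rates)

    n_arr <- length(arr_rates)
    if (ev <= n_arr) {                       # end-engaging arrival
      e <- free_ends[ev]
      id <- add_ligase("end", e, t)
      end_occ[e] <- id
    } else if (ev == n_arr + 1L) {           # colocalization-only arrival
      id <- add_ligase("hover", NA_integer_, t)
      active_hover <- c(active_hover, id)
    } else if (ev <= n_arr + 1L + length(dep_bound)) {   # bound-ligase departure
      id <- bound[ev - n_arr - 1L]
      lig_off[id] <- t
      was_bridge <- n_occ == 2L
      end_occ[lig_end[id]] <- 0L
      if (was_bridge) {
        poised <- end_occ[end_occ > 0L][1]   # bridge resolved: survivor poised
      } else if (poised == id) {
        poised <- 0L
      }
    } else if (ev <= n_arr + 1L + length(dep_bound) + length(dep_hover)) {
      id <- active_hover[ev - n_arr - 1L - length(dep_bound)]
      lig_off[id] <- t
      active_hover <- setdiff(active_hover, id)
    } else {                                 # synapsis
      synapsed <- TRUE
      synapsis_time <- t
      lig_surv[poised] <- TRUE
      end_occ[] <- poised                    # survivor captures both ends
    }
  }

  if (n_lig > 0L) {
    idx <- seq_len(n_lig)
    off <- lig_off[idx]
    off[is.na(off)] <- duration              # still present at record end
    ligases <- data.frame(
      ligase = idx, kind = lig_kind[idx], end = lig_end[idx],
      component = lig_comp[idx], t_on = lig_on[idx], t_off = off,
      survivor = lig_surv[idx])
  } else {
    ligases <- data.frame(ligase = integer(0), kind = character(0),
                          end = integer(0), component = integer(0),
                          t_on = numeric(0), t_off = numeric(0),
                          survivor = logical(0))
  }
  structure(list(ligases = ligases, synapsis_time = synapsis_time,
                 duration = duration), class = "ground_truth")
}

#' Ground-truth end-occupancy fractions
#'
#' Time-weighted fractions of pre-synapsis time spent with neither, one or
#' both DNA ends ligase-engaged, pooled across molecules. With
#' `labeled_only = TRUE` (requires rendered truth carrying labeling flags)
#' only Cy7-labeled ligases count, matching what a FRET-based classifier can
#' see.
#'
#' @param truth A `ground_truth_set`.
#' @param labeled_only Count only labeled ligases.
#' @return Named numeric vector (`neither`, `one`, `both`), in percent.
#' @export
truth_occupancy_fractions <- function(truth, labeled_only = FALSE) {
  tot <- c(neither = 0, one = 0, both = 0)
  for (gt in truth) {
    t_end <- if (is.na(gt$synapsis_time)) gt$duration else gt$synapsis_time
    lg <- gt$ligases
    lg <- lg[lg$kind == "end" & lg$t_on < t_end, , drop = FALSE]
    if (labeled_only) {
      if (is.null(lg$labeled)) stop("truth has no labeling flags; render first")
      lg <- lg[lg$labeled, , drop = FALSE]
    }
    brk <- sort(unique(c(0, t_end, pmin(lg$t_on, t_end), pmin(lg$t_off, t_end))))
    if (length(brk) < 2) { tot["neither"] <- tot["neither"] + t_end; next }
    mid <- (brk[-1] + brk[-length(brk)]) / 2
    len <- diff(brk)
    for (k in seq_along(mid)) {
      n <- sum(lg$t_on <= mid[k] & lg$t_off > mid[k])
      cat_k <- min(n, 2L) + 1L
      tot[cat_k] <- tot[cat_k] + len[k]
    }
  }
  100 * tot / sum(tot)
}

#' Simulate a filter-binding dose series
#'
#' Fraction of DNA bound follows the one-site isotherm `c / (c + kd)` with
#' additive Gaussian noise, clipped to `[0, 1]` (membrane counting cannot
#' produce negative or >100% binding).
#'
#' @param kd Dissociation constant (molar), > 0.
#' @param concentrations Protein concentrations (molar), descending or
#'   ascending 2-fold series; all > 0.
#' @param noise_sd Noise standard deviation on the bound fraction.
#' @param replicates Number of replicate series.
#' @param seed Integer seed.
#' @return A `binding_curve` data frame with columns `concentration`,
#'   `replicate`, `fraction_bound`; `kd` attached as attribute `kd_true`.
#' @export
simulate_filter_binding <- function(kd, concentrations, noise_sd = 0.02,
                                    replicates = 3, seed = 1) {
  if (!is.finite(kd) || kd <= 0) stop("simulate_filter_binding: kd must be > 0")
  if (any(concentrations <= 0)) stop("simulate_filter_binding: concentrations must be positive")
  set.seed(derive_seed(seed, 0L, 5L))
  grid <- expand.grid(concentration = concentrations,
                      replicate = seq_len(replicates))
  f <- grid$concentration / (grid$concentration + kd)
  if (noise_sd > 0) f <- f + stats::rnorm(nrow(grid), 0, noise_sd)
  grid$fraction_bound <- pmin(pmax(f, 0), 1)
  structure(grid, class = c("binding_curve", "data.frame"), kd_true = kd)
}
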