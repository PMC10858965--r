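#' Demultiplex interleaved-excitation frames into per-cycle channel streams
#'
#' Each cycle position of the acquisition scheme maps to exactly one labeled
#' stream (I3, I35, I37, I5, I57, I7 as supported by the cycle). Streams are
#' returned cycle-aligned: row k holds the channels of cycle k, so per-cycle
#' FRET efficiencies combine values acquired within one cycle. A trailing
#' partial cycle is dropped with a warning.
#'
#' @param molecule A rendered molecule (`list(raw, frame_time)`) from a
#'   `trajectory_set`, or a bare numeric matrix with columns named by channel.
#' @param scheme The [acquisition_scheme()] used for acquisition.
#' @return A `channel_streams` object: `values` and `times` matrices
#'   (cycles x channels), `period` (s) and `channels`.
#' @export
demultiplex <- function(molecule, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  raw <- if (is.matrix(molecule)) molecule else molecule$raw
  frame_time <- if (is.matrix(molecule)) {
    (seq_len(nrow(molecule)) - 0.5) * scheme$frame_period
  } else molecule$frame_time
  L <- length(scheme$cycle)
  n_frames <- nrow(raw)
  n_cycles <- n_frames %/% L
  if (n_cycles < 1) stop("demultiplex: input shorter than one full cycle")
  if (n_frames %% L != 0)
    warning(sprintf("demultiplex: dropping trailing partial cycle (%d frames)",
                    n_frames %% L))
  chans <- names(scheme$channels)
  if (!all(chans %in% colnames(raw)))
    stop("demultiplex: unknown channel labels; raw matrix must carry channel columns")
  vals <- matrix(NA_real_, n_cycles, length(chans), dimnames = list(NULL, chans))
  tims <- vals
  for (ch in chans) {
    p <- scheme$channels[[ch]]$pos
    rows <- (seq_len(n_cycles) - 1L) * L + p
    vals[, ch] <- raw[rows, ch]
    tims[, ch] <- frame_time[rows]
  }
  structure(list(values = vals, times = tims,
                 period = L * scheme$frame_period, channels = chans),
            class = "channel_streams")
}

#' Correct channel streams for bleed-through, direct excitation and gamma
#'
#' Applies, in order: donor bleed-through subtraction, direct-excitation
#' subtraction (referenced to the same dye's direct-excitation stream from
#' the same cycle), then gamma scaling of the donor channels. With the
#' coefficients used by the forward model this inverts the rendering
#' crosstalk exactly (per cycle). Negative corrected intensities are
#' retained. Apparent FRET efficiencies are computed per cycle with the
#' two- or three-color formulas, masked (NA, never clipped) where a
#' denominator is not positive or a required dye has bleached.
#'
#' @param streams A `channel_streams` object from [demultiplex()].
#' @param params A [crosstalk_params()] object, or a list
#'   `list(matrix = M, gamma = c(g3, g5))` giving an explicit invertible
#'   crosstalk matrix over the six canonical channels.
#' @param masks Optional logical matrix (cycles x dyes, columns `cy3b`,
#'   `cy5`) of pre-bleach validity flags; see [masks_from_truth()].
#' @return A `corrected_trajectory`: corrected `values`, efficiencies
#'   (`E35`, and `E37`/`E57` when the stream set supports them), `times`,
#'   `period`, `masks`, and the echoed `params`.
#' @export
correct_intensities <- function(streams, params, masks = NULL) {
  stopifnot(inherits(streams, "channel_streams"))
  v <- streams$values
  ch <- colnames(v)
  corr <- v
  if (inherits(params, "crosstalk_params")) {
    b <- params$beta; d <- params$delta; g <- params$gamma
    if (any(g <= 0)) stop("correct_intensities: gamma must be > 0")
    ref5 <- if ("I5" %in% ch) v[, "I5"] else 0
    ref7 <- if ("I7" %in% ch) v[, "I7"] else 0
    if ("I35" %in% ch) corr[, "I35"] <- v[, "I35"] - b[["b35"]] * v[, "I3"] - d[["d35"]] * ref5
    if ("I37" %in% ch) corr[, "I37"] <- v[, "I37"] - b[["b37"]] * v[, "I3"] - d[["d37"]] * ref7
    if ("I57" %in% ch) corr[, "I57"] <- v[, "I57"] - b[["b57"]] * v[, "I5"] - d[["d57"]] * ref7
    if ("I3" %in% ch) corr[, "I3"] <- g[["g3"]] * v[, "I3"]
    if ("I5" %in% ch) corr[, "I5"] <- g[["g5"]] * v[, "I5"]
  } else if (is.list(params) && !is.null(params$matrix)) {
    M <- params$matrix
    if (is.null(dimnames(M)))
      dimnames(M) <- list(c("I3", "I35", "I37", "I5", "I57", "I7"),
                          c("I3", "I35", "I37", "I5", "I57", "I7"))
    M <- M[ch, ch, drop = FALSE]
    if (abs(det(M)) < 1e-12) stop("correct_intensities: singular crosstalk matrix")
    corr <- t(solve(M, t(v)))
    colnames(corr) <- ch
    g <- if (!is.null(params$gamma)) params$gamma else c(g3 = 1, g5 = 1)
    if ("I3" %in% ch) corr[, "I3"] <- g[["g3"]] * corr[, "I3"]
    if ("I5" %in% ch) corr[, "I5"] <- g[["g5"]] * corr[, "I5"]
  } else stop("correct_intensities: params must be crosstalk_params or list(matrix=, gamma=)")

  three_color <- all(c("I3", "I35", "I37", "I5", "I57") %in% ch)
  if (three_color) {
    ef <- fret_three_color(corr[, "I3"], corr[, "I35"], corr[, "I37"],
                           corr[, "I5"], corr[, "I57"])
  } else {
    ef <- list(E35 = fret_two_color(corr[, "I3"], corr[, "I35"]))
  }
  if (!is.null(masks)) {
    bad3 <- !masks[, "cy3b"]
    bad5 <- if ("cy5" %in% colnames(masks)) !masks[, "cy5"] else FALSE
    ef$E35[bad3 | bad5] <- NA_real_
    if (three_color) {
      ef$E37[bad3] <- NA_real_
      ef$E57[bad5] <- NA_real_
    }
  }
  structure(list(values = corr, efficiencies = ef, times = streams$times,
                 period = streams$period, masks = masks, params = params),
            class = "corrected_trajectory")
}

#' Two-color apparent FRET efficiency
#'
#' `E35 = I35 / (I3 + I35)`, masked (NA) where the denominator is not
#' positive. Values outside `[0, 1]` arising from noise are retained.
#'
#' @param I3,I35 Corrected donor and acceptor intensities under donor
#'   excitation (vectors).
#' @return Numeric vector of efficiencies.
#' @export
fret_two_color <- function(I3, I35) {
  den <- I3 + I35
  ifelse(is.finite(den) & den > 0, I35 / den, NA_real_)
}

#' Three-color apparent FRET efficiencies
#'
#' `E35 = I35 / (I3 + I35 + I37)`, `E37 = I37 / (I3 + I35 + I37)`,
#' `E57 = I57 / (I5 + I57)`; each masked (NA) where its denominator is not
#' positive. For non-negative inputs `E35 + E37 <= 1`.
#'
#' @param I3,I35,I37 Corrected intensities under 532 nm excitation.
#' @param I5,I57 Corrected intensities under 641 nm excitation.
#' @return A list with components `E35`, `E37`, `E57`.
#' @export
fret_three_color <- function(I3, I35, I37, I5, I57) {
  den3 <- I3 + I35 + I37
  den5 <- I5 + I57
  ok3 <- is.finite(den3) & den3 > 0
  ok5 <- is.finite(den5) & den5 > 0
  list(E35 = ifelse(ok3, I35 / den3, NA_real_),
       E37 = ifelse(ok3, I37 / den3, NA_real_),
       E57 = ifelse(ok5, I57 / den5, NA_real_))
}

#' Per-cycle pre-bleach validity masks from the truth ledger
#'
#' @param truth_mol A rendered `ground_truth` entry (carrying substrate
#'   bleach times).
#' @param streams The molecule's `channel_streams`.
#' @return Logical matrix (cycles x `cy3b`, `cy5`).
#' @export
masks_from_truth <- function(truth_mol, streams) {
  tc <- rowMeans(streams$times, na.rm = TRUE)
  b3 <- min(truth_mol$bleach_cy3b %||% Inf, na.rm = TRUE)
  b5 <- truth_mol$bleach_cy5 %||% Inf
  cbind(cy3b = tc < b3, cy5 = tc < b5)
}

#' Estimate bleed-through and direct-excitation coefficients from controls
#'
#' Least-squares estimates: `beta` from donor-only control trajectories
#' (acceptor-channel signal regressed on the donor channel) and `delta` from
#' acceptor-only controls (acceptor-under-donor-excitation regressed on the
#' direct-excitation stream).
#'
#' @param donor_only,acceptor_only `channel_streams` from control molecules
#'   carrying only the donor or only the acceptor dye.
#' @return A [crosstalk_params()] object (gamma left at 1).
#' @export
estimate_crosstalk <- function(donor_only, acceptor_only) {
  fit1 <- function(y, x) {
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 2 || stats::var(x[ok]) == 0) return(0)
    max(0, unname(stats::coef(stats::lm(y[ok] ~ x[ok] - 1))[1]))
  }
  vd <- donor_only$values
  va <- acceptor_only$values
  beta <- c(b35 = fit1(vd[, "I35"], vd[, "I3"]),
            b37 = if ("I37" %in% colnames(vd)) fit1(vd[, "I37"], vd[, "I3"]) else 0,
            b57 = if ("I57" %in% colnames(vd)) fit1(vd[, "I57"], vd[, "I5"]) else 0)
  delta <- c(d35 = fit1(va[, "I35"], va[, "I5"]),
             d37 = if (all(c("I37", "I7") %in% colnames(va))) fit1(va[, "I37"], va[, "I7"]) else 0,
             d57 = if (all(c("I57", "I7") %in% colnames(va))) fit1(va[, "I57"], va[, "I7"]) else 0)
  crosstalk_params(beta = beta, delta = delta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
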