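# Shared fixture builders. Everything is generated in code; no stored data.

# Hand-built ground truth with events at chosen times (class-compatible with
# simulate_state_paths output, before rendering).
make_truth <- function(ligases, synapsis_time = NA_real_, duration = 60) {
  if (is.null(ligases$survivor)) ligases$survivor <- FALSE
  structure(list(ligases = ligases, synapsis_time = synapsis_time,
                 duration = duration), class = "ground_truth")
}

make_truth_set <- function(..., scheme) {
  structure(list(...), class = "ground_truth_set", scheme = scheme)
}

ligase_row <- function(ligase, kind, end, t_on, t_off, component = 2L) {
  data.frame(ligase = ligase, kind = kind, end = end, component = component,
             t_on = t_on, t_off = t_off, survivor = FALSE)
}

no_ligases <- function() {
  data.frame(ligase = integer(0), kind = character(0), end = integer(0),
             component = integer(0), t_on = numeric(0), t_off = numeric(0),
             survivor = logical(0))
}

# Noise-free, bleach-free, fully labeled photophysics for exactness tests.
clean_photophysics <- function(crosstalk = crosstalk_params(), ...) {
  photophysics_model(noise_sd = 0, labeling_efficiency = 1,
                     bleach_rates = c(cy3b = 0, cy5 = 0, cy7 = 0),
                     crosstalk = crosstalk, ...)
}

# Exhaustive least-squares oracle for exactly two change points (used to
# cross-check the seeded segmentation on short traces).
brute_force_two_breaks <- function(x, min_size = 2) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  seg_rss <- function(a, b) {
    s <- cs[b + 1] - cs[a]; q <- cs2[b + 1] - cs2[a]
    q - s^2 / (b - a + 1)
  }
  best <- c(NA, NA); best_rss <- Inf
  for (k1 in seq(min_size, n - 2 * min_size)) {
    for (k2 in seq(k1 + min_size, n - min_size)) {
      rss <- seg_rss(1, k1) + seg_rss(k1 + 1, k2) + seg_rss(k2 + 1, n)
      if (rss < best_rss) { best_rss <- rss; best <- c(k1, k2) }
    }
  }
  best
}
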