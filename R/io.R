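TRAJECTORY_SCHEMA_VERSION <- "1.0"

#' Write a trajectory set to a portable per-molecule CSV container
#'
#' Layout: `metadata.json` (schema version, assay, scheme, photophysics
#' echo), `raw.csv` (long format: molecule, frame, time, channel,
#' intensity), `truth_ligases.csv` and `truth_molecules.csv` (the ground
#' truth ledger).
#'
#' @param ts A `trajectory_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory_set <- function(ts, dir) {
  stopifnot(inherits(ts, "trajectory_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema_version = TRAJECTORY_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("nhejfret")),
    assay = ts$assay,
    n_molecules = length(ts$molecules),
    scheme = list(frame_period = ts$scheme$frame_period,
                  total_duration = ts$scheme$total_duration,
                  cycle = lapply(ts$scheme$cycle, function(fr)
                    list(laser = fr$laser, bands = as.list(fr$bands)))),
    photophysics = list(donor_budget = ts$photo$donor_budget,
                        acceptor_budget = ts$photo$acceptor_budget,
                        cy7_unit = ts$photo$cy7_unit,
                        labeling_efficiency = ts$photo$labeling_efficiency,
                        noise_sd = ts$photo$noise_sd,
                        bleach_rates = as.list(ts$photo$bleach_rates),
                        beta = as.list(ts$photo$crosstalk$beta),
                        delta = as.list(ts$photo$crosstalk$delta),
                        gamma = as.list(ts$photo$crosstalk$gamma),
                        fret_levels = as.list(ts$photo$fret_levels)))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  raw_rows <- lapply(seq_along(ts$molecules), function(i) {
    m <- ts$molecules[[i]]
    idx <- which(!is.na(m$raw), arr.ind = TRUE)
    data.frame(molecule = i, frame = idx[, 1],
               time = m$frame_time[idx[, 1]],
               channel = colnames(m$raw)[idx[, 2]],
               intensity = m$raw[idx])
  })
  utils::write.csv(do.call(rbind, raw_rows), file.path(dir, "raw.csv"),
                   row.names = FALSE)
  lig <- lapply(seq_along(ts$truth), function(i) {
    lg <- ts$truth[[i]]$ligases
    if (nrow(lg)) cbind(molecule = i, lg) else NULL
  })
  utils::write.csv(do.call(rbind, lig), file.path(dir, "truth_ligases.csv"),
                   row.names = FALSE)
  mol <- do.call(rbind, lapply(seq_along(ts$truth), function(i) {
    gt <- ts$truth[[i]]
    data.frame(molecule = i, synapsis_time = gt$synapsis_time,
               duration = gt$duration,
               bleach_cy3b_1 = gt$bleach_cy3b[1],
               bleach_cy3b_2 = if (length(gt$bleach_cy3b) > 1) gt$bleach_cy3b[2] else NA,
               bleach_cy5 = gt$bleach_cy5)
  }))
  utils::write.csv(mol, file.path(dir, "truth_molecules.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a trajectory set written by [write_trajectory_set()]
#'
#' @param dir Container directory.
#' @return A `trajectory_set` (photophysics/scheme reconstructed from the
#'   metadata echo).
#' @export
read_trajectory_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  if (is.null(meta$schema_version))
    stop("read_trajectory_set: missing schema version")
  scheme <- acquisition_scheme(
    frame_period = meta$scheme$frame_period,
    cycle = lapply(meta$scheme$cycle, function(fr)
      list(laser = fr$laser, bands = unlist(fr$bands))),
    total_duration = meta$scheme$total_duration)
  ph <- meta$photophysics
  photo <- photophysics_model(
    donor_budget = ph$donor_budget, acceptor_budget = ph$acceptor_budget,
    cy7_unit = ph$cy7_unit,
    crosstalk = crosstalk_params(beta = unlist(ph$beta), delta = unlist(ph$delta),
                                 gamma = unlist(ph$gamma)),
    labeling_efficiency = ph$labeling_efficiency,
    bleach_rates = unlist(ph$bleach_rates),
    noise_sd = ph$noise_sd,
    fret_levels = unlist(ph$fret_levels))
  raw <- utils::read.csv(file.path(dir, "raw.csv"))
  lig <- utils::read.csv(file.path(dir, "truth_ligases.csv"))
  mol <- utils::read.csv(file.path(dir, "truth_molecules.csv"))
  chs <- c("I3", "I35", "I37", "I5", "I57", "I7")
  n_frames <- scheme$n_frames
  molecules <- vector("list", meta$n_molecules)
  truth <- vector("list", meta$n_molecules)
  for (i in seq_len(meta$n_molecules)) {
    sub <- raw[raw$molecule == i, ]
    m <- matrix(NA_real_, n_frames, 6, dimnames = list(NULL, chs))
    m[cbind(sub$frame, match(sub$channel, chs))] <- sub$intensity
    molecules[[i]] <- list(raw = m,
                           frame_time = (seq_len(n_frames) - 0.5) * scheme$frame_period)
    lg <- lig[lig$molecule == i, setdiff(names(lig), "molecule"), drop = FALSE]
    rownames(lg) <- NULL
    mrow <- mol[mol$molecule == i, ]
    b3 <- as.numeric(c(mrow$bleach_cy3b_1, mrow$bleach_cy3b_2))
    b3 <- b3[!is.na(b3)]
    truth[[i]] <- structure(list(ligases = lg,
                                 synapsis_time = as.numeric(mrow$synapsis_time),
                                 duration = as.numeric(mrow$duration),
                                 bleach_cy3b = b3,
                                 bleach_cy5 = as.numeric(mrow$bleach_cy5),
                                 molecule = i),
                            class = "ground_truth")
  }
  structure(list(molecules = molecules,
                 truth = structure(truth, class = "ground_truth_set"),
                 scheme = scheme, photo = photo, assay = meta$assay),
            class = "trajectory_set")
}

#' Read a run configuration from YAML
#'
#' Recognized blocks: `preset` (kinetic preset name), `kinetics`,
#' `photophysics`, `scheme` (field overrides), `thresholds`
#' (`fret_high`, `occupancy`, `presynapsis_mask`, `synapsis_call`), `seed`.
#' Thresholds are schema-validated to lie in `[0, 1]`.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(preset = "wt", seed = 1,
                   thresholds = list(fret_high = 0.1, occupancy = 0.25,
                                     presynapsis_mask = 0.15, synapsis_call = 0.3))
  cfg <- utils::modifyList(defaults, cfg)
  th <- unlist(cfg$thresholds)
  if (any(!is.finite(th)) || any(th < 0) || any(th > 1))
    stop("read_run_config: thresholds must lie in [0, 1]")
  valid <- c("wt", "mdbd1", "mdbd2", "mdbd1+2", "ddbd", "dn-brct")
  if (!cfg$preset %in% valid)
    stop(sprintf("read_run_config: unknown preset '%s' (valid: %s)",
                 cfg$preset, paste(valid, collapse = ", ")))
  structure(cfg, class = "run_config")
}

#' Serialize events or fit summaries
#'
#' @param x A data frame (written as CSV) or list/fit object (written as
#'   JSON with the package version attached).
#' @param path Output file path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (grepl("[.]csv$", path)) {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    payload <- list(package_version = as.character(utils::packageVersion("nhejfret")),
                    results = strip_classes(x))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", force = TRUE)
  }
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}
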