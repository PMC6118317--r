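#' Quantify every well of a plate image set
#'
#' Runs \code{\link{quantify_well}} over all frame pairs of the set and
#' returns one mobility record per (well, timepoint).
#'
#' @param set A \code{plate_image_set}.
#' @param params A \code{\link{seg_params}}.
#' @param verbose Print a summary line with valid/invalid counts.
#' @return Data frame: well, time_min, fms, moving_px, total_px, valid.
#' @export
quantify_plate <- function(set, params = seg_params(), verbose = FALSE) {
  stopifnot(inherits(set, "plate_image_set"))
  fp <- set$frame_pairs
  rows <- vector("list", nrow(fp))
  for (i in seq_len(nrow(fp))) {
    frames <- read_frame_pair(set, fp$well[i], fp$timepoint_index[i])
    q <- quantify_well(frames$frame1, frames$frame2, params)
    rows[[i]] <- data.frame(
      well = fp$well[i],
      time_min = fp$timepoint_index[i] * set$cadence_min,
      fms = q$fms, moving_px = q$moving_px, total_px = q$total_px,
      valid = q$valid, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  rec <- rec[order(rec$well, rec$time_min), ]
  rownames(rec) <- NULL
  if (verbose) {
    message(sum(rec$valid), " valid / ", sum(!rec$valid),
            " invalid well-timepoints quantified")
  }
  rec
}

#' Read a run configuration file
#'
#' One YAML file holds every numeric parameter of a run so results are
#' reproducible: segmentation parameters (under \code{segmentation:}),
#' \code{cadence_min}, \code{adult_mode}, \code{control_floor} and
#' \code{seed}. Missing keys take the package defaults. Adult mode
#' enables the egg filter and therefore requires a positive
#' \code{min_object_px}.
#'
#' @param path YAML file, or NULL for all defaults.
#' @return List with \code{params} (a \code{\link{seg_params}}),
#'   \code{cadence_min}, \code{adult_mode}, \code{control_floor},
#'   \code{seed}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  seg <- do.call(seg_params, modifyList(
    list(), if (is.null(cfg$segmentation)) list() else cfg$segmentation))
  adult <- isTRUE(cfg$adult_mode)
  if (adult && seg$min_object_px == 0) {
    seg$min_object_px <- 150L  # default egg-exclusion size in adult mode
  }
  list(params = seg,
       cadence_min = if (is.null(cfg$cadence_min)) 5 else cfg$cadence_min,
       adult_mode = adult,
       control_floor = if (is.null(cfg$control_floor)) 0.05 else
         cfg$control_floor,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Quantify command: plate directory + plate map -> results CSV
#'
#' @param input Plate image directory.
#' @param plate_map_path Plate-map CSV.
#' @param out Output results CSV.
#' @param config Optional run-config YAML path.
#' @param adult_mode Enable the egg (small-object) filter.
#' @param min_object_px Egg-filter threshold when adult mode is on.
#' @return Invisibly, the results data frame.
#' @export
run_quantify <- function(input, plate_map_path, out, config = NULL,
                         adult_mode = FALSE, min_object_px = 150) {
  rc <- read_run_config(config)
  if (adult_mode) {
    rc$params$min_object_px <- as.integer(min_object_px)
  }
  pm <- read_plate_map(plate_map_path)
  set <- scan_image_directory(input, cadence_min = rc$cadence_min)
  rec <- quantify_plate(set, rc$params, verbose = TRUE)
  write_results(rec, pm, out)
}

#' Fit command: results CSV -> dose-response fits CSV
#'
#' @param results_path Results CSV from \code{\link{run_quantify}}.
#' @param out Output fits CSV.
#' @param time_min Timepoint of the dose-response slice; default last.
#' @param model Optional model override ("logistic3"/"exponential").
#' @param control_floor Control floor for normalization.
#' @return Invisibly, the fits data frame.
#' @export
run_fit <- function(results_path, out, time_min = NULL, model = NULL,
                    control_floor = 0.05) {
  res <- read_results(results_path)
  traces <- normalize_to_controls(res, control_floor = control_floor)
  drug <- traces[traces$dose > 0, , drop = FALSE]
  if (!nrow(drug)) {
    warning("no drug-treated conditions to fit; writing empty table")
    fits <- data.frame()
  } else {
    fits <- fit_dose_response(drug, time_min = time_min, model = model)
  }
  utils::write.csv(fits, out, row.names = FALSE, na = "")
  invisible(fits)
}

#' Recovery command: results CSV -> proportional recovery scores CSV
#'
#' @param results_path Results CSV.
#' @param out Output CSV (condition, score, fms_max_paralysis,
#'   fms_after_recovery, defined).
#' @param control_floor Control floor for normalization.
#' @return Invisibly, the recovery data frame.
#' @export
run_recovery <- function(results_path, out, control_floor = 0.05) {
  res <- read_results(results_path)
  traces <- normalize_to_controls(res, control_floor = control_floor)
  key <- interaction(traces$compound, traces$dose, traces$strain,
                     traces$stage, drop = TRUE)
  rows <- lapply(split(traces, key), function(g) {
    g <- g[order(g$time_min), ]
    rec <- proportional_recovery(g$time_min, g$fms_norm)
    data.frame(compound = g$compound[1], dose = g$dose[1],
               strain = g$strain[1], stage = g$stage[1],
               score = rec$score,
               fms_max_paralysis = rec$fms_max_paralysis,
               fms_after_recovery = rec$fms_after_recovery,
               defined = rec$defined, stringsAsFactors = FALSE)
  })
  out_df <- do.call(rbind, rows)
  rownames(out_df) <- NULL
  utils::write.csv(out_df, out, row.names = FALSE, na = "")
  invisible(out_df)
}
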