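#' Read a plate map CSV
#'
#' The plate map assigns each well a compound, dose, strain, developmental
#' stage and control flag. Required columns: \code{well} (A01--H12 style),
#' \code{compound}, \code{dose} (non-negative number), \code{unit},
#' \code{strain}, \code{stage} (L1|L2|L3|L4|adult), \code{is_control}
#' (logical; drug-free well).
#'
#' @param path CSV file path.
#' @return Data frame with validated columns.
#' @export
read_plate_map <- function(path) {
  pm <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("well", "compound", "dose", "unit", "strain", "stage",
                "is_control")
  missing_cols <- setdiff(required, names(pm))
  if (length(missing_cols)) {
    stop("plate map missing columns: ", paste(missing_cols, collapse = ", "))
  }
  pm$is_control <- as.logical(pm$is_control)
  validate_plate_map(pm)
  pm
}

validate_plate_map <- function(pm) {
  if (anyDuplicated(pm$well)) {
    stop("duplicate well ids in plate map: ",
         paste(unique(pm$well[duplicated(pm$well)]), collapse = ", "))
  }
  if (!all(grepl("^[A-H](0[1-9]|1[0-2])$", pm$well))) {
    bad <- pm$well[!grepl("^[A-H](0[1-9]|1[0-2])$", pm$well)]
    stop("malformed well ids (expect A01-H12): ",
         paste(bad, collapse = ", "))
  }
  if (any(pm$dose < 0)) stop("negative dose in plate map")
  bad_dose <- !pm$is_control & pm$dose <= 0
  if (any(bad_dose)) {
    stop("non-control wells with dose <= 0: ",
         paste(pm$well[bad_dose], collapse = ", "))
  }
  # units must be uniform within a compound series
  non_ctrl <- pm[!pm$is_control, , drop = FALSE]
  if (nrow(non_ctrl)) {
    n_units <- tapply(non_ctrl$unit, non_ctrl$compound,
                      function(u) length(unique(u)))
    if (any(n_units > 1)) {
      stop("mixed dose units within compound(s): ",
           paste(names(n_units)[n_units > 1], collapse = ", "))
    }
  }
  invisible(pm)
}

#' Build a standard plate map in code
#'
#' Convenience constructor for simulated plates: lays out wells row by
#' row (A01, A02, ...), assigning the given conditions.
#'
#' @param wells Character vector of well ids.
#' @param compound,dose,unit,strain,stage,is_control Vectors recycled to
#'   \code{length(wells)}.
#' @return Plate-map data frame.
#' @export
make_plate_map <- function(wells, compound = "compoundX", dose = 1,
                           unit = "mM", strain = "N2", stage = "L1",
                           is_control = FALSE) {
  pm <- data.frame(well = wells,
                   compound = rep_len(compound, length(wells)),
                   dose = rep_len(dose, length(wells)),
                   unit = rep_len(unit, length(wells)),
                   strain = rep_len(strain, length(wells)),
                   stage = rep_len(stage, length(wells)),
                   is_control = rep_len(is_control, length(wells)),
                   stringsAsFactors = FALSE)
  validate_plate_map(pm)
  pm
}

#' All 96 well ids of a standard plate
#' @return Character vector A01 ... H12, row-major.
#' @export
well_ids_96 <- function() {
  as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
}

#' Scan a plate image directory
#'
#' Expects the canonical layout: one subfolder per timepoint named
#' \code{t0000}, \code{t0001}, ... each holding grayscale TIFFs named
#' \code{{WellID}_f1.tif} and \code{{WellID}_f2.tif}. Wells with a
#' missing frame at a timepoint are excluded from that timepoint with a
#' warning rather than aborting the plate.
#'
#' @param root Plate directory.
#' @param cadence_min Minutes between consecutive timepoint indices
#'   (default 5, the standard acquisition loop over 3 h).
#' @return A \code{plate_image_set}: list with \code{root},
#'   \code{timepoints_min}, \code{wells}, \code{frame_pairs} (data frame
#'   well / timepoint_index / path1 / path2) and \code{bit_depth}.
#' @export
scan_image_directory <- function(root, cadence_min = 5) {
  if (!dir.exists(root)) stop("plate directory does not exist: ", root)
  tdirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  tdirs <- tdirs[grepl("^t[0-9]{4}$", tdirs)]
  if (!length(tdirs)) stop("no timepoint subfolders (t0000...) in ", root)
  tidx <- sort(as.integer(sub("^t", "", tdirs)))

  pairs <- list()
  all_wells <- character(0)
  bit_depths <- integer(0)
  for (ti in tidx) {
    tdir <- file.path(root, sprintf("t%04d", ti))
    files <- list.files(tdir, pattern = "\\.tif{1,2}$", ignore.case = TRUE)
    m <- regmatches(files,
                    regexec("^([A-H][0-9]{2})_f([12])\\.tiff?$", files))
    bad <- lengths(m) == 0
    if (any(bad)) {
      warning("skipping unparseable filename(s) in ", tdir, ": ",
              paste(files[bad], collapse = ", "))
    }
    ok <- files[!bad]
    wells <- vapply(m[!bad], `[`, "", 2)
    frames <- vapply(m[!bad], `[`, "", 3)
    for (w in unique(wells)) {
      f1 <- ok[wells == w & frames == "1"]
      f2 <- ok[wells == w & frames == "2"]
      if (length(f1) == 1 && length(f2) == 1) {
        pairs[[length(pairs) + 1L]] <- data.frame(
          well = w, timepoint_index = ti,
          path1 = file.path(tdir, f1), path2 = file.path(tdir, f2),
          stringsAsFactors = FALSE)
        all_wells <- union(all_wells, w)
      } else {
        warning("well ", w, " at t", sprintf("%04d", ti),
                " lacks a complete frame pair; excluded")
      }
    }
  }
  if (!length(pairs)) stop("no complete frame pairs found under ", root)
  fp <- do.call(rbind, pairs)
  fp <- fp[order(fp$well, fp$timepoint_index), , drop = FALSE]
  rownames(fp) <- NULL

  # check for a uniform bit depth on a sample of files
  sample_paths <- fp$path1[!duplicated(fp$timepoint_index)]
  for (p in utils::head(sample_paths, 10)) {
    info <- attr(tiff::readTIFF(p, info = TRUE), "bits.per.sample")
    if (!is.null(info)) bit_depths <- union(bit_depths, as.integer(info))
  }
  if (length(bit_depths) > 1) {
    stop("mixed bit depths in plate: ",
         paste(sort(bit_depths), collapse = ", "))
  }

  structure(list(root = root,
                 timepoints_min = tidx * cadence_min,
                 timepoint_indices = tidx,
                 cadence_min = cadence_min,
                 wells = sort(all_wells),
                 frame_pairs = fp,
                 bit_depth = if (length(bit_depths)) bit_depths else NA_integer_),
            class = "plate_image_set")
}

#' @export
print.plate_image_set <- function(x, ...) {
  cat("plate_image_set:", length(x$wells), "wells,",
      length(x$timepoint_indices), "timepoints,",
      nrow(x$frame_pairs), "frame pairs,",
      "bit depth", x$bit_depth, "\n")
  invisible(x)
}

#' Read the two frames of a well at a timepoint
#'
#' Frames are rescaled to a common [0,1] intensity range regardless of
#' the stored bit depth (the \pkg{tiff} reader already maps 8- and
#' 16-bit samples onto [0,1]).
#'
#' @param set A \code{plate_image_set} from
#'   \code{\link{scan_image_directory}}.
#' @param well_id Well id, e.g. "B07".
#' @param timepoint_index 0-based timepoint index.
#' @return List of two numeric matrices \code{frame1}, \code{frame2}.
#' @export
read_frame_pair <- function(set, well_id, timepoint_index) {
  stopifnot(inherits(set, "plate_image_set"))
  fp <- set$frame_pairs
  row <- fp[fp$well == well_id & fp$timepoint_index == timepoint_index, ]
  if (nrow(row) != 1) {
    stop("no frame pair for well ", well_id, " at timepoint ",
         timepoint_index)
  }
  f1 <- load_gray_tiff(row$path1)
  f2 <- load_gray_tiff(row$path2)
  if (!identical(dim(f1), dim(f2))) {
    stop("frame shape mismatch for well ", well_id, " at timepoint ",
         timepoint_index, ": ", paste(dim(f1), collapse = "x"), " vs ",
         paste(dim(f2), collapse = "x"))
  }
  list(frame1 = f1, frame2 = f2)
}

# Single-plane grayscale TIFF -> numeric matrix in [0,1].
load_gray_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1] else
      stop("multi-channel TIFF not supported: ", path)
  }
  img
}

#' Write mobility records joined with the plate map
#'
#' Long-format results CSV, one row per (well, timepoint), ordered by
#' well then time. Invalid wells keep their row with an empty \code{fms}
#' field and \code{valid = FALSE}.
#'
#' @param records Data frame with columns well, time_min, fms, moving_px,
#'   total_px, valid (as produced by \code{\link{quantify_plate}}).
#' @param plate_map Plate-map data frame covering every recorded well.
#' @param out Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_results <- function(records, plate_map, out) {
  stopifnot(nrow(records) > 0)
  unknown <- setdiff(unique(records$well), plate_map$well)
  if (length(unknown)) {
    stop("records reference wells absent from plate map: ",
         paste(unknown, collapse = ", "))
  }
  merged <- merge(records, plate_map, by = "well", sort = FALSE)
  cols <- c("well", "time_min", "compound", "dose", "unit", "strain",
            "stage", "is_control", "fms", "moving_px", "total_px", "valid")
  merged <- merged[order(merged$well, merged$time_min), cols]
  rownames(merged) <- NULL
  utils::write.csv(merged, out, row.names = FALSE, na = "")
  invisible(merged)
}

#' Read a results CSV written by \code{\link{write_results}}
#' @param path CSV path.
#' @return Data frame with typed columns (fms numeric with NA for
#'   invalid wells, is_control and valid logical).
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  df$is_control <- as.logical(df$is_control)
  df$valid <- as.logical(df$valid)
  df$fms <- as.numeric(df$fms)
  df
}
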