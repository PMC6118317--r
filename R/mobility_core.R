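#' Segmentation parameters for well-image analysis
#'
#' Bundles the tunable parameters of the per-well image pipeline. The
#' defaults were calibrated once against the synthetic well generator
#' (see the methods vignette) and are frozen; they can be overridden per
#' run or via a plate config file.
#'
#' @param blur_sigma Standard deviation (pixels) of the Gaussian blur
#'   applied to each frame before any other processing. 0 disables.
#' @param adaptive_block Side length (pixels, odd, >= 3) of the local
#'   window used by the adaptive (local-mean) threshold on the Sobel
#'   edge image.
#' @param adaptive_offset Intensity offset added to the local mean; a
#'   pixel is foreground when its edge magnitude exceeds local mean +
#'   offset. Units are the [0,1] intensity scale.
#' @param closing_iterations Number of binary-closing passes (3x3 box
#'   structuring element) used to fill worm bodies between their edges.
#' @param diff_threshold Absolute intensity difference above which a
#'   pixel of the frame-difference image is called moving.
#' @param mask_radius_frac Radius of the centred circular well mask, as a
#'   fraction of min(nrow, ncol)/2. Pixels outside are discarded so well
#'   rims do not register as objects.
#' @param min_object_px Connected components (8-connectivity) of the
#'   reference mask smaller than this many pixels are removed; used in
#'   adult mode to exclude eggs. 0 disables the filter.
#' @param min_worm_pixels Minimum reference-mask size for a well to be
#'   considered valid; below this the FMS is undefined (empty well).
#'
#' @return An object of class \code{seg_params} (a named list).
#' @export
seg_params <- function(blur_sigma = 1,
                       adaptive_block = 51,
                       adaptive_offset = 0.05,
                       closing_iterations = 2,
                       diff_threshold = 0.01,
                       mask_radius_frac = 0.95,
                       min_object_px = 0,
                       min_worm_pixels = 50) {
  stopifnot(blur_sigma >= 0,
            adaptive_block >= 3, adaptive_block %% 2 == 1,
            adaptive_offset >= 0,
            closing_iterations >= 0,
            diff_threshold > 0,
            mask_radius_frac > 0, mask_radius_frac <= 1,
            min_object_px >= 0,
            min_worm_pixels >= 0)
  structure(list(blur_sigma = blur_sigma,
                 adaptive_block = as.integer(adaptive_block),
                 adaptive_offset = adaptive_offset,
                 closing_iterations = as.integer(closing_iterations),
                 diff_threshold = diff_threshold,
                 mask_radius_frac = mask_radius_frac,
                 min_object_px = as.integer(min_object_px),
                 min_worm_pixels = as.integer(min_worm_pixels)),
            class = "seg_params")
}

#' Gaussian pre-smoothing of a frame
#'
#' @param frame Numeric matrix of intensities in [0,1].
#' @param blur_sigma Gaussian standard deviation in pixels; 0 returns the
#'   input unchanged.
#' @return Smoothed matrix of the same shape.
#' @export
preprocess <- function(frame, blur_sigma = 1) {
  stopifnot(is.matrix(frame), is.numeric(frame), blur_sigma >= 0)
  if (blur_sigma == 0) return(frame)
  out <- EBImage::gblur(frame, sigma = blur_sigma)
  matrix(as.numeric(out), nrow(frame), ncol(frame))
}

# Sobel gradient magnitude. EBImage has no Sobel primitive; the two 3x3
# kernels are applied by linear filtering and combined as sqrt(gx^2+gy^2).
sobel_magnitude <- function(frame) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(frame, kx)
  gy <- EBImage::filter2(frame, t(kx))
  m <- sqrt(gx^2 + gy^2)
  matrix(as.numeric(m), nrow(frame), ncol(frame))
}

# Centred circular mask: TRUE inside radius_frac * min(dim)/2.
circular_mask <- function(shape, radius_frac) {
  nr <- shape[1]; nc <- shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r <- radius_frac * min(nr, nc) / 2
  dy <- (seq_len(nr) - cy)^2
  dx <- (seq_len(nc) - cx)^2
  outer(dy, dx, `+`) <= r^2
}

#' Build the non-background reference mask for a well
#'
#' Segments worm bodies from a single (pre-smoothed) frame: Sobel edge
#' detection, adaptive local-mean threshold, repeated binary closing to
#' fill the area between a worm's two edges, and a circular mask that
#' removes the well rim.
#'
#' @param frame Preprocessed numeric matrix in [0,1].
#' @param params A \code{\link{seg_params}} object.
#' @return Logical matrix: TRUE for non-background (worm) pixels.
#' @export
build_reference_mask <- function(frame, params = seg_params()) {
  stopifnot(is.matrix(frame), inherits(params, "seg_params"))
  edges <- sobel_magnitude(frame)
  w <- (params$adaptive_block - 1L) / 2L
  bin <- EBImage::thresh(edges, w = w, h = w, offset = params$adaptive_offset)
  if (params$closing_iterations > 0) {
    kern <- EBImage::makeBrush(3, shape = "box")
    for (i in seq_len(params$closing_iterations)) {
      bin <- EBImage::closing(bin, kern)
    }
  }
  mask <- matrix(as.numeric(bin) > 0.5, nrow(frame), ncol(frame))
  mask & circular_mask(dim(frame), params$mask_radius_frac)
}

#' Remove small connected components from a binary mask
#'
#' Drops 8-connected components smaller than \code{min_object_px} pixels.
#' Used in adult mode to exclude eggs, which are far smaller than adult
#' worms, from the analysis.
#'
#' @param mask Logical matrix.
#' @param min_object_px Minimum component area to keep; 0 returns the
#'   mask unchanged.
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, min_object_px) {
  stopifnot(is.matrix(mask), min_object_px >= 0)
  if (min_object_px == 0 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_object_px)
  mask & (lab %in% keep)
}

#' Binary movement mask from a frame pair
#'
#' Thresholds the absolute difference of the two frames of a pair. The
#' result flags moved pixels from *both* parent images (a worm that moved
#' appears at its old and new positions), which is corrected downstream
#' by intersecting with the single-frame reference mask.
#'
#' @param frame1,frame2 Preprocessed numeric matrices of identical shape.
#' @param diff_threshold Absolute intensity difference above which a
#'   pixel is called moving.
#' @return Logical matrix.
#' @export
difference_mask <- function(frame1, frame2, diff_threshold = 0.04) {
  if (!identical(dim(frame1), dim(frame2))) {
    stop("frame shapes differ: ", paste(dim(frame1), collapse = "x"),
         " vs ", paste(dim(frame2), collapse = "x"))
  }
  abs(frame1 - frame2) > diff_threshold
}

#' Partition the reference mask into moving and stationary pixels
#'
#' The binary difference image is multiplied by the reference image to
#' keep movement pixels from a single frame only (correcting the double
#' counting of moved worms); stationary pixels are the reference times
#' the complement of the moving mask.
#'
#' @param diff Logical matrix from \code{\link{difference_mask}}.
#' @param reference Logical matrix from \code{\link{build_reference_mask}}.
#' @return A \code{well_masks} list with elements \code{reference},
#'   \code{moving}, \code{stationary}. By construction moving and
#'   stationary are disjoint and their union is the reference.
#' @export
partition_movement <- function(diff, reference) {
  stopifnot(identical(dim(diff), dim(reference)))
  moving <- diff & reference
  stationary <- reference & !moving
  structure(list(reference = reference, moving = moving,
                 stationary = stationary),
            class = "well_masks")
}

#' Fractional mobility score from well masks
#'
#' FMS is the ratio of movement-associated pixels to total non-background
#' pixels. Wells whose reference mask is smaller than
#' \code{min_worm_pixels} (empty or failed wells) are flagged invalid and
#' get an undefined (NA) score rather than an error.
#'
#' @param masks A \code{well_masks} object.
#' @param min_worm_pixels Validity floor on the reference-mask size.
#' @return List with \code{fms}, \code{moving_px}, \code{total_px},
#'   \code{valid}.
#' @export
fractional_mobility <- function(masks, min_worm_pixels = 50) {
  stopifnot(inherits(masks, "well_masks"))
  total_px <- sum(masks$reference)
  moving_px <- sum(masks$moving)
  valid <- total_px >= min_worm_pixels && total_px > 0
  list(fms = if (valid) moving_px / total_px else NA_real_,
       moving_px = moving_px, total_px = total_px, valid = valid)
}

#' Quantify movement in one well at one timepoint
#'
#' Full per-well pipeline: Gaussian blur on both frames, reference mask
#' from frame 1 (the designated reference frame), optional small-object
#' (egg) removal, frame differencing, partition into moving/stationary,
#' and the fractional mobility score. Deterministic for fixed inputs and
#' parameters.
#'
#' @param frame1,frame2 Numeric matrices in [0,1], identical shape.
#'   Frame 1 is the reference frame.
#' @param params A \code{\link{seg_params}} object.
#' @param return_masks If TRUE, attach the intermediate masks to the
#'   result (for inspection or debug export).
#' @return List with \code{fms}, \code{moving_px}, \code{total_px},
#'   \code{valid}, and optionally \code{masks}.
#' @export
quantify_well <- function(frame1, frame2, params = seg_params(),
                          return_masks = FALSE) {
  if (!identical(dim(frame1), dim(frame2))) {
    stop("frame shapes differ: ", paste(dim(frame1), collapse = "x"),
         " vs ", paste(dim(frame2), collapse = "x"))
  }
  f1 <- preprocess(frame1, params$blur_sigma)
  f2 <- preprocess(frame2, params$blur_sigma)
  ref <- build_reference_mask(f1, params)
  if (params$min_object_px > 0) {
    ref <- remove_small_objects(ref, params$min_object_px)
  }
  d <- difference_mask(f1, f2, params$diff_threshold)
  masks <- partition_movement(d, ref)
  res <- fractional_mobility(masks, params$min_worm_pixels)
  if (return_masks) res$masks <- masks
  res
}
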