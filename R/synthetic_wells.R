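#' Configuration for a synthetic well scene
#'
#' Describes one simulated well: a bright circular well on a dark
#' surround, containing elongated worm-shaped objects (smoothed
#' random-walk tubes of roughly constant width), an optional set of small
#' round egg objects, and additive Gaussian noise. A controllable subset
#' of worms is displaced between the two frames of the pair; displaced
#' worms land on fully disjoint positions so the ground-truth moving
#' fraction is unambiguous.
#'
#' Real wells contain on the order of 100 L1 larvae; oracle scenes
#' default to fewer, larger worms so that disjoint placement is always
#' feasible and every worm is individually resolvable.
#'
#' @param shape Raster dimensions (rows, cols).
#' @param n_worms Number of worms to render.
#' @param worm_length_px,worm_width_px Length/width ranges (min, max) in
#'   pixels; each worm draws its size uniformly from the range.
#' @param moving_fraction Fraction of worms displaced between frames
#'   (rounded to a whole number of worms).
#' @param displacement_px Magnitude of the displacement applied to moving
#'   worms. Must comfortably exceed the worm extent for disjoint
#'   placement to succeed.
#' @param n_eggs Number of small disc-shaped egg objects (static in both
#'   frames).
#' @param egg_radius_px Egg disc radius in pixels.
#' @param noise_sigma Standard deviation of additive Gaussian noise on
#'   the [0,1] intensity scale.
#' @param well_radius_frac Well radius as a fraction of min(shape)/2.
#' @param background_level,worm_level Intensities of the well interior
#'   and of worm/egg bodies. Must differ by at least 5 * noise_sigma.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A \code{scene_config} object (named list).
#' @export
scene_config <- function(shape = c(512, 512),
                         n_worms = 10,
                         worm_length_px = c(30, 50),
                         worm_width_px = c(4, 6),
                         moving_fraction = 0.5,
                         displacement_px = 60,
                         n_eggs = 0,
                         egg_radius_px = 3,
                         noise_sigma = 0.01,
                         well_radius_frac = 0.98,
                         background_level = 0.7,
                         worm_level = 0.3,
                         seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 64),
            n_worms >= 0, moving_fraction >= 0, moving_fraction <= 1,
            displacement_px > 0, n_eggs >= 0, egg_radius_px >= 1,
            noise_sigma >= 0,
            well_radius_frac > 0, well_radius_frac <= 1,
            abs(worm_level - background_level) >= 5 * noise_sigma)
  if (length(worm_length_px) == 1) worm_length_px <- rep(worm_length_px, 2)
  if (length(worm_width_px) == 1) worm_width_px <- rep(worm_width_px, 2)
  structure(list(shape = as.integer(shape), n_worms = as.integer(n_worms),
                 worm_length_px = worm_length_px,
                 worm_width_px = worm_width_px,
                 moving_fraction = moving_fraction,
                 displacement_px = displacement_px,
                 n_eggs = as.integer(n_eggs),
                 egg_radius_px = egg_radius_px,
                 noise_sigma = noise_sigma,
                 well_radius_frac = well_radius_frac,
                 background_level = background_level,
                 worm_level = worm_level,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Trace a smoothed random-walk tube and return the pixel indices of its
# footprint, or NULL if it leaves the allowed placement disc.
trace_worm_px <- function(shape, length_px, width_px, place_radius) {
  nr <- shape[1]; nc <- shape[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  # start uniformly inside the placement disc, away from its rim
  repeat {
    y0 <- stats::runif(1, cy - place_radius, cy + place_radius)
    x0 <- stats::runif(1, cx - place_radius, cx + place_radius)
    if ((y0 - cy)^2 + (x0 - cx)^2 < (0.8 * place_radius)^2) break
  }
  theta <- stats::runif(1, 0, 2 * pi)
  n_steps <- max(2L, as.integer(length_px))
  ys <- numeric(n_steps); xs <- numeric(n_steps)
  ys[1] <- y0; xs[1] <- x0
  for (i in 2:n_steps) {
    theta <- theta + stats::rnorm(1, 0, 0.10)
    ys[i] <- ys[i - 1] + sin(theta)
    xs[i] <- xs[i - 1] + cos(theta)
  }
  half_w <- width_px / 2
  if (any((ys - cy)^2 + (xs - cx)^2 > (place_radius - half_w - 1)^2)) {
    return(NULL)
  }
  # stamp a disc of radius width/2 at every path point
  r <- ceiling(half_w)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= half_w^2, , drop = FALSE]
  py <- as.vector(outer(off$dy, round(ys), `+`))
  px <- as.vector(outer(off$dx, round(xs), `+`))
  ok <- py >= 1 & py <= nr & px >= 1 & px <= nc
  unique((px[ok] - 1L) * nr + py[ok])  # column-major linear indices
}

# Dilate a set of linear pixel indices by a square margin (separation
# guard so blur/closing cannot bridge distinct objects).
dilate_px <- function(idx, shape, margin) {
  nr <- shape[1]; nc <- shape[2]
  y <- ((idx - 1L) %% nr) + 1L
  x <- ((idx - 1L) %/% nr) + 1L
  off <- expand.grid(dy = -margin:margin, dx = -margin:margin)
  py <- as.vector(outer(off$dy, y, `+`))
  px <- as.vector(outer(off$dx, x, `+`))
  ok <- py >= 1 & py <= nr & px >= 1 & px <= nc
  unique((px[ok] - 1L) * nr + py[ok])
}

#' Simulate one well-image frame pair with ground truth
#'
#' Renders two frames of the same well. Frame 2 equals frame 1 except
#' that moving worms are re-rendered at displaced, fully disjoint
#' positions and the additive noise is redrawn. Deterministic for a
#' fixed \code{cfg$seed}.
#'
#' @param cfg A \code{\link{scene_config}}.
#' @return List with \code{frame1}, \code{frame2} (numeric matrices in
#'   [0,1]) and \code{truth}: labelled worm rasters for both frames
#'   (\code{labels1}, \code{labels2}; 0 = background, k = worm k),
#'   \code{moving_ids}, \code{true_moving_fraction} (displaced frame-1
#'   worm pixels over all frame-1 worm pixels), and \code{egg_px} count.
#' @export
simulate_well_pair <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  well_r <- cfg$well_radius_frac * min(nr, nc) / 2
  # keep objects well inside the analysis mask (0.95 default) and rim
  place_radius <- 0.80 * min(nr, nc) / 2
  # separation guard: edge halos extend ~3 px beyond an object after blur
  # and Sobel banding, and closing bridges gaps up to twice its radius, so
  # nearby objects need >= 8 px of clearance to stay distinct components
  margin <- 8L

  n_moving <- round(cfg$moving_fraction * cfg$n_worms)
  occupied <- integer(0)   # dilated union of all placed footprints, both frames
  worms1 <- vector("list", cfg$n_worms)
  worms2 <- vector("list", cfg$n_worms)
  moving_ids <- integer(0)

  for (k in seq_len(cfg$n_worms)) {
    len <- stats::runif(1, cfg$worm_length_px[1], cfg$worm_length_px[2])
    wid <- stats::runif(1, cfg$worm_width_px[1], cfg$worm_width_px[2])
    placed <- FALSE
    for (try in 1:200) {
      px1 <- trace_worm_px(cfg$shape, len, wid, place_radius)
      if (is.null(px1) || any(px1 %in% occupied)) next
      if (k <= n_moving) {
        # displaced copy must be disjoint from everything incl. itself
        moved <- FALSE
        for (dtry in 1:40) {
          ang <- stats::runif(1, 0, 2 * pi)
          dy <- round(cfg$displacement_px * sin(ang))
          dx <- round(cfg$displacement_px * cos(ang))
          y <- ((px1 - 1L) %% nr) + 1L + dy
          x <- ((px1 - 1L) %/% nr) + 1L + dx
          if (any(y < 1 | y > nr | x < 1 | x > nc)) next
          cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
          if (any((y - cy)^2 + (x - cx)^2 > (place_radius - wid / 2)^2)) next
          px2 <- (x - 1L) * nr + y
          guard <- dilate_px(px1, cfg$shape, margin)
          if (any(px2 %in% occupied) || any(px2 %in% guard)) next
          worms1[[k]] <- px1; worms2[[k]] <- px2
          occupied <- c(occupied, dilate_px(px1, cfg$shape, margin),
                        dilate_px(px2, cfg$shape, margin))
          moving_ids <- c(moving_ids, k)
          moved <- TRUE
          break
        }
        if (!moved) next
      } else {
        worms1[[k]] <- px1; worms2[[k]] <- px1
        occupied <- c(occupied, dilate_px(px1, cfg$shape, margin))
      }
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place worm ", k, " without overlap after retries; ",
           "use fewer or smaller worms, or a larger scene")
    }
  }

  egg_px <- integer(0)
  if (cfg$n_eggs > 0) {
    r <- cfg$egg_radius_px
    off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
    off <- off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    for (e in seq_len(cfg$n_eggs)) {
      for (try in 1:200) {
        ey <- round(stats::runif(1, cy - place_radius, cy + place_radius))
        ex <- round(stats::runif(1, cx - place_radius, cx + place_radius))
        if ((ey - cy)^2 + (ex - cx)^2 > (place_radius - r - 1)^2) next
        py <- off$dy + ey; px <- off$dx + ex
        idx <- (px - 1L) * nr + py
        if (any(idx %in% occupied)) next
        egg_px <- c(egg_px, idx)
        occupied <- c(occupied, dilate_px(idx, cfg$shape, margin))
        break
      }
    }
  }

  base <- matrix(0.05, nr, nc)
  base[circular_mask(cfg$shape, cfg$well_radius_frac)] <- cfg$background_level

  labels1 <- matrix(0L, nr, nc)
  labels2 <- matrix(0L, nr, nc)
  f1 <- base; f2 <- base
  for (k in seq_len(cfg$n_worms)) {
    f1[worms1[[k]]] <- cfg$worm_level
    f2[worms2[[k]]] <- cfg$worm_level
    labels1[worms1[[k]]] <- k
    labels2[worms2[[k]]] <- k
  }
  if (length(egg_px)) {
    f1[egg_px] <- cfg$worm_level
    f2[egg_px] <- cfg$worm_level
  }
  if (cfg$noise_sigma > 0) {
    # noise comes from a substream derived only from the seed, so paired
    # scenes that differ in object content (e.g. with/without eggs) still
    # share the same noise field
    set.seed((cfg$seed + 777L) %% .Machine$integer.max)
    f1 <- f1 + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sigma), nr, nc)
    f2 <- f2 + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sigma), nr, nc)
  }
  f1 <- pmin(pmax(f1, 0), 1)
  f2 <- pmin(pmax(f2, 0), 1)

  total_worm_px <- sum(lengths(worms1))
  moving_px <- sum(lengths(worms1[moving_ids]))
  list(frame1 = f1, frame2 = f2,
       truth = list(labels1 = labels1, labels2 = labels2,
                    moving_ids = moving_ids,
                    true_moving_fraction =
                      if (total_worm_px > 0) moving_px / total_worm_px else 0,
                    egg_px = length(egg_px)))
}

#' Simulate a full plate image set on disk
#'
#' Writes a plate directory in the canonical layout
#' (\code{t0000/A01_f1.tif} ...), a plate-map CSV, and a ground-truth CSV
#' with the true moving fraction of every (well, timepoint).
#'
#' @param out Output directory (created if absent).
#' @param plate_map Plate-map data frame (see \code{\link{read_plate_map}}
#'   for the column contract); its wells define the plate.
#' @param n_timepoints Number of acquisition timepoints.
#' @param cadence_min Minutes between timepoints (default 5, the standard
#'   acquisition loop).
#' @param scene Base \code{\link{scene_config}}; per-well seeds are
#'   derived from \code{seed}.
#' @param moving_fractions Optional numeric matrix (wells x timepoints,
#'   rows named by well id) of true moving fractions; defaults to the
#'   scene's \code{moving_fraction} everywhere.
#' @param bit_depth 8 or 16; TIFF sample depth.
#' @param seed Master seed for the plate.
#' @return Invisibly, a list with \code{root}, \code{plate_map_csv},
#'   \code{truth_csv} and the truth data frame.
#' @export
simulate_plate <- function(out, plate_map, n_timepoints,
                           cadence_min = 5, scene = scene_config(),
                           moving_fractions = NULL, bit_depth = 8,
                           seed = 1L) {
  stopifnot(n_timepoints >= 1, bit_depth %in% c(8, 16))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  wells <- plate_map$well
  truth <- data.frame()
  counter <- 0L
  for (ti in seq_len(n_timepoints) - 1L) {
    tdir <- file.path(out, sprintf("t%04d", ti))
    dir.create(tdir, showWarnings = FALSE)
    for (w in wells) {
      counter <- counter + 1L
      cfg <- scene
      cfg$seed <- as.integer((seed * 10007L + counter) %% .Machine$integer.max)
      if (!is.null(moving_fractions)) {
        cfg$moving_fraction <- moving_fractions[w, ti + 1L]
      }
      sim <- simulate_well_pair(cfg)
      tiff::writeTIFF(sim$frame1, file.path(tdir, sprintf("%s_f1.tif", w)),
                      bits.per.sample = bit_depth)
      tiff::writeTIFF(sim$frame2, file.path(tdir, sprintf("%s_f2.tif", w)),
                      bits.per.sample = bit_depth)
      truth <- rbind(truth, data.frame(
        well = w, time_min = ti * cadence_min,
        true_moving_fraction = sim$truth$true_moving_fraction))
    }
  }
  pm_csv <- file.path(out, "plate_map.csv")
  utils::write.csv(plate_map, pm_csv, row.names = FALSE)
  truth_csv <- file.path(out, "truth.csv")
  utils::write.csv(truth, truth_csv, row.names = FALSE)
  invisible(list(root = out, plate_map_csv = pm_csv, truth_csv = truth_csv,
                 truth = truth))
}

#' Kinetic model configuration for simulated drug responses
#'
#' Two-phase kinetics emulating paralysis-then-recovery time courses:
#' normalized FMS decays exponentially (rate \code{paralysis_rate})
#' toward a dose-dependent floor, then optionally recovers toward full
#' movement after \code{recovery_onset_min} at rate \code{recovery_rate}.
#' The dose-dependent floor follows a three-parameter logistic in dose
#' with floor \code{A_true}, slope \code{B_true} and midpoint
#' \code{M_true} (the true EC50).
#'
#' @param paralysis_rate Onset rate, per minute.
#' @param A_true,B_true,M_true Logistic floor, slope and midpoint of the
#'   dose dependence.
#' @param recovery_onset_min Minutes before recovery begins.
#' @param recovery_rate Recovery rate, per minute; 0 disables recovery.
#' @param noise_sigma SD of additive Gaussian noise on normalized FMS.
#' @param seed Integer seed for the noise.
#' @return A \code{kinetics_config} object.
#' @export
kinetics_config <- function(paralysis_rate = 0.15,
                            A_true = 0.1, B_true = 5, M_true = 1,
                            recovery_onset_min = 60, recovery_rate = 0,
                            noise_sigma = 0, seed = 1L) {
  stopifnot(paralysis_rate >= 0, recovery_rate >= 0,
            A_true >= 0, A_true <= 1, B_true > 0, M_true > 0,
            noise_sigma >= 0)
  structure(list(paralysis_rate = paralysis_rate, A_true = A_true,
                 B_true = B_true, M_true = M_true,
                 recovery_onset_min = recovery_onset_min,
                 recovery_rate = recovery_rate,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "kinetics_config")
}

#' Simulate a normalized dose x time response surface
#'
#' @param kin A \code{\link{kinetics_config}}.
#' @param doses Strictly increasing concentrations.
#' @param times Strictly increasing times in minutes.
#' @return List with \code{matrix} (doses x times, dimnames set),
#'   \code{doses}, \code{times}, and \code{true} (the generating
#'   parameters and per-dose floor).
#' @export
simulate_response_surface <- function(kin, doses, times) {
  stopifnot(inherits(kin, "kinetics_config"),
            length(doses) > 0, length(times) > 0,
            all(diff(doses) > 0), all(diff(times) > 0))
  set.seed(kin$seed)
  floor_d <- logistic3_curve(doses, kin$A_true, kin$B_true, kin$M_true)
  depth <- 1 - floor_d
  m <- matrix(NA_real_, length(doses), length(times),
              dimnames = list(dose = as.character(doses),
                              time = as.character(times)))
  for (i in seq_along(doses)) {
    onset <- 1 - exp(-kin$paralysis_rate * times)
    rec <- 1 - exp(-kin$recovery_rate * pmax(0, times - kin$recovery_onset_min))
    if (kin$recovery_rate == 0) rec <- rep(0, length(times))
    v <- 1 - depth[i] * onset + depth[i] * onset * rec
    m[i, ] <- pmin(pmax(v, 0), 1.5)
  }
  if (kin$noise_sigma > 0) {
    m <- m + matrix(stats::rnorm(length(m), 0, kin$noise_sigma),
                    nrow(m), ncol(m))
    m <- pmax(m, 0)
  }
  list(matrix = m, doses = doses, times = times,
       true = list(A = kin$A_true, B = kin$B_true, M = kin$M_true,
                   floor_by_dose = floor_d))
}
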