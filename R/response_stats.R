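#' Three-parameter logistic dose-response curve
#'
#' \code{f(x) = A + (1 - A) / (1 + exp(-B (M - x)))}: upper plateau 1 at
#' low dose, lower asymptote \code{A} at high dose, midpoint \code{M}
#' (the EC50) and slope \code{B > 0}. The dose axis is linear
#' concentration, exactly as the model is written.
#'
#' @param x Doses.
#' @param A Lower asymptote in [0,1].
#' @param B Slope, per concentration unit.
#' @param M Midpoint concentration.
#' @return Predicted normalized response.
#' @export
logistic3_curve <- function(x, A, B, M) {
  A + (1 - A) / (1 + exp(-B * (M - x)))
}

#' Normalize FMS records to drug-free controls per timepoint
#'
#' For every timepoint, the mean FMS of valid control wells is computed;
#' each condition's mean FMS is divided by it. Timepoints where the
#' control mean falls below \code{control_floor} are marked missing (the
#' ratio would be dominated by noise) with a warning.
#'
#' @param results Data frame in the results-CSV layout (see
#'   \code{\link{write_results}}).
#' @param control_floor Minimum control-mean FMS for a timepoint to be
#'   usable (default 0.05).
#' @return Data frame of response traces: condition columns (compound,
#'   dose, unit, strain, stage), \code{time_min}, \code{fms_norm},
#'   \code{n_wells}.
#' @export
normalize_to_controls <- function(results, control_floor = 0.05) {
  ok <- results$valid & !is.na(results$fms)
  ctrl <- results[ok & results$is_control, , drop = FALSE]
  if (!nrow(ctrl)) stop("no valid control wells on plate")
  ctrl_mean <- tapply(ctrl$fms, ctrl$time_min, mean)
  low <- ctrl_mean < control_floor
  if (any(low)) {
    warning("control FMS below floor (", control_floor, ") at t = ",
            paste(names(ctrl_mean)[low], collapse = ", "),
            " min; those timepoints marked missing")
  }

  drug <- results[ok, , drop = FALSE]
  key <- interaction(drug$compound, drug$dose, drug$unit, drug$strain,
                     drug$stage, drug$time_min, drop = TRUE)
  agg <- do.call(rbind, lapply(split(drug, key), function(g) {
    data.frame(compound = g$compound[1], dose = g$dose[1], unit = g$unit[1],
               strain = g$strain[1], stage = g$stage[1],
               time_min = g$time_min[1],
               fms_mean = mean(g$fms), n_wells = nrow(g),
               stringsAsFactors = FALSE)
  }))
  cm <- ctrl_mean[as.character(agg$time_min)]
  agg$fms_norm <- ifelse(!is.na(cm) & cm >= control_floor,
                         agg$fms_mean / cm, NA_real_)
  agg <- agg[order(agg$compound, agg$dose, agg$time_min), ]
  rownames(agg) <- NULL
  agg[, c("compound", "dose", "unit", "strain", "stage", "time_min",
          "fms_norm", "n_wells")]
}

#' Assemble a dose x time matrix for one condition
#'
#' @param traces Normalized traces (one compound/strain/stage; one trace
#'   per dose) as returned by \code{\link{normalize_to_controls}}.
#' @return List with \code{values} (doses x times matrix, dimnames set),
#'   \code{doses}, \code{times}. Row extraction gives the kinetic trace
#'   at a fixed dose; column extraction the dose-response at a fixed
#'   time.
#' @export
build_dose_time_matrix <- function(traces) {
  stopifnot(length(unique(traces$compound)) == 1,
            length(unique(traces$strain)) == 1,
            length(unique(traces$stage)) == 1)
  doses <- sort(unique(traces$dose))
  times <- sort(unique(traces$time_min))
  per_dose_t <- tapply(traces$time_min, traces$dose, function(t)
    anyDuplicated(t) > 0)
  if (any(per_dose_t)) stop("duplicate dose/time combination in traces")
  m <- matrix(NA_real_, length(doses), length(times),
              dimnames = list(dose = as.character(doses),
                              time = as.character(times)))
  idx <- cbind(match(traces$dose, doses), match(traces$time_min, times))
  m[idx] <- traces$fms_norm
  list(values = m, doses = doses, times = times)
}

#' Fit the three-parameter logistic by least squares
#'
#' Minimizes the residual sum of squares of
#' \code{A + (1-A)/(1+exp(-B(M-x)))} with Levenberg-Marquardt from a
#' grid of starting values (A in {0, 0.25, 0.5}; M at the 25/50/75\%
#' dose quantiles; B in {0.5, 2, 10} divided by the dose range). The
#' best-RSS converged start wins; ties go to the smaller slope.
#'
#' @param doses Numeric, at least 4 distinct values.
#' @param responses Normalized responses, same length.
#' @return A \code{logistic_fit}: list with \code{A}, \code{B}, \code{M},
#'   \code{rss}, \code{converged}.
#' @export
fit_logistic3 <- function(doses, responses) {
  keep <- !is.na(responses) & !is.na(doses)
  doses <- doses[keep]; responses <- responses[keep]
  if (length(unique(doses)) < 4) {
    stop("fit_logistic3 requires at least 4 distinct doses")
  }
  scale <- diff(range(doses))
  if (scale <= 0) stop("doses must span a positive range")
  starts <- expand.grid(A = c(0, 0.25, 0.5),
                        M = stats::quantile(doses, c(0.25, 0.5, 0.75),
                                            names = FALSE),
                        B = c(0.5, 2, 10) / scale)
  m_lo <- 0.1 * min(doses); m_hi <- 10 * max(doses)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A + (1 - A) / (1 + exp(-B * (M - x))),
        data = data.frame(x = doses, y = responses),
        start = as.list(starts[i, ]),
        lower = c(A = 0, M = m_lo, B = 1e-8),
        upper = c(A = 1, M = m_hi, B = 1e6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && cf[["B"]] < best$B)) {
      best <- list(A = cf[["A"]], B = cf[["B"]], M = cf[["M"]],
                   rss = rss, converged = TRUE)
    }
  }
  # Levenberg-Marquardt can reject degenerate datasets (e.g. flat
  # plateaus) outright; a bounded quasi-Newton pass over the same start
  # grid still yields the least-squares optimum there.
  rss_fn <- function(p) {
    sum((logistic3_curve(doses, p[1], p[3], p[2]) - responses)^2)
  }
  for (i in if (is.null(best)) seq_len(nrow(starts)) else integer(0)) {
    o <- tryCatch(
      stats::optim(unlist(starts[i, ]), rss_fn, method = "L-BFGS-B",
                   lower = c(0, m_lo, 1e-8), upper = c(1, m_hi, 1e6)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$rss - 1e-12 ||
        (abs(o$value - best$rss) <= 1e-12 && o$par[3] < best$B)) {
      best <- list(A = unname(o$par[1]), B = unname(o$par[3]),
                   M = unname(o$par[2]), rss = o$value, converged = TRUE)
    }
  }
  if (is.null(best)) {
    best <- list(A = NA_real_, B = NA_real_, M = NA_real_,
                 rss = NA_real_, converged = FALSE)
  }
  structure(best, class = "logistic_fit")
}

#' Fit the exponential dose-response curve
#'
#' \code{f(x) = M exp(-x) + A} is linear in (M, A), so the least-squares
#' solution is exact via ordinary linear regression on \code{exp(-x)}.
#' Note the model has no concentration-scale parameter: \code{x} enters
#' as printed, so the fit inherits the dose unit.
#'
#' @param doses Numeric, at least 3 distinct values.
#' @param responses Same length.
#' @return An \code{exponential_fit}: list with \code{M}, \code{A},
#'   \code{rss}, \code{converged}.
#' @export
fit_exponential <- function(doses, responses) {
  keep <- !is.na(responses) & !is.na(doses)
  doses <- doses[keep]; responses <- responses[keep]
  if (length(unique(doses)) < 3) {
    stop("fit_exponential requires at least 3 distinct doses")
  }
  z <- exp(-doses)
  fit <- stats::lm(responses ~ z)
  cf <- stats::coef(fit)
  structure(list(M = unname(cf[2]), A = unname(cf[1]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE),
            class = "exponential_fit")
}

#' Choose the dose-response model from the data range
#'
#' The logistic is appropriate when the responses span both a high
#' plateau and substantial inhibition; shallow datasets fall back to the
#' exponential. An explicit override always wins.
#'
#' @param doses,responses Dose-response data.
#' @param override "logistic3" or "exponential" to force the choice.
#' @param high_plateau,deep_inhibition Range thresholds: logistic is
#'   chosen when max(response) > high_plateau and min(response) <
#'   deep_inhibition.
#' @return "logistic3" or "exponential".
#' @export
select_model <- function(doses, responses, override = NULL,
                         high_plateau = 0.8, deep_inhibition = 0.5) {
  if (!is.null(override)) {
    return(match.arg(override, c("logistic3", "exponential")))
  }
  r <- responses[!is.na(responses)]
  if (length(r) && max(r) > high_plateau && min(r) < deep_inhibition) {
    "logistic3"
  } else {
    "exponential"
  }
}

#' EC50 of a fitted logistic
#'
#' The midpoint \code{M} of the three-parameter logistic is the dose of
#' half-maximal transition between the upper plateau (1, normalized) and
#' the lower asymptote \code{A}; the fitted curve at \code{x = M} equals
#' \code{(1 + A) / 2} exactly.
#'
#' @param fit A converged \code{logistic_fit}.
#' @return The EC50 (same unit as the doses).
#' @export
ec50 <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!isTRUE(fit$converged)) stop("cannot extract EC50 from a non-converged fit")
  fit$M
}

#' Proportional recovery score of a time course
#'
#' Quantifies recovery from maximal paralysis as
#' \code{(FMS_after_recovery - FMS_at_max_paralysis) /
#' (1 - FMS_at_max_paralysis)}, where FMS after recovery is the mean
#' normalized FMS over the recovery window (default 150--180 min) and
#' maximum paralysis is the minimum over the whole trace. Undefined when
#' the trace never drops below 1 - epsilon (no paralysis to recover
#' from).
#'
#' @param times Minutes, strictly increasing.
#' @param fms_norm Normalized FMS at those times.
#' @param window Recovery window in minutes; when the assay length T
#'   differs from 180 min the default becomes (T - 30, T).
#' @param epsilon No-paralysis tolerance (default 0.05).
#' @return List with \code{score}, \code{fms_max_paralysis},
#'   \code{fms_after_recovery}, \code{defined}.
#' @export
proportional_recovery <- function(times, fms_norm, window = NULL,
                                  epsilon = 0.05) {
  stopifnot(length(times) == length(fms_norm), all(diff(times) > 0))
  t_end <- max(times)
  if (is.null(window)) {
    window <- if (abs(t_end - 180) < 1e-9) c(150, 180) else
      c(t_end - 30, t_end)
  }
  if (t_end < window[2] || min(times) > window[1]) {
    stop("trace does not cover the recovery window [", window[1], ", ",
         window[2], "] min")
  }
  ok <- !is.na(fms_norm)
  fms_min <- min(fms_norm[ok])
  in_win <- ok & times >= window[1] & times <= window[2]
  if (!any(in_win)) stop("no timepoints inside the recovery window")
  fms_rec <- mean(fms_norm[in_win])
  if (fms_min >= 1 - epsilon) {
    return(list(score = NA_real_, fms_max_paralysis = fms_min,
                fms_after_recovery = fms_rec, defined = FALSE))
  }
  list(score = (fms_rec - fms_min) / (1 - fms_min),
       fms_max_paralysis = fms_min, fms_after_recovery = fms_rec,
       defined = TRUE)
}

#' Classify the shape of a response time course
#'
#' Heuristic labelling of the multi-phase ("complex") response
#' archetypes: \code{no_effect} when the trace never drops below
#' \code{no_effect_floor}; \code{sustained_paralysis} when the recovery
#' score stays below \code{recovery_min}; \code{sustained_recovery} when
#' the final-window mean is within \code{sustain_tol} of the post-
#' paralysis maximum; \code{transient_recovery} otherwise. The thresholds
#' are this package's operational choices, exposed as arguments; they are
#' not a published classification.
#'
#' @param times,fms_norm The trace.
#' @param no_effect_floor,recovery_min,sustain_tol Classification
#'   thresholds (defaults 0.8, 0.2, 0.1).
#' @param window Recovery window passed to
#'   \code{\link{proportional_recovery}}.
#' @return One of "no_effect", "sustained_paralysis",
#'   "sustained_recovery", "transient_recovery".
#' @export
classify_response <- function(times, fms_norm, no_effect_floor = 0.8,
                              recovery_min = 0.2, sustain_tol = 0.1,
                              window = NULL) {
  ok <- !is.na(fms_norm)
  if (min(fms_norm[ok]) > no_effect_floor) return("no_effect")
  rec <- proportional_recovery(times, fms_norm, window = window)
  if (!rec$defined || rec$score < recovery_min) return("sustained_paralysis")
  i_min <- which.min(fms_norm)
  post_max <- max(fms_norm[ok & seq_along(fms_norm) >= i_min])
  if (abs(rec$fms_after_recovery - post_max) <= sustain_tol) {
    "sustained_recovery"
  } else {
    "transient_recovery"
  }
}

#' Fit dose-response curves across conditions
#'
#' For each compound/strain/stage at a given timepoint, extracts the
#' dose-response vector from the normalized traces, chooses a model (or
#' uses the override) and fits it.
#'
#' @param traces Output of \code{\link{normalize_to_controls}}.
#' @param time_min Timepoint at which to take the dose response; default
#'   the last common timepoint.
#' @param model Optional override passed to \code{\link{select_model}}.
#' @return Data frame: compound, strain, stage, time_min, model, A, B, M,
#'   rss, ec50, converged, n_doses. Conditions with too few doses are
#'   flagged (converged = FALSE) rather than fatal.
#' @export
fit_dose_response <- function(traces, time_min = NULL, model = NULL) {
  if (is.null(time_min)) time_min <- max(traces$time_min)
  at_t <- traces[traces$time_min == time_min & !is.na(traces$fms_norm), ]
  key <- interaction(at_t$compound, at_t$strain, at_t$stage, drop = TRUE)
  rows <- lapply(split(at_t, key), function(g) {
    g <- g[order(g$dose), ]
    out <- data.frame(compound = g$compound[1], strain = g$strain[1],
                      stage = g$stage[1], time_min = time_min,
                      model = NA_character_, A = NA_real_, B = NA_real_,
                      M = NA_real_, rss = NA_real_, ec50 = NA_real_,
                      converged = FALSE, n_doses = length(unique(g$dose)),
                      stringsAsFactors = FALSE)
    chosen <- select_model(g$dose, g$fms_norm, override = model)
    out$model <- chosen
    if (chosen == "logistic3" && out$n_doses >= 4) {
      f <- fit_logistic3(g$dose, g$fms_norm)
      out$A <- f$A; out$B <- f$B; out$M <- f$M; out$rss <- f$rss
      out$converged <- f$converged
      if (f$converged) out$ec50 <- ec50(f)
    } else if (chosen == "exponential" && out$n_doses >= 3) {
      f <- fit_exponential(g$dose, g$fms_norm)
      out$A <- f$A; out$M <- f$M; out$rss <- f$rss
      out$converged <- f$converged
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
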