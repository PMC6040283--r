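# Michaelis-Menten kinetics via Lineweaver-Burk regression and
# activity/stability profile normalization.
#
# Substrate concentrations are in mg/mL (1% w/v soluble starch =
# 10 mg/mL) and velocities in mg/mL/min of reducing sugar released.

#' Michaelis-Menten velocity
#'
#' `v = Vmax * s / (Km + s)`.
#'
#' @param s Substrate concentration (mg/mL), `>= 0`; vectorized.
#' @param km Michaelis constant (mg/mL), `> 0`.
#' @param vmax Limiting velocity (mg/mL/min), `> 0`.
#' @return Velocity (mg/mL/min).
#' @export
mm_velocity <- function(s, km, vmax) {
  stopifnot(all(s >= 0), km > 0, vmax > 0)
  vmax * s / (km + s)
}

#' Kinetic dataset
#'
#' @param substrate Substrate concentrations (mg/mL), all `> 0`.
#' @param velocity Observed velocities (mg/mL/min), all `>= 0`.
#' @param notes Optional assay-condition note (pH, temperature).
#' @return An object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(substrate, velocity, notes = "") {
  stopifnot(length(substrate) == length(velocity), length(substrate) >= 2L,
            all(substrate > 0), all(velocity >= 0))
  structure(list(substrate = as.numeric(substrate),
                 velocity = as.numeric(velocity), notes = notes),
            class = "kinetic_dataset")
}

#' Lineweaver-Burk fit
#'
#' Ordinary least squares of `1/v` on `1/s` (the double-reciprocal
#' linearization): slope = Km/Vmax, intercept = 1/Vmax, so Km =
#' slope/intercept and Vmax = 1/intercept. A non-positive intercept means
#' the linearization failed (it would imply a non-positive Vmax) and is an
#' error; so is any zero velocity, for which a nonlinear fit
#' ([mm_fit_nls()]) is advised instead.
#'
#' @param d A [kinetic_dataset()].
#' @return An object of class `kinetic_fit` with `km`, `vmax`, `slope`,
#'   `intercept`, `r2` and `n`.
#' @export
lineweaver_burk_fit <- function(d) {
  stopifnot(inherits(d, "kinetic_dataset"))
  if (any(d$velocity <= 0)) {
    stop("zero velocity in dataset: 1/v undefined; use a nonlinear ",
         "Michaelis-Menten fit (mm_fit_nls) instead")
  }
  if (length(unique(d$substrate)) < 2L) {
    stop("need at least 2 distinct substrate concentrations")
  }
  inv_s <- 1 / d$substrate
  inv_v <- 1 / d$velocity
  fit <- stats::lm(inv_v ~ inv_s)
  b <- unname(stats::coef(fit))
  intercept <- b[1]; slope <- b[2]
  if (intercept <= 0) {
    stop("Lineweaver-Burk fit failed: non-positive intercept (",
         signif(intercept, 4), ") implies non-positive Vmax")
  }
  if (slope <= 0) {
    stop("Lineweaver-Burk fit failed: non-positive slope implies ",
         "non-positive Km")
  }
  r2 <- summary(fit)$r.squared
  structure(list(km = slope / intercept, vmax = 1 / intercept,
                 slope = slope, intercept = intercept, r2 = r2,
                 n = length(inv_s)),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> Km = %.4g mg/mL, Vmax = %.4g mg/mL/min (R2 = %.4f, n = %d)\n",
    x$km, x$vmax, x$r2, x$n))
  invisible(x)
}

#' Nonlinear Michaelis-Menten fit
#'
#' Direct least-squares fit of `v = Vmax s / (Km + s)` via [stats::nls()],
#' provided as a cross-check on the Lineweaver-Burk estimates (on
#' noiseless data the two coincide).
#'
#' @param d A [kinetic_dataset()].
#' @return A list with `km` and `vmax`.
#' @export
mm_fit_nls <- function(d) {
  stopifnot(inherits(d, "kinetic_dataset"))
  vmax0 <- max(d$velocity) * 1.2
  km0 <- stats::median(d$substrate)
  # scaleOffset keeps the convergence test meaningful on (near-)exact data
  fit <- stats::nls(velocity ~ vmax * substrate / (km + substrate),
                    data = list(substrate = d$substrate,
                                velocity = d$velocity),
                    start = list(km = km0, vmax = vmax0),
                    control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                                 scaleOffset = 1))
  cf <- stats::coef(fit)
  list(km = unname(cf["km"]), vmax = unname(cf["vmax"]))
}

#' Relative activity profile
#'
#' Normalizes raw assay values to percentages, either of the maximum
#' (optimum profiles: the optimum reads 100%) or of a designated control
#' point (e.g. "activity without NaCl defined as 100%").
#'
#' @param condition Ordered condition axis (deg C, pH units, or M NaCl).
#' @param raw Raw activities, all `>= 0`, same length.
#' @param mode `"max"` or `"control"`.
#' @param control_index Index of the control point (required in control
#'   mode; its raw value must be `> 0`).
#' @return An object of class `activity_profile` with `condition`, `raw`,
#'   `relative` (percent) and `mode`.
#' @export
relative_activity <- function(condition, raw, mode = c("max", "control"),
                              control_index = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(condition) == length(raw), length(raw) >= 1L,
            all(raw >= 0))
  denom <- if (mode == "max") {
    max(raw)
  } else {
    if (is.null(control_index)) stop("control mode needs control_index")
    stopifnot(control_index >= 1L, control_index <= length(raw))
    raw[control_index]
  }
  if (denom <= 0) stop("normalization denominator must be > 0")
  structure(list(condition = condition, raw = raw,
                 relative = 100 * raw / denom, mode = mode,
                 control_index = control_index),
            class = "activity_profile")
}

#' Condition of maximal activity
#'
#' Returns the condition value at the profile maximum. Ties resolve to the
#' lowest condition value and are flagged, as are boundary optima (maximum
#' at either end of the measured range) and single-point profiles.
#'
#' @param p An [relative_activity()] profile.
#' @return A list with `optimum`, `relative_at_optimum`, `tie` and
#'   `boundary` flags.
#' @export
find_optimum <- function(p) {
  stopifnot(inherits(p, "activity_profile"))
  ord <- order(p$condition)
  cond <- p$condition[ord]
  rel <- p$relative[ord]
  mx <- max(rel)
  at <- which(rel == mx)
  list(optimum = cond[at[1]], relative_at_optimum = mx,
       tie = length(at) > 1L,
       boundary = at[1] == 1L || at[1] == length(rel) || length(rel) == 1L)
}

#' Residual-activity stability series
#'
#' Normalizes a time series of activities to the time-zero value (100%).
#'
#' @param times Time points in minutes, strictly increasing.
#' @param raw Raw activities at those times.
#' @param t0_index Index of the reference (time-zero) point; its value
#'   must be `> 0`.
#' @param label Condition label (e.g. `"40C, 1 M NaCl"`).
#' @return An object of class `stability_series` with `times`, `residual`
#'   (percent of time zero) and `label`.
#' @export
residual_activity <- function(times, raw, t0_index = 1L, label = "") {
  stopifnot(length(times) == length(raw), all(diff(times) > 0))
  if (raw[t0_index] <= 0) stop("activity at the reference time must be > 0")
  structure(list(times = times, residual = 100 * raw / raw[t0_index],
                 label = label),
            class = "stability_series")
}
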