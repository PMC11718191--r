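## Metabolic phenotyping indices from glucose/insulin curves.

#' Glucose curve from a tolerance test
#'
#' @param animal_id Animal identifier.
#' @param test `"GTT"` (glucose tolerance, 2 g/kg IP glucose) or `"ITT"`
#'   (insulin tolerance, 0.75 IU/kg).
#' @param times_min Sampling times (min), strictly increasing.
#' @param glucose_mM Blood glucose (mmol/L, `> 0`), same length.
#' @return An object of class `glucose_curve`.
#' @export
glucose_curve <- function(animal_id, test = c("GTT", "ITT"),
                          times_min, glucose_mM) {
  test <- match.arg(test)
  stopifnot(is.numeric(times_min), is.numeric(glucose_mM),
            length(times_min) == length(glucose_mM),
            length(times_min) >= 2L)
  if (any(diff(times_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(glucose_mM)) || any(glucose_mM <= 0))
    stop("glucose values must be finite and positive", call. = FALSE)
  structure(list(animal_id = as.character(animal_id), test = test,
                 times_min = times_min, glucose_mM = glucose_mM),
            class = "glucose_curve")
}

#' HOMA-IR insulin-resistance index
#'
#' `insulin_mU_L * glucose_mM / 22.5`, with insulin supplied either in
#' mU/L or in pmol/L (converted by dividing by 6.945). Linear in each
#' argument. The index is computed per subject; a group HOMA-IR is the
#' mean of per-subject indices, not the index of group means.
#'
#' @param fasting_glucose_mM Fasting glucose (mmol/L, `> 0`).
#' @param fasting_insulin Fasting insulin (`> 0`), unit given by
#'   `insulin_unit`.
#' @param insulin_unit `"mU_L"` or `"pmol_L"`; mandatory tag, no default
#'   guessing beyond these two.
#' @return HOMA-IR (dimensionless).
#' @export
#' @examples
#' homa_ir(5.0, 4.5, "mU_L")     # 1.00
#' homa_ir(5.0, 51.1, "pmol_L")  # 1.635
homa_ir <- function(fasting_glucose_mM, fasting_insulin,
                    insulin_unit = c("mU_L", "pmol_L")) {
  if (missing(insulin_unit))
    stop("insulin_unit tag ('mU_L' or 'pmol_L') is required", call. = FALSE)
  insulin_unit <- match.arg(insulin_unit)
  check_scalar(fasting_glucose_mM, "fasting_glucose_mM", min = 0,
               strict_min = TRUE)
  check_scalar(fasting_insulin, "fasting_insulin", min = 0,
               strict_min = TRUE)
  ins_mUL <- if (insulin_unit == "pmol_L")
    convert_units(fasting_insulin, "insulin_pmolL_to_mUL")
  else fasting_insulin
  ins_mUL * fasting_glucose_mM / 22.5
}

#' Glucose-tolerance-test area under the curve
#'
#' Trapezoidal area of glucose versus time from the first to the last
#' sample, with no baseline subtraction (absolute, not incremental, AUC).
#' Additive over contiguous intervals and invariant to inserting a
#' collinear midpoint.
#'
#' @param curve A [glucose_curve()].
#' @return AUC (mM * min).
#' @export
#' @examples
#' gtt_auc(glucose_curve("m1", "GTT", c(0, 15, 30), c(5, 10, 5)))  # 225
gtt_auc <- function(curve) {
  stopifnot(inherits(curve, "glucose_curve"))
  t <- curve$times_min; g <- curve$glucose_mM
  sum(diff(t) * (g[-length(g)] + g[-1]) / 2)
}

#' Glucose decay rate during an insulin tolerance test (kITT)
#'
#' Least-squares slope `b` of `ln(glucose)` versus time on the fit window
#' (default the first 30 minutes), returned as `-100 * b` so that falling
#' glucose gives a positive rate in %/min. On exactly exponential decay
#' the decay constant is recovered for any window. Rising glucose yields
#' a negative value, which is permitted and flagged with a warning.
#'
#' @param curve A [glucose_curve()].
#' @param fit_window_min Closed time window `[lo, hi]` (min) for the fit;
#'   default `c(0, 30)`.
#' @return Decay rate (%/min).
#' @export
#' @examples
#' kitt(glucose_curve("m1", "ITT", c(0, 30), c(10, 5)))  # 100*ln(2)/30 = 2.31
kitt <- function(curve, fit_window_min = c(0, 30)) {
  stopifnot(inherits(curve, "glucose_curve"),
            length(fit_window_min) == 2L,
            fit_window_min[1] < fit_window_min[2])
  sel <- curve$times_min >= fit_window_min[1] &
    curve$times_min <= fit_window_min[2]
  if (sum(sel) < 2L)
    stop("need at least 2 points inside the fit window", call. = FALSE)
  t <- curve$times_min[sel]; y <- log(curve$glucose_mM[sel])
  b <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  out <- -100 * b
  if (out < 0)
    warning("glucose rising over the fit window: negative kITT",
            call. = FALSE)
  out
}

#' Insulin response to a glucose challenge
#'
#' Change in plasma insulin from fasting to 15 minutes post-glucose,
#' `insulin_15min - fasting_insulin`, in the units of the inputs (which
#' must share a unit tag). Negative deltas are permitted.
#'
#' @param fasting_insulin,insulin_15min Insulin levels (`>= 0`).
#' @param unit Shared unit tag, `"pmol_L"` or `"mU_L"`.
#' @return Insulin delta, same units as the inputs.
#' @export
#' @examples
#' insulin_delta(50, 120, "pmol_L")  # 70
insulin_delta <- function(fasting_insulin, insulin_15min,
                          unit = c("pmol_L", "mU_L")) {
  unit <- match.arg(unit)
  check_scalar(fasting_insulin, "fasting_insulin", min = 0)
  check_scalar(insulin_15min, "insulin_15min", min = 0)
  insulin_15min - fasting_insulin
}
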