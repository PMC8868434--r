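# Colorimetric bioassay readouts: radical scavenging (DPPH/ABTS), ACE
# inhibition, and IC50 estimation from dose-response series.

#' Absorbance triple (control / sample / sample blank)
#'
#' Container for one well-set of a colorimetric assay. For radical
#' scavenging (DPPH at 517 nm, ABTS at 734 nm) the fields are the control
#' absorbance (radical solution without sample), the test-sample absorbance
#' (radical plus sample), and the sample-only blank. The ACE assay adds an
#' inhibitor-free blank (`a_inhibitor_blank`, 0 for the scavenging assays).
#'
#' @param a_control control absorbance (Ac, or C in the ACE assay).
#' @param a_sample test sample absorbance (As / S).
#' @param a_sample_blank sample-only blank (Asc / Bs), default 0.
#' @param a_inhibitor_blank ACE-assay blank without enzyme and substrate
#'   (Bi), default 0.
#' @return object of class `absorbance_triple`.
#' @export
absorbance_triple <- function(a_control, a_sample, a_sample_blank = 0,
                              a_inhibitor_blank = 0) {
  vals <- c(a_control = a_control, a_sample = a_sample,
            a_sample_blank = a_sample_blank,
            a_inhibitor_blank = a_inhibitor_blank)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_assay("absorbances must be finite and non-negative")
  }
  structure(as.list(vals), class = "absorbance_triple")
}

#' Radical-scavenging activity percentage
#'
#' Blank-corrected percent drop in radical absorbance:
#' `100 * (Ac - (As - Asc)) / Ac`. The same expression serves both the DPPH
#' and the ABTS assay. Values outside \[0, 100\] are possible with noisy or
#' turbid samples; they are returned as-is with a warning, never clipped.
#'
#' @param t an [absorbance_triple()].
#' @return numeric scalar, percent.
#' @examples
#' scavenging_percent(absorbance_triple(0.8, 0.4, 0.1)) # 62.5
#' @export
scavenging_percent <- function(t) {
  stopifnot(inherits(t, "absorbance_triple"))
  if (t$a_control <= 0) {
    stop_assay("control absorbance must be positive")
  }
  pct <- 100 * (t$a_control - (t$a_sample - t$a_sample_blank)) / t$a_control
  warn_range(pct, "scavenging")
  pct
}

#' ACE inhibition percentage
#'
#' Standard enzymatic-inhibition form with enzyme-free and substrate-free
#' blanks: `100 * ((C - Bi) - (S - Bs)) / (C - Bi)`. Requires a positive
#' blank-corrected control signal.
#'
#' @param t an [absorbance_triple()] with `a_inhibitor_blank` set (Bi).
#' @return numeric scalar, percent; out-of-range values are warned about,
#'   not clipped.
#' @examples
#' ace_inhibition_percent(absorbance_triple(1.0, 0.6, 0.2, 0.2)) # 50
#' @export
ace_inhibition_percent <- function(t) {
  stopifnot(inherits(t, "absorbance_triple"))
  ctrl <- t$a_control - t$a_inhibitor_blank
  if (ctrl <= 0) {
    stop_assay("blank-corrected control (C - Bi) must be positive")
  }
  pct <- 100 * (ctrl - (t$a_sample - t$a_sample_blank)) / ctrl
  warn_range(pct, "ACE inhibition")
  pct
}

warn_range <- function(pct, what) {
  if (pct < 0 || pct > 100) {
    warning(sprintf("%s activity %.2f%% outside [0, 100]; kept as-is",
                    what, pct), call. = FALSE)
  }
  invisible(pct)
}

#' Dose-response series
#'
#' Pairs strictly increasing positive concentrations with percent
#' activities. The concentration unit is an explicit tag and is never
#' converted; series in different units cannot be combined.
#'
#' @param concentrations strictly positive, strictly increasing numeric
#'   vector.
#' @param activities percent activities, same length.
#' @param unit concentration unit tag, `"mg/mL"` (default) or `"ug/mL"`.
#' @return object of class `dose_response`: data frame with columns
#'   `concentration` and `activity`, attribute `unit`.
#' @export
dose_response <- function(concentrations, activities, unit = "mg/mL") {
  conc <- as.numeric(concentrations)
  act <- as.numeric(activities)
  if (length(conc) != length(act)) stop_assay("lengths differ")
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop_assay("concentrations must be positive and finite")
  }
  if (is.unsorted(conc, strictly = TRUE)) {
    stop_assay("concentrations must be strictly increasing")
  }
  unit <- match.arg(unit, c("mg/mL", "ug/mL"))
  structure(data.frame(concentration = conc, activity = act),
            unit = unit, class = c("dose_response", "data.frame"))
}

#' Estimate the half-maximal inhibitory concentration (IC50)
#'
#' Default route is a four-parameter logistic (4PL) least-squares fit on
#' log-concentration,
#' `activity(x) = bottom + (top - bottom) / (1 + (ic50/x)^hill)`,
#' whose midpoint parameter is the IC50 estimate. When the fit fails to
#' converge, or returns a midpoint outside the dosed range, the estimator
#' falls back to linear interpolation in log-concentration between the two
#' doses bracketing 50% activity. Decreasing (inverted) series are handled
#' by a negative Hill slope / a downward 50% crossing. The route taken is
#' recorded in the result.
#'
#' @param d a [dose_response()] with at least 3 points (4 for the logistic
#'   route).
#' @param method `"auto"` (default: 4PL, interpolation fallback),
#'   `"logistic"` (4PL only) or `"interpolation"`.
#' @return object of class `ic50_estimate`: list with `ic50` (in the input
#'   unit), `unit`, `method` (`"logistic-fit"` or `"interpolation"`) and,
#'   for the logistic route, `fit_params` = c(bottom, top, ic50, hill).
#' @examples
#' d <- dose_response(c(1, 2, 4), c(25, 50, 75))
#' estimate_ic50(d, method = "interpolation")$ic50 # 2
#' @export
estimate_ic50 <- function(d, method = c("auto", "logistic", "interpolation")) {
  stopifnot(inherits(d, "dose_response"))
  method <- match.arg(method)
  if (nrow(d) < 3L) stop_assay("need at least 3 dose-response points")

  fit <- NULL
  if (method %in% c("auto", "logistic")) {
    if (nrow(d) >= 4L) fit <- fit_4pl(d$concentration, d$activity)
    if (is.null(fit) && method == "logistic") {
      stop_no_estimate("logistic fit failed to converge or gave an implausible midpoint")
    }
  }
  if (!is.null(fit)) {
    return(structure(list(ic50 = unname(fit[["ic50"]]), unit = attr(d, "unit"),
                          method = "logistic-fit", fit_params = fit),
                     class = "ic50_estimate"))
  }
  ic50 <- interpolate_50(d$concentration, d$activity)
  if (is.na(ic50)) {
    stop_no_estimate(sprintf(
      "activities (range %.1f..%.1f%%) never cross 50%%, and no converged fit",
      min(d$activity), max(d$activity)))
  }
  structure(list(ic50 = ic50, unit = attr(d, "unit"),
                 method = "interpolation", fit_params = NULL),
            class = "ic50_estimate")
}

#' @export
print.ic50_estimate <- function(x, ...) {
  cat(sprintf("IC50 = %.4g %s  [%s]\n", x$ic50, x$unit, x$method))
  if (!is.null(x$fit_params)) {
    cat(sprintf("  4PL: bottom=%.3g top=%.3g ic50=%.4g hill=%.3g\n",
                x$fit_params[["bottom"]], x$fit_params[["top"]],
                x$fit_params[["ic50"]], x$fit_params[["hill"]]))
  }
  invisible(x)
}

# 4PL least squares on log-concentration; returns named vector or NULL on
# failure. The model is reparameterised with log(ic50) for stability;
# scaleOffset handles the zero-residual (noise-free) case, where nls's
# relative-offset criterion is otherwise ill-defined.
fit_4pl <- function(conc, act) {
  lx <- log(conc)
  direction <- if (stats::cor(lx, act) < 0) -1 else 1
  start <- c(bottom = min(act), top = max(act),
             lic50 = lx[which.min(abs(act - (min(act) + max(act)) / 2))],
             hill = direction * 1)
  df <- data.frame(lx = lx, act = act)
  cf <- NULL
  fit <- tryCatch(
    stats::nls(act ~ bottom + (top - bottom) / (1 + exp(-hill * (lx - lic50))),
               data = df, start = as.list(start),
               control = stats::nls.control(maxiter = 500, minFactor = 1e-10,
                                            scaleOffset = 1, warnOnly = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) cf <- stats::coef(fit)
  if (is.null(cf)) {
    # direct least squares backs up nls, whose Gauss-Newton step hits a
    # singular gradient on (near-)zero-residual data
    ssr <- function(p) {
      sum((act - (p[1] + (p[2] - p[1]) / (1 + exp(-p[4] * (lx - p[3])))))^2)
    }
    o <- tryCatch({
      o1 <- stats::optim(start, ssr, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-15))
      stats::optim(o1$par, ssr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-15))
    }, error = function(e) NULL)
    if (is.null(o) || o$convergence != 0L) return(NULL)
    cf <- o$par
  }
  ic50 <- exp(cf[["lic50"]])
  # reject implausible midpoints (outside the dosed range by > 1 log-decade)
  if (!is.finite(ic50) || ic50 <= 0 ||
      ic50 < min(conc) / 10 || ic50 > max(conc) * 10) {
    return(NULL)
  }
  c(bottom = unname(cf[["bottom"]]), top = unname(cf[["top"]]),
    ic50 = unname(ic50), hill = unname(cf[["hill"]]))
}

# Linear interpolation in log-concentration at the first 50% crossing,
# in either direction. NA when the series never brackets 50%.
interpolate_50 <- function(conc, act) {
  hit <- which(act == 50)
  if (length(hit)) return(conc[hit[1L]])
  s <- sign(act - 50)
  cross <- which(s[-1] * s[-length(s)] < 0)
  if (!length(cross)) return(NA_real_)
  i <- cross[1L]
  lx1 <- log(conc[i]); lx2 <- log(conc[i + 1L])
  y1 <- act[i]; y2 <- act[i + 1L]
  exp(lx1 + (50 - y1) * (lx2 - lx1) / (y2 - y1))
}

#' Read a bioassay plate CSV
#'
#' Expected columns: `concentration,unit,a_control,a_sample,a_sample_blank`
#' and, for the ACE assay, `a_inhibitor_blank`. All rows must share one
#' unit; mixing units in a series is an error.
#'
#' @param path CSV path.
#' @return data frame with one row per dose plus a `unit` attribute.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop_assay(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration", "unit", "a_control", "a_sample", "a_sample_blank")
  if (!all(need %in% names(df))) {
    stop_assay(sprintf("missing column(s): %s",
                       paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (nrow(df) == 0L) stop_assay(sprintf("%s: no data rows", path))
  if (length(unique(df$unit)) != 1L) {
    stop_assay(sprintf("mixed concentration units in one series: %s",
                       paste(unique(df$unit), collapse = ", ")))
  }
  if (!"a_inhibitor_blank" %in% names(df)) df$a_inhibitor_blank <- 0
  df <- df[order(df$concentration), , drop = FALSE]
  attr(df, "unit") <- df$unit[1L]
  df
}

#' Evaluate a plate: per-dose activity and IC50
#'
#' Applies [scavenging_percent()] (assays `"dpph"`, `"abts"`) or
#' [ace_inhibition_percent()] (`"ace"`) row-wise, then estimates the IC50
#' from the resulting dose-response series.
#'
#' @param plate data frame as returned by [read_plate_csv()].
#' @param assay one of `"dpph"`, `"abts"`, `"ace"`.
#' @return list with `assay`, `doses` (data frame concentration/activity),
#'   and `ic50` (an `ic50_estimate`, or `NULL` with `ic50_error` set when no
#'   estimate is possible).
#' @export
evaluate_plate <- function(plate, assay = c("dpph", "abts", "ace")) {
  assay <- match.arg(assay)
  act <- vapply(seq_len(nrow(plate)), function(i) {
    t <- absorbance_triple(plate$a_control[i], plate$a_sample[i],
                           plate$a_sample_blank[i], plate$a_inhibitor_blank[i])
    if (assay == "ace") ace_inhibition_percent(t) else scavenging_percent(t)
  }, numeric(1))
  d <- dose_response(plate$concentration, act, unit = attr(plate, "unit"))
  est <- tryCatch(estimate_ic50(d), lipidqi_no_estimate_error = function(e) e)
  if (inherits(est, "error")) {
    list(assay = assay, doses = as.data.frame(d), unit = attr(d, "unit"),
         ic50 = NULL, ic50_error = conditionMessage(est))
  } else {
    list(assay = assay, doses = as.data.frame(d), unit = attr(d, "unit"),
         ic50 = est, ic50_error = NULL)
  }
}

stop_assay <- function(msg) {
  stop(errorCondition(msg, class = c("lipidqi_assay_error", "lipidqi_error")))
}

stop_no_estimate <- function(msg) {
  stop(errorCondition(paste0("no IC50 estimate: ", msg),
                      class = c("lipidqi_no_estimate_error",
                                "lipidqi_assay_error", "lipidqi_error")))
}
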