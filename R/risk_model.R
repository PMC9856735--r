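#' Fit the TRD prognostic risk model
#'
#' The package's model-building pipeline in one fitting function: multiple
#' imputation of missing candidate features (chained-equations predictive
#' mean matching), a pooled full Cox model of TRD within one year of episode
#' start, step-down approximation of the full model to a compact variable
#' set, bootstrap validation (Harrell C with optimism correction,
#' calibration by decile), and a nomogram point table.
#'
#' @param features feature table from [build_features()].
#' @param covariates candidate variables (default: the table's `covariates`
#'   attribute).
#' @param m number of imputations.
#' @param threshold explained-variation target of the reduced model.
#' @param n_boot bootstrap replicates for validation.
#' @param seed RNG seed for imputation and validation.
#' @param horizon_days risk horizon.
#' @return object of class `trd_risk_model` with components `full`
#'   (pooled Cox fit), `reduced` (step-down approximation), `validation`,
#'   `nomogram`, `reference` (first completed data set) and the settings;
#'   supports [print()], [summary()], [coef()], [predict()] and [plot()].
#' @export
trd_risk_model <- function(features, covariates = attr(features, "covariates"),
                           m = 20L, threshold = 0.95, n_boot = 200L,
                           seed = 1L, horizon_days = 365) {
  imps <- impute_missing(features, m = m, seed = seed,
                         covariates = covariates)
  full <- fit_full_model(imps, covariates = covariates)
  reference <- imps[[1L]]
  reduced <- reduce_model(full, reference, threshold = threshold)
  validation <- validate_model(reduced, reference, n_boot = n_boot,
                               seed = seed, horizon_days = horizon_days)
  nomogram <- export_nomogram(reduced, reference, horizon_days = horizon_days)
  structure(list(full = full, reduced = reduced, validation = validation,
                 nomogram = nomogram, reference = reference,
                 covariates = covariates, m = m, threshold = threshold,
                 n_boot = n_boot, seed = seed, horizon_days = horizon_days,
                 n = nrow(features), n_events = sum(features$event)),
            class = "trd_risk_model")
}

#' @export
print.trd_risk_model <- function(x, ...) {
  cat("TRD prognostic risk model\n")
  cat(sprintf("  %d episodes, %d TRD events within %d days\n",
              x$n, x$n_events, as.integer(x$horizon_days)))
  cat(sprintf("  full model: %d variables pooled over %d imputations\n",
              length(x$full$covariates), x$full$m))
  cat(sprintf("  reduced model: %d variables, %.1f%% of the full model\n",
              length(x$reduced$variables), 100 * x$reduced$achieved))
  cat(sprintf("  C index %.3f apparent, %.3f optimism-corrected (%d bootstraps)\n",
              x$validation$c_apparent, x$validation$c_corrected, x$n_boot))
  invisible(x)
}

#' @export
summary.trd_risk_model <- function(object, ...) {
  print(object)
  cat("\nFull-model pooled coefficients:\n")
  se <- sqrt(diag(object$full$vcov))
  print(round(cbind(coef = object$full$coefficients,
                    HR = exp(object$full$coefficients), se = se), 3))
  cat("\nReduced-model approximation coefficients:\n")
  print(round(object$reduced$coefficients, 4))
  cat("\nCalibration at the horizon (by predicted-risk decile):\n")
  print(object$validation$calibration)
  invisible(object)
}

#' @export
coef.trd_risk_model <- function(object, model = c("reduced", "full"), ...) {
  model <- match.arg(model)
  if (model == "reduced") object$reduced$coefficients
  else object$full$coefficients
}

#' Predict linear predictor or one-year TRD risk
#'
#' @param object a `trd_risk_model`.
#' @param newdata data with the reduced model's variables (default: the
#'   reference data set).
#' @param type `"lp"` (reduced-model linear predictor) or `"risk"`
#'   (absolute risk at the model horizon).
#' @param ... unused.
#' @export
predict.trd_risk_model <- function(object, newdata = NULL,
                                   type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  d <- if (is.null(newdata)) object$reference else newdata
  lp <- reduced_lp(object$reduced, d)
  if (type == "lp") return(lp)
  ref_lp <- reduced_lp(object$reduced, object$reference)
  lpc <- lp - mean(ref_lp)
  1 - exp(-object$nomogram$baseline_cumhaz * exp(lpc))
}

#' @export
plot.trd_risk_model <- function(x, ...) {
  cal <- x$validation$calibration
  lim <- range(0, cal$predicted, cal$observed)
  graphics::plot(cal$predicted, cal$observed, xlim = lim, ylim = lim,
                 xlab = "Predicted risk", ylab = "Observed risk (KM)",
                 main = sprintf("Calibration at %d days", as.integer(x$horizon_days)),
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Export the nomogram point table
#'
#' Converts a reduced model into nomogram form: per-variable point scales
#' (the widest-spanning variable spans 0-100 points, others proportional to
#' coefficient times observed range) and a monotone lookup from total points
#' to absolute risk at the horizon.
#'
#' @param reduced a `reduced_cox` model (or a `trd_risk_model`, whose
#'   reduced component is used).
#' @param data reference data for variable ranges and baseline hazard.
#' @param horizon_days risk horizon.
#' @param grid_points number of rows in the per-variable point tables.
#' @return list of class `trd_nomogram`: `points` (variable, value, points),
#'   `risk_lookup` (total_points, risk), `baseline_cumhaz`.
#' @export
export_nomogram <- function(reduced, data, horizon_days = 365,
                            grid_points = 11L) {
  if (inherits(reduced, "trd_risk_model")) reduced <- reduced$reduced
  stopifnot(inherits(reduced, "reduced_cox"))
  d <- data.table::as.data.table(data)
  vars <- reduced$variables
  beta <- reduced$coefficients[-1]
  X <- as.matrix(d[, lapply(.SD, as.numeric), .SDcols = vars])
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  span <- abs(beta) * (hi - lo)
  if (all(span == 0)) {
    warning("all retained covariates are constant; nomogram has zero-point scales")
    scale <- 0
  } else scale <- 100 / max(span)
  pts <- data.table::rbindlist(lapply(seq_along(vars), function(j) {
    if (span[j] == 0)
      warning(sprintf("constant covariate '%s' has a zero-point scale", vars[j]))
    vals <- if (hi[j] - lo[j] <= 1 && all(X[, j] %in% c(0, 1))) c(0, 1)
    else seq(lo[j], hi[j], length.out = grid_points)
    # points increase in the risk-increasing direction of the variable
    ref <- if (beta[j] >= 0) lo[j] else hi[j]
    data.table::data.table(variable = vars[j], value = vals,
                           points = abs(beta[j]) * abs(vals - ref) * scale)
  }))

  lp <- reduced_lp(reduced, d)
  risk_base <- predict_risk_from_lp(lp, d, horizon_days)
  # recover baseline cumulative hazard at the horizon from the offset fit
  lpc <- lp - mean(lp)
  H0 <- -log(1 - risk_base[1]) / exp(lpc[1])
  lp_min <- sum(reduced$coefficients[1],
                beta[beta >= 0] * lo[beta >= 0],
                beta[beta < 0] * hi[beta < 0])
  total_grid <- seq(0, sum(span) * ifelse(scale > 0, scale, 0),
                    length.out = 101L)
  lp_at <- lp_min + if (scale > 0) total_grid / scale else 0
  risk <- 1 - exp(-H0 * exp(lp_at - mean(lp)))
  structure(list(points = pts[],
                 risk_lookup = data.table::data.table(total_points = total_grid,
                                                      risk = risk),
                 baseline_cumhaz = H0, horizon_days = horizon_days),
            class = "trd_nomogram")
}

#' @export
print.trd_nomogram <- function(x, ...) {
  cat(sprintf("Nomogram (risk at %d days)\n", as.integer(x$horizon_days)))
  rng <- x$points[, .(max_points = max(points)), by = variable]
  print(rng)
  invisible(x)
}
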