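# Observed-versus-predicted validation statistics: no-intercept regression,
# RMSE, R^2, the +/- 2 SE confidence interval, and error-rate summaries.

#' No-intercept regression of predicted on observed values
#'
#' Fits \eqn{y = b x} by least squares: \eqn{b = \sum xy / \sum x^2}. The
#' slope's standard error uses the one-parameter residual variance with
#' \eqn{n - 1} degrees of freedom, and the reported confidence interval is
#' \eqn{b \pm 2\,SE} (a CI overlapping 1 means predictions do not differ
#' significantly from observations). RMSE is
#' \eqn{\sqrt{\sum (y - bx)^2 / n}}. Because \eqn{R^2} is ambiguous for
#' no-intercept fits, both conventions are returned: \code{r2} about the
#' mean of \eqn{y} (the reported one) and \code{r2_zero} about zero.
#'
#' @param observed Observed values (x), all > 0, length >= 3.
#' @param predicted Predicted values (y), same length.
#' @return A list of class \code{no_intercept_fit}: \code{slope}, \code{se},
#'   \code{ci_low}, \code{ci_high}, \code{rmse}, \code{r2}, \code{r2_zero},
#'   \code{n}.
#' @examples
#' fit_no_intercept(c(1, 2, 3), c(2, 4, 6))
#' @export
fit_no_intercept <- function(observed, predicted) {
  x <- as.numeric(observed); y <- as.numeric(predicted)
  n <- length(x)
  if (n != length(y)) stop("observed and predicted must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  sxx <- sum(x^2)
  if (sxx == 0) stop("degenerate observed values: all zero")

  slope <- sum(x * y) / sxx
  resid <- y - slope * x
  se <- sqrt(sum(resid^2) / (n - 1)) / sqrt(sxx)
  rmse <- sqrt(sum(resid^2) / n)
  ss_res <- sum(resid^2)
  r2 <- 1 - ss_res / sum((y - mean(y))^2)
  r2_zero <- 1 - ss_res / sum(y^2)
  structure(list(slope = slope, se = se,
                 ci_low = slope - 2 * se, ci_high = slope + 2 * se,
                 rmse = rmse, r2 = r2, r2_zero = r2_zero, n = n),
            class = "no_intercept_fit")
}

#' @export
print.no_intercept_fit <- function(x, ...) {
  cat(sprintf("y ~ x (no intercept), n = %d\n", x$n))
  cat(sprintf("slope = %.4g  95%% CI [%.4g, %.4g]  RMSE = %.4g  R2 = %.3g\n",
              x$slope, x$ci_low, x$ci_high, x$rmse, x$r2))
  invisible(x)
}

#' Average error rate of model predictions
#'
#' RMSE expressed as a fraction of the largest observed value:
#' \code{rmse / max_observed}.
#'
#' @param rmse Root mean square error (same units as the observations).
#' @param max_observed Largest observed value (> 0).
#' @return Proportion.
#' @export
error_rate <- function(rmse, max_observed) {
  if (any(!is.finite(max_observed)) || any(max_observed <= 0)) {
    stop("max_observed must be > 0")
  }
  rmse / max_observed
}

#' Half-width of the 95% residual coverage band
#'
#' Assuming normally distributed residuals, 95% of observed values fall
#' within \eqn{\pm 2 \times} RMSE of the predictions.
#'
#' @param rmse Root mean square error (>= 0).
#' @return \code{2 * rmse}.
#' @export
coverage_band <- function(rmse) {
  if (any(!is.finite(rmse)) || any(rmse < 0)) stop("rmse must be >= 0")
  2 * rmse
}

#' Collapse multi-source observed values to a single figure
#'
#' Applies the convention used when collating observations: the median when
#' a value range was reported, the mean when a series of observations was
#' reported.
#'
#' @param values Numeric values.
#' @param kind \code{"range"} or \code{"series"}.
#' @return A single numeric value.
#' @export
summarize_observed <- function(values, kind = c("range", "series")) {
  kind <- match.arg(kind)
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  if (kind == "range") stats::median(values) else mean(values)
}

#' Validate model predictions against caller-supplied observations
#'
#' Runs the full DEB-IPM pipeline for every valid species in the table at
#' one feeding level and pairs the predicted generation time (\code{T}),
#' longevity (\code{L_alpha + L_omega}) and age at maturity
#' (\code{L_alpha}) with supplied observed values, then fits a no-intercept
#' regression per trait. Species infeasible at the feeding level are
#' excluded and counted. Observed values are never fetched; they are the
#' caller's responsibility.
#'
#' @param table A \code{trait_table}.
#' @param observations A \code{data.frame} with columns \code{species} (or
#'   \code{record_id}), \code{trait_name} (one of \code{"generation_time"},
#'   \code{"longevity"}, \code{"age_at_maturity"}) and
#'   \code{observed_value} (years, > 0).
#' @param E_Y Experienced feeding level.
#' @param env_base A [deb_env()] supplying the dispersion settings.
#' @param n_bins,tol Model resolution and life-table tolerance.
#' @return A list: \code{fits} (named list of [fit_no_intercept()] results
#'   per trait, or \code{NULL} when fewer than 3 feasible pairs exist),
#'   \code{predictions} (per-species predicted values), \code{n_excluded}
#'   and \code{excluded} (infeasible species ids).
#' @export
validate_predictions <- function(table, observations, E_Y,
                                 env_base = deb_env(1), n_bins = 200L,
                                 tol = 1e-9) {
  stopifnot(all(c("trait_name", "observed_value") %in% names(observations)))
  key <- if ("record_id" %in% names(observations)) "record_id" else "species"
  if (!key %in% names(observations)) {
    stop("observations need a 'species' or 'record_id' column")
  }
  env <- deb_env(E_Y, sigma_Y = env_base$sigma_Y, sigma_Lb = env_base$sigma_Lb,
                 sigma_Lb_frac = env_base$sigma_Lb_frac)

  preds <- list(); excluded <- character(0)
  for (i in which(table$valid)) {
    t <- species_traits(table, i)
    if (!feasibility(t, env)$feasible) {
      excluded <- c(excluded, table[[key]][i])
      next
    }
    k <- build_kernels(t, env, n_bins = n_bins)
    dt <- derived_traits(k, tol = tol)
    preds[[length(preds) + 1L]] <- data.frame(
      id = table[[key]][i],
      generation_time = dt$T,
      longevity = dt$L_alpha + dt$L_omega,
      age_at_maturity = dt$L_alpha,
      stringsAsFactors = FALSE
    )
  }
  preds <- if (length(preds)) do.call(rbind, preds) else
    data.frame(id = character(0), generation_time = numeric(0),
               longevity = numeric(0), age_at_maturity = numeric(0))

  fits <- list()
  for (tr in c("generation_time", "longevity", "age_at_maturity")) {
    obs_tr <- observations[observations$trait_name == tr, , drop = FALSE]
    mi <- match(preds$id, obs_tr[[key]])
    ok <- !is.na(mi) & is.finite(preds[[tr]])
    if (sum(ok) < 3L) {
      fits[[tr]] <- NULL
      next
    }
    fits[[tr]] <- fit_no_intercept(obs_tr$observed_value[mi[ok]],
                                   preds[[tr]][ok])
  }
  if (length(fits) == 0L) stop("fewer than 3 feasible observed/predicted pairs for every trait")
  list(fits = fits, predictions = preds,
       n_excluded = length(excluded), excluded = excluded)
}
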