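# Closed-form trait estimators used to populate DEBBIES-style records for
# data-poor species (the elasmobranch workflow): growth rate from longevity,
# reproduction from clutch data, mortality rates from longevity and age at
# maturity, and length-unit conversion.

# Fraction of the asymptotic length assumed to be attained by the age t_max.
.RB_ASYMPTOTE_FRACTION <- 0.95

#' von Bertalanffy growth rate from longevity
#'
#' Assumes an individual reaches a fixed fraction (default 0.95) of its
#' asymptotic length by its maximum age:
#' \eqn{\dot{r}_B = -\log(1 - 0.95)/t_{max}}.
#'
#' @param t_max Longevity in years (> 0).
#' @param asymptote_fraction Fraction of the asymptotic length attained by
#'   \code{t_max}. Default 0.95.
#' @return Growth rate, per year.
#' @export
rb_from_longevity <- function(t_max, asymptote_fraction = .RB_ASYMPTOTE_FRACTION) {
  if (any(!is.finite(t_max)) || any(t_max <= 0)) stop("t_max must be > 0")
  stopifnot(asymptote_fraction > 0, asymptote_fraction < 1)
  -log(1 - asymptote_fraction) / t_max
}

#' Maximum reproduction rate from clutch data
#'
#' \eqn{R_m = (c \times n)/i} with mean clutch size \eqn{c}, litters per
#' year \eqn{n} and remigration interval \eqn{i} (minimum years between
#' reproductive seasons). When minimum and maximum pup counts are supplied
#' instead of a clutch size, their mean is used.
#'
#' @param clutch Mean clutch size (offspring); may be omitted when
#'   \code{pups_min}/\code{pups_max} are given.
#' @param litters Litters per year (> 0). Default 1.
#' @param interval Remigration interval in years (>= 1). Default 1.
#' @param pups_min,pups_max Optional minimum/maximum pup counts whose mean
#'   replaces \code{clutch}.
#' @return Offspring per year.
#' @export
max_reproduction <- function(clutch = NULL, litters = 1, interval = 1,
                             pups_min = NULL, pups_max = NULL) {
  if (!is.null(pups_min) && !is.null(pups_max)) {
    clutch <- (pups_min + pups_max) / 2
  }
  if (is.null(clutch) || any(!is.finite(clutch)) || any(clutch <= 0)) {
    stop("clutch size must be > 0 (or supply pups_min and pups_max)")
  }
  if (any(!is.finite(litters)) || any(litters <= 0)) stop("litters must be > 0")
  if (any(!is.finite(interval)) || any(interval <= 0)) stop("interval must be > 0")
  (clutch * litters) / interval
}

#' Adult mortality rate from longevity and age at maturity
#'
#' The inverse of the mean of longevity and age at maturity:
#' \eqn{\mu_a = 2/(t_{max} + a)}.
#'
#' @param t_max Longevity in years.
#' @param a Age at maturity in years; must satisfy \eqn{t_{max} > a > 0}.
#' @return Mortality rate, per year.
#' @export
adult_mortality <- function(t_max, a) {
  if (any(!is.finite(t_max)) || any(!is.finite(a)) || any(a <= 0) ||
      any(t_max <= a)) {
    stop("requires t_max > a > 0")
  }
  2 / (t_max + a)
}

#' Survival to maturity
#'
#' \eqn{l_\alpha = e^{-\mu_a (t_{max} - a)}}: the survival probability over
#' the adult lifespan used to back out juvenile mortality.
#'
#' @param mu_a Adult mortality rate, per year.
#' @param t_max Longevity in years.
#' @param a Age at maturity in years.
#' @return Probability in (0, 1].
#' @export
survival_to_maturity <- function(mu_a, t_max, a) {
  if (any(!is.finite(mu_a)) || any(mu_a <= 0)) stop("mu_a must be > 0")
  if (any(!is.finite(t_max)) || any(!is.finite(a)) || any(a <= 0) ||
      any(t_max < a)) {
    stop("requires t_max >= a > 0")
  }
  exp(-mu_a * (t_max - a))
}

#' Juvenile mortality rate from survival to maturity
#'
#' \eqn{\mu_j = -\log(l_\alpha^{1/a}) = -\log(l_\alpha)/a}.
#'
#' @param l_alpha Survival to maturity, in (0, 1].
#' @param a Age at maturity in years (> 0).
#' @return Mortality rate, per year.
#' @export
juvenile_mortality <- function(l_alpha, a) {
  if (any(!is.finite(l_alpha)) || any(l_alpha <= 0) || any(l_alpha > 1)) {
    stop("l_alpha must be in (0, 1]")
  }
  if (any(!is.finite(a)) || any(a <= 0)) stop("a must be > 0")
  -log(l_alpha) / a
}

#' Total-to-fork length conversion
#'
#' @param TL Total length, cm (> 0).
#' @param fork_factor Species-specific scalar in (0, 1].
#' @return Fork length, cm.
#' @export
total_to_fork <- function(TL, fork_factor) {
  if (any(!is.finite(TL)) || any(TL <= 0)) stop("TL must be > 0")
  if (any(!is.finite(fork_factor)) || any(fork_factor <= 0) ||
      any(fork_factor > 1)) {
    stop("fork_factor must be in (0, 1]")
  }
  TL * fork_factor
}

#' Aggregate candidate trait values across sources by priority tier
#'
#' When several sources give a value for the same trait, values from the
#' highest-priority tier present are kept and their median is returned
#' (ties across sources within a tier resolve to the median).
#'
#' @param values Numeric candidate values.
#' @param tiers Priority labels, one per value; lower values = higher
#'   priority (e.g. 1 = primary literature, 2 = database, 3 = derived).
#' @return The median of the highest-priority tier's values.
#' @export
prioritized_median <- function(values, tiers) {
  stopifnot(length(values) == length(tiers), length(values) >= 1)
  keep <- !is.na(values)
  values <- values[keep]; tiers <- tiers[keep]
  if (length(values) == 0L) stop("no non-missing candidate values")
  best <- min(tiers)
  stats::median(values[tiers == best])
}

#' Derive the mortality, growth and reproduction traits from raw observations
#'
#' Chains the closed-form estimators: \eqn{\mu_a = 2/(t_{max}+a)},
#' \eqn{l_\alpha = e^{-\mu_a(t_{max}-a)}}, \eqn{\mu_j = -\log(l_\alpha)/a},
#' \eqn{\dot{r}_B = -\log(0.05)/t_{max}} and \eqn{R_m = (c \times n)/i}.
#'
#' @param t_max Longevity, years.
#' @param a Age at maturity, years (\eqn{t_{max} > a > 0}).
#' @param clutch,litters,interval,pups_min,pups_max See [max_reproduction()].
#' @return Named list: \code{mu_a}, \code{l_alpha}, \code{mu_j}, \code{r_B},
#'   \code{R_m}.
#' @examples
#' derive_rates(t_max = 30, a = 10, clutch = 4, litters = 1, interval = 2)
#' @export
derive_rates <- function(t_max, a, clutch = NULL, litters = 1, interval = 1,
                         pups_min = NULL, pups_max = NULL) {
  mu_a <- adult_mortality(t_max, a)
  l_alpha <- survival_to_maturity(mu_a, t_max, a)
  list(mu_a = mu_a,
       l_alpha = l_alpha,
       mu_j = juvenile_mortality(l_alpha, a),
       r_B = rb_from_longevity(t_max),
       R_m = max_reproduction(clutch, litters, interval, pups_min, pups_max))
}
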