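# Scalar DEB-IPM kernel functions: survival, von Bertalanffy cohort growth,
# Kooijman-Metz reproduction, and the parent-offspring size distribution.
# All are pure functions of (length, traits, environment), vectorized in L.

#' Feeding environment for a DEB-IPM
#'
#' The environment an individual experiences is summarized by the mean
#' experienced feeding level \eqn{E(Y)} (0 = empty gut, 1 = full gut), its
#' among-individual standard deviation \eqn{\sigma(Y)} (demographic
#' stochasticity in feeding experience), and the standard deviation of
#' offspring length \eqn{\sigma_{L_b}}.
#'
#' @param E_Y Mean experienced feeding level, in (0, 1].
#' @param sigma_Y Standard deviation of the experienced feeding level
#'   (>= 0). Default 0.1.
#' @param sigma_Lb Standard deviation of offspring length in cm, or
#'   \code{NULL} (default) to use \code{sigma_Lb_frac * L_b} of the species
#'   being modelled (offspring size dispersion is assumed very small).
#' @param sigma_Lb_frac Fraction of \code{L_b} used for \code{sigma_Lb} when
#'   the latter is \code{NULL}. Default 0.01.
#' @return A list of class \code{deb_env}.
#' @examples
#' deb_env(0.9)
#' @export
deb_env <- function(E_Y, sigma_Y = 0.1, sigma_Lb = NULL, sigma_Lb_frac = 0.01) {
  stopifnot(length(E_Y) == 1L, is.finite(E_Y), E_Y > 0, E_Y <= 1,
            length(sigma_Y) == 1L, is.finite(sigma_Y), sigma_Y >= 0,
            is.finite(sigma_Lb_frac), sigma_Lb_frac > 0)
  if (!is.null(sigma_Lb)) {
    stopifnot(length(sigma_Lb) == 1L, is.finite(sigma_Lb), sigma_Lb > 0)
  }
  structure(list(E_Y = E_Y, sigma_Y = sigma_Y, sigma_Lb = sigma_Lb,
                 sigma_Lb_frac = sigma_Lb_frac),
            class = "deb_env")
}

# Resolve the offspring-size sd for a given species.
.sigma_Lb <- function(t, env) {
  if (!is.null(env$sigma_Lb)) env$sigma_Lb else env$sigma_Lb_frac * t$L_b
}

#' Ultimate and starvation lengths
#'
#' At a constant feeding level the asymptotic ("ultimate") length is
#' \eqn{L_\infty = L_m E(Y)}; maintenance exceeds assimilation -- and
#' survival drops to zero -- above the starvation length
#' \eqn{L_m E(Y)/\kappa = L_\infty/\kappa}. With the conventional
#' \eqn{\kappa = 0.8} the starvation length is exactly \eqn{1.25 L_\infty},
#' so individuals at a constant feeding level never starve.
#'
#' @param t Species traits (list or one-row \code{trait_table} row).
#' @param env A [deb_env()].
#' @return List with \code{L_inf} and \code{L_starv} (cm).
#' @export
derived_lengths <- function(t, env) {
  L_inf <- t$L_m * env$E_Y
  list(L_inf = L_inf, L_starv = L_inf / t$kappa)
}

#' Survival probability over one projection interval
#'
#' Juveniles (\eqn{L_b \le L < L_p}) survive with probability
#' \eqn{e^{-\mu_j}}, adults (\eqn{L_p \le L \le L_m}) with \eqn{e^{-\mu_a}},
#' in both cases only while below the starvation length
#' \eqn{L_m E(Y)/\kappa}; survival is zero otherwise.
#'
#' @param L Body length(s), cm.
#' @inheritParams derived_lengths
#' @return Survival probabilities in \[0, 1\], same length as \code{L}.
#' @export
deb_survival <- function(L, t, env) {
  L_starv <- t$L_m * env$E_Y / t$kappa
  s <- numeric(length(L))
  juv <- L >= t$L_b & L < t$L_p & L <= L_starv
  adu <- L >= t$L_p & L <= t$L_m & L <= L_starv
  s[juv] <- exp(-t$mu_j)
  s[adu] <- exp(-t$mu_a)
  s
}

#' Expected length after one projection interval
#'
#' Discrete-time von Bertalanffy growth of a cohort towards the ultimate
#' length \eqn{L_\infty = L_m E(Y)}:
#' \eqn{E(L') = L e^{-\dot{r}_B} + (1 - e^{-\dot{r}_B}) L_m E(Y)} for
#' \eqn{L \le L_m E(Y)}; individuals above the ultimate length do not shrink.
#'
#' @inheritParams deb_survival
#' @return Expected lengths at the next time step, cm.
#' @export
deb_growth_mean <- function(L, t, env) {
  L_inf <- t$L_m * env$E_Y
  ifelse(L <= L_inf, L * exp(-t$r_B) + (1 - exp(-t$r_B)) * L_inf, L)
}

#' Variance of length after one projection interval
#'
#' Individuals within a cohort experience independently drawn feeding levels
#' with sd \eqn{\sigma(Y)}, giving a length variance of
#' \eqn{(1 - e^{-\dot{r}_B})^2 L_m^2 \sigma(Y)^2} below the ultimate length
#' and 0 above it.
#'
#' @inheritParams deb_survival
#' @return Length variances, cm^2.
#' @export
deb_growth_var <- function(L, t, env) {
  L_inf <- t$L_m * env$E_Y
  ifelse(L <= L_inf,
         (1 - exp(-t$r_B))^2 * t$L_m^2 * env$sigma_Y^2,
         0)
}

#' Growth kernel density
#'
#' Gaussian density of next length \code{L_next} given current length
#' \code{L}, with mean [deb_growth_mean()] and variance [deb_growth_var()].
#' When the variance is zero the transition is deterministic; this function
#' then returns \code{Inf} at the expected length and 0 elsewhere, and the
#' discretization represents it as a unit point mass (see [build_kernels()]).
#'
#' @param L_next Destination length(s), cm.
#' @inheritParams deb_survival
#' @return Probability density per cm.
#' @export
deb_growth_kernel <- function(L_next, L, t, env) {
  m <- deb_growth_mean(L, t, env)
  v <- deb_growth_var(L, t, env)
  out <- numeric(length(L_next))
  pos <- v > 0
  if (length(v) == 1L) pos <- rep(pos, length(L_next))
  if (length(m) == 1L) m <- rep(m, length(L_next))
  if (length(v) == 1L) v <- rep(v, length(L_next))
  out[pos] <- stats::dnorm(L_next[pos], m[pos], sqrt(v[pos]))
  out[!pos] <- ifelse(L_next[!pos] == m[!pos], Inf, 0)
  out
}

#' Per-capita reproduction over one projection interval
#'
#' Number of offspring produced by an individual of length \code{L}:
#' zero for juveniles (\eqn{L < L_p});
#' \eqn{E(Y) R_m L^2 / L_m^2} for adults up to the ultimate length; and, for
#' adults between the ultimate and the starvation length (possible when the
#' cohort grew under better conditions than it currently experiences),
#' \eqn{\frac{R_m}{1-\kappa}\left[E(Y) L^2 - \kappa L^3/L_m\right]/L_m^2},
#' which declines continuously from the ultimate-length value to exactly zero
#' at the starvation length \eqn{L_m E(Y)/\kappa}.
#'
#' @inheritParams deb_survival
#' @return Offspring per year, >= 0.
#' @export
deb_reproduction <- function(L, t, env) {
  E <- env$E_Y
  L_inf <- t$L_m * E
  L_starv <- L_inf / t$kappa
  r <- numeric(length(L))
  b2 <- L >= t$L_p & L <= L_inf
  b3 <- L >= t$L_p & L > L_inf & L <= L_starv
  r[b2] <- E * t$R_m * L[b2]^2 / t$L_m^2
  r[b3] <- t$R_m / (1 - t$kappa) *
    (E * L[b3]^2 - t$kappa * L[b3]^3 / t$L_m) / t$L_m^2
  r
}

#' Parent-offspring size kernel density
#'
#' Offspring length is independent of parent length: for parents at or above
#' the puberty length the kernel is a Gaussian density centred on the birth
#' length \eqn{L_b} with the (small) offspring-size sd \eqn{\sigma_{L_b}};
#' pre-pubertal "parents" contribute zero.
#'
#' @param L_next Offspring length(s), cm.
#' @inheritParams deb_survival
#' @return Probability density per cm.
#' @export
deb_offspring_kernel <- function(L_next, L, t, env) {
  if (length(L) == 1L && L < t$L_p) return(numeric(length(L_next)))
  d <- stats::dnorm(L_next, t$L_b, .sigma_Lb(t, env))
  if (length(L) == 1L) d else d * (L >= t$L_p)
}
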