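# Trait elasticities of the population growth rate, model feasibility, and
# feeding-level sweeps.

.elasticity_traits <- c("kappa", "L_b", "L_p", "L_m", "mu_j", "mu_a", "r_B", "R_m")

# Dominant eigenvalue of the projection matrix for given traits/env.
.lambda_of <- function(t, env, n_bins) {
  k <- build_kernels(t, env, n_bins = n_bins)
  .dominant_eigen(k$A, vectors = FALSE)$lambda
}

#' Model feasibility at a feeding level
#'
#' A DEB-IPM "runs" only when some adult length can both survive and
#' reproduce, i.e. when the starvation length exceeds the puberty length:
#' \eqn{L_m E(Y)/\kappa > L_p}, equivalently \eqn{E(Y) > \kappa L_p / L_m}.
#' Below that threshold, starvation kills all lengths at which reproduction
#' is possible.
#'
#' @param t Species traits.
#' @param env A [deb_env()].
#' @return A list: \code{feasible} (logical), \code{reason} (\code{NA} when
#'   feasible), and the analytic \code{threshold} feeding level
#'   \eqn{\kappa L_p / L_m}.
#' @export
feasibility <- function(t, env) {
  threshold <- t$kappa * t$L_p / t$L_m
  feasible <- env$E_Y > threshold
  reason <- if (feasible) NA_character_ else {
    sprintf(paste0("starvation length L_m*E(Y)/kappa = %.4g cm is not above ",
                   "the puberty length L_p = %.4g cm (requires E(Y) > %.4g)"),
            t$L_m * env$E_Y / t$kappa, t$L_p, threshold)
  }
  list(feasible = feasible, reason = reason, threshold = threshold)
}

#' Elasticity of the population growth rate to one input trait
#'
#' Central-difference proportional perturbation: the full model (mesh and
#' kernels) is rebuilt at \eqn{\theta(1 \pm \delta)} and
#' \eqn{e = (\lambda_+ - \lambda_-) / (2 \delta \lambda_0)}.
#' Perturbations that break the length ordering \eqn{L_b < L_p < L_m},
#' push \eqn{\kappa} out of (0, 1), or make the model infeasible are not
#' evaluated; the result carries an explanatory flag instead.
#'
#' @param t Species traits.
#' @param env A [deb_env()].
#' @param trait_name One of \code{"kappa"}, \code{"L_b"}, \code{"L_p"},
#'   \code{"L_m"}, \code{"mu_j"}, \code{"mu_a"}, \code{"r_B"}, \code{"R_m"}.
#' @param step Proportional perturbation in (0, 0.1]. Default 0.01.
#' @param n_bins Mesh resolution. Default 200.
#' @return One-row \code{data.frame}: \code{trait_name}, \code{elasticity},
#'   \code{step}, \code{lam_base}, \code{flag}.
#' @export
elasticity <- function(t, env, trait_name, step = 0.01, n_bins = 200L) {
  stopifnot(step > 0, step <= 0.1)
  trait_name <- match.arg(trait_name, .elasticity_traits)
  lam0 <- .lambda_of(t, env, n_bins)

  row <- function(e, flag = NA_character_) {
    data.frame(trait_name = trait_name, elasticity = e, step = step,
               lam_base = lam0, flag = flag, stringsAsFactors = FALSE)
  }

  lam_pm <- numeric(2)
  for (s in c(1, 2)) {
    t2 <- t
    t2[[trait_name]] <- t[[trait_name]] * (1 + c(step, -step)[s])
    viol <- validate_traits(t2)
    if (length(viol) > 0L) {
      return(row(NA_real_, paste("infeasible perturbation:",
                                 paste(viol, collapse = "; "))))
    }
    if (!feasibility(t2, env)$feasible) {
      return(row(NA_real_, "infeasible perturbation: crosses the feasibility boundary"))
    }
    lam_pm[s] <- .lambda_of(t2, env, n_bins)
  }
  row((lam_pm[1] - lam_pm[2]) / (2 * step * lam0))
}

#' Elasticities of the growth rate to all eight input traits
#'
#' @inheritParams elasticity
#' @return An eight-row \code{data.frame}, one row per trait.
#' @export
elasticity_all <- function(t, env, step = 0.01, n_bins = 200L) {
  do.call(rbind, lapply(.elasticity_traits, function(nm) {
    elasticity(t, env, nm, step = step, n_bins = n_bins)
  }))
}

#' Sweep a species over feeding levels
#'
#' Evaluates feasibility at each feeding level and, where feasible, the full
#' set of demographic outputs ([derived_traits()]). Rows for infeasible
#' levels carry the feasibility reason and \code{NA} results.
#'
#' @param t Species traits.
#' @param levels Feeding levels in (0, 1]. Default \code{c(0.5, 0.7, 0.9)}.
#' @param env_base A [deb_env()] supplying \code{sigma_Y} and the
#'   offspring-size dispersion; its \code{E_Y} is replaced by each level.
#' @param n_bins,tol,max_age Passed to the model build and life table.
#' @return A \code{data.frame} with one row per level: \code{feasible},
#'   \code{reason}, and the [derived_traits()] columns. The attribute
#'   \code{min_feasible} holds the smallest feasible level (\code{NA} if
#'   none).
#' @export
feeding_sweep <- function(t, levels = c(0.5, 0.7, 0.9), env_base = deb_env(1),
                          n_bins = 200L, tol = 1e-9, max_age = 5000L) {
  if (length(levels) == 0L) stop("empty feeding-level grid")
  if (any(!is.finite(levels)) || any(levels <= 0) || any(levels > 1)) {
    stop("feeding levels must lie in (0, 1]")
  }
  rows <- lapply(levels, function(ey) {
    env <- deb_env(ey, sigma_Y = env_base$sigma_Y, sigma_Lb = env_base$sigma_Lb,
                   sigma_Lb_frac = env_base$sigma_Lb_frac)
    fz <- feasibility(t, env)
    if (!fz$feasible) {
      out <- derived_traits_na(t, env)
      out$feasible <- FALSE
      out$reason <- fz$reason
      return(out)
    }
    k <- build_kernels(t, env, n_bins = n_bins)
    out <- derived_traits(k, tol = tol, max_age = max_age)
    out$feasible <- TRUE
    out$reason <- NA_character_
    out
  })
  out <- do.call(rbind, rows)
  feas_levels <- levels[out$feasible]
  attr(out, "min_feasible") <- if (length(feas_levels)) min(feas_levels) else NA_real_
  out
}

# An all-NA derived-traits row (infeasible species x level combinations).
derived_traits_na <- function(t, env) {
  data.frame(
    record_id = if (!is.null(t$record_id)) t$record_id else NA_character_,
    E_Y = env$E_Y, sigma_Y = env$sigma_Y,
    lambda = NA_real_, damping = NA_real_, T = NA_real_, H = NA_real_,
    L_alpha = NA_real_, gamma = NA_real_, rho = NA_real_, phi = NA_real_,
    S_itero = NA_real_, R0 = NA_real_, R0_lifetable = NA_real_,
    L_omega = NA_real_, eta_e = NA_real_, flags = "",
    stringsAsFactors = FALSE
  )
}
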