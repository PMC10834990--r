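# Age-from-stage life-history traits: life table, Keyfitz entropy, age at
# maturity, mature life expectancy, growth directionality, recruitment,
# degree of iteroparity, and the assembled trait set.

#' Age-from-stage life table of a discretized DEB-IPM
#'
#' Starts a cohort from the offspring length distribution (the adult-averaged
#' column of \code{D}) and projects it with survival-and-growth \code{GS}:
#' \eqn{n_{x+1} = GS\, n_x}. Survivorship is \eqn{l_x = \sum n_x}
#' (with \eqn{l_0 = 1}) and age-specific fertility is
#' \eqn{m_x = \sum (V n_x)/l_x}. The table is truncated at the first age with
#' \eqn{l_x <} \code{tol} or at \code{max_age}.
#'
#' @param k A \code{deb_ipm} (or any list with matrices \code{GS}, \code{V};
#'   the starting cohort is taken from \code{D} or from \code{cohort_init}).
#' @param tol Survivorship truncation tolerance (> 0). Default 1e-9.
#' @param max_age Hard cap on the number of age classes. Default 5000.
#' @param cohort_init Optional starting length distribution (overrides the
#'   offspring distribution; normalized internally).
#' @return A list of class \code{life_table}: \code{ages} (0..x_max),
#'   \code{l_x}, \code{m_x}, \code{cohort_init}.
#' @export
life_table <- function(k, tol = 1e-9, max_age = 5000L, cohort_init = NULL) {
  stopifnot(tol > 0)
  if (is.null(cohort_init)) {
    adult_cols <- which(colSums(k$D) > 0)
    if (length(adult_cols) == 0L) stop("no adult columns in D: cannot form a cohort")
    cohort_init <- rowMeans(k$D[, adult_cols, drop = FALSE])
  }
  n0 <- cohort_init / sum(cohort_init)

  l <- numeric(0); m <- numeric(0)
  nvec <- n0
  lx <- 1
  age <- 0L
  while (lx >= tol && age <= max_age) {
    l <- c(l, lx)
    m <- c(m, sum(k$V %*% nvec) / lx)
    nvec <- k$GS %*% nvec
    lx <- sum(nvec)
    age <- age + 1L
  }
  structure(list(ages = seq_along(l) - 1L, l_x = l, m_x = m,
                 cohort_init = n0),
            class = "life_table")
}

#' Keyfitz entropy of a survivorship schedule
#'
#' \eqn{H = -\sum_x l_x \log(l_x) / \sum_x l_x}. Under a constant mortality
#' rate \eqn{H \approx 1}; \eqn{H < 1} indicates mortality increasing with
#' age and \eqn{H > 1} mortality decreasing with age.
#'
#' @param lt A \code{life_table}, or a numeric survivorship vector
#'   \code{l_x} starting at \eqn{l_0 = 1}.
#' @return Keyfitz entropy (dimensionless); \code{NA} with a warning for a
#'   degenerate one-age schedule.
#' @export
keyfitz_entropy <- function(lt) {
  l <- if (inherits(lt, "life_table")) lt$l_x else as.numeric(lt)
  l <- l[l > 0]
  if (length(l) < 2L) {
    warning("degenerate survivorship schedule: entropy undefined")
    return(NA_real_)
  }
  -sum(log(l) * l) / sum(l)
}

# Indices of juvenile and adult bins, and the bins holding L_b and L_p.
.stage_bins <- function(k) {
  x <- k$mesh$midpoints
  list(juv = which(x < k$traits$L_p),
       adult = which(x >= k$traits$L_p),
       birth = .bin_of(k$mesh, k$traits$L_b),
       puberty = .bin_of(k$mesh, k$traits$L_p))
}

#' Age at maturity
#'
#' Expected number of years spent in juvenile length bins by an individual
#' starting in the bin containing the birth length, from the
#' juvenile-restricted fundamental matrix
#' \eqn{(I - (GS)_{JJ})^{-1}}. By default the expectation is over all
#' newborns, including those that die before maturing; with
#' \code{conditional = TRUE} it is conditioned on reaching maturity
#' (computed on the maturation-conditioned juvenile chain), which gives
#' larger values when juvenile mortality is substantial.
#'
#' @param k A \code{deb_ipm}.
#' @param conditional Condition on surviving to maturity? Default
#'   \code{FALSE}.
#' @return Age at maturity in years; 0 with a warning if no juvenile bins
#'   exist.
#' @export
age_at_maturity <- function(k, conditional = FALSE) {
  st <- .stage_bins(k)
  if (length(st$juv) == 0L) {
    warning("no juvenile bins below L_p: age at maturity reported as 0")
    return(0)
  }
  M <- k$GS[st$juv, st$juv, drop = FALSE]
  bcol <- match(st$birth, st$juv)
  if (is.na(bcol)) stop("birth-length bin is not a juvenile bin")
  Nj <- solve(diag(length(st$juv)) - M)
  if (!conditional) return(sum(Nj[, bcol]))

  # one-step maturation probabilities, then the alpha-conditioned chain
  u <- colSums(k$GS[st$adult, st$juv, drop = FALSE])
  alpha <- as.numeric(crossprod(Nj, u)) # P(ever mature | start in j)
  if (alpha[bcol] <= 0) {
    warning("no maturation path from the birth bin")
    return(NA_real_)
  }
  keep <- alpha > 0
  Mc <- M[keep, keep, drop = FALSE] *
    outer(alpha[keep], alpha[keep], function(ai, aj) ai / aj)
  Nc <- solve(diag(sum(keep)) - Mc)
  sum(Nc[, match(bcol, which(keep))])
}

#' Mature life expectancy
#'
#' Expected number of years lived from the bin containing the puberty
#' length: the column sum of the full fundamental matrix
#' \eqn{N = (I - GS)^{-1}} at that bin.
#'
#' @param k A \code{deb_ipm}.
#' @param Nfund Optional precomputed fundamental matrix (e.g. from
#'   [core_demography()]).
#' @return Years.
#' @export
mature_life_expectancy <- function(k, Nfund = NULL) {
  st <- .stage_bins(k)
  if (is.null(Nfund)) Nfund <- solve(diag(nrow(k$GS)) - k$GS)
  sum(Nfund[, st$puberty])
}

#' Mean life expectancy from birth
#'
#' Expected total years lived by an individual starting in the bin
#' containing the birth length (column sum of the fundamental matrix).
#' Approximately decomposes as age at maturity plus mature life expectancy.
#'
#' @inheritParams mature_life_expectancy
#' @return Years.
#' @export
life_expectancy_at_birth <- function(k, Nfund = NULL) {
  st <- .stage_bins(k)
  if (is.null(Nfund)) Nfund <- solve(diag(nrow(k$GS)) - k$GS)
  sum(Nfund[, st$birth])
}

#' Progressive and retrogressive growth probabilities
#'
#' Stable-structure-weighted mean probabilities of moving to a larger
#' (\eqn{\gamma}) or smaller (\eqn{\rho}) length bin in one step. Rows of
#' \code{G} are destinations, so progressive mass lies below the diagonal.
#'
#' @param k A \code{deb_ipm}.
#' @param w Stable length distribution; computed from \code{A} if omitted.
#' @return Named numeric vector \code{c(gamma = , rho = )}, both in \[0, 1\].
#' @export
growth_directionality <- function(k, w = NULL) {
  if (is.null(w)) w <- .dominant_eigen(k$A)$w
  G <- k$G
  gamma <- sum(w * colSums(G * lower.tri(G)))
  rho <- sum(w * colSums(G * upper.tri(G)))
  c(gamma = gamma, rho = rho)
}

#' Mean recruitment success
#'
#' Stable-structure-weighted mean per-capita recruit production:
#' \eqn{\varphi = \sum_j w_j \sum_i V_{ij}}.
#'
#' @inheritParams growth_directionality
#' @return Recruits per capita per year.
#' @export
mean_recruitment <- function(k, w = NULL) {
  if (is.null(w)) w <- .dominant_eigen(k$A)$w
  sum(w * colSums(k$V))
}

#' Degree of iteroparity
#'
#' Coefficient of variation of the age-at-reproduction distribution, with
#' ages weighted by net fertility \eqn{f_x = l_x m_x}:
#' \eqn{S = \sqrt{V_f}/\bar{a}_f}. \eqn{S = 0} is the semelparous extreme
#' (all reproduction at a single age); spreading reproduction over more ages
#' increases \eqn{S}.
#'
#' @param lt A [life_table()].
#' @return Dimensionless CV; \code{NA} with a warning when the schedule has
#'   no reproduction.
#' @export
degree_of_iteroparity <- function(lt) {
  f <- lt$l_x * lt$m_x
  if (sum(f) <= 0) {
    warning("no reproduction in the life table: iteroparity undefined")
    return(NA_real_)
  }
  x <- as.numeric(lt$ages)
  abar <- sum(x * f) / sum(f)
  Vf <- max(sum(x^2 * f) / sum(f) - abar^2, 0)
  if (abar == 0) {
    warning("all reproduction at age 0: iteroparity undefined")
    return(NA_real_)
  }
  sqrt(Vf) / abar
}

#' Derived life-history traits of a DEB-IPM
#'
#' Assembles the full set of derived traits for one species at one feeding
#' level: generation time \code{T}, Keyfitz entropy \code{H}, age at
#' maturity \code{L_alpha}, progressive/retrogressive growth
#' \code{gamma}/\code{rho}, mean recruitment success \code{phi}, degree of
#' iteroparity \code{S_itero}, net reproductive rate \code{R0} and mature
#' life expectancy \code{L_omega}, together with \code{lambda}, the damping
#' ratio, the mean life expectancy from birth \code{eta_e}, and the
#' life-table cross-check of \eqn{R_0} (\eqn{\sum_x l_x m_x}); a flag is
#' raised if the two \eqn{R_0} routes disagree by more than 1%.
#'
#' @param k A \code{deb_ipm}.
#' @param core Optional precomputed [core_demography()].
#' @param tol,max_age Passed to [life_table()].
#' @param conditional_maturity Passed to [age_at_maturity()].
#' @return A one-row \code{data.frame} of class \code{life_history_result}.
#' @examples
#' tab <- simulate_debbies(1, seed = 4)
#' k <- build_kernels(species_traits(tab), deb_env(0.9))
#' derived_traits(k)
#' @export
derived_traits <- function(k, core = NULL, tol = 1e-9, max_age = 5000L,
                           conditional_maturity = FALSE) {
  if (is.null(core)) core <- core_demography(k)
  lt <- life_table(k, tol = tol, max_age = max_age)
  gr <- growth_directionality(k, w = core$w)
  R0_lt <- sum(lt$l_x * lt$m_x)

  flags <- paste(core$flags, collapse = "; ")
  if (core$R0 > 0 && abs(R0_lt - core$R0) / core$R0 > 0.01) {
    flags <- paste0(flags, if (nzchar(flags)) "; ",
                    sprintf("R0 routes disagree: eigenvalue %.6g vs life table %.6g",
                            core$R0, R0_lt))
  }

  res <- data.frame(
    record_id = if (!is.null(k$traits$record_id)) k$traits$record_id else NA_character_,
    E_Y = k$env$E_Y,
    sigma_Y = k$env$sigma_Y,
    lambda = core$lambda,
    damping = core$damping,
    T = core$T,
    H = keyfitz_entropy(lt),
    L_alpha = age_at_maturity(k, conditional = conditional_maturity),
    gamma = unname(gr["gamma"]),
    rho = unname(gr["rho"]),
    phi = mean_recruitment(k, w = core$w),
    S_itero = suppressWarnings(degree_of_iteroparity(lt)),
    R0 = core$R0,
    R0_lifetable = R0_lt,
    L_omega = mature_life_expectancy(k, Nfund = core$Nfund),
    eta_e = life_expectancy_at_birth(k, Nfund = core$Nfund),
    flags = flags,
    stringsAsFactors = FALSE
  )
  class(res) <- c("life_history_result", "data.frame")
  res
}
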