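# Discretization of the length-structured projection kernel into matrices
# (S, G, R, D, V, A) and the core demographic quantities derived from them.

#' Build a length mesh for kernel discretization
#'
#' The length domain runs from just below the birth length (at least 6
#' offspring-size standard deviations, so that effectively all offspring
#' mass is representable) up to the larger of the maximum length and the
#' starvation length. The lower bound is placed so that \eqn{L_b} falls
#' exactly on a bin midpoint: the offspring-size distribution is much
#' narrower than a bin at realistic resolutions, so recruits are effectively
#' a point mass at \eqn{L_b}, and anchoring that point to a midpoint keeps
#' their represented length exact at every resolution (otherwise the
#' sub-bin offset of \eqn{L_b} oscillates with \code{n_bins} and so does
#' the growth rate).
#'
#' @param t Species traits.
#' @param env A [deb_env()].
#' @param n_bins Number of equal-width bins; default 200.
#' @return A list of class \code{deb_mesh}: \code{n_bins}, \code{lower},
#'   \code{upper}, \code{midpoints}, \code{width}, \code{edges}.
#' @export
build_mesh <- function(t, env, n_bins = 200L) {
  stopifnot(n_bins >= 10)
  vals <- c(t$L_b, t$L_p, t$L_m, t$kappa, t$mu_j, t$mu_a, t$r_B, t$R_m)
  if (!all(is.finite(as.numeric(vals)))) stop("non-finite trait values")
  n_bins <- as.integer(n_bins)
  s_lb <- .sigma_Lb(t, env)
  # upper bound covers the starvation length at ANY feeding level (E(Y) = 1)
  # so that the mesh is identical across a feeding sweep; bins above the
  # current starvation length are simply dead. An E(Y)-dependent domain
  # changes the bin layout between feeding levels and the resulting
  # discretization noise can mask the monotone response of lambda to food.
  upper <- max(t$L_m, t$L_m / t$kappa)
  h0 <- (upper - max(t$L_b - 6 * s_lb, 1e-4)) / n_bins
  # number of bin midpoints at or below L_b needed to cover the 6-sigma
  # offspring margin, then solve the width so L_b sits on midpoint j0
  j0 <- max(1, ceiling(6 * s_lb / h0 + 0.5))
  width <- (upper - t$L_b) / (n_bins - j0 + 0.5)
  lower <- t$L_b - (j0 - 0.5) * width
  if (lower <= 0) { # very wide bins relative to L_b: fall back, unaligned
    lower <- max(t$L_b - 6 * s_lb, 1e-4)
    width <- (upper - lower) / n_bins
  }
  structure(list(n_bins = n_bins, lower = lower, upper = upper,
                 midpoints = lower + (seq_len(n_bins) - 0.5) * width,
                 width = width,
                 edges = lower + (0:n_bins) * width),
            class = "deb_mesh")
}

# Index of the bin containing length L (ties on an edge go to the lower bin).
.bin_of <- function(mesh, L) {
  i <- ceiling((L - mesh$lower) / mesh$width)
  min(mesh$n_bins, max(1L, as.integer(i)))
}

# Bin-average a piecewise function over the mesh: each bin is split at the
# supplied knots (branch boundaries), the function is evaluated at each
# piece's midpoint, and pieces are width-weighted. Exact for the step
# discontinuities of survival/reproduction; midpoint-accurate between knots.
# Evaluating bins by raw midpoints instead makes survival of the bin holding
# L_b (where essentially all offspring land) flip between 0 and e^(-mu_j)
# with mesh resolution, which wrecks eigenvalue convergence.
.bin_average <- function(f, mesh, knots) {
  edges <- mesh$edges
  knots <- knots[knots > mesh$lower & knots < mesh$upper]
  brk <- sort(unique(c(edges, knots)))
  mid <- (brk[-1L] + brk[-length(brk)]) / 2
  w <- diff(brk)
  bin <- findInterval(mid, edges, rightmost.closed = TRUE)
  as.numeric(rowsum(f(mid) * w, bin, reorder = TRUE)) / mesh$width
}

# Sub-bin source pieces: bins split at the supplied knots, with each piece's
# midpoint, parent bin, and width as a fraction of the bin width.
.source_pieces <- function(mesh, knots) {
  edges <- mesh$edges
  knots <- knots[knots > mesh$lower & knots < mesh$upper]
  brk <- sort(unique(c(edges, knots)))
  mid <- (brk[-1L] + brk[-length(brk)]) / 2
  list(mid = mid,
       lo = brk[-length(brk)],
       hi = brk[-1L],
       frac = diff(brk) / mesh$width,
       bin = findInterval(mid, edges, rightmost.closed = TRUE))
}

#' Discretize the DEB-IPM kernel into projection matrices
#'
#' Divides the length domain into \code{n_bins} bins and assembles, with
#' sources as columns and destinations as rows:
#' the survival vector \code{S} and fecundity vector \code{R} (exact bin
#' averages of the piecewise kernel functions, with bins split at the branch
#' boundaries \eqn{L_b}, \eqn{L_p}, \eqn{L_\infty}, the starvation length
#' and \eqn{L_m}, so that boundary bins carry the correct partial rates),
#' the growth transition matrix \code{G} (Gaussian bin masses by CDF
#' differences, renormalized column-wise; zero-variance columns become unit
#' point masses at the bin containing the expected length), the
#' offspring-size matrix \code{D} (renormalized for adult columns), the
#' recruitment matrix \code{V = D diag(R)} and the projection matrix
#' \code{A = V + G diag(S)}, the matrix form of the one-step kernel
#' \code{D R + G S}.
#'
#' A warning reports the lost-mass figure if more than \code{1e-6} of the
#' offspring distribution falls outside the mesh before renormalization.
#'
#' @inheritParams build_mesh
#' @param mesh A [build_mesh()] result, or \code{NULL} to build one.
#' @return A list of class \code{deb_ipm}: \code{S}, \code{G}, \code{R},
#'   \code{D}, \code{V}, \code{GS}, \code{A}, \code{mesh}, \code{traits},
#'   \code{env}.
#' @examples
#' tab <- simulate_debbies(1, seed = 4)
#' k <- build_kernels(species_traits(tab), deb_env(0.9))
#' dim(k$A)
#' @export
build_kernels <- function(t, env, n_bins = 200L, mesh = NULL) {
  viol <- validate_traits(t)
  if (length(viol) > 0L) stop("invalid traits: ", paste(viol, collapse = "; "))
  if (is.null(mesh)) mesh <- build_mesh(t, env, n_bins)
  n <- mesh$n_bins
  x <- mesh$midpoints
  edges <- mesh$edges

  dl <- derived_lengths(t, env)
  knots <- c(t$L_b, t$L_p, t$L_m, dl$L_inf, dl$L_starv)
  S <- .bin_average(function(L) deb_survival(L, t, env), mesh, knots)
  R <- .bin_average(function(L) deb_reproduction(L, t, env), mesh, knots)

  # Growth columns are built from sub-bin pieces (bins split at the L_inf
  # knot where the growth variance drops to zero) so that a source bin
  # straddling the ultimate length contributes fractionally to both the
  # diffusing and the frozen regime; a per-bin binary switch there is an
  # O(h) error that high-fecundity species amplify. Below L_inf the growth
  # mean is linear in the source length, so the uniform-source bin mass has
  # a closed form via the Gaussian CDF antiderivative (exact integration
  # over both source piece and destination bin).
  pieces <- .source_pieces(mesh, dl$L_inf)
  v_p <- deb_growth_var(pieces$mid, t, env)
  G <- matrix(0, n, n)
  pos <- which(v_p > 0)
  if (length(pos) > 0L) {
    sd_g <- sqrt(v_p[pos[1L]]) # growth variance is constant where positive
    b <- exp(-t$r_B)           # slope of the growth mean in source length
    cc <- (1 - b) * dl$L_inf   # intercept of the growth mean
    psi <- function(u) u * stats::pnorm(u) + stats::dnorm(u)
    l1 <- pieces$lo[pos]; l2 <- pieces$hi[pos]
    # I(e, piece) = mean over the piece of P(L' <= e)
    U1 <- (outer(edges, cc + b * l1, "-")) / sd_g
    U2 <- (outer(edges, cc + b * l2, "-")) / sd_g
    Iacc <- sd_g * (psi(U1) - psi(U2)) / rep(b * (l2 - l1), each = n + 1L)
    masses <- Iacc[-1L, , drop = FALSE] - Iacc[-(n + 1L), , drop = FALSE]
    masses <- pmax(masses, 0)
    masses <- sweep(masses, 2L, colSums(masses), "/")
    contrib <- rowsum(t(masses) * pieces$frac[pos], pieces$bin[pos],
                      reorder = TRUE)
    G[, unique(sort(pieces$bin[pos]))] <- t(contrib)
  }
  for (p in setdiff(seq_along(pieces$mid), pos)) {
    # deterministic transition (sigma_Y = 0, or source above L_inf where
    # lengths do not change): unit mass at the expected length
    dest <- .bin_of(mesh, deb_growth_mean(pieces$mid[p], t, env))
    G[dest, pieces$bin[p]] <- G[dest, pieces$bin[p]] + pieces$frac[p]
  }
  G <- sweep(G, 2L, colSums(G), "/")

  d_raw <- diff(stats::pnorm(edges, t$L_b, .sigma_Lb(t, env)))
  lost <- 1 - sum(d_raw)
  if (lost > 1e-6) {
    warning(sprintf("offspring mass outside the mesh before renormalization: %.3g",
                    lost))
  }
  d_col <- d_raw / sum(d_raw)
  D <- matrix(0, n, n)
  adult <- edges[-1L] > t$L_p # any adult fraction; R carries the L_p gating
  D[, adult] <- d_col

  V <- D * rep(R, each = n)
  GS <- G * rep(S, each = n)
  A <- V + GS
  structure(list(S = S, G = G, R = R, D = D, V = V, GS = GS, A = A,
                 mesh = mesh, traits = t, env = env),
            class = "deb_ipm")
}

# Dominant eigenpair of a non-negative matrix; asserts the dominant
# eigenvalue is real (Perron-Frobenius) within tolerance.
.dominant_eigen <- function(A, vectors = TRUE) {
  e <- eigen(A, only.values = !vectors)
  mods <- Mod(e$values)
  i1 <- which.max(mods)
  lam <- e$values[i1]
  if (abs(Im(lam)) > 1e-10 * max(1, abs(Re(lam)))) {
    stop("dominant eigenvalue has a non-negligible imaginary part")
  }
  w <- NULL
  if (vectors) {
    w <- Re(e$vectors[, i1])
    if (sum(w) < 0) w <- -w
    w[w < 0 & w > -1e-12 * max(abs(w))] <- 0
    w <- w / sum(w)
  }
  list(lambda = Re(lam), w = w, mods = sort(mods, decreasing = TRUE))
}

#' Core demography of a discretized DEB-IPM
#'
#' Computes the population growth rate \eqn{\lambda} (dominant eigenvalue of
#' \code{A}), the stable length distribution \code{w} (right eigenvector,
#' scaled to sum to 1), reproductive values \code{v} (left eigenvector,
#' scaled so \code{v \%*\% w = 1}), the damping ratio
#' \eqn{\lambda_1/|\lambda_2|} (demographic resilience), the fundamental
#' matrix \eqn{N = (I - GS)^{-1}} (expected years spent in each length bin
#' per starting bin), the next-generation matrix \eqn{F = V N}, the net
#' reproductive rate \eqn{R_0} (dominant eigenvalue of \code{F}) and the
#' generation time \eqn{T = \log R_0 / \log \lambda}.
#'
#' @param k A \code{deb_ipm} from [build_kernels()], or any list with
#'   non-negative matrices \code{A}, \code{GS} and \code{V} (e.g. a toy
#'   stage-structured model).
#' @return A list of class \code{core_demography}: \code{lambda}, \code{w},
#'   \code{v}, \code{damping}, \code{R0}, \code{T}, \code{Nfund}, \code{F},
#'   and \code{flags} (character; e.g. when \code{T} is undefined at
#'   \eqn{\lambda = 1}).
#' @export
core_demography <- function(k) {
  A <- k$A
  if (any(!is.finite(A)) || any(A < 0)) stop("A must be non-negative and finite")
  n <- nrow(A)
  flags <- character(0)

  dom <- .dominant_eigen(A)
  lambda <- dom$lambda
  if (lambda <= 0) stop("computed population growth rate is not positive")
  damping <- if (n >= 2L && dom$mods[2L] > 0) lambda / dom$mods[2L] else Inf

  vdom <- .dominant_eigen(t(A))
  v <- vdom$w
  v <- v / sum(v * dom$w)

  Nfund <- solve(diag(n) - k$GS)
  Fmat <- k$V %*% Nfund
  R0 <- .dominant_eigen(Fmat, vectors = FALSE)$lambda
  if (R0 < 0 && R0 > -1e-12) R0 <- 0

  if (abs(lambda - 1) < 1e-12) {
    Tg <- NA_real_
    flags <- c(flags, "generation time undefined: lambda = 1")
  } else if (R0 <= 0) {
    Tg <- NA_real_
    flags <- c(flags, "generation time undefined: R0 = 0")
  } else {
    Tg <- log(R0) / log(lambda)
  }

  structure(list(lambda = lambda, w = dom$w, v = v, damping = damping,
                 R0 = R0, T = Tg, Nfund = Nfund, F = Fmat, flags = flags),
            class = "core_demography")
}

#' Generation time from net reproductive rate and growth rate
#'
#' \eqn{T = \log(R_0)/\log(\lambda)}: the time over which the population
#' grows by its net reproductive rate, i.e. is fully replaced.
#'
#' @param R0 Net reproductive rate (> 0).
#' @param lambda Population growth rate (> 0).
#' @return Generation time in years; \code{NA} with a warning when
#'   \eqn{\lambda = 1} (the ratio is undefined).
#' @export
generation_time <- function(R0, lambda) {
  stopifnot(is.finite(R0), R0 > 0, is.finite(lambda), lambda > 0)
  if (abs(lambda - 1) < 1e-12) {
    warning("generation time undefined at lambda = 1")
    return(NA_real_)
  }
  log(R0) / log(lambda)
}

#' @export
print.deb_ipm <- function(x, ...) {
  cat(sprintf("DEB-IPM kernel set: %d x %d, E(Y) = %g, sigma(Y) = %g\n",
              x$mesh$n_bins, x$mesh$n_bins, x$env$E_Y, x$env$sigma_Y))
  cat(sprintf("length domain [%.4g, %.4g] cm, bin width %.4g cm\n",
              x$mesh$lower, x$mesh$upper, x$mesh$width))
  invisible(x)
}

#' @export
print.core_demography <- function(x, ...) {
  cat(sprintf("lambda = %.6g  damping = %.4g  R0 = %.6g  T = %.4g yr\n",
              x$lambda, x$damping, x$R0, x$T))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Export kernel matrices as plain-text files
#'
#' Writes \code{S}, \code{G}, \code{R}, \code{D}, \code{V} and \code{A} as
#' CSV files named \code{<record_id>_EY<level>_<matrix>.csv} in
#' deterministic order.
#'
#' @param k A \code{deb_ipm}.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_kernels <- function(k, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- if (!is.null(k$traits$record_id)) k$traits$record_id else "species"
  stem <- file.path(dir, sprintf("%s_EY%g", id, k$env$E_Y))
  files <- character(0)
  for (nm in c("S", "G", "R", "D", "V", "A")) {
    f <- sprintf("%s_%s.csv", stem, nm)
    utils::write.table(k[[nm]], f, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
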