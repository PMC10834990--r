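test_that("life table reproduces geometric survivorship for one state", {
  lt <- life_table(one_state_toy(0.7), tol = 1e-6)
  expect_equal(lt$l_x, 0.7^(lt$ages))
  expect_equal(lt$l_x[1], 1)
  expect_true(all(diff(lt$l_x) <= 0))
  expect_true(min(lt$l_x) >= 1e-6) # truncation contract
  expect_error(life_table(one_state_toy(0.7), tol = 0), "tol")
})

test_that("life-table net fertility matches the closed-form R0 of the toy", {
  p <- 0.3; s <- 0.8; f <- 2.5
  lt <- life_table(two_stage_toy(p, s, f), tol = 1e-12)
  expect_equal(sum(lt$l_x * lt$m_x), p * f / (1 - s), tolerance = 1e-9)
  # the cohort starts entirely juvenile: no age-0 reproduction here
  expect_equal(lt$m_x[1], 0)
})

test_that("Keyfitz entropy separates constant, rising and falling mortality", {
  x <- 0:1500
  # constant mortality: H -> 1 (exact limit -log(s) s/(1-s) for s = e^-0.05)
  H_const <- keyfitz_entropy(exp(-0.05 * x))
  expect_lt(abs(H_const - 1), 0.03)
  expect_equal(H_const, 0.05 * exp(-0.05) / (1 - exp(-0.05)), tolerance = 1e-6)
  # mortality rising with age (hazard 0.01 + 0.002 x): H < 1
  mu_up <- 0.01 + 0.002 * x
  expect_lt(keyfitz_entropy(exp(-cumsum(c(0, mu_up)))), 1)
  # mortality falling with age (hazard decaying 0.25 -> 0.05): H > 1
  mu_dn <- 0.05 + 0.2 * exp(-0.05 * x)
  expect_gt(keyfitz_entropy(exp(-cumsum(c(0, mu_dn)))), 1)
  # survivorship plateau then death: H -> 0 as the plateau lengthens
  expect_lt(keyfitz_entropy(c(rep(1, 50), 1e-12)), 0.01)
  expect_warning(H <- keyfitz_entropy(c(1)), "degenerate")
  expect_true(is.na(H))
})

test_that("age at maturity is the geometric waiting time in the toy", {
  # per-step maturation probability p, no juvenile mortality
  p <- 0.25
  k <- two_stage_toy(p, s = 0.5, f = 1, stay_juv = 1 - p)
  expect_equal(age_at_maturity(k), 1 / p)
  # with competing juvenile death the unconditional time shortens ...
  k2 <- two_stage_toy(p, s = 0.5, f = 1, stay_juv = 0.5)
  expect_lt(age_at_maturity(k2), 1 / p)
  # ... and conditioning cannot shorten it for a single juvenile state
  expect_equal(age_at_maturity(k2, conditional = TRUE),
               age_at_maturity(k2))
})

test_that("conditional age at maturity exceeds unconditional under mortality", {
  tab <- simulate_debbies(30, seed = 4)
  t <- species_traits(tab, which.max(tab$mu_j * (tab$L_p / tab$L_b)))
  k <- build_kernels(t, deb_env(0.9))
  La_u <- age_at_maturity(k)
  La_c <- age_at_maturity(k, conditional = TRUE)
  expect_true(is.finite(La_u) && is.finite(La_c))
  expect_gte(La_c, La_u)
})

test_that("mature life expectancy is geometric for a growth-free adult", {
  mu_a <- 0.3
  k <- two_stage_toy(0.5, exp(-mu_a), 1)
  expect_equal(mature_life_expectancy(k), 1 / (1 - exp(-mu_a)))
  # one-state adult: 1/(1-s)
  expect_equal(sum(solve(diag(1) - one_state_toy(0.9)$GS)), 10)
})

test_that("growth directionality weights sub/super-diagonal mass by w", {
  k <- build_kernels(make_traits(), deb_env(0.9))
  gr <- growth_directionality(k)
  expect_true(all(gr >= 0 & gr <= 1))
  expect_lte(sum(gr), 1)
  # deterministic growth strictly toward L_inf: no retrogression
  k0 <- build_kernels(make_traits(), deb_env(0.9, sigma_Y = 0))
  gr0 <- growth_directionality(k0)
  expect_equal(unname(gr0["rho"]), 0)
  expect_gt(unname(gr0["gamma"]), 0)
  # identity growth matrix: no movement at all
  k_id <- k
  k_id$G <- diag(nrow(k$A))
  expect_equal(unname(growth_directionality(k_id, w = core_demography(k)$w)),
               c(0, 0))
})

test_that("mean recruitment is the w-weighted column sum of V", {
  k <- build_kernels(make_traits(), deb_env(0.9))
  core <- core_demography(k)
  phi <- mean_recruitment(k, w = core$w)
  expect_equal(phi, sum(core$w * colSums(k$V)))
  # no reproduction, no recruitment
  kz <- k; kz$V <- matrix(0, nrow(k$A), ncol(k$A))
  expect_equal(mean_recruitment(kz, w = core$w), 0)
  # linear in R_m with the structure held fixed
  k2 <- k; k2$V <- 2 * k$V
  expect_equal(mean_recruitment(k2, w = core$w), 2 * phi)
})

test_that("degree of iteroparity is the CV of the age-at-reproduction weights", {
  lt1 <- structure(list(ages = 0:3, l_x = c(1, 0.5, 0.25, 0.125),
                        m_x = c(0, 0, 8, 0)), class = "life_table")
  expect_equal(degree_of_iteroparity(lt1), 0) # semelparous extreme
  # equal net fertility at ages 1 and 3: abar = 2, Vf = 1, S = 0.5
  lt2 <- structure(list(ages = 0:3, l_x = c(1, 0.5, 0.25, 0.125),
                        m_x = c(0, 2, 0, 8)), class = "life_table")
  expect_equal(degree_of_iteroparity(lt2), 0.5)
  # spreading reproduction at fixed mean age increases S
  lt3 <- structure(list(ages = 0:4, l_x = rep(1, 5),
                        m_x = c(0, 1, 1, 1, 0)), class = "life_table")
  lt4 <- structure(list(ages = 0:4, l_x = rep(1, 5),
                        m_x = c(0, 1, 0, 1, 0)), class = "life_table")
  expect_gt(degree_of_iteroparity(lt4), degree_of_iteroparity(lt3))
  ltz <- structure(list(ages = 0:2, l_x = c(1, 0.5, 0.25),
                        m_x = c(0, 0, 0)), class = "life_table")
  expect_warning(S <- degree_of_iteroparity(ltz), "no reproduction")
  expect_true(is.na(S))
})

test_that("derived traits assemble finite values and matching R0 routes", {
  k <- build_kernels(make_traits(), deb_env(0.9))
  dt <- derived_traits(k)
  for (cn in c("lambda", "damping", "T", "H", "L_alpha", "gamma", "rho",
               "phi", "S_itero", "R0", "L_omega", "eta_e")) {
    expect_true(is.finite(dt[[cn]]), info = cn)
  }
  expect_gte(dt$damping, 1)
  expect_true(dt$gamma >= 0 && dt$gamma <= 1 && dt$rho >= 0 && dt$rho <= 1)
  expect_equal(dt$R0, dt$R0_lifetable, tolerance = 1e-6)
  expect_false(grepl("disagree", dt$flags))
})

test_that("the two R0 routes coincide once truncation is tightened", {
  # a slow-growing, high-juvenile-mortality species reproduces only at ages
  # where survivorship is astronomically small; at the default tolerance the
  # life-table sum misses that tail, but tightening the tolerance recovers
  # the next-generation-matrix value
  tab <- simulate_debbies(50, seed = 1)
  t <- species_traits(tab, 35)
  k <- build_kernels(t, deb_env(0.9))
  R0_eig <- core_demography(k)$R0
  lt_loose <- life_table(k, tol = 1e-9)
  lt_tight <- life_table(k, tol = 1e-150, max_age = 20000L)
  expect_gt(abs(sum(lt_loose$l_x * lt_loose$m_x) - R0_eig), 0.01 * R0_eig)
  expect_equal(sum(lt_tight$l_x * lt_tight$m_x), R0_eig, tolerance = 1e-6)
})

test_that("life expectancy from birth rises with feeding when adult life is safer", {
  # more food shrinks the starvation band and speeds growth into the adult
  # band; when adults face no more mortality than juveniles that can only
  # lengthen life. (When mu_a > mu_j faster maturation can shorten life, so
  # the comparison is restricted to mu_a <= mu_j species.)
  tab <- simulate_debbies(30, seed = 21)
  idx <- which(tab$mu_a <= tab$mu_j)[1:3]
  for (i in idx) {
    t <- species_traits(tab, i)
    if (!feasibility(t, deb_env(0.5))$feasible) next
    eta_lo <- derived_traits(build_kernels(t, deb_env(0.5)))$eta_e
    eta_hi <- derived_traits(build_kernels(t, deb_env(0.9)))$eta_e
    expect_gte(eta_hi, eta_lo * (1 - 1e-8))
  }
})
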