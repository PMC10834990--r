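# Shared fixtures: a hand-specified reference species, toy stage-structured
# models with closed-form demography, and a fake two-bin mesh for
# age-from-stage oracles.

# A well-behaved reference species (lengths in cm, rates per year).
make_traits <- function(...) {
  t <- list(record_id = "TST0001", species = "Testudo exemplaris",
            kappa = 0.8, L_b = 30, L_p = 100, L_m = 200,
            mu_j = 0.2, mu_a = 0.1, r_B = 0.2, R_m = 5)
  utils::modifyList(t, list(...))
}

# Two-state toy: a juvenile that matures with probability p per step, stays
# juvenile with probability stay_juv (dies otherwise), and an adult
# surviving with probability s producing f recruits per step. Closed forms:
# R0 = [p/(1 - stay_juv)] f/(1 - s) from the birth state; juvenile waiting
# time 1/(1 - stay_juv).
two_stage_toy <- function(p, s, f, stay_juv = 0) {
  stopifnot(p + stay_juv <= 1)
  GS <- matrix(c(stay_juv, p, 0, s), 2, 2)
  D <- matrix(c(0, 0, 1, 0), 2, 2)
  R <- c(0, f)
  V <- D * rep(R, each = 2)
  mesh <- structure(list(n_bins = 2L, lower = 0, upper = 4,
                         midpoints = c(1, 3), width = 2, edges = c(0, 2, 4)),
                    class = "deb_mesh")
  traits <- list(record_id = "TOY", L_b = 1, L_p = 2.5, L_m = 4)
  structure(list(S = c(stay_juv + p, s), G = diag(2), R = R, D = D, V = V,
                 GS = GS, A = V + GS, mesh = mesh, traits = traits,
                 env = deb_env(0.9)),
            class = "deb_ipm")
}

# Single absorbing state with survival s and fecundity f.
one_state_toy <- function(s, f = 0) {
  structure(list(S = s, G = matrix(1), R = f, D = matrix(1),
                 V = matrix(f), GS = matrix(s), A = matrix(s + f)),
            class = "deb_ipm")
}
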