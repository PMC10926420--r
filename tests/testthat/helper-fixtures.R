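# Shared fixtures built in code; all randomness is locally seeded.

# Records on a noiseless concave paraboloid with peak at (p_peak, c_peak);
# intakes scattered over a grid of rails so the quadratic terms are
# identifiable.
paraboloid_records <- function(n = 120, p_peak = 2, c_peak = 20,
                               gPP = -0.5, gCC = -0.05, seed = 42,
                               noise_sd = 0) {
  set.seed(seed)
  ratios <- list(c(0, 1), c(1, 8), c(1, 4), c(1, 2), c(1, 1))
  rail <- sample(seq_along(ratios), n, replace = TRUE)
  tot <- runif(n, 5, 35)  # total daily intake mg
  fr <- vapply(ratios[rail], function(r) r[1] / sum(r), numeric(1))
  P <- tot * fr
  C <- tot * (1 - fr)
  y <- 50 + gPP * (P - p_peak)^2 + gCC * (C - c_peak)^2 +
    rnorm(n, 0, noise_sd)
  data.frame(P_day_mg = P, C_day_mg = C, LS = y,
             replicate = rep_len(paste0("r", 1:4), n))
}

# Two-group records generated from (possibly different) true surfaces with
# gaussian noise; used for comparison power / type-I checks.
two_group_records <- function(n_per = 150, surf_a, surf_b, seed = 1,
                              noise_sd = 3) {
  set.seed(seed)
  mk <- function(s, lab, rep_prefix) {
    ratios <- list(c(0, 1), c(1, 8), c(1, 4), c(1, 2), c(1, 1))
    rail <- sample(seq_along(ratios), n_per, replace = TRUE)
    tot <- runif(n_per, 5, 35)
    fr <- vapply(ratios[rail], function(r) r[1] / sum(r), numeric(1))
    P <- tot * fr; C <- tot * (1 - fr)
    data.frame(P_day_mg = P, C_day_mg = C,
               LS = surface_value(s, P, C) + rnorm(n_per, 0, noise_sd),
               replicate = rep_len(paste0(rep_prefix, 1:4), n_per),
               group = lab)
  }
  rbind(mk(surf_a, "A", "a"), mk(surf_b, "B", "b"))
}

flat_surface <- function(beta_P = 0.2, beta_C = 1) {
  true_surface(intercept = 30, beta_P = beta_P, beta_C = beta_C)
}
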