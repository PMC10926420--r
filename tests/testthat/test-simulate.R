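test_that("generators reproduce the factorial design counts", {
  x1 <- generate_experiment1(design_exp1(seed = 3))
  expect_equal(nrow(x1$flies), 1200)  # 15 x 2 x 4 x 2 x 5
  x2 <- generate_experiment2(design_exp2(seed = 3))
  expect_equal(nrow(x2$flies), 280)   # 4 pairs x (4 + 3) reps x 2 x 5
  expect_equal(nrow(x2$tubes), 280 * 4 * 2)
  small <- generate_experiment1(design_exp1(
    lines = "CT", replicates = c(CT = 1), sexes = "F", flies_per_cell = 1,
    diets = diet_grid(ratios = list(c(1, 1)), concentrations = 180),
    seed = 9))
  expect_equal(nrow(small$flies), 1)
})

test_that("an identical seed and config gives identical tables", {
  a <- generate_experiment1(design_exp1(flies_per_cell = 2, seed = 77))
  b <- generate_experiment1(design_exp1(flies_per_cell = 2, seed = 77))
  expect_identical(a$flies, b$flies)
  expect_identical(a$dishes, b$dishes)
  c2 <- generate_experiment2(design_exp2(flies_per_cell = 2, seed = 77))
  d2 <- generate_experiment2(design_exp2(flies_per_cell = 2, seed = 77))
  expect_identical(c2$flies, d2$flies)
})

test_that("flies lie on their diet rails and totals are consistent", {
  x <- generate_experiment1(design_exp1(flies_per_cell = 2, seed = 5))
  g <- x$design$diets
  i <- match(x$flies$diet_label, g$label)
  with_p <- g$p_parts[i] > 0
  expect_equal(x$flies$C_day_mg[with_p] / x$flies$P_day_mg[with_p],
               g$c_parts[i][with_p] / g$p_parts[i][with_p])
  expect_equal(x$flies$total_P_mg,
               x$flies$P_day_mg * x$flies$lifespan_days)
})

test_that("the noiseless limit returns lifespans exactly on the surface", {
  surf <- default_surfaces()
  for (ln in c("CT", "US")) for (sx in c("F", "M"))
    surf$LS[[ln]][[sx]]$noise_sd <- 0
  x <- generate_experiment1(design_exp1(flies_per_cell = 1, seed = 8),
                            surfaces = surf, replicate_sd_ls = 0,
                            nonnatural_frac = 0)
  f <- x$flies
  for (ln in c("CT", "US")) for (sx in c("F", "M")) {
    sub <- f[f$line == ln & f$sex == sx, ]
    expect_equal(sub$lifespan_days,
                 pmax(surface_value(surf$LS[[ln]][[sx]],
                                    sub$P_day_mg, sub$C_day_mg), 1))
  }
})

test_that("a missing surface is a configuration error", {
  surf <- default_surfaces()
  surf$LS$US$M <- NULL
  expect_error(generate_experiment1(design_exp1(seed = 1), surfaces = surf),
               "missing lifespan surface")
})

test_that("choice generator solves the two-tube mixing equations", {
  # noiseless, target on the 1:3 blend of pair 1: equal volumes of both tubes
  des <- design_exp2(pairs = choice_pairs()[1],
                     lines = "CT", replicates = c(CT = 1),
                     sexes = "F", flies_per_cell = 1, seed = 2)
  x <- generate_experiment2(des, targets = list(CT = c(P = 9, C = 27)),
                            fly_cv = 0, interval_cv = 0)
  v <- tapply(x$tubes$volume_uL, x$tubes$tube, sum)
  expect_equal(unname(v[1]), unname(v[2]))
  expect_equal(x$flies$protein_mg, 9)
  expect_equal(x$flies$carb_mg, 27)
  # target on the 1:1 rail: all consumption from the 1:1 tube
  y <- generate_experiment2(des, targets = list(CT = c(P = 10, C = 10)),
                            fly_cv = 0, interval_cv = 0)
  vy <- tapply(y$tubes$volume_uL, y$tubes$tube, sum)
  expect_equal(unname(vy[2]), 0)
  expect_equal(y$flies$protein_mg, y$flies$carb_mg)
})

test_that("an unreachable choice target falls back to the nearest rail", {
  des <- design_exp2(pairs = choice_pairs()[1], lines = "CT",
                     replicates = c(CT = 1), sexes = "F",
                     flies_per_cell = 1, seed = 2)
  expect_message(
    x <- generate_experiment2(des, targets = list(CT = c(P = 10, C = 5)),
                              fly_cv = 0, interval_cv = 0),
    "not reachable")
  # nearest reachable point is on the 1:1 rail
  expect_equal(x$flies$protein_mg, x$flies$carb_mg)
})

test_that("cumulative choice intake equals the sum over intervals", {
  x <- generate_experiment2(design_exp2(flies_per_cell = 1, seed = 21))
  pr <- vapply(split(x$tubes, x$tubes$fly_id), function(tt) {
    g <- choice_pairs()
    dens <- vapply(tt$diet_label, function(l) {
      for (p in g) for (d in p) if (d$label == l) return(d$protein_mg_per_uL)
      NA_real_
    }, 1)
    sum(tt$volume_uL * dens)
  }, 1)
  expect_equal(unname(pr[as.character(x$flies$fly_id)]), x$flies$protein_mg)
})
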