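test_that("expected random intake halves the volume between the two tubes", {
  pair <- list(diet(1, 1, 180), diet(0, 1, 180))
  e <- expected_random_intake(100, pair)
  expect_equal(unname(e), c(4.5, 13.5))  # a 1:3 blend
  expect_equal(unname(expected_random_intake(0, pair)), c(0, 0))
  # identical diets: expectation equals observed regardless of the split
  same <- list(diet(1, 2, 180), diet(1, 2, 180))
  v <- 80
  e2 <- expected_random_intake(v, same)
  expect_equal(unname(e2["protein_mg"]), v * same[[1]]$protein_mg_per_uL)
  # conservation: expected P + C is half the volume times summed densities
  for (p in choice_pairs()) {
    ee <- expected_random_intake(57, p)
    expect_equal(unname(sum(ee)),
                 57 / 2 * (p[[1]]$concentration + p[[2]]$concentration) / 1000)
  }
})

test_that("random-feeding t-test matches a hand-computed oracle", {
  # observed (5, 7, 9) vs expected (4, 4, 4): diffs (1, 3, 5),
  # mean 3, sd 2, t = 3 / (2 / sqrt(3))
  out <- random_feeding_test(c(5, 7, 9), c(4, 4, 4),
                             c(10, 10, 10), c(10, 10, 10))
  expect_equal(out$t[out$nutrient == "protein"], 3 / (2 / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(out$t[out$nutrient == "carbohydrate"], 0)
  expect_equal(out$p[out$nutrient == "carbohydrate"], 1)
  expect_equal(out$preference[out$nutrient == "carbohydrate"], "random")
  expect_error(random_feeding_test(1:2, 1:2, 1:2, 1:2), "3 flies")
  expect_error(random_feeding_test(c(5, 5, 6), c(4, 4, 5) + 0.5,
                                   1:3, 1:3), "zero variance")
})

test_that("regulating flies are detected as non-random at study effect size", {
  hit <- 0L
  for (s in 1:10) {
    des <- design_exp2(pairs = choice_pairs()[4], lines = "CT",
                       replicates = c(CT = 4), sexes = "F",
                       flies_per_cell = 5, seed = 400 + s)
    x <- generate_experiment2(des)
    fl <- choice_expectations(x)
    out <- random_feeding_test(fl$protein_mg, fl$expected_P_mg,
                               fl$carb_mg, fl$expected_C_mg)
    if (all(out$p < 0.05)) hit <- hit + 1L
  }
  expect_gte(hit, 9)
})

test_that("regulated intake points reproduce printed group ratios", {
  pm <- published_choice_means()
  ct <- pm[pm$line == "CT", ]
  us <- pm[pm$line == "US", ]
  # pooling the printed female and male means (equal fly counts per sex)
  p_ct <- regulated_intake_point(ct$protein_mg, ct$carb_mg)
  p_us <- regulated_intake_point(us$protein_mg, us$carb_mg)
  expect_equal(round(p_ct$C_to_P_ratio, 1), 3.6)
  expect_equal(round(p_us$C_to_P_ratio, 1), 3.2)
  single <- regulated_intake_point(10, 30)
  expect_equal(single$C_to_P_ratio, 3)
  pure <- regulated_intake_point(c(0, 0), c(5, 7))
  expect_true(is.infinite(pure$C_to_P_ratio) && pure$pure_carbohydrate)
})

test_that("the line point is the fly-weighted mean of the sex points", {
  x <- generate_experiment2(design_exp2(seed = 6))
  fl <- x$flies[x$flies$line == "CT", ]
  whole <- regulated_intake_point(fl$protein_mg, fl$carb_mg)
  parts <- lapply(split(fl, fl$sex), function(s)
    regulated_intake_point(s$protein_mg, s$carb_mg))
  wP <- sum(vapply(parts, function(p) p$mean_P * p$n, 1)) /
    sum(vapply(parts, function(p) p$n, 1))
  expect_equal(whole$mean_P, wP, tolerance = 1e-12)
})

test_that("generated choice data recover the target ratio within 0.2", {
  x <- generate_experiment2(design_exp2(seed = 10))
  fl <- x$flies[x$flies$line == "US", ]
  pt <- regulated_intake_point(fl$protein_mg, fl$carb_mg)
  expect_lt(abs(pt$C_to_P_ratio - 64.47 / 20.00), 0.2)
})

test_that("regulation comparison has the three-row test structure and
           detects slope differences", {
  x <- generate_experiment2(design_exp2(seed = 14))
  fl <- x$flies
  rf <- compare_regulation(fl, "line")
  expect_equal(nrow(rf$tests), 3)
  expect_equal(rf$tests$term, c("protein", "line", "line x protein"))
  expect_true(all(rf$tests$df == 1))
  expect_true(all(rf$tests$p >= 0 & rf$tests$p <= 1))
  expect_error(compare_regulation(fl[fl$line == "CT", ], "line"),
               "two groups")
  # groups regulating to very different C-vs-P slopes: interaction detected
  des <- design_exp2(seed = 15)
  y <- generate_experiment2(des, targets = list(CT = c(P = 10, C = 60),
                                                US = c(P = 25, C = 50)))
  ry <- compare_regulation(y$flies, "line")
  expect_lt(ry$tests["interaction", "p"], 0.01)
})
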