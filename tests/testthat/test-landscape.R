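test_that("a noiseless plane is reproduced exactly inside the hull", {
  set.seed(1)
  P <- runif(60, 0, 10); C <- runif(60, 0, 30)
  y <- 2 + 0.5 * P + 1.5 * C
  L <- fit_landscape(P, C, y)
  inside <- L$grid[L$grid$inside, ]
  expect_lt(max(abs(inside$fit - (2 + 0.5 * inside$P + 1.5 * inside$C))),
            1e-6)
  # monotone plane: optimum sits on the hull boundary (max P, max C corner)
  opt <- find_optimum(L)
  expect_gt(opt["value"], 2 + 0.5 * max(P) * 0.9 + 1.5 * max(C) * 0.9)
})

test_that("a noiseless paraboloid optimum is found within one grid cell", {
  set.seed(2)
  P <- runif(150, 0, 6); C <- runif(150, 5, 35)
  y <- 50 - 0.8 * (P - 2)^2 - 0.06 * (C - 20)^2
  L <- fit_landscape(P, C, y)
  opt <- find_optimum(L)
  expect_lt(abs(opt["P"] - 2), L$cell["P"])
  expect_lt(abs(opt["C"] - 20), L$cell["C"])
  expect_equal(unname(opt["value"]), 50, tolerance = 0.01)
})

test_that("the landscape is invariant to row permutation", {
  set.seed(3)
  P <- runif(60, 0, 6); C <- runif(60, 5, 30)
  y <- 40 - 0.5 * (P - 3)^2 - 0.05 * (C - 18)^2 + rnorm(60, 0, 1)
  L1 <- fit_landscape(P, C, y)
  i <- sample(60)
  L2 <- fit_landscape(P[i], C[i], y[i])
  expect_equal(L1$grid$fit, L2$grid$fit, tolerance = 1e-8)
})

test_that("degenerate 1-D intake clouds and flat landscapes are handled", {
  P <- seq(1, 5, length.out = 30)
  expect_error(fit_landscape(P, 2 * P, rnorm(30)), "single line")
  set.seed(4)
  Px <- runif(40, 0, 5); Cx <- runif(40, 0, 20)
  expect_warning(opt <- find_optimum(fit_landscape(Px, Cx,
                                                   rep(7, 40) + 0 * Px)),
                 "flat landscape")
  expect_equal(unname(opt["value"]), 7, tolerance = 1e-6)
})

test_that("exactly tied twin peaks break toward lower protein", {
  # fit any landscape, then impose an exactly symmetric two-peak grid so the
  # argmax tie is exact: the grid-level optimum must take the lower-P peak
  set.seed(5)
  P <- runif(100, 0, 10); C <- runif(100, 5, 25)
  L <- fit_landscape(P, C, rnorm(100))
  L$grid$fit <- exp(-((L$grid$P - 2)^2 + (L$grid$C - 15)^2 / 10)) +
    exp(-((L$grid$P - 8)^2 + (L$grid$C - 15)^2 / 10))
  i_lo <- which.min((L$grid$P - 2)^2 + (L$grid$C - 15)^2)
  i_hi <- which.min((L$grid$P - 8)^2 + (L$grid$C - 15)^2)
  L$grid$fit[c(i_lo, i_hi)] <- max(L$grid$fit) + 1  # exact tie at the top
  L$grid$inside <- TRUE
  opt <- find_optimum(L, refine = FALSE)
  expect_equal(unname(opt["P"]), L$grid$P[i_lo])
  expect_lt(opt["P"], 5)
})

test_that("increasing the smoothing parameter never increases curvature", {
  set.seed(6)
  P <- runif(80, 0, 6); C <- runif(80, 5, 30)
  y <- 40 - 0.8 * (P - 2)^2 - 0.06 * (C - 18)^2 + rnorm(80, 0, 2)
  curv <- vapply(c(0.01, 1, 100), function(sp) {
    L <- fit_landscape(P, C, y, smoothing = sp, grid_n = 40)
    g <- L$grid
    z <- matrix(g$fit, 40, 40)
    # discrete bending energy: squared second differences in both directions
    sum(diff(z, differences = 2)^2) +
      sum(t(diff(t(z), differences = 2))^2) +
      2 * sum(diff(t(diff(z)))^2)
  }, 1)
  expect_true(all(diff(curv) < 1e-8))
})

test_that("bootstrap optimum regions behave on noiseless data and nest", {
  set.seed(7)
  P <- runif(80, 0, 6); C <- runif(80, 5, 30)
  y <- 50 - 0.8 * (P - 2.5)^2 - 0.08 * (C - 17)^2
  r05 <- optimum_region(P, C, y, B = 60, alpha = 0.05, grid_n = 30,
                        k = 25, seed = 3)
  # noiseless: region collapses to a small neighbourhood of the optimum
  expect_lt(nrow(r05$cells), 0.05 * sum(fit_landscape(P, C, y,
                                                      grid_n = 30,
                                                      k = 25)$grid$inside))
  expect_lt(max(abs(r05$cells$P - 2.5)), 4 * r05$cell["P"])
  expect_lt(max(abs(r05$cells$C - 17)), 4 * r05$cell["C"])
  r50 <- optimum_region(P, C, y, B = 60, alpha = 0.45, grid_n = 30,
                        k = 25, seed = 3)
  key <- function(r) paste(r$cells$P, r$cells$C)
  expect_true(all(key(r50) %in% key(r05)))
  # the region always contains the point optimum's cell
  gx <- sort(unique(r05$cells$P))
  expect_true(any(abs(r05$cells$P - r05$optimum["P"]) <= r05$cell["P"] &
                    abs(r05$cells$C - r05$optimum["C"]) <= r05$cell["C"]))
  expect_error(optimum_region(P, C, y, B = 60, alpha = 0.7), "alpha")
})

test_that("carbohydrate-dominant lifespan surfaces put the optimum on a
           low P:C rail", {
  x <- generate_experiment1(
    design_exp1(lines = "CT", replicates = c(CT = 4), sexes = "F",
                seed = 23))
  rec <- prepare_analysis(x$flies)$records
  L <- fit_landscape(rec$P_day_mg, rec$C_day_mg, rec$LS)
  opt <- find_optimum(L)
  # optimum ratio is carbohydrate-biased: below 1:2 P:C
  expect_gt(opt["C"] / max(opt["P"], 1e-9), 2)
})
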