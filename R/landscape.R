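#' Fit a thin-plate-spline nutritional landscape
#'
#' Fits a nonparametric surface of a trait over daily (protein,
#' carbohydrate) intake with a thin-plate regression spline, smoothing
#' chosen by generalized cross-validation unless given. Landscapes are
#' fitted on untransformed trait values and mg/day intakes. Predictions are
#' evaluated on a regular grid over the observed bounding box and masked to
#' the convex hull of the observed intakes: the spline is not trusted
#' outside the region the data cover.
#'
#' @param P,C Daily intakes, mg/day (>= 20 points spanning >= 3 rails).
#' @param values Trait values at the intakes.
#' @param smoothing `"auto"` (GCV) or a non-negative smoothing parameter.
#' @param grid_n Grid resolution per axis (default 100).
#' @param k Spline basis dimension (capped at n - 2; large enough that
#'   noiseless surfaces are near-interpolated).
#' @return Object of class `"nutri_landscape"`: the fitted `gam`, the
#'   prediction `grid` (columns `P`, `C`, `fit`, `inside`), the `hull`
#'   polygon, grid cell sizes and the data. Methods: `print`, `predict`,
#'   `plot`.
#' @export
fit_landscape <- function(P, C, values, smoothing = "auto",
                          grid_n = 100, k = 100) {
  ok <- stats::complete.cases(P, C, values)
  P <- P[ok]; C <- C[ok]; values <- values[ok]
  if (length(P) < 20)
    stop("need at least 20 intake points to fit a landscape", call. = FALSE)
  M <- cbind(P - mean(P), C - mean(C))
  sv <- svd(M)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate intake cloud: points lie on a single line in (P, C) ",
         "space", call. = FALSE)
  k <- min(k, length(P) - 2)
  # isotropic thin-plate penalty: put both axes on a comparable scale
  scale_ <- c(P = stats::sd(P), C = stats::sd(C))
  d <- data.frame(u = P / scale_["P"], v = C / scale_["C"], y = values)
  args <- list(formula = y ~ s(u, v, bs = "tp", k = k), data = d,
               method = "GCV.Cp")
  if (!identical(smoothing, "auto")) args$sp <- as.numeric(smoothing)
  g <- do.call(mgcv::gam, args)
  gx <- seq(min(P), max(P), length.out = grid_n)
  gy <- seq(min(C), max(C), length.out = grid_n)
  grid <- expand.grid(P = gx, C = gy)
  hull_i <- grDevices::chull(P, C)
  hull <- cbind(P = P[hull_i], C = C[hull_i])
  inside <- mgcv::in.out(rbind(hull, hull[1, ]), as.matrix(grid))
  grid$fit <- as.numeric(mgcv::predict.gam(
    g, newdata = data.frame(u = grid$P / scale_["P"],
                            v = grid$C / scale_["C"])))
  grid$inside <- inside
  structure(list(gam = g, grid = grid, hull = hull,
                 cell = c(P = diff(gx[1:2]), C = diff(gy[1:2])),
                 sp = unname(g$sp), scale = scale_,
                 data = data.frame(P = P, C = C, y = values)),
            class = "nutri_landscape")
}

# Spline predictions at original-scale (P, C) coordinates.
.predict_tps <- function(landscape, P, C) {
  as.numeric(mgcv::predict.gam(
    landscape$gam,
    newdata = data.frame(u = P / landscape$scale["P"],
                         v = C / landscape$scale["C"])))
}

#' @export
print.nutri_landscape <- function(x, ...) {
  opt <- find_optimum(x)
  cat(sprintf(
    "Thin-plate-spline landscape: n = %d, sp = %.4g\n", nrow(x$data), x$sp))
  cat(sprintf("Optimum inside observed hull: P = %.3f, C = %.3f (value %.3f)\n",
              opt["P"], opt["C"], opt["value"]))
  invisible(x)
}

#' @export
predict.nutri_landscape <- function(object, newdata, ...) {
  .predict_tps(object, newdata$P, newdata$C)
}

#' Locate the optimum of a fitted landscape
#'
#' Argmax of the gridded predictions inside the convex-hull mask, refined by
#' continuous optimization of the spline from the best grid cell (refined
#' points falling outside the hull are discarded in favour of the grid
#' point). Ties are broken toward lower protein, then lower carbohydrate.
#'
#' @param landscape A [fit_landscape()] object.
#' @param refine Continuously refine from the best grid cell (default TRUE);
#'   `FALSE` returns the grid-cell argmax itself.
#' @param refine_tol Convergence tolerance of the continuous refinement.
#' @return Named vector `c(P, C, value)`.
#' @export
find_optimum <- function(landscape, refine = TRUE, refine_tol = 1e-8) {
  g <- landscape$grid[landscape$grid$inside, , drop = FALSE]
  if (nrow(g) == 0) g <- landscape$grid
  if (diff(range(g$fit)) < 1e-12) {
    warning("flat landscape: all predictions equal; returning hull centroid",
            call. = FALSE)
    return(c(P = mean(landscape$hull[, "P"]), C = mean(landscape$hull[, "C"]),
             value = g$fit[1]))
  }
  # ties toward lower P then lower C
  ord <- order(-g$fit, g$P, g$C)
  best <- g[ord[1], ]
  if (!refine) return(c(P = best$P, C = best$C, value = best$fit))
  hull <- rbind(landscape$hull, landscape$hull[1, ])
  obj <- function(x) {
    if (!mgcv::in.out(hull, matrix(x, 1))) return(Inf)
    -.predict_tps(landscape, x[1], x[2])
  }
  ref <- tryCatch(
    stats::optim(c(best$P, best$C), obj, method = "Nelder-Mead",
                 control = list(reltol = refine_tol)),
    error = function(e) NULL)
  if (!is.null(ref) && is.finite(ref$value) && -ref$value >= best$fit)
    c(P = ref$par[1], C = ref$par[2], value = -ref$value)
  else c(P = best$P, C = best$C, value = best$fit)
}

#' Bootstrap optimum region of a nutritional landscape
#'
#' Case-resampling bootstrap of the thin-plate-spline argmax: rows are
#' resampled with replacement, the landscape refitted, and the grid argmax
#' recorded. The (1 - alpha) optimum region is the smallest set of grid
#' cells (by bootstrap count rank) covering at least that share of the
#' bootstrap argmaxes; the point-estimate optimum cell is always included.
#'
#' @param P,C,values As in [fit_landscape()].
#' @param B Bootstrap replicates (>= 200 recommended).
#' @param alpha Region level in (0, 0.5).
#' @param grid_n,k Passed to [fit_landscape()] (a smaller basis speeds up
#'   the refits).
#' @param seed Seed for the resampling.
#' @return Object of class `"optimum_region"`: `cells` (grid cells of the
#'   region with bootstrap counts), `optimum`, `alpha`, `B`, `failures`.
#' @export
optimum_region <- function(P, C, values, B = 200, alpha = 0.05,
                           grid_n = 50, k = 30, seed = 1L) {
  if (B < 2) stop("need at least 2 bootstrap replicates", call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)",
                                       call. = FALSE)
  base <- fit_landscape(P, C, values, grid_n = grid_n, k = k)
  opt <- find_optimum(base)
  gx <- sort(unique(base$grid$P)); gy <- sort(unique(base$grid$C))
  snap <- function(p, c) c(gx[which.min(abs(gx - p))],
                           gy[which.min(abs(gy - c))])
  n <- length(P)
  hits <- matrix(NA_real_, B, 2)
  fails <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      i <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(fit_landscape(P[i], C[i], values[i],
                                   grid_n = grid_n, k = k),
                     error = function(e) NULL)
      if (is.null(fb)) { fails <- fails + 1L; next }
      ob <- suppressWarnings(find_optimum(fb))
      hits[b, ] <- snap(ob["P"], ob["C"])
    }
  })
  if (fails > 0.1 * B)
    stop(sprintf("bootstrap refit failures exceed 10%% (%d of %d)", fails, B),
         call. = FALSE)
  hits <- hits[stats::complete.cases(hits), , drop = FALSE]
  key <- paste(hits[, 1], hits[, 2])
  cnt <- sort(table(key), decreasing = TRUE)
  cum <- cumsum(cnt) / sum(cnt)
  take <- seq_len(min(which(cum >= 1 - alpha)))
  cells <- do.call(rbind, strsplit(names(cnt)[take], " "))
  cells <- data.frame(P = as.numeric(cells[, 1]), C = as.numeric(cells[, 2]),
                      count = as.integer(cnt[take]))
  oc <- snap(opt["P"], opt["C"])
  if (!any(cells$P == oc[1] & cells$C == oc[2]))
    cells <- rbind(cells, data.frame(P = oc[1], C = oc[2], count = 0L))
  structure(list(cells = cells, optimum = opt, alpha = alpha, B = B,
                 failures = fails, cell = base$cell),
            class = "optimum_region")
}

#' @export
print.optimum_region <- function(x, ...) {
  cat(sprintf(
    "%.0f%% bootstrap optimum region: %d grid cells (B = %d, %d failures)\n",
    100 * (1 - x$alpha), nrow(x$cells), x$B, x$failures))
  cat(sprintf("Point optimum: P = %.3f, C = %.3f\n",
              x$optimum["P"], x$optimum["C"]))
  invisible(x)
}

#' Plot a nutritional landscape
#'
#' Filled image of the masked predictions with contours, observed intakes
#' and the optimum.
#'
#' @param x A [fit_landscape()] object.
#' @param show_points Overlay observed intakes.
#' @param ... Passed to [graphics::image()].
#' @export
plot.nutri_landscape <- function(x, show_points = TRUE, ...) {
  gx <- sort(unique(x$grid$P)); gy <- sort(unique(x$grid$C))
  z <- matrix(ifelse(x$grid$inside, x$grid$fit, NA),
              nrow = length(gx), ncol = length(gy))
  graphics::image(gx, gy, z, xlab = "Protein intake (mg/day)",
                  ylab = "Carbohydrate intake (mg/day)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::contour(gx, gy, z, add = TRUE, col = "grey30")
  if (show_points)
    graphics::points(x$data$P, x$data$C, pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("black", 0.4))
  opt <- suppressWarnings(find_optimum(x))
  graphics::points(opt["P"], opt["C"], pch = 17, col = "red", cex = 1.4)
  invisible(x)
}
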