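#' Design of the no-choice diet-grid experiment
#'
#' Defaults reproduce the full factorial: 15 diets x 2 selection lines x
#' 4 replicates x 2 sexes x 5 flies = 1200 flies.
#'
#' @param lines Selection-line labels.
#' @param replicates Named integer vector, replicates per line.
#' @param sexes Sex labels (`"F"`, `"M"`).
#' @param flies_per_cell Flies per diet x line x replicate x sex cell.
#' @param diets Diet grid data frame (see [diet_grid()]).
#' @param seed Integer seed; a fixed seed makes the generated table
#'   reproducible to the byte.
#' @return List of class `"design_exp1"`.
#' @export
design_exp1 <- function(lines = c("CT", "US"),
                        replicates = c(CT = 4, US = 4),
                        sexes = c("F", "M"),
                        flies_per_cell = 5,
                        diets = diet_grid(),
                        seed = 1L) {
  stopifnot(all(replicates >= 1), flies_per_cell >= 1,
            all(lines %in% names(replicates)))
  structure(list(lines = lines, replicates = replicates, sexes = sexes,
                 flies_per_cell = flies_per_cell, diets = diets,
                 seed = as.integer(seed)),
            class = "design_exp1")
}

# Diet-specific mean daily volume (uL/day): flies on dilute diets drink more,
# so realized intakes spread along each rail while total nutrient intake stays
# comparable across concentrations.
mean_daily_volume <- function(concentration, base_uL = 100, ref_conc = 180) {
  base_uL * sqrt(ref_conc / concentration)
}

#' Generate fly-level data for the no-choice experiment
#'
#' For every fly: a daily feeding volume is drawn lognormally around the
#' diet-specific mean, so its realized (P, C) daily intake lies on the diet's
#' nutritional rail; lifespan is gamma-distributed around the lifespan
#' surface value at that intake (deterministic when `noise_sd = 0`); for
#' females, egg counts per 6-day oviposition dish are negative binomial with
#' daily mean given by the daily-egg-production surface. Replicate effects
#' are additive normal shifts on the trait means, and a small fraction of
#' flies is flagged as non-natural deaths (trapped in diet) for the
#' exclusion-rule machinery downstream.
#'
#' @param design A [design_exp1()].
#' @param surfaces Nested surface list as in [default_surfaces()]:
#'   `$LS[[line]][[sex]]` and `$DEP[[line]]` [true_surface()] objects.
#' @param volume_cv Coefficient of variation of the per-fly daily volume.
#' @param line_volume_mult Named multipliers on mean daily volume per line;
#'   the default has upward-selected flies consuming more than controls.
#' @param replicate_sd_ls,replicate_sd_dep SD of additive replicate shifts on
#'   lifespan (days) and daily egg production (eggs/day).
#' @param egg_dispersion Negative-binomial size for dish egg counts
#'   (`Inf` gives Poisson).
#' @param nonnatural_frac Fraction of flies flagged as non-natural deaths.
#' @return Object of class `"nutri_exp1"`: list with `flies` (one row per
#'   fly), `dishes` (one row per female oviposition dish) and the `design`.
#' @examples
#' x <- generate_experiment1(design_exp1(flies_per_cell = 1, seed = 7))
#' nrow(x$flies)  # 15 diets x 2 lines x 4 reps x 2 sexes = 240
#' @export
generate_experiment1 <- function(design = design_exp1(),
                                 surfaces = default_surfaces(),
                                 volume_cv = 0.35,
                                 line_volume_mult = c(CT = 0.9, US = 1.1),
                                 replicate_sd_ls = 1.5,
                                 replicate_sd_dep = 0.3,
                                 egg_dispersion = 8,
                                 nonnatural_frac = 0.02) {
  for (ln in design$lines) for (sx in design$sexes)
    if (is.null(surfaces$LS[[ln]][[sx]]))
      stop("missing lifespan surface for line ", ln, ", sex ", sx,
           call. = FALSE)
  for (ln in design$lines)
    if ("F" %in% design$sexes && is.null(surfaces$DEP[[ln]]))
      stop("missing daily-egg-production surface for line ", ln, call. = FALSE)

  with_seed(design$seed, {
    cells <- expand.grid(diet_label = design$diets$label,
                         line = design$lines,
                         sex = design$sexes,
                         stringsAsFactors = FALSE)
    rows <- list()
    dish_rows <- list()
    fid <- 0L
    for (ln in design$lines) {
      nrep <- design$replicates[[ln]]
      # replicate shifts drawn once per replicate x trait
      shift_ls <- stats::rnorm(nrep, 0, replicate_sd_ls)
      shift_dep <- stats::rnorm(nrep, 0, replicate_sd_dep)
      for (rep_i in seq_len(nrep)) for (sx in design$sexes)
        for (di in seq_len(nrow(design$diets)))
          for (f in seq_len(design$flies_per_cell)) {
            fid <- fid + 1L
            dlab <- design$diets$label[di]
            vmult <- if (ln %in% names(line_volume_mult))
              line_volume_mult[[ln]] else 1
            vol <- mean_daily_volume(design$diets$concentration_g_per_L[di]) *
              vmult * rlnorm1(1, volume_cv)
            P <- vol * design$diets$protein_mg_per_uL[di]
            C <- vol * design$diets$carb_mg_per_uL[di]
            s_ls <- surfaces$LS[[ln]][[sx]]
            mu_ls <- max(surface_value(s_ls, P, C) + shift_ls[rep_i], 1)
            ls <- if (s_ls$noise_sd == 0) mu_ls else
              stats::rgamma(1, shape = (mu_ls / s_ls$noise_sd)^2,
                            rate = mu_ls / s_ls$noise_sd^2)
            ls <- max(ls, 1)
            eggs <- NA_real_
            if (sx == "F") {
              s_dep <- surfaces$DEP[[ln]]
              mu_dep <- max(surface_value(s_dep, P, C) + shift_dep[rep_i], 0)
              n_dish <- max(1L, ceiling(ls / 6))
              days <- c(rep(6, n_dish - 1), ls - 6 * (n_dish - 1))
              mu_dish <- mu_dep * days
              cnt <- if (is.infinite(egg_dispersion))
                stats::rpois(n_dish, mu_dish)
              else stats::rnbinom(n_dish, size = egg_dispersion, mu = mu_dish)
              eggs <- sum(cnt)
              dish_rows[[length(dish_rows) + 1L]] <-
                data.frame(fly_id = fid, dish = seq_len(n_dish), eggs = cnt)
            }
            rows[[fid]] <- data.frame(
              fly_id = fid, line = ln, replicate = paste0(ln, rep_i),
              sex = sx, diet_label = dlab,
              P_day_mg = P, C_day_mg = C,
              lifespan_days = ls,
              total_P_mg = P * ls, total_C_mg = C * ls,
              eggs_total = eggs, stringsAsFactors = FALSE)
          }
    }
    flies <- do.call(rbind, rows)
    flies$death_cause <- ifelse(stats::runif(nrow(flies)) < nonnatural_frac,
                                "non_natural", "natural")
    structure(list(flies = flies,
                   dishes = if (length(dish_rows))
                     do.call(rbind, dish_rows) else NULL,
                   design = design, surfaces = surfaces),
              class = "nutri_exp1")
  })
}

#' @export
print.nutri_exp1 <- function(x, ...) {
  cat(sprintf(
    "No-choice experiment: %d flies (%d diets x %s lines, %s)\n",
    nrow(x$flies), nrow(x$design$diets),
    paste(x$design$lines, collapse = "/"),
    paste(names(x$design$replicates), x$design$replicates,
          sep = "x", collapse = ", ")))
  invisible(x)
}

#' Design of the paired-diet choice experiment
#'
#' Defaults reproduce the choice assay: 4 complementary diet pairs
#' (1:1 vs 0:1 at 180 or 360 g/L) x (4 control + 3 upward-selected
#' replicates) x 2 sexes x 5 flies = 280 flies, followed over 16 days in
#' four 4-day measurement intervals.
#'
#' @param pairs List of diet pairs; each element is a list of two [diet()]s.
#' @param replicates Named integer vector of replicates per line.
#' @inheritParams design_exp1
#' @param duration_days Assay length in days.
#' @param n_intervals Number of equal measurement intervals.
#' @return List of class `"design_exp2"`.
#' @export
design_exp2 <- function(pairs = choice_pairs(),
                        lines = c("CT", "US"),
                        replicates = c(CT = 4, US = 3),
                        sexes = c("F", "M"),
                        flies_per_cell = 5,
                        duration_days = 16,
                        n_intervals = 4,
                        seed = 1L) {
  stopifnot(all(replicates >= 1), flies_per_cell >= 1, n_intervals >= 1)
  structure(list(pairs = pairs, lines = lines, replicates = replicates,
                 sexes = sexes, flies_per_cell = flies_per_cell,
                 duration_days = duration_days, n_intervals = n_intervals,
                 seed = as.integer(seed)),
            class = "design_exp2")
}

#' The four complementary diet pairs of the choice experiment
#' @return List of 4 pairs; each pair is a list of two [diet()] objects
#'   (a 1:1 diet and a protein-free 0:1 diet at 180 or 360 g/L).
#' @export
choice_pairs <- function() {
  list(
    pair1 = list(diet(1, 1, 180), diet(0, 1, 180)),
    pair2 = list(diet(1, 1, 180), diet(0, 1, 360)),
    pair3 = list(diet(1, 1, 360), diet(0, 1, 180)),
    pair4 = list(diet(1, 1, 360), diet(0, 1, 360)))
}

#' Default regulated-intake targets for the choice generator
#'
#' Cumulative 16-day (protein, carbohydrate) targets per selection line,
#' matching the reported mean intakes: control flies defend roughly a 1:3.6
#' P:C blend and upward-selected flies a 1:3.2 blend at a higher total.
#' @return Named list of `c(P, C)` mg targets.
#' @export
default_choice_targets <- function() {
  list(CT = c(P = 15.56, C = 56.39), US = c(P = 20.00, C = 64.47))
}

# Total tube volumes (uL) on a two-diet pair whose expected cumulative intake
# is nearest the (P, C) mg target; components clamped to >= 0 with fallback to
# the closest single-rail point when the exact solution needs a negative
# volume.
solve_pair_volumes <- function(pair, target) {
  A <- cbind(c(pair[[1]]$protein_mg_per_uL, pair[[1]]$carb_mg_per_uL),
             c(pair[[2]]$protein_mg_per_uL, pair[[2]]$carb_mg_per_uL))
  v <- tryCatch(solve(A, target), error = function(e) c(-1, -1))
  if (all(v >= 0)) return(v)
  # project target onto each rail, keep the closer one
  best <- NULL; bestd <- Inf
  for (j in 1:2) {
    a <- A[, j]
    vj <- max(0, sum(a * target) / sum(a * a))
    d <- sum((a * vj - target)^2)
    if (d < bestd) { bestd <- d; best <- c(0, 0); best[j] <- vj }
  }
  message("choice target not reachable from pair rails; ",
          "using nearest single-rail point")
  best
}

#' Generate fly-level data for the paired-diet choice experiment
#'
#' Each fly receives two complementary diets and regulates towards its
#' line's cumulative (P, C) target: total tube volumes solve the two-diet
#' mixing equations for the target (or its nearest reachable point), are
#' split over the measurement intervals, and perturbed by lognormal
#' multipliers per fly and per interval. No fly dies before the end of the
#' assay.
#'
#' @param design A [design_exp2()].
#' @param targets Named list of cumulative `c(P, C)` mg targets per line,
#'   as in [default_choice_targets()].
#' @param fly_cv,interval_cv Coefficients of variation of the per-fly and
#'   per-interval lognormal volume multipliers (0 = noiseless).
#' @return Object of class `"nutri_exp2"`: list with `flies` (one row per
#'   fly, cumulative intakes), `tubes` (one row per fly x interval x tube,
#'   consumed volume in uL) and the `design`.
#' @examples
#' x <- generate_experiment2(design_exp2(flies_per_cell = 1, seed = 3))
#' nrow(x$flies)  # 4 pairs x (4 + 3) reps x 2 sexes = 56
#' @export
generate_experiment2 <- function(design = design_exp2(),
                                 targets = default_choice_targets(),
                                 fly_cv = 0.15,
                                 interval_cv = 0.20) {
  if (!all(design$lines %in% names(targets)))
    stop("a cumulative intake target is required for every line",
         call. = FALSE)
  with_seed(design$seed, {
    flies_l <- list(); tubes_l <- list(); fid0 <- 0L
    nI <- design$n_intervals
    ilen <- design$duration_days / nI
    for (pi in seq_along(design$pairs)) {
      pair <- design$pairs[[pi]]
      pname <- names(design$pairs)[pi]
      if (is.null(pname) || pname == "") pname <- paste0("pair", pi)
      dens_P <- c(pair[[1]]$protein_mg_per_uL, pair[[2]]$protein_mg_per_uL)
      dens_C <- c(pair[[1]]$carb_mg_per_uL, pair[[2]]$carb_mg_per_uL)
      for (ln in design$lines) {
        v_tot <- solve_pair_volumes(pair, targets[[ln]])
        nrep <- design$replicates[[ln]]
        nsx <- length(design$sexes)
        npc <- design$flies_per_cell
        nfly <- nrep * nsx * npc
        mult_f <- rlnorm1(nfly, fly_cv)
        # vol[fly, interval, tube]
        noise <- array(rlnorm1(nfly * nI * 2, interval_cv), c(nfly, nI, 2))
        vol <- array(rep(v_tot / nI, each = nfly * nI), c(nfly, nI, 2)) *
          array(mult_f, c(nfly, nI, 2)) * noise
        P_cum <- rowSums(vol[, , 1, drop = FALSE]) * dens_P[1] +
          rowSums(vol[, , 2, drop = FALSE]) * dens_P[2]
        C_cum <- rowSums(vol[, , 1, drop = FALSE]) * dens_C[1] +
          rowSums(vol[, , 2, drop = FALSE]) * dens_C[2]
        ids <- fid0 + seq_len(nfly)
        flies_l[[length(flies_l) + 1L]] <- data.frame(
          fly_id = ids, line = ln,
          replicate = paste0(ln, rep(seq_len(nrep), each = nsx * npc)),
          sex = rep(rep(design$sexes, each = npc), nrep),
          pair = pname,
          diet1 = pair[[1]]$label, diet2 = pair[[2]]$label,
          protein_mg = P_cum, carb_mg = C_cum,
          stringsAsFactors = FALSE)
        tubes_l[[length(tubes_l) + 1L]] <- data.frame(
          fly_id = rep(ids, times = nI * 2),
          interval = rep(rep(seq_len(nI), each = nfly), 2),
          interval_start_day = rep(rep((seq_len(nI) - 1) * ilen,
                                       each = nfly), 2),
          interval_end_day = rep(rep(seq_len(nI) * ilen, each = nfly), 2),
          tube = rep(1:2, each = nfly * nI),
          diet_label = rep(c(pair[[1]]$label, pair[[2]]$label),
                           each = nfly * nI),
          volume_uL = as.vector(vol), stringsAsFactors = FALSE)
        fid0 <- fid0 + nfly
      }
    }
    flies <- do.call(rbind, flies_l)
    tubes <- do.call(rbind, tubes_l)
    tubes <- tubes[order(tubes$fly_id, tubes$interval, tubes$tube), ]
    rownames(tubes) <- NULL
    structure(list(flies = flies, tubes = tubes,
                   design = design, targets = targets),
              class = "nutri_exp2")
  })
}

#' @export
print.nutri_exp2 <- function(x, ...) {
  cat(sprintf(
    "Choice experiment: %d flies, %d diet pairs, %d-day assay (%d intervals)\n",
    nrow(x$flies), length(x$design$pairs), x$design$duration_days,
    x$design$n_intervals))
  invisible(x)
}

#' Emit tube-length measurement tables for generated data
#'
#' Converts a generated experiment's per-interval consumed volumes into the
#' raw tube-measurement format that [compute_intakes()] reads: initial and
#' final diet lengths per tube per interval, with evaporation added to every
#' fly tube and matching control tubes per diet x interval. With
#' `control_cv = 0` the corrected intakes recovered by [compute_intakes()]
#' equal the generated ones exactly.
#'
#' @param tubes Data frame with `fly_id`, `diet_label`, `interval_start_day`,
#'   `interval_end_day`, `volume_uL` (e.g. `generate_experiment2()$tubes`).
#' @param cal A [calibration()] object.
#' @param evap_uL Evaporative loss per tube per interval, uL.
#' @param n_controls Control tubes per diet x interval.
#' @param control_cv CV of lognormal noise on control losses.
#' @param full_volume_uL Tube fill volume, uL.
#' @param seed Seed for the control noise.
#' @return Data frame in [compute_intakes()] format (fly and control rows).
#' @export
as_tube_measurements <- function(tubes, cal = calibration(slope = 2),
                                 evap_uL = 5, n_controls = 3,
                                 control_cv = 0, full_volume_uL = 100,
                                 seed = 1L) {
  with_seed(seed, {
    L0 <- (full_volume_uL - cal$intercept) / cal$slope
    fly <- data.frame(
      id = tubes$fly_id, role = "fly", diet_label = tubes$diet_label,
      interval_start_day = tubes$interval_start_day,
      interval_end_day = tubes$interval_end_day,
      initial_length_mm = L0,
      final_length_mm = L0 - (tubes$volume_uL + evap_uL) / cal$slope,
      stringsAsFactors = FALSE)
    cells <- unique(tubes[, c("diet_label", "interval_start_day",
                              "interval_end_day")])
    ctrl <- cells[rep(seq_len(nrow(cells)), each = n_controls), ]
    loss <- evap_uL * rlnorm1(nrow(ctrl), control_cv)
    ctrl <- data.frame(
      id = paste0("ctrl", seq_len(nrow(ctrl))), role = "control",
      diet_label = ctrl$diet_label,
      interval_start_day = ctrl$interval_start_day,
      interval_end_day = ctrl$interval_end_day,
      initial_length_mm = L0,
      final_length_mm = L0 - loss / cal$slope,
      stringsAsFactors = FALSE)
    out <- rbind(fly, ctrl)
    rownames(out) <- NULL
    out
  })
}
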