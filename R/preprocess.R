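#' Express cumulative nutrient intake per day lived
#'
#' Because longevity varies widely across diet groups, cumulative intakes are
#' divided by days lived so consumption is comparable across individuals.
#'
#' @param total_P_mg,total_C_mg Cumulative intakes, mg.
#' @param lifespan_days Days lived (> 0).
#' @return Data frame with `P_day_mg` and `C_day_mg` (mg/day).
#' @examples
#' per_day_intake(100, 300, 50)  # 2 and 6 mg/day
#' @export
per_day_intake <- function(total_P_mg, total_C_mg, lifespan_days) {
  if (any(lifespan_days <= 0))
    stop("lifespan must be > 0 days; exclude zero-lifespan records instead",
         call. = FALSE)
  data.frame(P_day_mg = total_P_mg / lifespan_days,
             C_day_mg = total_C_mg / lifespan_days)
}

#' Lifetime and daily egg production from dish counts
#'
#' Oviposition dishes are replaced every 6 days and eggs counted per dish.
#' Lifetime egg production (LEP) is the sum over dishes; daily egg
#' production (DEP) is LEP divided by days lived.
#'
#' @param dish_counts Non-negative integer egg counts, one per dish.
#' @param lifespan_days Days lived (> 0).
#' @return Named vector `c(LEP, DEP)`.
#' @examples
#' derive_egg_traits(c(10, 20, 30), 60)  # LEP 60, DEP 1
#' @export
derive_egg_traits <- function(dish_counts, lifespan_days) {
  if (any(dish_counts < 0)) stop("egg counts must be non-negative", call. = FALSE)
  if (lifespan_days <= 0) stop("lifespan must be > 0 days", call. = FALSE)
  lep <- sum(dish_counts)
  c(LEP = lep, DEP = lep / lifespan_days)
}

#' Remove flies that escaped or died non-naturally
#'
#' Records flagged by `death_cause` other than `"natural"` (escapes, flies
#' trapped in a drop of liquid diet) are removed before analysis.
#'
#' @param records Data frame with a `death_cause` column.
#' @return List with `kept` (records retained) and `log` (data frame of
#'   excluded `fly_id` + `reason`); kept + excluded counts equal the input.
#' @export
apply_exclusions <- function(records) {
  if (!"death_cause" %in% names(records))
    stop("records must carry a death_cause column", call. = FALSE)
  drop <- records$death_cause != "natural"
  log <- data.frame(fly_id = records$fly_id[drop],
                    reason = records$death_cause[drop],
                    stringsAsFactors = FALSE)
  if (all(drop)) warning("all records excluded", call. = FALSE)
  list(kept = records[!drop, , drop = FALSE], log = log)
}

#' Z-standardize values within analysis groups
#'
#' Centres to mean zero and scales to sample standard deviation one
#' (denominator n - 1), independently within each group. Standardization is
#' recomputed for every model-fitting dataset, so pooled two-group
#' comparisons share a common scale.
#'
#' @param values Numeric vector.
#' @param groups Optional grouping (vector or list of vectors); `NULL`
#'   standardizes the whole vector as one group.
#' @return Numeric vector of z-scores.
#' @examples
#' z_transform(c(1, 2, 3))  # -1 0 1
#' @export
z_transform <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, length(values))
  g <- interaction(groups, drop = TRUE)
  out <- numeric(length(values))
  for (lev in levels(g)) {
    i <- g == lev
    s <- stats::sd(values[i])
    if (!is.finite(s) || s == 0)
      stop("degenerate (constant) group in z-transform: ", lev, call. = FALSE)
    out[i] <- (values[i] - mean(values[i])) / s
  }
  out
}

#' Build an analysis-ready table from generated or imported fly records
#'
#' Applies the exclusion rules, recomputes per-day intakes from cumulative
#' intake and lifespan, and attaches egg traits for females.
#'
#' @param flies Fly-level data frame with `total_P_mg`, `total_C_mg`,
#'   `lifespan_days`, `death_cause` and (females) `eggs_total`.
#' @return List with `records` (analysis rows, columns `P_day_mg`,
#'   `C_day_mg`, `LS`, `LEP`, `DEP`) and `exclusions` (the log).
#' @export
prepare_analysis <- function(flies) {
  ex <- apply_exclusions(flies)
  k <- ex$kept
  pd <- per_day_intake(k$total_P_mg, k$total_C_mg, k$lifespan_days)
  k$P_day_mg <- pd$P_day_mg
  k$C_day_mg <- pd$C_day_mg
  k$LS <- k$lifespan_days
  k$LEP <- k$eggs_total
  k$DEP <- k$eggs_total / k$lifespan_days
  list(records = k, exclusions = ex$log)
}
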