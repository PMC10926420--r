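#' Define a liquid experimental diet
#'
#' A diet is characterised by its protein:carbohydrate mass ratio (in parts)
#' and the combined protein + carbohydrate concentration in g/L. Nutrient
#' densities in mg/uL follow from the two: a 1:1 diet at 180 g/L carries
#' 0.09 mg of protein and 0.09 mg of carbohydrate per microlitre.
#'
#' @param p_parts Non-negative mass parts of protein in the ratio.
#' @param c_parts Non-negative mass parts of carbohydrate in the ratio.
#' @param concentration Total protein + carbohydrate concentration, g/L (> 0).
#' @param label Optional diet label; defaults to `"p:c (conc g/L)"`.
#' @return An object of class `"diet"`: a list with the ratio parts, the
#'   concentration, the label and the derived `protein_mg_per_uL` /
#'   `carb_mg_per_uL` densities.
#' @examples
#' d <- diet(1, 4, 180)
#' nutrient_densities(d)
#' @export
diet <- function(p_parts, c_parts, concentration, label = NULL) {
  if (!is.numeric(p_parts) || !is.numeric(c_parts) || p_parts < 0 || c_parts < 0)
    stop("diet ratio parts must be non-negative numbers", call. = FALSE)
  if (p_parts + c_parts <= 0)
    stop("invalid diet: protein and carbohydrate parts are both zero", call. = FALSE)
  if (!is.numeric(concentration) || concentration <= 0)
    stop("diet concentration must be > 0 g/L", call. = FALSE)
  if (is.null(label))
    label <- sprintf("%g:%g (%g g/L)", p_parts, c_parts, concentration)
  frac_p <- p_parts / (p_parts + c_parts)
  structure(list(
    p_parts = p_parts, c_parts = c_parts,
    concentration = concentration, label = label,
    protein_mg_per_uL = frac_p * concentration / 1000,
    carb_mg_per_uL = (1 - frac_p) * concentration / 1000
  ), class = "diet")
}

#' @export
print.diet <- function(x, ...) {
  cat(sprintf("Diet %s: %.4f mg P/uL, %.4f mg C/uL\n",
              x$label, x$protein_mg_per_uL, x$carb_mg_per_uL))
  invisible(x)
}

#' Nutrient densities of a diet
#'
#' @param d A [diet()] object.
#' @return Named numeric vector `c(protein_mg_per_uL, carb_mg_per_uL)`; the two
#'   densities always sum to `concentration / 1000` (mass balance).
#' @export
nutrient_densities <- function(d) {
  stopifnot(inherits(d, "diet"))
  c(protein_mg_per_uL = d$protein_mg_per_uL, carb_mg_per_uL = d$carb_mg_per_uL)
}

#' The factorial diet grid of the no-choice experiment
#'
#' Five P:C ratios (0:1, 1:8, 1:4, 1:2, 1:1) crossed with three total
#' concentrations (45, 180, 360 g/L) give the 15 experimental diets.
#'
#' @param ratios List of two-element numeric vectors `c(p_parts, c_parts)`.
#' @param concentrations Numeric vector of total concentrations, g/L.
#' @return A data frame with one row per diet: `label`, `p_parts`, `c_parts`,
#'   `concentration_g_per_L`, `protein_mg_per_uL`, `carb_mg_per_uL`.
#' @examples
#' nrow(diet_grid())  # 15
#' @export
diet_grid <- function(ratios = list(c(0, 1), c(1, 8), c(1, 4), c(1, 2), c(1, 1)),
                      concentrations = c(45, 180, 360)) {
  rows <- lapply(ratios, function(r) {
    lapply(concentrations, function(k) {
      d <- diet(r[1], r[2], k)
      data.frame(label = d$label, p_parts = d$p_parts, c_parts = d$c_parts,
                 concentration_g_per_L = d$concentration,
                 protein_mg_per_uL = d$protein_mg_per_uL,
                 carb_mg_per_uL = d$carb_mg_per_uL,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' Reconstruct a diet object from a diet-grid row or label
#' @param grid A data frame as returned by [diet_grid()] or [read_diet_grid()].
#' @param label Diet label to look up.
#' @return A [diet()] object.
#' @export
diet_from_grid <- function(grid, label) {
  i <- match(label, grid$label)
  if (is.na(i)) stop("unknown diet label: ", label, call. = FALSE)
  diet(grid$p_parts[i], grid$c_parts[i], grid$concentration_g_per_L[i],
       grid$label[i])
}

#' Read / write a diet grid as delimited text
#'
#' The file has columns `label, p_parts, c_parts, concentration_g_per_L`.
#' @param path File path.
#' @param grid Data frame of diets.
#' @return `read_diet_grid()` returns the grid with derived densities added.
#' @export
read_diet_grid <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "p_parts", "c_parts", "concentration_g_per_L")
  if (!all(need %in% names(g)))
    stop("diet grid file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  frac <- g$p_parts / (g$p_parts + g$c_parts)
  g$protein_mg_per_uL <- frac * g$concentration_g_per_L / 1000
  g$carb_mg_per_uL <- (1 - frac) * g$concentration_g_per_L / 1000
  g
}

#' @rdname read_diet_grid
#' @export
write_diet_grid <- function(grid, path) {
  utils::write.csv(grid[, c("label", "p_parts", "c_parts",
                            "concentration_g_per_L")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Linear length-to-volume calibration for feeding tubes
#'
#' Consumption is read as the difference between initial and remaining diet
#' length in a graduated pipette tip and converted to microlitres with a
#' linear standard curve. The default anchors the calibration so a full tube
#' (initial length `full_length_mm`) holds `full_volume_uL` = 100 uL.
#'
#' @param slope uL per mm of tube length (> 0).
#' @param intercept uL offset, default 0.
#' @param full_length_mm,full_volume_uL Alternative anchored parameterisation:
#'   slope = `full_volume_uL / full_length_mm`, intercept 0.
#' @return An object of class `"calibration"`.
#' @export
calibration <- function(slope = NULL, intercept = 0,
                        full_length_mm = NULL, full_volume_uL = 100) {
  if (is.null(slope)) {
    if (is.null(full_length_mm))
      stop("supply either slope or full_length_mm", call. = FALSE)
    slope <- full_volume_uL / full_length_mm
    intercept <- 0
  }
  if (slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  structure(list(slope = slope, intercept = intercept), class = "calibration")
}

#' Volume consumed from tube-length readings
#'
#' @param initial_length_mm,final_length_mm Tube diet lengths before and after
#'   the interval, mm. Negative computed volumes (final > initial, measurement
#'   noise) are returned as-is; they are corrected downstream.
#' @param cal A [calibration()] object.
#' @return Consumed volume in uL.
#' @examples
#' volume_consumed(50, 25, calibration(slope = 2))  # 50
#' @export
volume_consumed <- function(initial_length_mm, final_length_mm, cal) {
  stopifnot(inherits(cal, "calibration"))
  cal$slope * (initial_length_mm - final_length_mm) + cal$intercept
}

#' Correct a consumed volume for evaporation
#'
#' Control tubes of the same diet over the same interval measure evaporative
#' loss; the mean control loss is subtracted from the measured consumption and
#' the result floored at zero (negative intake is physically impossible).
#'
#' @param consumed_uL Measured consumption for one fly-interval, uL.
#' @param control_losses_uL Volumes lost from >= 1 control tube of the same
#'   diet over the same interval, uL.
#' @return Corrected consumption in uL, never negative.
#' @examples
#' evaporation_correction(60, c(8, 10, 12))  # 50
#' evaporation_correction(5, 10)             # 0
#' @export
evaporation_correction <- function(consumed_uL, control_losses_uL) {
  if (length(control_losses_uL) < 1 || all(is.na(control_losses_uL)))
    stop("no control tubes available for evaporation correction", call. = FALSE)
  pmax(0, consumed_uL - mean(control_losses_uL, na.rm = TRUE))
}

#' Convert a corrected volume into protein and carbohydrate mass
#'
#' @param corrected_uL Non-negative consumed volume, uL.
#' @param d A [diet()] object.
#' @return Named numeric vector `c(protein_mg, carb_mg)`.
#' @examples
#' intake_mg(100, diet(1, 1, 180))  # 9 mg P, 9 mg C
#' @export
intake_mg <- function(corrected_uL, d) {
  stopifnot(inherits(d, "diet"))
  if (any(corrected_uL < 0))
    stop("corrected volume must be non-negative", call. = FALSE)
  c(protein_mg = corrected_uL * d$protein_mg_per_uL,
    carb_mg = corrected_uL * d$carb_mg_per_uL)
}

#' Compute corrected per-fly intakes from a tube-measurement table
#'
#' Takes one row per tube per interval (flies and evaporation controls
#' distinguished by a `role` column), converts length differences to volumes,
#' subtracts the per-diet per-interval mean control loss, floors at zero, and
#' converts to mg of protein and carbohydrate using each diet's densities.
#'
#' @param tubes Data frame with columns `id`, `role` (`"fly"` or `"control"`),
#'   `diet_label`, `interval_start_day`, `interval_end_day`,
#'   `initial_length_mm`, `final_length_mm`.
#' @param grid Diet grid (see [diet_grid()] / [read_diet_grid()]).
#' @param cal A [calibration()] object.
#' @return Data frame with one row per fly-interval: the corrected volume and
#'   `protein_mg`, `carb_mg`, plus a per-fly total via [total_intake()].
#' @export
compute_intakes <- function(tubes, grid, cal) {
  need <- c("id", "role", "diet_label", "interval_start_day",
            "interval_end_day", "initial_length_mm", "final_length_mm")
  if (!all(need %in% names(tubes)))
    stop("tube table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tubes$volume_uL <- volume_consumed(tubes$initial_length_mm,
                                     tubes$final_length_mm, cal)
  key <- interaction(tubes$diet_label, tubes$interval_start_day,
                     tubes$interval_end_day, drop = TRUE)
  ctrl <- tubes$role == "control"
  loss <- tapply(tubes$volume_uL[ctrl], key[ctrl], mean)
  loss <- loss[!is.na(loss)]
  fly <- tubes[!ctrl, , drop = FALSE]
  fkey <- as.character(key[!ctrl])
  miss <- !(fkey %in% names(loss))
  if (any(miss))
    stop("no evaporation controls for diet/interval: ",
         paste(unique(fkey[miss]), collapse = "; "), call. = FALSE)
  fly$corrected_uL <- pmax(0, fly$volume_uL - unname(loss[fkey]))
  i <- match(fly$diet_label, grid$label)
  if (anyNA(i))
    stop("tube table refers to diets absent from the grid", call. = FALSE)
  fly$protein_mg <- fly$corrected_uL * grid$protein_mg_per_uL[i]
  fly$carb_mg <- fly$corrected_uL * grid$carb_mg_per_uL[i]
  rownames(fly) <- NULL
  fly
}

#' Sum interval intakes to per-fly totals
#' @param intakes Output of [compute_intakes()].
#' @return One row per fly id with total `protein_mg` and `carb_mg`.
#' @export
total_intake <- function(intakes) {
  agg <- stats::aggregate(intakes[, c("protein_mg", "carb_mg")],
                          by = list(id = intakes$id), FUN = sum)
  agg[order(agg$id), , drop = FALSE]
}
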