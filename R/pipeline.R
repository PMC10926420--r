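#' Default pipeline configuration
#'
#' @param seed Master seed; stage seeds derive from it deterministically.
#' @param flies_per_cell Flies per design cell for both generators.
#' @param bootstrap_B Bootstrap replicates for optimum regions (0 skips).
#' @param alpha Significance level used throughout.
#' @param out Output directory, or `NULL` to skip writing files.
#' @return Named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, flies_per_cell = 5, bootstrap_B = 0,
                            alpha = 0.05, out = NULL) {
  list(seed = as.integer(seed), flies_per_cell = flies_per_cell,
       bootstrap_B = bootstrap_B, alpha = alpha, out = out)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config Configuration list.
#' @return `read_pipeline_config()` returns the config list; the round trip
#'   through YAML leaves a [pipeline_config()] unchanged.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  missing <- setdiff(setdiff(names(defaults), "out"), names(cfg))
  if (length(missing))
    stop("configuration is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full analysis pipeline on generated data
#'
#' Generates both experiments, preprocesses the no-choice data, fits
#' linear and full response surfaces per line and sex for lifespan (plus
#' female egg traits), fits the total-consumption model, runs the
#' between-line landscape comparisons per sex, fits thin-plate-spline
#' landscapes with optima (and bootstrap regions when `bootstrap_B > 0`),
#' and analyses the choice experiment (random-feeding tests per line and
#' pair, regulated intake points, regulation comparisons by line and by
#' sex). Deterministic given the config seed. When `config$out` is set,
#' tables are written as CSV and fitted summaries as JSON, each stamped
#' with a hash of the configuration.
#'
#' @param config A [pipeline_config()] list or path to a YAML file.
#' @return Named list with elements `exp1`, `exp2`, `records`,
#'   `surfaces`, `total_consumption`, `comparisons`, `landscapes`,
#'   `optima`, `regions`, `choice`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.numeric(config$seed), is.numeric(config$flies_per_cell))
  hash <- config_hash(config)
  seed <- config$seed

  exp1 <- generate_experiment1(design_exp1(
    flies_per_cell = config$flies_per_cell, seed = seed))
  exp2 <- generate_experiment2(design_exp2(
    flies_per_cell = config$flies_per_cell, seed = seed + 1L))
  prep <- prepare_analysis(exp1$flies)
  rec <- prep$records

  surfaces <- list(); landscapes <- list(); optima <- list(); regions <- list()
  for (ln in unique(rec$line)) for (sx in unique(rec$sex)) {
    key <- paste0("LS.", ln, ".", sx)
    sub <- rec[rec$line == ln & rec$sex == sx, ]
    surfaces[[key]] <- surface_fit(sub, "LS")
    landscapes[[key]] <- fit_landscape(sub$P_day_mg, sub$C_day_mg, sub$LS)
    optima[[key]] <- suppressWarnings(find_optimum(landscapes[[key]]))
    if (config$bootstrap_B > 0)
      regions[[key]] <- optimum_region(sub$P_day_mg, sub$C_day_mg, sub$LS,
                                       B = config$bootstrap_B,
                                       alpha = config$alpha,
                                       seed = seed + 2L)
  }
  for (ln in unique(rec$line)) for (tr in c("LEP", "DEP")) {
    key <- paste0(tr, ".", ln, ".F")
    sub <- rec[rec$line == ln & rec$sex == "F", ]
    surfaces[[key]] <- surface_fit(sub, tr)
    landscapes[[key]] <- fit_landscape(sub$P_day_mg, sub$C_day_mg, sub[[tr]])
    optima[[key]] <- suppressWarnings(find_optimum(landscapes[[key]]))
  }

  comparisons <- list()
  for (sx in unique(rec$sex)) {
    a <- rec[rec$line == "CT" & rec$sex == sx, ]
    b <- rec[rec$line == "US" & rec$sex == sx, ]
    comparisons[[paste0("CT_vs_US.", sx)]] <-
      sequential_compare(a, b, "LS", labels = c("CT", "US"),
                         alpha = config$alpha)
  }
  for (ln in unique(rec$line)) {
    f <- rec[rec$line == ln & rec$sex == "F", ]
    m <- rec[rec$line == ln & rec$sex == "M", ]
    comparisons[[paste0(ln, ".F_vs_M")]] <-
      sequential_compare(f, m, "LS", labels = c("F", "M"),
                         alpha = config$alpha)
    comparisons[[paste0(ln, ".LS_vs_DEP.F")]] <-
      sequential_compare(f, f, "LS", "DEP", labels = c("LS", "DEP"),
                         standardize = "by_group", alpha = config$alpha)
  }

  tot <- fit_total_consumption(rec)

  flies2 <- choice_expectations(exp2)
  feeding <- list()
  for (ln in unique(flies2$line)) for (pr in unique(flies2$pair)) {
    sub <- flies2[flies2$line == ln & flies2$pair == pr, ]
    feeding[[paste0(ln, ".", pr)]] <- random_feeding_test(
      sub$protein_mg, sub$expected_P_mg, sub$carb_mg, sub$expected_C_mg)
  }
  points <- lapply(split(flies2, flies2$line), function(s)
    regulated_intake_point(s$protein_mg, s$carb_mg))
  regl <- list(line = compare_regulation(flies2, "line"))
  for (ln in unique(flies2$line))
    regl[[paste0("sex.", ln)]] <-
      compare_regulation(flies2[flies2$line == ln, ], "sex")

  out <- list(exp1 = exp1, exp2 = exp2, records = rec,
              exclusions = prep$exclusions,
              surfaces = surfaces, total_consumption = tot,
              comparisons = comparisons, landscapes = landscapes,
              optima = optima, regions = regions,
              choice = list(flies = flies2, feeding = feeding,
                            intake_points = points, regulation = regl),
              config = config, config_hash = hash)
  if (!is.null(config$out)) write_pipeline_outputs(out, config$out)
  out
}

# Stable short hash of the configuration (polynomial rolling hash over its
# serialized bytes).
config_hash <- function(config) {
  bytes <- as.integer(serialize(config[order(names(config))], NULL,
                                version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- res$config_hash
  utils::write.csv(res$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(res$choice$flies, file.path(dir, "choice_records.csv"),
                   row.names = FALSE)
  fits <- list(
    config_hash = stamp,
    surfaces = lapply(res$surfaces, function(f)
      list(trait = f$trait, n = f$n, coefficients = as.list(f$coefficients),
           se = as.list(f$se), logLik = f$logLik, engine = f$engine)),
    optima = lapply(res$optima, as.list),
    comparisons = lapply(res$comparisons, function(x) x$table),
    total_consumption = list(coefficients =
                               as.list(res$total_consumption$coefficients),
                             tests = res$total_consumption$tests),
    intake_points = lapply(res$choice$intake_points, function(p)
      list(mean_P = p$mean_P, mean_C = p$mean_C, n = p$n,
           C_to_P_ratio = p$C_to_P_ratio)),
    regulation = lapply(res$choice$regulation, function(x) x$tests))
  jsonlite::write_json(fits, file.path(dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
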