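#' Published summary statistics bundled with the package
#'
#' Two small tables transcribed from the marula-fly oviposition-selection
#' study that this package's methods implement, used to verify the
#' computational machinery against printed results without raw data:
#'
#' * `published_comparison_ss()` — residual sums of squares, degrees of
#'   freedom and printed F-statistics of the sequential lifespan-landscape
#'   comparisons between selection lines and sexes. For every row that is
#'   internally consistent, [partial_f()] applied to the printed
#'   `SSr`/`SSc`/`DF1`/`DF2` reproduces `F_printed` at 2 decimal places;
#'   the "CT females vs CT males" linear and correlational rows are not
#'   internally consistent under the partial-F formula and are excluded by
#'   `consistent_only = TRUE`.
#' * `published_choice_means()` — reported mean cumulative protein and
#'   carbohydrate intakes (mg over a 16-day choice assay) per selection
#'   line and sex. Pooling the sexes and taking the carbohydrate:protein
#'   ratio gives the reported regulated intake ratios 1:3.6 (CT) and
#'   1:3.2 (US).
#'
#' @param consistent_only Drop rows whose printed F disagrees with the
#'   partial-F formula applied to the printed sums of squares.
#' @return A data frame.
#' @export
published_comparison_ss <- function(consistent_only = FALSE) {
  x <- utils::read.csv(system.file("extdata", "lifespan_comparison_ss.csv",
                                   package = "nutriscape"),
                       stringsAsFactors = FALSE)
  if (consistent_only) {
    Fcalc <- mapply(function(r, c, d1, d2) partial_f(r, c, d1, d2)["F"],
                    x$SSr, x$SSc, x$DF1, x$DF2)
    x <- x[round(Fcalc, 2) == x$F_printed, , drop = FALSE]
  }
  x
}

#' @rdname published_comparison_ss
#' @export
published_choice_means <- function() {
  utils::read.csv(system.file("extdata", "choice_mean_intakes.csv",
                              package = "nutriscape"),
                  stringsAsFactors = FALSE)
}
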