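#' Bundled forest plot summaries
#'
#' Descriptive summaries of the validation plots: five ULS plots in
#' Saihanba National Forest Park (China) and the Alpine benchmark plots
#' with individually known areas. Columns include tree count, published
#' stem density (trees/m2) and plot area (m2); the published densities can
#' be re-derived as `round(n_trees / area_m2, 2)`.
#'
#' @param which `"saihanba"` or `"alpine"`.
#' @return data frame of plot summaries.
#' @export
plot_summaries <- function(which = c("saihanba", "alpine")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_plots.csv"),
                   package = "canopycce", mustWork = TRUE)
  utils::read.csv(f, colClasses = c(plot = "character"))
}

#' Published treetop detection rates of the five Saihanba plots
#'
#' Matching and extraction rates per plot, from which the remaining three
#' metrics follow algebraically (see [metrics_from_rates()]). Included so
#' the metric identities can be exercised without the (undeposited) field
#' data.
#'
#' @return data frame with `plot`, `r_match`, `r_extraction` and the
#'   published `f`, `r_omission`, `r_commission` cells.
#' @export
published_detection_rates <- function() {
  data.frame(
    plot = c("P1", "P2", "P3", "P4", "P5"),
    r_match = c(0.61, 0.75, 0.92, 0.71, 0.89),
    r_extraction = c(0.80, 1.24, 1.76, 0.92, 1.34),
    f = c(0.68, 0.67, 0.66, 0.74, 0.75),
    r_omission = c(0.39, 0.25, 0.08, 0.29, 0.11),
    r_commission = c(0.23, 0.39, 0.48, 0.23, 0.34))
}
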