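#' Worked-example conspecific thinning table
#'
#' Published d(r) values (change in additional aggregation from the sapling
#' to the juvenile stage, scales 0-10 m) for the 11 focal species of a 9-ha
#' temperate broadleaved-Korean pine forest dynamics plot that exhibited
#' thinning effects with habitat heterogeneity factored out. Cells are `NA`
#' where the statistic was not computable. Bundled as the worked-example
#' surface for [findDmax()]: e.g. *Pinus koraiensis* attains its maximum
#' thinning strength 58.1 at the 0 m scale, and the largest radius of
#' maximum thinning across species is 6 m (*Acer tegmentosum*).
#'
#' @return A `data.frame` with a `species` column and columns `d_0` ...
#'   `d_10`.
#' @examples
#' tab <- exampleThinningTable()
#' findDmax(as.numeric(tab[tab$species == "Pinus koraiensis", -1]), 0:10)
#' @export
exampleThinningTable <- function() {
  read.csv(system.file("extdata", "example_thinning_d.csv",
                       package = "densdep"), check.names = TRUE,
           stringsAsFactors = FALSE)
}

#' Average annual mortality from an interval mortality
#'
#' Converts mortality observed over a multi-year census interval to a
#' per-year figure. The default, `"proportional"`, is the simple per-year
#' average `m / years` conventionally quoted for seedling banks (29.8 %
#' over five years averages about 6 % per year); `"compound"` returns the
#' constant annual rate `1 - (1 - m)^(1/years)` that compounds to the
#' interval mortality.
#'
#' @param mortality interval mortality, as a proportion in `[0, 1]` or a
#'   percentage in `(1, 100]`; the result is returned in the same units.
#' @param years interval length in years (default 5).
#' @param method `"proportional"` or `"compound"`.
#' @return Per-year mortality in the units of the input.
#' @examples
#' annualMortalityRate(29.8, years = 5)  # ~6 % per year
#' @export
annualMortalityRate <- function(mortality, years = 5,
                                method = c("proportional", "compound")) {
  method <- match.arg(method)
  stopifnot(mortality >= 0, mortality <= 100, years > 0)
  pct <- mortality > 1
  m <- if (pct) mortality / 100 else mortality
  out <- switch(method,
                proportional = m / years,
                compound = 1 - (1 - m)^(1 / years))
  if (pct) out * 100 else out
}
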