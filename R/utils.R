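# Small shared helpers and the worked-example reference values.

#' Percentage by which one value exceeds another
#'
#' `100 * (a / b - 1)`: e.g. how much deeper one group's mean depth is than
#' another's, in percent of the second group.
#'
#' @param a,b numeric values, `b` non-zero.
#' @return percent excess of `a` over `b`.
#' @examples
#' percent_excess(28.3, 18.3) # ~54.6
#' @export
percent_excess <- function(a, b) {
  stopifnot(b != 0)
  100 * (a / b - 1)
}

#' Published group estimates used in worked examples
#'
#' Reference predicted/observed group estimates for the Lake Champlain lake
#' trout system, shipped as plain CSV: mean occupied depth by maturity stage
#' and model-predicted per-season region use by origin. Used by the worked
#' examples and the acceptance report; they are inputs, not outputs, of this
#' package.
#'
#' @return data.frame `quantity`, `group`, `value`, `unit`.
#' @export
reference_estimates <- function() {
  path <- system.file("extdata", "reference_group_estimates.csv",
                      package = "troutline", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
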