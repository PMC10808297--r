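# Soil chemistry helpers used by the examples and the pipeline summaries.

#' Example soil property table
#'
#' Per-treatment means of standard soil chemistry measurements (soil water,
#' organic carbon, total nitrogen, total/available phosphorus, pH) from a
#' four-level phosphorus-addition trial, shipped as example data for the
#' derived-ratio helpers.
#'
#' @return data.frame with a \code{property} column and one column per
#'   treatment.
#' @export
soilProperties <- function() {
  utils::read.delim(system.file("extdata", "soil_properties.tsv",
                                package = "microfoodweb", mustWork = TRUE),
                    comment.char = "#", check.names = FALSE)
}

#' Soil carbon-to-nitrogen ratio
#'
#' The C/N ratio of soil organic matter, SOC divided by total N (both in
#' the same mass units, conventionally g per kg dry soil).
#'
#' @param soc soil organic carbon.
#' @param tn total nitrogen.
#' @param digits decimals to round to; \code{NULL} for no rounding.
#' @return numeric vector of ratios.
#' @examples
#' carbonNitrogenRatio(11.60, 0.83)  # 13.98
#' @export
carbonNitrogenRatio <- function(soc, tn, digits = 2) {
  stopifnot(all(tn > 0))
  r <- soc / tn
  if (is.null(digits)) r else round(r, digits)
}
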