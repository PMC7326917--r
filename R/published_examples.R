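#' Published worked examples
#'
#' Two small tables of published reference values from the 552-line
#' sunflower screen, shipped for worked examples and verification:
#' \code{"mfv"} holds the per-trait membership values, mean MFV and grade of
#' the five most tolerant and five most sensitive lines; \code{"sti"} holds
#' the 15 verification lines (three per grade) with their seven STIs, mean
#' MFV and published Y score.
#'
#' @param which \code{"sti"} or \code{"mfv"}.
#' @return Data frame.
#' @export
#' @examples
#' ex <- published_examples("sti")
#' predict_y(published_model(), ex[1, ])
published_examples <- function(which = c("sti", "mfv")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("published_", which, "_examples.csv"),
                      package = "germscreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$germplasm <- as.character(df$germplasm)
  df
}
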