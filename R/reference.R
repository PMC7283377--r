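#' Published reference intervals for the seven SER QTLs
#'
#' Interval endpoints, estimated and maximum lengths, screen p-values and
#' additive effects (percentage points, mean over five cropping seasons)
#' of the seven stigma-exsertion-rate QTLs mapped in the HJX74 x
#' O. glumaepatula SSSL library, as published. Two rows
#' (\code{width_consistent == FALSE}) have printed estimated lengths that
#' disagree with their own interval endpoints by 0.1 kb — an upstream
#' rounding artifact; this package's own rounding rule ([round_kb()])
#' reproduces the endpoint arithmetic, not those two printed cells.
#'
#' @return data.frame with one row per QTL.
#' @export
qser_reference <- function() {
  path <- system.file("extdata", "qser_qtl_reference.tsv", package = "sslmap")
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", rep("numeric", 7),
                                   "logical"))
}
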