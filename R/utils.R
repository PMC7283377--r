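#' Round to one decimal, halves away from zero
#'
#' Lengths and interval bounds are reported in kb to one decimal place.
#' Base \code{round()} rounds halves to even; segment-length reporting in the
#' SSSL literature rounds halves away from zero, so that rule is used for all
#' printed kb quantities.
#'
#' @param x numeric vector.
#' @return numeric vector rounded to 0.1.
#' @export
round_kb <- function(x) {
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sslmap <- function(..., class = "sslmap_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop_sslmap(name, " must be a single number in (0, 1)",
                class = "sslmap_config_error")
  invisible(x)
}
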