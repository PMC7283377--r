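#' Stigma exsertion rate from spikelet counts
#'
#' Stigma exsertion is scored per spikelet as single (one stigma exserted,
#' SSE) or dual (both stigmas exserted, DSE); the stigma exsertion rate
#' (SER) of a panicle is the percentage of spikelets with any exserted
#' stigma, i.e. the sum of the SSE and DSE rates.
#'
#' @param n_spikelets total spikelets counted (> 0).
#' @param n_sse spikelets with single stigma exsertion.
#' @param n_dse spikelets with dual stigma exsertion.
#' @return named numeric \code{c(ser, sse_rate, dse_rate)} in percent.
#' @examples
#' compute_ser(200, 30, 10) # SER 20, SSE 15, DSE 5
#' @export
compute_ser <- function(n_spikelets, n_sse, n_dse) {
  if (any(n_spikelets <= 0))
    stop_sslmap("n_spikelets must be > 0", class = "sslmap_pheno_error")
  if (any(n_sse < 0) || any(n_dse < 0) || any(n_sse + n_dse > n_spikelets))
    stop_sslmap("require 0 <= n_sse + n_dse <= n_spikelets",
                class = "sslmap_pheno_error")
  c(ser = 100 * (n_sse + n_dse) / n_spikelets,
    sse_rate = 100 * n_sse / n_spikelets,
    dse_rate = 100 * n_dse / n_spikelets)
}

#' Read a long-format phenotype table
#'
#' Expected CSV columns: \code{line_id, season_id, unit_id} and either
#' spikelet counts (\code{n_spikelets, n_sse, n_dse}) or a precomputed
#' \code{ser_percent}. When counts are present, \code{ser_percent} is
#' (re)computed from them.
#'
#' @param path CSV file.
#' @return data.frame with a \code{ser_percent} column.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "season_id", "unit_id")
  if (!all(need %in% names(df)))
    stop_sslmap("phenotype file needs columns: ", paste(need, collapse = ", "),
                class = "sslmap_io_error")
  df$line_id <- as.character(df$line_id)
  df$season_id <- as.character(df$season_id)
  add_ser(df)
}

#' Add (or validate) the ser_percent column of a phenotype table
#' @param pheno phenotype data.frame (see [read_phenotypes()]).
#' @return the table with \code{ser_percent} filled in.
#' @export
add_ser <- function(pheno) {
  counts <- all(c("n_spikelets", "n_sse", "n_dse") %in% names(pheno))
  if (counts) {
    bad <- which(pheno$n_spikelets <= 0 | pheno$n_sse < 0 | pheno$n_dse < 0 |
                   pheno$n_sse + pheno$n_dse > pheno$n_spikelets)
    if (length(bad))
      stop_sslmap("invalid spikelet counts at row(s): ",
                  paste(utils::head(bad, 5), collapse = ", "),
                  class = "sslmap_pheno_error")
    pheno$ser_percent <-
      100 * (pheno$n_sse + pheno$n_dse) / pheno$n_spikelets
  } else if (!"ser_percent" %in% names(pheno)) {
    stop_sslmap("need either spikelet counts or ser_percent",
                class = "sslmap_pheno_error")
  }
  if (any(pheno$ser_percent < 0 | pheno$ser_percent > 100))
    stop_sslmap("ser_percent outside [0, 100]", class = "sslmap_pheno_error")
  pheno
}

#' Write a phenotype table to CSV
#' @param pheno phenotype data.frame.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-line-per-season SER means
#'
#' The panicle is the replicate unit: the default aggregation is the mean of
#' per-panicle SER values within a line and season. \code{"pooled_counts"}
#' instead pools the spikelet counts of all panicles of a line-season cell
#' and computes one rate (requires count columns).
#'
#' @param pheno phenotype data.frame with \code{ser_percent}.
#' @param aggregation \code{"panicle_mean"} (default) or
#'   \code{"pooled_counts"}.
#' @return data.frame \code{line_id, season_id, ser_mean, n_units}.
#' @export
aggregate_ser <- function(pheno, aggregation = c("panicle_mean", "pooled_counts")) {
  aggregation <- match.arg(aggregation)
  pheno <- add_ser(pheno)
  if (aggregation == "panicle_mean") {
    agg <- stats::aggregate(ser_percent ~ line_id + season_id, data = pheno, FUN = mean)
    names(agg)[names(agg) == "ser_percent"] <- "ser_mean"
  } else {
    if (!all(c("n_spikelets", "n_sse", "n_dse") %in% names(pheno)))
      stop_sslmap("pooled_counts aggregation needs spikelet count columns",
                  class = "sslmap_pheno_error")
    agg <- stats::aggregate(cbind(n_spikelets, n_sse, n_dse) ~ line_id + season_id,
                            data = pheno, FUN = sum)
    agg$ser_mean <- 100 * (agg$n_sse + agg$n_dse) / agg$n_spikelets
    agg <- agg[c("line_id", "season_id", "ser_mean")]
  }
  cnt <- stats::aggregate(ser_percent ~ line_id + season_id, data = pheno, FUN = length)
  names(cnt)[names(cnt) == "ser_percent"] <- "n_units"
  merge(agg, cnt, by = c("line_id", "season_id"), sort = TRUE)
}
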