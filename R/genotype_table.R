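#' Genotype call codes
#'
#' Marker calls are coded \code{"R"} (recipient / recurrent-parent
#' homozygote), \code{"D"} (donor homozygote), \code{"H"} (heterozygous) and
#' \code{"-"} (missing).
#'
#' @format character vector of the four admissible call symbols.
#' @export
GENO_CALLS <- c(RECIPIENT = "R", DONOR = "D", HETEROZYGOUS = "H", MISSING = "-")

#' Construct and validate a genotype table
#'
#' A genotype table is a character matrix of marker calls, rows = lines,
#' columns = markers. Every column must name a marker present in the map and
#' every line must have at least one non-missing call.
#'
#' @param calls character matrix with rownames (line ids) and colnames
#'   (marker ids), cells in \code{c("R","D","H","-")}.
#' @param map a [marker_map()] the columns are validated against.
#' @return the validated matrix, class \code{genotype_table}.
#' @export
genotype_table <- function(calls, map) {
  if (!is.matrix(calls) || is.null(rownames(calls)) || is.null(colnames(calls)))
    stop_sslmap("calls must be a matrix with line rownames and marker colnames",
                class = "sslmap_geno_error")
  calls <- matrix(as.character(calls), nrow = nrow(calls),
                  dimnames = dimnames(calls))
  bad <- matrix(!(calls %in% GENO_CALLS), nrow = nrow(calls))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_sslmap("unknown genotype symbol '", calls[bad][1], "' at line ",
                rownames(calls)[idx[1]], ", marker ", colnames(calls)[idx[2]],
                class = "sslmap_geno_error")
  }
  unknown <- setdiff(colnames(calls), map$marker_id)
  if (length(unknown))
    stop_sslmap("markers absent from map: ", paste(unknown, collapse = ", "),
                class = "sslmap_geno_error")
  all_missing <- rowSums(calls != GENO_CALLS[["MISSING"]]) == 0
  if (any(all_missing))
    stop_sslmap("line(s) with no non-missing call: ",
                paste(rownames(calls)[all_missing], collapse = ", "),
                class = "sslmap_geno_error")
  class(calls) <- c("genotype_table", class(calls))
  calls
}

#' Read a genotype matrix from TSV
#'
#' Rows are lines, columns are markers; the first column (header
#' \code{line_id}) holds line ids; cells are in \code{R D H -}.
#'
#' @param path file path.
#' @param map a [marker_map()].
#' @return a \code{genotype_table}.
#' @export
read_genotype_table <- function(path, map) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!nrow(df) || names(df)[1] != "line_id")
    stop_sslmap("genotype file must be non-empty with first column line_id",
                class = "sslmap_io_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$line_id
  genotype_table(m, map)
}

#' Write a genotype matrix to TSV
#' @param geno a \code{genotype_table}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_genotype_table <- function(geno, path) {
  df <- data.frame(line_id = rownames(geno), unclass(geno),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
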