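#' Construct a marker map
#'
#' A marker map is the ordered table of codominant markers used to genotype a
#' substitution-line library: one row per marker with its chromosome and
#' physical position in kilobases. Positions must be strictly increasing
#' within a chromosome. Each chromosome also carries an extent
#' (\code{start_kb}, \code{end_kb}) used as the flanking coordinate when a
#' donor segment reaches a chromosome end and has no flanking recipient
#' marker (a telomeric introgression).
#'
#' @param marker_id character vector of unique marker names.
#' @param chromosome character (or coercible) vector of chromosome labels.
#' @param position_kb numeric physical positions in kb, >= 0.
#' @param chrom_extent optional data.frame with columns \code{chromosome},
#'   \code{start_kb}, \code{end_kb}. Defaults to \code{[0, max marker
#'   position]} per chromosome. Must span all markers of its chromosome.
#' @return a \code{marker_map}: a data.frame with columns \code{marker_id},
#'   \code{chromosome}, \code{position_kb}, sorted by chromosome then
#'   position, with the extent table in \code{attr(, "chrom_extent")}.
#' @examples
#' mm <- marker_map(c("M1", "M2", "M3"), "1", c(50, 100, 200))
#' @export
marker_map <- function(marker_id, chromosome, position_kb, chrom_extent = NULL) {
  marker_id <- as.character(marker_id)
  chromosome <- as.character(chromosome)
  position_kb <- as.numeric(position_kb)
  n <- length(marker_id)
  if (length(chromosome) != n || length(position_kb) != n)
    stop_sslmap("marker_id, chromosome and position_kb must have equal length",
                class = "sslmap_map_error")
  if (anyDuplicated(marker_id))
    stop_sslmap("duplicate marker_id: ",
                paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "),
                class = "sslmap_map_error")
  if (any(is.na(position_kb)) || any(position_kb < 0))
    stop_sslmap("positions must be non-missing and >= 0",
                class = "sslmap_map_error")

  map <- data.frame(marker_id = marker_id, chromosome = chromosome,
                    position_kb = position_kb, stringsAsFactors = FALSE)
  map <- map[order(map$chromosome, map$position_kb), , drop = FALSE]
  rownames(map) <- NULL
  for (chr in unique(map$chromosome)) {
    pos <- map$position_kb[map$chromosome == chr]
    if (any(diff(pos) <= 0))
      stop_sslmap("positions not strictly increasing on chromosome ", chr,
                  class = "sslmap_map_error")
  }

  if (is.null(chrom_extent)) {
    chrom_extent <- do.call(rbind, lapply(unique(map$chromosome), function(chr) {
      pos <- map$position_kb[map$chromosome == chr]
      data.frame(chromosome = chr, start_kb = 0, end_kb = max(pos),
                 stringsAsFactors = FALSE)
    }))
  } else {
    chrom_extent <- as.data.frame(chrom_extent, stringsAsFactors = FALSE)
    need <- c("chromosome", "start_kb", "end_kb")
    if (!all(need %in% names(chrom_extent)))
      stop_sslmap("chrom_extent needs columns chromosome, start_kb, end_kb",
                  class = "sslmap_map_error")
    chrom_extent$chromosome <- as.character(chrom_extent$chromosome)
    for (chr in unique(map$chromosome)) {
      i <- match(chr, chrom_extent$chromosome)
      pos <- map$position_kb[map$chromosome == chr]
      if (is.na(i))
        stop_sslmap("chrom_extent missing chromosome ", chr,
                    class = "sslmap_map_error")
      if (chrom_extent$start_kb[i] > min(pos) || chrom_extent$end_kb[i] < max(pos))
        stop_sslmap("chrom_extent does not span markers on chromosome ", chr,
                    class = "sslmap_map_error")
    }
  }
  attr(map, "chrom_extent") <- chrom_extent
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Per-chromosome extent of a marker map
#' @param map a \code{marker_map}.
#' @param chromosome chromosome label.
#' @return numeric \code{c(start_kb, end_kb)}.
#' @export
chrom_extent <- function(map, chromosome) {
  ext <- attr(map, "chrom_extent")
  i <- match(as.character(chromosome), ext$chromosome)
  if (is.na(i))
    stop_sslmap("unknown chromosome: ", chromosome, class = "sslmap_map_error")
  c(start_kb = ext$start_kb[i], end_kb = ext$end_kb[i])
}

#' Read a marker map from TSV
#'
#' Expected header: \code{marker_id  chromosome  position_kb}.
#'
#' @param path file path.
#' @param chrom_extent optional extent table (see [marker_map()]).
#' @return a \code{marker_map}.
#' @export
read_marker_map <- function(path, chrom_extent = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  need <- c("marker_id", "chromosome", "position_kb")
  if (!all(need %in% names(df)))
    stop_sslmap("marker map file must have header: ",
                paste(need, collapse = "  "), class = "sslmap_io_error")
  marker_map(df$marker_id, df$chromosome, df$position_kb,
             chrom_extent = chrom_extent)
}

#' Write a marker map to TSV
#' @param map a \code{marker_map}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[c("marker_id", "chromosome", "position_kb")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
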