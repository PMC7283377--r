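#' Length statistics of a substituted segment
#'
#' A donor segment detected by markers is bounded from the inside by the
#' outermost donor-genotype markers and from the outside by the nearest
#' flanking recipient-genotype markers. The minimum length is the distance
#' between the outermost donor markers, the maximum length the distance
#' between the flanking recipient markers, and the estimated length their
#' mean:
#' \deqn{L_{min} = last\ donor - first\ donor,\quad
#'       L_{max} = right\ flank - left\ flank,\quad
#'       L_{est} = (L_{min} + L_{max})/2.}
#'
#' @param first_donor_kb,last_donor_kb positions (kb) of the outermost donor
#'   markers of the run.
#' @param flank_left_kb,flank_right_kb positions (kb) of the flanking
#'   recipient markers, or of the chromosome extent when the run reaches a
#'   chromosome end.
#' @return named numeric \code{c(l_min, l_max, l_est)} in kb, full precision.
#' @examples
#' segment_lengths(100, 200, 50, 260) # c(100, 210, 155)
#' @export
segment_lengths <- function(first_donor_kb, last_donor_kb,
                            flank_left_kb, flank_right_kb) {
  if (any(is.na(c(first_donor_kb, last_donor_kb, flank_left_kb, flank_right_kb))))
    stop_sslmap("missing position", class = "sslmap_map_error")
  if (!(flank_left_kb <= first_donor_kb && first_donor_kb <= last_donor_kb &&
        last_donor_kb <= flank_right_kb && flank_left_kb < flank_right_kb))
    stop_sslmap("unordered positions: flanks must bracket the donor run",
                class = "sslmap_map_error")
  l_min <- last_donor_kb - first_donor_kb
  l_max <- flank_right_kb - flank_left_kb
  c(l_min = l_min, l_max = l_max, l_est = (l_min + l_max) / 2)
}

#' Estimated interval of a substituted segment
#'
#' The estimated interval places each end of the segment halfway between the
#' outermost donor marker and the adjacent flanking recipient marker, so its
#' width equals the estimated length \code{(L_min + L_max)/2}.
#'
#' @inheritParams segment_lengths
#' @return named numeric \code{c(start, end)} in kb.
#' @examples
#' estimated_interval(100, 200, 50, 260) # c(75, 230)
#' @export
estimated_interval <- function(first_donor_kb, last_donor_kb,
                               flank_left_kb, flank_right_kb) {
  segment_lengths(first_donor_kb, last_donor_kb, flank_left_kb, flank_right_kb)
  c(start = (flank_left_kb + first_donor_kb) / 2,
    end = (last_donor_kb + flank_right_kb) / 2)
}

#' Infer substituted segments from marker genotypes
#'
#' Scans each line chromosome by chromosome for maximal runs of donor calls.
#' Missing calls inside a run are bridged; missing calls at run edges do not
#' extend the run (the inner bound stays conservative). Each run is flanked
#' by the nearest recipient-genotype marker on either side, or by the
#' chromosome extent (\code{CHROM_BOUNDARY}) for telomeric introgressions.
#'
#' Heterozygous calls are handled per \code{het_policy}: \code{"error"}
#' (default; SSSLs are homozygous by construction, so a heterozygous call
#' means the line is not a finished SSSL and the whole call set is rejected
#' with a diagnostic), \code{"as_donor"} (count as donor; appropriate for
#' secondary-line intermediates), or \code{"as_break"} (count as
#' non-donor).
#'
#' @param geno a [genotype_table()].
#' @param map a [marker_map()].
#' @param het_policy one of \code{"error"}, \code{"as_donor"},
#'   \code{"as_break"}.
#' @return data.frame with one row per segment: \code{line_id},
#'   \code{chromosome}, \code{first_donor_marker}, \code{last_donor_marker},
#'   \code{left_flank}, \code{right_flank} (marker id or
#'   \code{"CHROM_BOUNDARY"}), \code{n_donor_markers}, \code{l_min_kb},
#'   \code{l_max_kb}, \code{l_est_kb}, \code{int_start_kb},
#'   \code{int_end_kb}. A line with no donor call contributes no rows.
#' @export
infer_segments <- function(geno, map,
                           het_policy = c("error", "as_donor", "as_break")) {
  het_policy <- match.arg(het_policy)
  if (het_policy == "error") {
    n_het <- rowSums(geno == GENO_CALLS[["HETEROZYGOUS"]])
    if (any(n_het > 0))
      stop_sslmap("heterozygous call(s) under het_policy='error' in line(s): ",
                  paste0(rownames(geno)[n_het > 0], " (", n_het[n_het > 0],
                         " markers)", collapse = ", "),
                  class = "sslmap_het_error")
  }

  out <- vector("list", nrow(geno) * length(unique(map$chromosome)))
  k <- 0L
  for (line in rownames(geno)) {
    for (chr in unique(map$chromosome)) {
      sub <- map[map$chromosome == chr, , drop = FALSE]
      calls <- geno[line, sub$marker_id]
      if (het_policy == "as_donor")
        calls[calls == GENO_CALLS[["HETEROZYGOUS"]]] <- GENO_CALLS[["DONOR"]]
      if (het_policy == "as_break")
        calls[calls == GENO_CALLS[["HETEROZYGOUS"]]] <- GENO_CALLS[["RECIPIENT"]]
      runs <- .donor_runs(calls)
      ext <- chrom_extent(map, chr)
      for (r in runs) {
        first_i <- r[1]; last_i <- r[2]
        # nearest non-missing, non-donor (hence recipient) marker outside run
        before <- seq_len(first_i - 1L)
        after <- if (last_i < nrow(sub)) (last_i + 1L):nrow(sub) else integer()
        li <- before[calls[before] == GENO_CALLS[["RECIPIENT"]]]
        ri <- after[calls[after] == GENO_CALLS[["RECIPIENT"]]]
        left_flank <- if (length(li)) sub$marker_id[max(li)] else "CHROM_BOUNDARY"
        right_flank <- if (length(ri)) sub$marker_id[min(ri)] else "CHROM_BOUNDARY"
        fl <- if (length(li)) sub$position_kb[max(li)] else ext[["start_kb"]]
        fr <- if (length(ri)) sub$position_kb[min(ri)] else ext[["end_kb"]]
        len <- segment_lengths(sub$position_kb[first_i], sub$position_kb[last_i], fl, fr)
        int <- estimated_interval(sub$position_kb[first_i], sub$position_kb[last_i], fl, fr)
        k <- k + 1L
        out[[k]] <- data.frame(
          line_id = line, chromosome = chr,
          first_donor_marker = sub$marker_id[first_i],
          last_donor_marker = sub$marker_id[last_i],
          left_flank = left_flank, right_flank = right_flank,
          n_donor_markers = sum(calls[first_i:last_i] == GENO_CALLS[["DONOR"]]),
          l_min_kb = len[["l_min"]], l_max_kb = len[["l_max"]],
          l_est_kb = len[["l_est"]],
          int_start_kb = int[["start"]], int_end_kb = int[["end"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L)
    return(data.frame(line_id = character(), chromosome = character(),
                      first_donor_marker = character(),
                      last_donor_marker = character(),
                      left_flank = character(), right_flank = character(),
                      n_donor_markers = integer(), l_min_kb = numeric(),
                      l_max_kb = numeric(), l_est_kb = numeric(),
                      int_start_kb = numeric(), int_end_kb = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

# maximal donor runs in a call vector; missing bridged inside, not at edges.
# returns list of c(first_index, last_index)
.donor_runs <- function(calls) {
  informative <- which(calls != GENO_CALLS[["MISSING"]])
  donor <- calls[informative] == GENO_CALLS[["DONOR"]]
  if (!any(donor)) return(list())
  runs <- list()
  i <- 1L
  while (i <= length(informative)) {
    if (donor[i]) {
      j <- i
      while (j < length(informative) && donor[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(informative[i], informative[j])
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

#' Check that a line is a single-segment substitution line
#'
#' An SSSL carries exactly one donor segment on exactly one chromosome; any
#' other configuration fails QC.
#'
#' @param line_id line to check.
#' @param segments output of [infer_segments()].
#' @param line_ids optional vector of all genotyped line ids; when given,
#'   asking about a line outside it is an error (rather than a zero-segment
#'   verdict).
#' @return list with \code{line_id}, \code{pass} (logical) and
#'   \code{n_segments}.
#' @export
verify_single_segment <- function(line_id, segments, line_ids = NULL) {
  if (!is.null(line_ids) && !(line_id %in% line_ids))
    stop_sslmap("unknown line: ", line_id, class = "sslmap_lookup_error")
  n <- sum(segments$line_id == line_id)
  list(line_id = line_id, pass = n == 1L, n_segments = n)
}

#' Write a segments report to TSV
#'
#' Lengths and interval bounds are rounded to 0.1 kb (halves away from
#' zero) for reporting.
#'
#' @param segments output of [infer_segments()].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_segments <- function(segments, path) {
  seg <- segments
  for (col in c("l_min_kb", "l_max_kb", "l_est_kb", "int_start_kb", "int_end_kb"))
    seg[[col]] <- round_kb(seg[[col]])
  utils::write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert kb intervals to BED6
#'
#' Positions in kb are 1-based and closed; BED is 0-based, half-open, in bp.
#' A kb coordinate maps to bp by multiplying by 1000; the start is floored
#' and shifted to 0-based, the end is ceiled, so the bp interval always
#' covers the kb interval.
#'
#' @param chromosome,start_kb,end_kb vectors describing the intervals.
#' @param name BED name column.
#' @return data.frame in BED6 column order.
#' @export
intervals_to_bed <- function(chromosome, start_kb, end_kb, name) {
  data.frame(chrom = as.character(chromosome),
             chromStart = floor(start_kb * 1000 + 1e-6) - 1,
             chromEnd = ceiling(end_kb * 1000 - 1e-6),
             name = as.character(name), score = 0L, strand = ".",
             stringsAsFactors = FALSE)
}

#' Write intervals as a BED6 file
#' @param bed data.frame from [intervals_to_bed()].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
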