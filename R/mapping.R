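#' Screen lines for elevated SER against the recurrent parent
#'
#' Runs [lsd_vs_control()] on per-panicle SER values and flags lines whose
#' SER exceeds the control's. Under \code{"every_season"} (the default) a
#' line must exceed the control at \code{p <= alpha} in every season
#' separately; \code{"pooled"} runs one comparison over all seasons pooled
#' (for small designs).
#'
#' @param pheno long phenotype data.frame (per-panicle rows) with
#'   \code{line_id}, \code{season_id}, \code{ser_percent} (or counts, see
#'   [add_ser()]).
#' @param control_id recurrent-parent line id; must be phenotyped in every
#'   season.
#' @param alpha per-season significance threshold (default 0.001).
#' @param mode \code{"every_season"} or \code{"pooled"}.
#' @return data.frame \code{line_id, mean_diff, max_p, pooled_p, detected},
#'   one row per non-control line. \code{max_p} is the largest per-season
#'   comparison p (the deciding one under \code{"every_season"}).
#' @export
detect_qtl_lines <- function(pheno, control_id, alpha = 0.001,
                             mode = c("every_season", "pooled")) {
  mode <- match.arg(mode)
  assert_prob(alpha, "alpha")
  pheno <- add_ser(pheno)
  if (!control_id %in% pheno$line_id)
    stop_sslmap("control line '", control_id, "' absent from phenotypes",
                class = "sslmap_config_error")
  seasons <- sort(unique(pheno$season_id))
  split_groups <- function(d) split(d$ser_percent, d$line_id)

  pooled <- lsd_vs_control(split_groups(pheno), control_id, alpha)
  ids <- pooled$line_id
  res <- data.frame(line_id = ids, mean_diff = pooled$diff,
                    max_p = NA_real_, pooled_p = pooled$p,
                    detected = NA, stringsAsFactors = FALSE)

  if (mode == "pooled") {
    res$max_p <- pooled$p
    res$detected <- pooled$p <= alpha & pooled$diff > 0
    return(res)
  }
  per_season <- lapply(seasons, function(s) {
    d <- pheno[pheno$season_id == s, , drop = FALSE]
    if (!control_id %in% d$line_id)
      stop_sslmap("control line missing in season ", s,
                  class = "sslmap_config_error")
    lsd_vs_control(split_groups(d), control_id, alpha)
  })
  for (i in seq_along(ids)) {
    rows <- lapply(per_season, function(cmp) cmp[cmp$line_id == ids[i], ])
    present <- vapply(rows, nrow, integer(1)) == 1L
    ps <- vapply(rows[present], function(r) r$p, numeric(1))
    up <- vapply(rows[present], function(r) r$diff > 0, logical(1))
    res$max_p[i] <- if (length(ps)) max(ps) else NA_real_
    res$detected[i] <- all(present) && all(up) && all(ps <= alpha)
  }
  res
}

#' Cluster significant lines' segments into QTL calls
#'
#' Segments of significant lines on the same chromosome are clustered by
#' overlap of their estimated intervals (transitive closure). Each cluster
#' yields one QTL whose interval is the intersection of its members'
#' estimated intervals — for nested segments this is the shortest member's
#' interval, the classical substitution-mapping rule. If a staggered chain
#' has an empty pairwise intersection the call falls back to the shortest
#' member's interval and is flagged.
#'
#' @param segments [infer_segments()] rows of the significant lines only;
#'   each line must have exactly one segment.
#' @param comparisons optional [detect_qtl_lines()] output; supplies each
#'   call's p-value as the minimum \code{pooled_p} among supporting lines.
#' @return data.frame \code{chromosome, int_start_kb, int_end_kb,
#'   est_length_kb, max_length_kb, p_value, supporting_lines, flag}.
#' @export
assign_qtls <- function(segments, comparisons = NULL) {
  if (!nrow(segments))
    return(data.frame(chromosome = character(), int_start_kb = numeric(),
                      int_end_kb = numeric(), est_length_kb = numeric(),
                      max_length_kb = numeric(), p_value = numeric(),
                      supporting_lines = character(), flag = character(),
                      stringsAsFactors = FALSE))
  multi <- names(which(table(segments$line_id) > 1L))
  if (length(multi))
    stop_sslmap("line(s) with multiple segments (not SSSLs): ",
                paste(multi, collapse = ", "), class = "sslmap_qc_error")
  out <- lapply(unique(segments$chromosome), function(chr) {
    seg <- segments[segments$chromosome == chr, , drop = FALSE]
    seg <- seg[order(seg$int_start_kb, seg$line_id), , drop = FALSE]
    run_max_end <- cummax(seg$int_end_kb)
    new_cluster <- c(TRUE, seg$int_start_kb[-1] > run_max_end[-nrow(seg)])
    cl <- cumsum(new_cluster)
    do.call(rbind, lapply(split(seg, cl), function(mem) {
      lo <- max(mem$int_start_kb); hi <- min(mem$int_end_kb)
      flag <- ""
      if (lo > hi) {
        warning("empty interval intersection on chromosome ", chr,
                " (lines ", paste(mem$line_id, collapse = ", "),
                "); falling back to shortest member segment")
        best <- which.min(mem$l_est_kb)
        lo <- mem$int_start_kb[best]; hi <- mem$int_end_kb[best]
        flag <- "empty_intersection_fallback"
      }
      p <- NA_real_
      if (!is.null(comparisons)) {
        ps <- comparisons$pooled_p[comparisons$line_id %in% mem$line_id]
        if (length(ps)) p <- min(ps)
      }
      data.frame(chromosome = chr, int_start_kb = lo, int_end_kb = hi,
                 est_length_kb = hi - lo, max_length_kb = min(mem$l_max_kb),
                 p_value = p,
                 supporting_lines = paste(sort(mem$line_id), collapse = ","),
                 flag = flag, stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Name QTL calls
#'
#' Standard rice QTL nomenclature: \code{q<TRAIT>-<chromosome>}, with
#' lower-case letter suffixes a, b, c, ... in ascending interval-start order
#' when one chromosome hosts several QTLs (ties broken by supporting-line
#' ids).
#'
#' @param calls [assign_qtls()] output.
#' @param trait trait tag, default \code{"SER"}.
#' @return \code{calls} with a \code{name} column first.
#' @export
name_qtls <- function(calls, trait = "SER") {
  if (!nrow(calls)) {
    calls$name <- character(0)
    return(calls[c("name", setdiff(names(calls), "name"))])
  }
  calls <- calls[order(calls$chromosome, calls$int_start_kb,
                       calls$supporting_lines), , drop = FALSE]
  calls$name <- NA_character_
  for (chr in unique(calls$chromosome)) {
    i <- which(calls$chromosome == chr)
    base <- paste0("q", trait, "-", chr)
    calls$name[i] <- if (length(i) == 1L) base else
      paste0(base, letters[seq_along(i)])
  }
  rownames(calls) <- NULL
  calls[c("name", setdiff(names(calls), "name"))]
}

#' Classify secondary lines as carrying or lacking the QTL
#'
#' Secondary recombinant lines are classified from a Duncan compact letter
#' display containing the recipient control and the parent SSSL: a line
#' sharing a letter with the control but not the parent is \code{LOW}
#' (recipient-like, QTL absent); sharing with the parent but not the control
#' is \code{HIGH} (parent-like, QTL present); anything else is
#' \code{UNCLASSIFIED} and excluded from mapping. The control and the
#' parent must not share a letter, otherwise there is no contrast to map
#' against.
#'
#' @param letters_df [duncan_groups()] output including control and parent.
#' @param control_id recipient line id.
#' @param parent_id parent SSSL line id.
#' @return data.frame \code{line_id, class} for every other line.
#' @export
classify_secondary_lines <- function(letters_df, control_id, parent_id) {
  lt <- function(id) {
    i <- match(id, letters_df$line_id)
    if (is.na(i)) stop_sslmap("line '", id, "' absent from letter display",
                              class = "sslmap_lookup_error")
    strsplit(letters_df$letters[i], "")[[1]]
  }
  shares <- function(a, b) length(intersect(a, b)) > 0L
  ctrl <- lt(control_id); par <- lt(parent_id)
  if (shares(ctrl, par))
    stop_sslmap("control and parent share a Duncan letter: ",
                "no contrast, secondary mapping impossible",
                class = "sslmap_no_contrast_error")
  ids <- setdiff(letters_df$line_id, c(control_id, parent_id))
  cls <- vapply(ids, function(id) {
    l <- lt(id)
    low <- shares(l, ctrl); high <- shares(l, par)
    if (low && !high) "LOW" else if (high && !low) "HIGH" else "UNCLASSIFIED"
  }, character(1))
  data.frame(line_id = ids, class = unname(cls), stringsAsFactors = FALSE)
}

#' Delimit a QTL interval by secondary substitution mapping
#'
#' Within the parent SSSL's donor run, the QTL must sit at a marker that is
#' donor in every HIGH (parent-like) secondary line and not donor in any
#' LOW (recipient-like) line. The delimited interval is the estimated
#' interval of the run of such candidate markers, flanked by the nearest
#' excluded markers (or the parent's own flanks at the run ends).
#'
#' Heterozygous calls in secondary lines are counted as donor material: a
#' HIGH line needs homozygous donor evidence (\code{D}) for a marker to stay
#' candidate, while any donor dose (\code{D} or \code{H}) in a LOW line
#' excludes the marker. Missing calls neither confirm nor exclude.
#'
#' @param classes [classify_secondary_lines()] output (UNCLASSIFIED lines
#'   are dropped with a message).
#' @param geno [genotype_table()] holding the secondary lines.
#' @param map a [marker_map()].
#' @param parent_segment the parent SSSL's row from [infer_segments()].
#' @return list with \code{first_marker}, \code{last_marker},
#'   \code{left_flank}, \code{right_flank}, \code{l_min_kb},
#'   \code{l_max_kb}, \code{l_est_kb}, \code{int_start_kb},
#'   \code{int_end_kb}, \code{candidate_markers}, \code{n_high},
#'   \code{n_low}, \code{excluded_lines}.
#' @export
secondary_mapping <- function(classes, geno, map, parent_segment) {
  excluded <- classes$line_id[classes$class == "UNCLASSIFIED"]
  if (length(excluded))
    message("excluding UNCLASSIFIED secondary line(s): ",
            paste(excluded, collapse = ", "))
  high <- classes$line_id[classes$class == "HIGH"]
  low <- classes$line_id[classes$class == "LOW"]
  if (!length(high))
    stop_sslmap("no HIGH secondary line: cannot place the QTL",
                class = "sslmap_inconsistency_error")

  chr <- parent_segment$chromosome
  sub <- map[map$chromosome == chr, , drop = FALSE]
  run_i <- which(sub$position_kb >=
                   sub$position_kb[sub$marker_id == parent_segment$first_donor_marker] &
                 sub$position_kb <=
                   sub$position_kb[sub$marker_id == parent_segment$last_donor_marker])
  if (!length(run_i))
    stop_sslmap("parent segment markers not found on chromosome ", chr,
                class = "sslmap_lookup_error")
  run_markers <- sub$marker_id[run_i]

  is_cand <- vapply(run_markers, function(m) {
    hc <- geno[high, m]
    lc <- if (length(low)) geno[low, m] else character()
    all(hc == GENO_CALLS[["DONOR"]]) &&
      !any(lc %in% c(GENO_CALLS[["DONOR"]], GENO_CALLS[["HETEROZYGOUS"]]))
  }, logical(1))
  if (!any(is_cand))
    stop_sslmap("no single-QTL placement explains the line classes",
                class = "sslmap_inconsistency_error")

  cand_i <- run_i[is_cand]
  first_i <- min(cand_i); last_i <- max(cand_i)
  ext <- chrom_extent(map, chr)
  left_flank <- if (first_i > 1L) sub$marker_id[first_i - 1L] else
    parent_segment$left_flank
  right_flank <- if (last_i < nrow(sub)) sub$marker_id[last_i + 1L] else
    parent_segment$right_flank
  fl <- if (first_i > 1L) sub$position_kb[first_i - 1L] else ext[["start_kb"]]
  fr <- if (last_i < nrow(sub)) sub$position_kb[last_i + 1L] else ext[["end_kb"]]
  len <- segment_lengths(sub$position_kb[first_i], sub$position_kb[last_i], fl, fr)
  int <- estimated_interval(sub$position_kb[first_i], sub$position_kb[last_i], fl, fr)
  if (int[["start"]] < parent_segment$int_start_kb - 1e-9 ||
      int[["end"]] > parent_segment$int_end_kb + 1e-9)
    stop_sslmap("delimited interval escapes the parent interval",
                class = "sslmap_inconsistency_error")
  list(first_marker = sub$marker_id[first_i], last_marker = sub$marker_id[last_i],
       left_flank = left_flank, right_flank = right_flank,
       l_min_kb = len[["l_min"]], l_max_kb = len[["l_max"]],
       l_est_kb = len[["l_est"]],
       int_start_kb = int[["start"]], int_end_kb = int[["end"]],
       candidate_markers = sub$marker_id[cand_i],
       n_high = length(high), n_low = length(low),
       excluded_lines = excluded)
}
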