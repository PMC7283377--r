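# Small in-code fixtures and the independent brute-force fine-mapping oracle.

# 1-chromosome map with m markers at the given positions
tiny_map <- function(positions, chr = "1", ids = NULL) {
  ids <- ids %||% sprintf("M%d", seq_along(positions))
  marker_map(ids, rep(chr, length(positions)), positions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype matrix from per-line call strings, e.g. "RDDR"
geno_from_strings <- function(calls, map, line_ids = NULL) {
  line_ids <- line_ids %||% sprintf("L%d", seq_along(calls))
  m <- do.call(rbind, lapply(calls, function(s) strsplit(s, "")[[1]]))
  dimnames(m) <- list(line_ids, map$marker_id)
  genotype_table(m, map)
}

# Brute-force secondary-mapping oracle: tries every marker of the parent run
# as the putative QTL position and keeps those consistent with every line
# class (donor in all HIGH, no donor dose in any LOW). Independent of the
# candidate-set code path in secondary_mapping().
oracle_secondary <- function(classes, geno, map, parent_segment) {
  sub <- map[map$chromosome == parent_segment$chromosome, , drop = FALSE]
  i0 <- match(parent_segment$first_donor_marker, sub$marker_id)
  i1 <- match(parent_segment$last_donor_marker, sub$marker_id)
  high <- classes$line_id[classes$class == "HIGH"]
  low <- classes$line_id[classes$class == "LOW"]
  if (!length(high)) return(NULL)
  ok <- integer()
  for (i in i0:i1) {
    m <- sub$marker_id[i]
    consistent <- TRUE
    for (h in high) if (geno[h, m] != "D") consistent <- FALSE
    for (l in low) if (geno[l, m] %in% c("D", "H")) consistent <- FALSE
    if (consistent) ok <- c(ok, i)
  }
  if (!length(ok)) return(NULL)
  fi <- min(ok); la <- max(ok)
  ext <- chrom_extent(map, parent_segment$chromosome)
  fl <- if (fi > 1) sub$position_kb[fi - 1] else ext[["start_kb"]]
  fr <- if (la < nrow(sub)) sub$position_kb[la + 1] else ext[["end_kb"]]
  list(markers = sub$marker_id[ok],
       int_start = (fl + sub$position_kb[fi]) / 2,
       int_end = (sub$position_kb[la] + fr) / 2)
}

# random secondary-mapping configuration on a fresh small map; returns the
# pieces both the implementation and the oracle need
random_secondary_config <- function(n_markers = 12, n_lines = 6) {
  pos <- sort(sample(seq(100, 20000, by = 50), n_markers))
  map <- tiny_map(pos)
  parent_calls <- paste(rep("D", n_markers), collapse = "")
  parent <- geno_from_strings(parent_calls, map, "PARENT")
  parent_seg <- infer_segments(parent, map)
  qtl_i <- sample(seq_len(n_markers), 1)
  runs <- replicate(n_lines, sort(sample(seq_len(n_markers), 2)),
                    simplify = FALSE)
  calls <- vapply(runs, function(r) {
    v <- rep("R", n_markers); v[r[1]:r[2]] <- "D"
    paste(v, collapse = "")
  }, character(1))
  geno <- geno_from_strings(calls, map, sprintf("SEC%02d", seq_len(n_lines)))
  classes <- data.frame(
    line_id = rownames(geno),
    class = ifelse(vapply(runs, function(r) r[1] <= qtl_i & qtl_i <= r[2],
                          logical(1)), "HIGH", "LOW"),
    stringsAsFactors = FALSE)
  list(map = map, geno = geno, classes = classes,
       parent_segment = parent_seg[1, ], qtl_marker = map$marker_id[qtl_i])
}
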