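make_pheno <- function(line_means, seasons = paste0("S", 1:3), n = 8, sd = 2,
                       seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(line_means), function(id)
    do.call(rbind, lapply(seasons, function(s)
      data.frame(line_id = id, season_id = s,
                 unit_id = sprintf("P%02d", seq_len(n)),
                 ser_percent = pmin(100, pmax(0, rnorm(n, line_means[[id]], sd))),
                 stringsAsFactors = FALSE)))))
}

test_that("line screen detects a large planted effect in every season", {
  ph <- make_pheno(c(HJX74 = 30, carrier = 55, null = 30))
  cmp <- detect_qtl_lines(ph, "HJX74", alpha = 0.001)
  expect_true(cmp$detected[cmp$line_id == "carrier"])
  expect_false(cmp$detected[cmp$line_id == "null"])
  # pooled mode agrees here
  cmp2 <- detect_qtl_lines(ph, "HJX74", alpha = 0.001, mode = "pooled")
  expect_true(cmp2$detected[cmp2$line_id == "carrier"])
  expect_error(detect_qtl_lines(ph, "nope"), class = "sslmap_config_error")
})

test_that("a line identical to the control is never detected", {
  ph <- make_pheno(c(HJX74 = 30, twin = 30), sd = 0.5)
  ph$ser_percent[ph$line_id == "twin"] <-
    ph$ser_percent[ph$line_id == "HJX74"]
  cmp <- detect_qtl_lines(ph, "HJX74")
  expect_false(cmp$detected)
})

test_that("nested segments collapse to one QTL with the shortest interval", {
  mm <- tiny_map(seq(100, 1500, by = 100))
  g <- geno_from_strings(c("RRRRRRDDDRRRRRR",
                           "RRRRRDDDDDRRRRR",
                           "RRRRDDDDDDDRRRR"), mm, c("s22", "s23", "s25"))
  seg <- infer_segments(g, mm)
  calls <- assign_qtls(seg)
  expect_equal(nrow(calls), 1L)
  inner <- seg[seg$line_id == "s22", ]
  expect_equal(calls$int_start_kb, inner$int_start_kb)
  expect_equal(calls$int_end_kb, inner$int_end_kb)
  expect_equal(calls$max_length_kb, min(seg$l_max_kb))
  expect_equal(calls$supporting_lines, "s22,s23,s25")
})

test_that("disjoint segments on one chromosome yield distinct QTLs", {
  mm <- tiny_map(seq(100, 1500, by = 100))
  g <- geno_from_strings(c("RDDRRRRRRRRRRRR",
                           "RRRRRRRRRRRDDRR"), mm, c("left", "right"))
  calls <- assign_qtls(infer_segments(g, mm))
  expect_equal(nrow(calls), 2L)
  named <- name_qtls(calls)
  expect_equal(named$name, c("qSER-1a", "qSER-1b"))
})

test_that("a single significant line yields its own interval as the QTL", {
  mm <- tiny_map(seq(100, 600, by = 100))
  seg <- infer_segments(geno_from_strings("RDDRRR", mm, "solo"), mm)
  calls <- name_qtls(assign_qtls(seg))
  expect_equal(calls$name, "qSER-1")
  expect_equal(calls$int_start_kb, seg$int_start_kb)
})

test_that("staggered overlap with empty intersection falls back, flagged", {
  # a-b overlap, b-c overlap, but a and c are disjoint
  mm <- tiny_map(seq(100, 1200, by = 100))
  g <- geno_from_strings(c("DDDDRRRRRRRR",
                           "RRRDDDDDDRRR",
                           "RRRRRRRRDDDD"), mm, c("a", "b", "c"))
  seg <- infer_segments(g, mm)
  expect_warning(calls <- assign_qtls(seg), "empty")
  expect_equal(calls$flag, "empty_intersection_fallback")
  shortest <- seg[which.min(seg$l_est_kb), ]
  expect_equal(calls$int_start_kb, shortest$int_start_kb)
})

test_that("QTL naming follows chromosome and position order", {
  calls <- data.frame(
    chromosome = c("5", "1", "1", "1"),
    int_start_kb = c(100, 900, 100, 500), int_end_kb = c(200, 950, 150, 520),
    est_length_kb = 1, max_length_kb = 1, p_value = NA,
    supporting_lines = c("w", "x", "y", "z"), flag = "",
    stringsAsFactors = FALSE)
  named <- name_qtls(calls)
  expect_equal(named$name[named$supporting_lines == "y"], "qSER-1a")
  expect_equal(named$name[named$supporting_lines == "z"], "qSER-1b")
  expect_equal(named$name[named$supporting_lines == "x"], "qSER-1c")
  expect_equal(named$name[named$supporting_lines == "w"], "qSER-5")
})

test_that("QTL intervals never overlap within a chromosome", {
  set.seed(8)
  for (rep in 1:20) {
    mm <- tiny_map(seq(100, 3000, by = 100))
    n <- sample(2:6, 1)
    calls <- vapply(seq_len(n), function(i) {
      r <- sort(sample(2:29, 2))
      paste(ifelse(seq_len(30) %in% r[1]:r[2], "D", "R"), collapse = "")
    }, character(1))
    seg <- infer_segments(geno_from_strings(calls, mm), mm)
    qt <- suppressWarnings(assign_qtls(seg))
    if (nrow(qt) > 1) {
      qt <- qt[order(qt$int_start_kb), ]
      expect_true(all(qt$int_start_kb[-1] > qt$int_end_kb[-nrow(qt)]))
    }
  }
})

test_that("secondary lines classify from Duncan letters against the contrast", {
  letters_df <- data.frame(
    line_id = c("parent", "h1", "amb", "l1", "HJX74"),
    mean = c(50, 49, 40, 31, 30),
    n = 5, letters = c("b", "b", "ab", "a", "a"), stringsAsFactors = FALSE)
  cls <- classify_secondary_lines(letters_df, "HJX74", "parent")
  expect_equal(cls$class[cls$line_id == "h1"], "HIGH")
  expect_equal(cls$class[cls$line_id == "l1"], "LOW")
  expect_equal(cls$class[cls$line_id == "amb"], "UNCLASSIFIED")

  letters_df$letters <- "a"
  expect_error(classify_secondary_lines(letters_df, "HJX74", "parent"),
               class = "sslmap_no_contrast_error")
})

test_that("secondary mapping delimits the run shared by HIGH, absent in LOW", {
  mm <- tiny_map(seq(100, 1000, by = 100)) # M1..M10
  parent <- geno_from_strings(paste(rep("D", 10), collapse = ""), mm, "P")
  pseg <- infer_segments(parent, mm)[1, ]
  sec <- geno_from_strings(c("RRRDDDDRRR",  # HIGH covers M4-M7
                             "DDDRRRRRRR",  # LOW covers M1-M3
                             "RRRRRRRDDD"), # LOW covers M8-M10
                           mm, c("h1", "lo1", "lo2"))
  cls <- data.frame(line_id = c("h1", "lo1", "lo2"),
                    class = c("HIGH", "LOW", "LOW"), stringsAsFactors = FALSE)
  res <- secondary_mapping(cls, sec, mm, pseg)
  expect_equal(res$first_marker, "M4")
  expect_equal(res$last_marker, "M7")
  expect_equal(res$left_flank, "M3")
  expect_equal(res$right_flank, "M8")
  expect_equal(res$candidate_markers, paste0("M", 4:7))
  # contained in the parent interval
  expect_gte(res$int_start_kb, pseg$int_start_kb)
  expect_lte(res$int_end_kb, pseg$int_end_kb)

  # no LOW lines: the delimited run is the HIGH intersection
  res2 <- secondary_mapping(cls[1, , drop = FALSE], sec, mm, pseg)
  expect_equal(c(res2$first_marker, res2$last_marker), c("M4", "M7"))

  # LOW covering everything HIGH shares -> inconsistency
  cls3 <- data.frame(line_id = c("h1", "lo3"), class = c("HIGH", "LOW"),
                     stringsAsFactors = FALSE)
  sec3 <- geno_from_strings(c("RRRDDDDRRR", "RDDDDDDDDR"), mm, c("h1", "lo3"))
  expect_error(secondary_mapping(cls3, sec3, mm, pseg),
               class = "sslmap_inconsistency_error")
})

test_that("secondary mapping agrees with the per-marker placement oracle", {
  set.seed(9)
  for (rep in 1:100) {
    cfg <- random_secondary_config()
    ora <- oracle_secondary(cfg$classes, cfg$geno, cfg$map, cfg$parent_segment)
    if (is.null(ora)) {
      expect_error(secondary_mapping(cfg$classes, cfg$geno, cfg$map,
                                     cfg$parent_segment),
                   class = "sslmap_inconsistency_error")
    } else {
      res <- secondary_mapping(cfg$classes, cfg$geno, cfg$map,
                               cfg$parent_segment)
      expect_equal(range(match(res$candidate_markers, cfg$map$marker_id)),
                   range(match(ora$markers, cfg$map$marker_id)))
      expect_equal(res$int_start_kb, ora$int_start)
      expect_equal(res$int_end_kb, ora$int_end)
      # the true QTL marker is always among the candidates
      expect_true(cfg$qtl_marker %in% ora$markers)
    }
  }
})
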