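test_that("marker map enforces uniqueness, ordering and extent coverage", {
  expect_error(marker_map(c("A", "A"), c("1", "1"), c(1, 2)), "duplicate")
  expect_error(marker_map(c("A", "B"), c("1", "1"), c(5, 5)),
               "strictly increasing")
  expect_error(marker_map("A", "1", -1), ">= 0")
  mm <- marker_map(c("B", "A"), c("1", "1"), c(200, 100))
  expect_equal(mm$marker_id, c("A", "B")) # sorted by position
  expect_equal(unname(chrom_extent(mm, "1")), c(0, 200))
  expect_error(marker_map("A", "1", 100,
                          chrom_extent = data.frame(chromosome = "1",
                                                    start_kb = 0, end_kb = 50)),
               "does not span")
})

test_that("genotype table validation catches bad symbols and empty lines", {
  mm <- tiny_map(c(50, 100))
  m <- matrix(c("R", "X"), 1, 2, dimnames = list("L1", mm$marker_id))
  expect_error(genotype_table(m, mm), "unknown genotype symbol 'X'")
  m2 <- matrix("-", 1, 2, dimnames = list("L1", mm$marker_id))
  expect_error(genotype_table(m2, mm), "no non-missing call")
  m3 <- matrix("R", 1, 2, dimnames = list("L1", c("M1", "ZZ")))
  expect_error(genotype_table(m3, mm), "absent from map")
})

test_that("segment length arithmetic follows the L_min/L_max/L_est rule", {
  expect_equal(unname(segment_lengths(100, 200, 50, 260)), c(100, 210, 155))
  # a single-marker run has zero minimum length
  expect_equal(unname(segment_lengths(100, 100, 50, 260)), c(0, 210, 105))
  # published worked case: L_max 718.7 with L_min 385.1 gives L_est 551.9
  expect_equal(segment_lengths(0, 385.1, -166.8, 551.9)[["l_est"]], 551.9)
  expect_error(segment_lengths(200, 100, 50, 260), "unordered")
})

test_that("estimated interval is the mid-flank interval with width L_est", {
  expect_equal(unname(estimated_interval(100, 200, 50, 260)), c(75, 230))
  int <- estimated_interval(100, 200, 50, 260)
  len <- segment_lengths(100, 200, 50, 260)
  expect_equal(int[["end"]] - int[["start"]], len[["l_est"]])
  # run starting at the first marker: boundary flank at chromosome start 0
  expect_equal(estimated_interval(120, 200, 0, 300)[["start"]], 60)
})

test_that("infer_segments finds donor runs, flanks, bridges missing calls", {
  mm <- tiny_map(c(50, 100, 200, 260))
  g <- geno_from_strings("RDDR", mm)
  seg <- infer_segments(g, mm)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$first_donor_marker, "M2")
  expect_equal(seg$last_donor_marker, "M3")
  expect_equal(seg$left_flank, "M1")
  expect_equal(seg$right_flank, "M4")
  expect_equal(seg$l_est_kb, 155)

  # all-recipient line yields no segment
  expect_equal(nrow(infer_segments(geno_from_strings("RRRR", mm), mm)), 0L)

  # missing bridged inside a run, not extended at edges
  mm6 <- tiny_map(c(10, 20, 30, 40, 50, 60))
  seg2 <- infer_segments(geno_from_strings("RD-DR-", mm6), mm6)
  expect_equal(nrow(seg2), 1L)
  expect_equal(c(seg2$first_donor_marker, seg2$last_donor_marker), c("M2", "M4"))
  # an edge-missing marker leaves the flank at the nearest recipient call
  seg3 <- infer_segments(geno_from_strings("R-DDR-", mm6), mm6)
  expect_equal(seg3$left_flank, "M1")
  expect_equal(seg3$first_donor_marker, "M3")

  # recipient call splits runs
  seg4 <- infer_segments(geno_from_strings("DRDDRD", mm6), mm6)
  expect_equal(nrow(seg4), 3L)

  # telomeric run: boundary flank uses the chromosome extent
  seg5 <- infer_segments(geno_from_strings("DDRRRR", mm6), mm6)
  expect_equal(seg5$left_flank, "CHROM_BOUNDARY")
  expect_equal(seg5$int_start_kb, (0 + 10) / 2)
})

test_that("a two-marker donor run mirrors the shortest published segment", {
  # line genotyped donor exactly between two named markers, recipient elsewhere
  mm <- marker_map(c("RM1", "RM403", "RM6648", "RM2"), rep("1", 4),
                   c(29000, 29800, 32000, 32500))
  g <- geno_from_strings("RDDR", mm, "SG22")
  seg <- infer_segments(g, mm)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$first_donor_marker, "RM403")
  expect_equal(seg$last_donor_marker, "RM6648")
})

test_that("heterozygous handling follows the policy", {
  mm <- tiny_map(c(10, 20, 30, 40))
  g <- geno_from_strings("RDHR", mm)
  expect_error(infer_segments(g, mm), class = "sslmap_het_error")
  as_d <- infer_segments(g, mm, het_policy = "as_donor")
  expect_equal(as_d$last_donor_marker, "M3")
  as_b <- infer_segments(g, mm, het_policy = "as_break")
  expect_equal(as_b$last_donor_marker, "M2")
  expect_equal(as_b$right_flank, "M3")
})

test_that("segment invariants hold and marker order does not matter", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(6:15, 1)
    pos <- sort(sample(seq(10, 5000, 10), n))
    mm <- tiny_map(pos)
    calls <- paste(sample(c("R", "D", "-"), n, replace = TRUE,
                          prob = c(0.5, 0.4, 0.1)), collapse = "")
    if (!grepl("D", calls)) calls <- sub("R", "D", calls)
    g <- geno_from_strings(calls, mm)
    seg <- infer_segments(g, mm)
    expect_true(all(seg$l_min_kb <= seg$l_est_kb + 1e-12))
    expect_true(all(seg$l_est_kb <= seg$l_max_kb + 1e-12))
    expect_equal(2 * seg$l_est_kb, seg$l_min_kb + seg$l_max_kb)
    expect_equal(seg$int_end_kb - seg$int_start_kb, seg$l_est_kb,
                 tolerance = 1e-9)
    # shuffled marker input resorts to the same map, hence same segments
    shuf <- sample(n)
    mm2 <- marker_map(mm$marker_id[shuf], mm$chromosome[shuf],
                      mm$position_kb[shuf])
    seg2 <- infer_segments(g[, mm2$marker_id, drop = FALSE], mm2)
    expect_equal(seg2, seg)
  }
})

test_that("verify_single_segment gives PASS/FAIL with counts", {
  mm <- tiny_map(c(10, 20, 30, 40, 50, 60))
  g <- geno_from_strings(c("RDDRRR", "DDRRDD", "RRRRRR"), mm,
                         c("ok", "double", "none"))
  seg <- infer_segments(g, mm)
  expect_true(verify_single_segment("ok", seg)$pass)
  v2 <- verify_single_segment("double", seg)
  expect_false(v2$pass); expect_equal(v2$n_segments, 2L)
  v0 <- verify_single_segment("none", seg, rownames(g))
  expect_false(v0$pass); expect_equal(v0$n_segments, 0L)
  expect_error(verify_single_segment("ghost", seg, rownames(g)),
               class = "sslmap_lookup_error")
})
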