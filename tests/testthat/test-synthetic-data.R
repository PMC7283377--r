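test_that("simulated marker maps are deterministic, bounded and valid", {
  cfg <- sim_config(seed = 11)
  m1 <- simulate_marker_map(cfg, seed = 11)
  m2 <- simulate_marker_map(cfg, seed = 11)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 12 * 60)
  expect_true(all(m1$position_kb <= 43000 & m1$position_kb >= 0))
  for (chr in unique(m1$chromosome))
    expect_true(all(diff(m1$position_kb[m1$chromosome == chr]) > 0))
  expect_error(simulate_marker_map(sim_config(markers_per_chromosome = 5000)),
               class = "sslmap_config_error")
})

test_that("every library line is a single-segment line and runs are recovered", {
  cfg <- sim_config(seed = 12, n_lines = 40)
  map <- simulate_marker_map(cfg, seed = 12)
  lib <- simulate_sssl_library(map, cfg)
  expect_equal(nrow(lib$geno), 40)
  seg <- infer_segments(lib$geno, map)
  expect_equal(nrow(seg), 40) # exactly one segment per line
  for (i in seq_len(nrow(lib$truth$lines))) {
    tr <- lib$truth$lines[i, ]
    s <- seg[seg$line_id == tr$line_id, ]
    expect_true(verify_single_segment(tr$line_id, seg)$pass)
    # inference recovers the planted donor run exactly
    expect_equal(s$first_donor_marker, tr$first_donor_marker)
    expect_equal(s$last_donor_marker, tr$last_donor_marker)
    expect_equal(s$chromosome, tr$chromosome)
  }
})

test_that("carrier segments flank their planted locus with donor markers", {
  cfg <- sim_config(seed = 13)
  map <- simulate_marker_map(cfg, seed = 13)
  lib <- simulate_sssl_library(map, cfg)
  carriers <- lib$truth$lines[!is.na(lib$truth$lines$carried_qtl), ]
  expect_equal(nrow(carriers), 9) # 7 QTLs, one with three nested carriers
  for (i in seq_len(nrow(carriers))) {
    tr <- carriers[i, ]
    p <- lib$truth$qtls$position_kb[lib$truth$qtls$qtl == tr$carried_qtl]
    first <- map$position_kb[map$marker_id == tr$first_donor_marker]
    last <- map$position_kb[map$marker_id == tr$last_donor_marker]
    expect_lte(first, p)
    expect_gte(last, p)
  }
  # exclusive carriers: no background line covers a planted locus
  bg <- lib$truth$lines[is.na(lib$truth$lines$carried_qtl), ]
  for (q in seq_len(nrow(lib$truth$qtls))) {
    qt <- lib$truth$qtls[q, ]
    covers <- bg$chromosome == qt$chromosome &
      bg$seg_start_kb <= qt$position_kb & bg$seg_end_kb >= qt$position_kb
    expect_false(any(covers))
  }
})

test_that("noise-free phenotypes hit the latent means exactly", {
  cfg <- sim_config(seed = 14, n_lines = 9, season_effects = c(0, 0),
                    interaction_sd = 0, residual_sd = 0, n_panicles = 3)
  map <- simulate_marker_map(cfg, seed = 14)
  lib <- simulate_sssl_library(map, cfg)
  ph <- simulate_phenotypes(lib$truth, cfg)
  agg <- aggregate_ser(ph)
  ctrl <- agg$ser_mean[agg$line_id == "HJX74"]
  expect_true(all(ctrl == 29.6))
  # a carrier with a = 11.9 sits exactly 2a above the control
  car <- lib$truth$lines$line_id[which(lib$truth$lines$carried_qtl == 1)][1]
  expect_true(all(agg$ser_mean[agg$line_id == car] == 29.6 + 2 * 11.9))
})

test_that("binomial counts average to the latent rate", {
  cfg <- sim_config(seed = 15, n_lines = 1, planted_qtls = list(),
                    season_effects = 0, interaction_sd = 0,
                    n_panicles = 10000, count_mode = "binomial")
  map <- simulate_marker_map(cfg, seed = 15)
  lib <- simulate_sssl_library(map, cfg)
  ph <- simulate_phenotypes(lib$truth, cfg)
  ctrl <- ph[ph$line_id == "HJX74", ]
  expect_true(all(c("n_spikelets", "n_sse", "n_dse") %in% names(ctrl)))
  expect_equal(mean(ctrl$ser_percent), 29.6, tolerance = 0.5)
  # SSE fraction of exserted spikelets near its configured value
  expect_equal(sum(ctrl$n_sse) / sum(ctrl$n_sse + ctrl$n_dse), 0.75,
               tolerance = 0.02)
})

test_that("secondary lines are sub-runs of the parent with both classes", {
  cfg <- sim_config(seed = 16)
  map <- simulate_marker_map(cfg, seed = 16)
  lib <- simulate_sssl_library(map, cfg)
  parent_tr <- lib$truth$lines[which(lib$truth$lines$carried_qtl == 4), ]
  pseg <- infer_segments(lib$geno[parent_tr$line_id, , drop = FALSE], map)
  p <- lib$truth$qtls$position_kb[4]
  sec <- simulate_secondary_lines(map, pseg[1, ], p, n_lines = 5, seed = 16)
  idx <- function(m) match(m, map$marker_id)
  for (i in 1:5) {
    expect_gte(idx(sec$truth$first_marker[i]), idx(pseg$first_donor_marker))
    expect_lte(idx(sec$truth$last_marker[i]), idx(pseg$last_donor_marker))
  }
  expect_true(any(sec$truth$carries))
  expect_true(any(!sec$truth$carries))
  # determinism
  sec2 <- simulate_secondary_lines(map, pseg[1, ], p, n_lines = 5, seed = 16)
  expect_identical(sec$truth, sec2$truth)
})

test_that("secondary mapping on noise-free classes brackets the true locus", {
  cfg <- sim_config(seed = 17)
  map <- simulate_marker_map(cfg, seed = 17)
  lib <- simulate_sssl_library(map, cfg)
  parent_tr <- lib$truth$lines[which(lib$truth$lines$carried_qtl == 5), ]
  pseg <- infer_segments(lib$geno[parent_tr$line_id, , drop = FALSE], map)[1, ]
  p <- lib$truth$qtls$position_kb[5]
  for (s in 1:10) {
    sec <- simulate_secondary_lines(map, pseg, p, n_lines = 6, seed = 100 + s)
    cls <- data.frame(line_id = sec$truth$line_id,
                      class = ifelse(sec$truth$carries, "HIGH", "LOW"),
                      stringsAsFactors = FALSE)
    res <- secondary_mapping(cls, sec$geno, map, pseg)
    qpos <- map$position_kb[map$marker_id == sec$qtl_marker]
    expect_gte(qpos, map$position_kb[map$marker_id == res$first_marker])
    expect_lte(qpos, map$position_kb[map$marker_id == res$last_marker])
    expect_gte(res$int_start_kb, pseg$int_start_kb - 1e-9)
    expect_lte(res$int_end_kb, pseg$int_end_kb + 1e-9)
  }
})

test_that("F2 simulation matches its parameterization", {
  f2 <- simulate_f2(n = 60, a = 10, d = 3, mu = 30, sd = 0, seed = 18)
  m <- tapply(f2$ser_percent, f2$genotype, mean)
  expect_equal(as.vector(m[c("aa", "Aa", "AA")]), c(30, 43, 50))
  # d = a gives the complete-dominance pattern
  f2c <- simulate_f2(n = 60, a = 10, d = 10, mu = 30, sd = 0, seed = 18)
  mc <- tapply(f2c$ser_percent, f2c$genotype, mean)
  expect_equal(mc[["Aa"]], mc[["AA"]])
  # determinism
  expect_identical(simulate_f2(n = 40, seed = 19), simulate_f2(n = 40, seed = 19))
})

test_that("whole-study simulation is reproducible end to end", {
  s1 <- simulate_study(sim_config(seed = 20, n_lines = 30))
  s2 <- simulate_study(sim_config(seed = 20, n_lines = 30))
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth, s2$truth)
})
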