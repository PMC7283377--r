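#' Pipeline run configuration
#'
#' Validated bundle of the statistical and I/O choices of a pipeline run.
#' Defaults follow the screening design the package implements: detection
#' against the recurrent parent at alpha 0.001 in every season, post-hoc
#' letters at alpha 0.001, heterozygous SSSL calls rejected, panicle-mean
#' aggregation.
#'
#' @param control_id recurrent-parent line id (required).
#' @param alpha_detect line-screen threshold, default 0.001.
#' @param alpha_posthoc Duncan/letter threshold, default 0.001.
#' @param detection_mode \code{"every_season"} or \code{"pooled"}.
#' @param het_policy passed to [infer_segments()].
#' @param aggregation passed to [aggregate_ser()].
#' @param dominance_thresholds passed to [dominance_degree()].
#' @param trait trait tag for QTL names, default \code{"SER"}.
#' @param out_dir optional output directory for reports.
#' @param seed optional seed echoed into the run report.
#' @return a \code{sslmap_run_config} list.
#' @export
run_config <- function(control_id,
                       alpha_detect = 0.001, alpha_posthoc = 0.001,
                       detection_mode = c("every_season", "pooled"),
                       het_policy = c("error", "as_donor", "as_break"),
                       aggregation = c("panicle_mean", "pooled_counts"),
                       dominance_thresholds = c(0.2, 0.8, 1.2),
                       trait = "SER", out_dir = NULL, seed = NULL) {
  assert_prob(alpha_detect, "alpha_detect")
  assert_prob(alpha_posthoc, "alpha_posthoc")
  structure(list(control_id = control_id, alpha_detect = alpha_detect,
                 alpha_posthoc = alpha_posthoc,
                 detection_mode = match.arg(detection_mode),
                 het_policy = match.arg(het_policy),
                 aggregation = match.arg(aggregation),
                 dominance_thresholds = dominance_thresholds,
                 trait = trait, out_dir = out_dir, seed = seed),
            class = "sslmap_run_config")
}

#' Run the substitution-mapping pipeline end to end
#'
#' Screen, map and estimate: (1) infer donor segments from the genotype
#' table; (2) screen every line's SER against the recurrent parent; (3)
#' keep detected lines passing single-segment QC, cluster their segments
#' into named QTL calls; (4) estimate per-season additive effects for each
#' call. Inputs may be file paths (marker-map TSV, genotype TSV, phenotype
#' CSV) or the corresponding in-memory objects. All validation happens
#' before any file is written; with \code{out_dir} set, reports
#' (\code{segments.tsv}, \code{qtl_report.tsv}, \code{effects_by_season.tsv},
#' \code{qtls.bed}, \code{run_report.json}) are written only after every
#' stage has succeeded.
#'
#' @param map a [marker_map()] or TSV path.
#' @param geno a [genotype_table()] or TSV path.
#' @param pheno phenotype data.frame or CSV path.
#' @param config a [run_config()].
#' @return list \code{segments, comparisons, qtls, effects_by_season,
#'   report} (the QTL table carries additive effects and standard errors).
#' @export
run_pipeline <- function(map, geno, pheno, config) {
  if (!inherits(config, "sslmap_run_config"))
    stop_sslmap("config must come from run_config()",
                class = "sslmap_config_error")
  t0 <- proc.time()[["elapsed"]]
  warnings_seen <- character()
  note <- function(w) warnings_seen <<- c(warnings_seen, w)

  is_path <- function(x) is.character(x) && length(x) == 1L && !is.matrix(x)
  if (is_path(map)) map <- read_marker_map(map)
  if (is_path(geno)) geno <- read_genotype_table(geno, map)
  if (is_path(pheno)) pheno <- read_phenotypes(pheno)
  pheno <- add_ser(pheno)
  if (!config$control_id %in% pheno$line_id)
    stop_sslmap("control line '", config$control_id,
                "' absent from phenotypes", class = "sslmap_config_error")

  segments <- infer_segments(geno, map, het_policy = config$het_policy)
  comparisons <- detect_qtl_lines(pheno, config$control_id,
                                  alpha = config$alpha_detect,
                                  mode = config$detection_mode)
  detected <- comparisons$line_id[comparisons$detected]

  genotyped <- intersect(detected, rownames(geno))
  if (length(setdiff(detected, rownames(geno)))) {
    note(paste0("detected line(s) without genotypes dropped: ",
                paste(setdiff(detected, rownames(geno)), collapse = ", ")))
  }
  qc <- vapply(genotyped, function(id)
    verify_single_segment(id, segments, rownames(geno))$pass, logical(1))
  if (length(genotyped) && any(!qc))
    note(paste0("detected line(s) failing single-segment QC dropped: ",
                paste(genotyped[!qc], collapse = ", ")))
  keep <- genotyped[qc]

  withCallingHandlers({
    qtls <- name_qtls(assign_qtls(
      segments[segments$line_id %in% keep, , drop = FALSE],
      comparisons = comparisons), trait = config$trait)
  }, warning = function(w) {
    note(conditionMessage(w)); invokeRestart("muffleWarning")
  })

  agg <- aggregate_ser(pheno, aggregation = config$aggregation)
  ctrl <- agg[agg$line_id == config$control_id, ]
  ctrl_means <- stats::setNames(ctrl$ser_mean, ctrl$season_id)
  eff_rows <- list()
  qtls$additive_effect <- NA_real_
  qtls$se <- NA_real_
  for (i in seq_len(nrow(qtls))) {
    lines <- strsplit(qtls$supporting_lines[i], ",")[[1]]
    sub <- agg[agg$line_id %in% lines, ]
    line_means <- tapply(sub$ser_mean, sub$season_id, mean)
    eff <- additive_effect(stats::setNames(as.numeric(line_means),
                                           names(line_means)), ctrl_means)
    qtls$additive_effect[i] <- eff$additive_effect
    qtls$se[i] <- eff$se
    eff_rows[[i]] <- data.frame(name = qtls$name[i],
                                season_id = names(eff$per_season),
                                additive_effect = as.numeric(eff$per_season),
                                stringsAsFactors = FALSE)
  }
  effects_by_season <- if (length(eff_rows)) do.call(rbind, eff_rows) else
    data.frame(name = character(), season_id = character(),
               additive_effect = numeric(), stringsAsFactors = FALSE)

  report <- list(
    n_lines_genotyped = nrow(geno),
    n_lines_phenotyped = length(unique(pheno$line_id)),
    n_segments = nrow(segments),
    n_detected = length(detected),
    n_detected_kept = length(keep),
    n_qtls = nrow(qtls),
    warnings = warnings_seen,
    config = unclass(config),
    elapsed_s = proc.time()[["elapsed"]] - t0)

  result <- list(segments = segments, comparisons = comparisons, qtls = qtls,
                 effects_by_season = effects_by_season, report = report)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

#' Write the pipeline reports
#'
#' Writes all report files of a [run_pipeline()] result to a directory.
#' Files are staged to temporary names and renamed into place only after
#' every file has been written, so a failure leaves no partial report set.
#'
#' @param result [run_pipeline()] output.
#' @param out_dir directory (created if missing).
#' @return invisibly, the vector of paths written.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  staged <- list()
  stage <- function(final, writer) {
    tmp <- tempfile(tmpdir = out_dir)
    writer(tmp)
    staged[[length(staged) + 1L]] <<- c(tmp, file.path(out_dir, final))
  }
  stage("segments.tsv", function(p) write_segments(result$segments, p))
  stage("qtl_report.tsv", function(p) write_qtl_report(result$qtls, p))
  stage("effects_by_season.tsv", function(p)
    utils::write.table(result$effects_by_season, p, sep = "\t",
                       quote = FALSE, row.names = FALSE))
  stage("qtls.bed", function(p)
    write_bed(intervals_to_bed(result$qtls$chromosome,
                               result$qtls$int_start_kb,
                               result$qtls$int_end_kb,
                               result$qtls$name), p))
  # wall-clock timing and the output path stay in the in-memory report only,
  # so reruns of the same inputs write byte-identical files anywhere
  stage("run_report.json", function(p) {
    rep <- result$report[setdiff(names(result$report), "elapsed_s")]
    rep$config <- rep$config[setdiff(names(rep$config), "out_dir")]
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA,
                         null = "null")
  })
  for (s in staged) file.rename(s[1], s[2])
  invisible(vapply(staged, `[`, character(1), 2))
}

#' Write a QTL report to TSV
#'
#' Columns: name, chromosome, interval_start_kb, interval_end_kb,
#' estimated_length_kb, max_length_kb, p_value, additive_effect, se,
#' supporting_lines, flag. kb quantities rounded to 0.1.
#'
#' @param qtls QTL table from [run_pipeline()] (or [name_qtls()]).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_qtl_report <- function(qtls, path) {
  out <- data.frame(
    name = qtls$name, chromosome = qtls$chromosome,
    interval_start_kb = round_kb(qtls$int_start_kb),
    interval_end_kb = round_kb(qtls$int_end_kb),
    estimated_length_kb = round_kb(qtls$est_length_kb),
    max_length_kb = round_kb(qtls$max_length_kb),
    p_value = qtls$p_value,
    additive_effect = qtls$additive_effect %||% NA_real_,
    se = qtls$se %||% NA_real_,
    supporting_lines = qtls$supporting_lines,
    flag = qtls$flag, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
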