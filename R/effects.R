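#' Additive effect of a QTL across seasons
#'
#' In an SSSL the homozygous donor substitution displaces the phenotype by
#' twice the additive effect, so per season
#' \deqn{A_j = (\bar y_{line,j} - \bar y_{control,j}) / 2,}
#' the reported effect is the mean over seasons and its standard error the
#' season-to-season sd divided by the square root of the number of seasons.
#' For a QTL supported by several lines, supply the per-season mean over its
#' supporting lines.
#'
#' @param line_season_means named numeric vector (names = season ids) of the
#'   line (or supporting-line average) SER means.
#' @param control_season_means named numeric vector over the same seasons
#'   for the control.
#' @return list \code{additive_effect, se, per_season} (per-season effects,
#'   named by season). With a single season the effect is reported and
#'   \code{se} is \code{NA} with a \code{single_season} flag.
#' @export
additive_effect <- function(line_season_means, control_season_means) {
  seasons <- names(line_season_means)
  if (is.null(seasons) || is.null(names(control_season_means)))
    stop_sslmap("season means must be named by season", class = "sslmap_stats_error")
  if (!setequal(seasons, names(control_season_means)))
    stop_sslmap("line and control cover different season sets",
                class = "sslmap_stats_error")
  per <- (line_season_means - control_season_means[seasons]) / 2
  k <- length(per)
  list(additive_effect = mean(per),
       se = if (k > 1L) stats::sd(per) / sqrt(k) else NA_real_,
       per_season = per,
       single_season = k == 1L)
}

#' Chi-square goodness-of-fit test for a segregation ratio
#'
#' Tests observed genotype-class counts against an expected segregation
#' ratio (1:2:1 for codominant marker classes in an F2 by default) with the
#' plain Pearson statistic \eqn{\chi^2 = \sum (O-E)^2/E} (no continuity
#' correction) against the upper-\eqn{\alpha} quantile of the chi-square
#' distribution on \code{length(counts) - 1} df.
#'
#' @param counts integer vector of observed class counts, e.g.
#'   \code{c(aa = 20, Aa = 40, AA = 20)}.
#' @param ratio expected ratio, same length as counts, all positive.
#' @param alpha test level, default 0.01.
#' @return list \code{chi2, df, critical, alpha, fits, expected}.
#' @examples
#' chi_square_segregation(c(22, 38, 20)) # chi2 = 0.3, fits
#' @export
chi_square_segregation <- function(counts, ratio = c(1, 2, 1), alpha = 0.01) {
  assert_prob(alpha, "alpha")
  if (length(counts) != length(ratio))
    stop_sslmap("counts and ratio must have equal length",
                class = "sslmap_stats_error")
  if (any(ratio <= 0))
    stop_sslmap("expected ratio classes must all be positive",
                class = "sslmap_stats_error")
  n <- sum(counts)
  if (n <= 0)
    stop_sslmap("total count must be > 0", class = "sslmap_stats_error")
  expected <- n * ratio / sum(ratio)
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  critical <- stats::qchisq(1 - alpha, df)
  list(chi2 = chi2, df = df, critical = critical, alpha = alpha,
       fits = chi2 < critical, expected = expected)
}

#' Additive effect, dominance deviation and dominance degree
#'
#' From the three F2 genotype-class means: \eqn{a = (\bar y_{AA} - \bar
#' y_{aa})/2}, \eqn{d = \bar y_{Aa} - (\bar y_{AA} + \bar y_{aa})/2}. The
#' dominance degree d/a is classified by thresholds on its magnitude
#' (configurable): additive below 0.2, incomplete dominance 0.2–0.8,
#' complete dominance 0.8–1.2, overdominance above 1.2.
#'
#' @param mean_aa,mean_Aa,mean_AA class means (recipient homozygote,
#'   heterozygote, donor homozygote).
#' @param thresholds numeric c(additive, complete_low, complete_high)
#'   boundaries on |d/a|, default \code{c(0.2, 0.8, 1.2)}.
#' @return list \code{a, d, d_over_a, class}; if the homozygote means are
#'   equal, \code{d_over_a} is \code{NA} and class is
#'   \code{"NO_ADDITIVE_EFFECT"}.
#' @export
dominance_degree <- function(mean_aa, mean_Aa, mean_AA,
                             thresholds = c(0.2, 0.8, 1.2)) {
  if (any(is.na(c(mean_aa, mean_Aa, mean_AA))))
    stop_sslmap("all three genotype-class means are required",
                class = "sslmap_stats_error")
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0))
    stop_sslmap("thresholds must be three increasing values",
                class = "sslmap_config_error")
  a <- (mean_AA - mean_aa) / 2
  d <- mean_Aa - (mean_AA + mean_aa) / 2
  if (a == 0)
    return(list(a = a, d = d, d_over_a = NA_real_, class = "NO_ADDITIVE_EFFECT"))
  r <- abs(d / a)
  cls <- if (r < thresholds[1]) "ADDITIVE"
    else if (r <= thresholds[2]) "INCOMPLETE_DOMINANCE"
    else if (r <= thresholds[3]) "COMPLETE_DOMINANCE"
    else "OVERDOMINANCE"
  list(a = a, d = d, d_over_a = d / a, class = cls)
}

#' Compare F2 genotype classes and classify dominance
#'
#' One-way ANOVA plus Duncan letters over the aa/Aa/AA classes of a focal
#' marker, then [dominance_degree()] on the class means. Classes with fewer
#' than 2 individuals are excluded with a warning; dominance needs all three
#' classes.
#'
#' @param f2 data.frame with columns \code{genotype} (\code{aa/Aa/AA}) and
#'   \code{ser_percent}.
#' @param alpha Duncan protection level, default 0.001.
#' @param thresholds passed to [dominance_degree()].
#' @return list \code{class_summary} (mean, se, n, letters per class),
#'   \code{anova}, \code{dominance}.
#' @export
f2_class_comparison <- function(f2, alpha = 0.001, thresholds = c(0.2, 0.8, 1.2)) {
  if (!all(c("genotype", "ser_percent") %in% names(f2)))
    stop_sslmap("f2 needs columns genotype and ser_percent",
                class = "sslmap_io_error")
  bad <- setdiff(unique(f2$genotype), c("aa", "Aa", "AA"))
  if (length(bad))
    stop_sslmap("unknown genotype class(es): ", paste(bad, collapse = ", "),
                class = "sslmap_io_error")
  groups <- split(f2$ser_percent, factor(f2$genotype, c("aa", "Aa", "AA")))
  small <- names(groups)[vapply(groups, length, integer(1)) < 2L]
  if (length(small)) {
    warning("excluding genotype class(es) with < 2 individuals: ",
            paste(small, collapse = ", "))
    groups <- groups[setdiff(names(groups), small)]
  }
  if (length(groups) < 2L)
    stop_sslmap("need >= 2 genotype classes with >= 2 individuals",
                class = "sslmap_stats_error")
  fit <- one_way_anova(groups)
  dg <- duncan_groups(groups, alpha)
  summ <- data.frame(
    genotype = names(groups),
    mean = vapply(groups, mean, numeric(1)),
    se = vapply(groups, function(g) stats::sd(g) / sqrt(length(g)), numeric(1)),
    n = vapply(groups, length, integer(1)),
    letters = dg$letters[match(names(groups), dg$line_id)],
    stringsAsFactors = FALSE, row.names = NULL)
  dom <- if (all(c("aa", "Aa", "AA") %in% names(groups)))
    dominance_degree(mean(groups$aa), mean(groups$Aa), mean(groups$AA),
                     thresholds = thresholds) else NULL
  list(class_summary = summ, anova = fit, dominance = dom)
}

#' Read an F2 genotype/phenotype table
#'
#' Expected CSV columns: \code{individual_id, genotype, ser_percent} with
#' genotype in \code{aa/Aa/AA}.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_f2 <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "genotype", "ser_percent")
  if (!all(need %in% names(df)))
    stop_sslmap("F2 file needs columns: ", paste(need, collapse = ", "),
                class = "sslmap_io_error")
  bad <- setdiff(unique(df$genotype), c("aa", "Aa", "AA"))
  if (length(bad))
    stop_sslmap("unknown genotype class(es): ", paste(bad, collapse = ", "),
                class = "sslmap_io_error")
  df
}

#' Write an F2 table to CSV
#' @param f2 data.frame.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_f2 <- function(f2, path) {
  utils::write.csv(f2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
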