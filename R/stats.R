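#' One-way fixed-effect analysis of variance
#'
#' Standard between/within decomposition used throughout the line screen.
#' Returned as a list carrying the ANOVA table plus the pieces the post-hoc
#' procedures need (group means and sizes, MSE, error df).
#'
#' If the data are perfectly constant the F statistic is 0/0; that case is
#' guarded and reported as F = 0, p = 1.
#'
#' @param groups named list of numeric observation vectors (>= 2 groups,
#'   each non-empty, at least one group with >= 2 observations).
#' @return object of class \code{sslmap_anova}: list with \code{table}
#'   (data.frame term/SS/df/MS/F/p), \code{means}, \code{n}, \code{mse},
#'   \code{df_error}.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_sslmap("need >= 2 groups", class = "sslmap_stats_error")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop_sslmap("groups must be uniquely named", class = "sslmap_stats_error")
  n <- vapply(groups, length, integer(1))
  if (any(n < 1L))
    stop_sslmap("every group needs >= 1 observation", class = "sslmap_stats_error")
  if (!any(n >= 2L))
    stop_sslmap("at least one group needs >= 2 observations",
                class = "sslmap_stats_error")
  y <- unlist(groups, use.names = FALSE)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(y)
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_between <- length(groups) - 1L
  df_error <- length(y) - length(groups)
  ms_between <- ss_between / df_between
  mse <- ss_within / df_error
  if (ss_within == 0 && ss_between == 0) {
    f <- 0; p <- 1
  } else if (ss_within == 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_between / mse
    p <- stats::pf(f, df_between, df_error, lower.tail = FALSE)
  }
  structure(list(
    table = data.frame(
      term = c("between", "error"),
      ss = c(ss_between, ss_within),
      df = c(df_between, df_error),
      ms = c(ms_between, mse),
      f = c(f, NA), p = c(p, NA), stringsAsFactors = FALSE),
    means = means, n = n, mse = mse, df_error = df_error),
    class = "sslmap_anova")
}

#' LSD comparisons of every line against a control
#'
#' Fisher's least significant difference applied to a screen against the
#' recurrent parent: one pooled one-way ANOVA supplies the error mean square
#' and error degrees of freedom, then each non-control group is compared to
#' the control with
#' \deqn{t = (\bar y_i - \bar y_c) / \sqrt{MSE (1/n_i + 1/n_c)}}
#' on the pooled error df, two-tailed.
#'
#' @param groups named list of numeric vectors.
#' @param control_id name of the control group.
#' @param alpha significance threshold, default 0.05.
#' @return data.frame \code{line_id, mean, n, diff, t, p, significant},
#'   one row per non-control group, plus the fit in
#'   \code{attr(, "anova")}.
#' @export
lsd_vs_control <- function(groups, control_id, alpha = 0.05) {
  assert_prob(alpha, "alpha")
  if (!control_id %in% names(groups))
    stop_sslmap("control group '", control_id, "' not found",
                class = "sslmap_config_error")
  fit <- one_way_anova(groups)
  if (fit$df_error < 1L)
    stop_sslmap("no error degrees of freedom for LSD",
                class = "sslmap_stats_error")
  ids <- setdiff(names(groups), control_id)
  mc <- fit$means[[control_id]]
  nc <- fit$n[[control_id]]
  diffs <- fit$means[ids] - mc
  se <- sqrt(fit$mse * (1 / fit$n[ids] + 1 / nc))
  t <- ifelse(se == 0, ifelse(diffs == 0, 0, Inf * sign(diffs)), diffs / se)
  p <- ifelse(is.infinite(t), 0,
              2 * stats::pt(abs(t), fit$df_error, lower.tail = FALSE))
  out <- data.frame(line_id = ids, mean = unname(fit$means[ids]),
                    n = unname(fit$n[ids]), diff = unname(diffs),
                    t = unname(t), p = unname(p),
                    significant = unname(p <= alpha),
                    stringsAsFactors = FALSE)
  attr(out, "anova") <- fit
  attr(out, "control_id") <- control_id
  out
}

#' Duncan's multiple range test with compact letter display
#'
#' Means are sorted and a span of p adjacent ordered means is declared
#' heterogeneous when its range exceeds the critical range
#' \deqn{R_p = q(1-(1-\alpha)^{p-1};\ p,\ df_e)\ \sqrt{MSE/n_h},}
#' where q is the studentized-range quantile at Duncan's protection level
#' and \eqn{n_h} is the harmonic mean group size (handles mild imbalance).
#' Following the multiple-range protocol, a span whose range does not exceed
#' its critical range is declared homogeneous and is not subdivided.
#' Homogeneous maximal spans become the letters of the compact letter
#' display.
#'
#' @param groups named list of numeric vectors.
#' @param alpha protection level per comparison, default 0.05.
#' @return data.frame \code{line_id, mean, n, letters} sorted by decreasing
#'   mean; critical ranges in \code{attr(, "critical_ranges")}.
#' @export
duncan_groups <- function(groups, alpha = 0.05) {
  assert_prob(alpha, "alpha")
  if (length(groups) == 1L) {
    return(data.frame(line_id = names(groups),
                      mean = mean(groups[[1]]), n = length(groups[[1]]),
                      letters = "a", stringsAsFactors = FALSE))
  }
  fit <- one_way_anova(groups)
  k <- length(groups)
  ord <- order(fit$means, decreasing = TRUE)
  m <- fit$means[ord]
  nh <- k / sum(1 / fit$n)
  crit <- vapply(2:k, function(p) {
    a_p <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(a_p, p, fit$df_error, lower.tail = FALSE) * sqrt(fit$mse / nh)
  }, numeric(1))
  crit <- c(NA, crit) # crit[p] = critical range for a span of p means

  homogeneous <- list()
  covered <- function(i, j) any(vapply(homogeneous, function(s)
    s[1] <= i && j <= s[2], logical(1)))
  # recursion over spans, largest first; homogeneous spans absorb sub-spans
  test_span <- function(i, j) {
    if (j <= i || covered(i, j)) return(invisible())
    p <- j - i + 1L
    if (m[i] - m[j] > crit[p]) {
      test_span(i, j - 1L)
      test_span(i + 1L, j)
    } else {
      homogeneous[[length(homogeneous) + 1L]] <<- c(i, j)
    }
    invisible()
  }
  test_span(1L, k)

  letters_per <- rep("", k)
  spans <- homogeneous[order(vapply(homogeneous, `[`, numeric(1), 1))]
  # singletons not inside any homogeneous span get their own letter
  singles <- setdiff(seq_len(k), unlist(lapply(spans, function(s) s[1]:s[2])))
  spans <- c(spans, lapply(singles, function(i) c(i, i)))
  spans <- spans[order(vapply(spans, `[`, numeric(1), 1))]
  for (s in seq_along(spans)) {
    idx <- spans[[s]][1]:spans[[s]][2]
    letters_per[idx] <- paste0(letters_per[idx], letters[(s - 1L) %% 26L + 1L])
  }
  out <- data.frame(line_id = names(m), mean = unname(m),
                    n = unname(fit$n[ord]), letters = letters_per,
                    stringsAsFactors = FALSE)
  attr(out, "critical_ranges") <- crit
  attr(out, "anova") <- fit
  out
}

#' Two-way fixed-effect ANOVA for lines x seasons
#'
#' Fits the balanced fixed-effect model SER ~ line + season + line:season
#' via [stats::aov()] and returns the per-term table. Unbalanced or
#' incomplete designs are rejected outright: with missing cells the
#' orthogonal decomposition no longer holds and a silent fallback to
#' adjusted sums of squares would change the meaning of the table.
#'
#' @param pheno data.frame with columns \code{line_id}, \code{season_id} and
#'   \code{ser_percent} (one row per replicate unit).
#' @return data.frame \code{term, ss, df, ms, f, p} with terms line, season,
#'   line:season, error.
#' @export
two_way_fixed_anova <- function(pheno) {
  pheno <- add_ser(pheno)
  tab <- table(pheno$line_id, pheno$season_id)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop_sslmap("need >= 2 lines and >= 2 seasons", class = "sslmap_stats_error")
  if (length(unique(as.vector(tab))) != 1L || any(tab < 2L))
    stop_sslmap("unbalanced or incomplete line x season design ",
                "(every cell needs the same replicate count, >= 2)",
                class = "sslmap_design_error")
  d <- data.frame(y = pheno$ser_percent,
                  line = factor(pheno$line_id),
                  season = factor(pheno$season_id))
  fit <- stats::aov(y ~ line + season + line:season, data = d)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  out <- data.frame(
    term = c("line", "season", "line:season", "error")[
      match(terms, c("line", "season", "line:season", "Residuals"))],
    ss = s[["Sum Sq"]], df = s[["Df"]], ms = s[["Mean Sq"]],
    f = s[["F value"]], p = s[["Pr(>F)"]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pooled-variance two-sample t-test (season contrast)
#'
#' Used to compare the first and second cropping seasons. Degenerate inputs
#' are guarded: zero pooled variance with equal means gives t = 0, p = 1;
#' zero pooled variance with unequal means gives p = 0 and a
#' \code{degenerate} flag.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @return list \code{t, df, p, mean_x, mean_y, degenerate}.
#' @export
season_contrast <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_sslmap("each sample needs >= 2 observations", class = "sslmap_stats_error")
  df <- length(x) + length(y) - 2L
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (sp2 == 0) {
    eq <- mean(x) == mean(y)
    return(list(t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                df = df, p = if (eq) 1 else 0,
                mean_x = mean(x), mean_y = mean(y), degenerate = !eq))
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       mean_x = mean(x), mean_y = mean(y), degenerate = FALSE)
}
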