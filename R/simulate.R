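#' Default planted-QTL layout for simulated SSSL libraries
#'
#' Seven QTLs on five chromosomes with additive effects between 10.6 and
#' 14.8 SER percentage points, the effect range reported for major stigma
#' exsertion loci introgressed from wild rice; two chromosomes carry two
#' QTLs each so that suffixed naming and within-chromosome clustering are
#' exercised. One QTL is supported by three nested carrier segments, the
#' others by one carrier each (nine carrier lines in total). Dominance
#' deviations default to incomplete dominance (d/a = 0.3).
#'
#' @return list of per-QTL lists with \code{chromosome},
#'   \code{position_kb}, \code{a} (pp), \code{d} (pp) and
#'   \code{carrier_lengths_kb}.
#' @export
default_planted_qtls <- function() {
  list(
    list(chromosome = "1",  position_kb = 17662.5, a = 11.9, d = 3.6,
         carrier_lengths_kb = 10741.8),
    list(chromosome = "1",  position_kb = 30913.9, a = 12.4, d = 3.7,
         carrier_lengths_kb = c(2611.3, 5874.5, 11059.7)),
    list(chromosome = "3",  position_kb = 13972.9, a = 11.1, d = 3.3,
         carrier_lengths_kb = 4632.1),
    list(chromosome = "3",  position_kb = 28126.5, a = 10.7, d = 3.2,
         carrier_lengths_kb = 9095.6),
    list(chromosome = "5",  position_kb = 11421.7, a = 13.5, d = 4.1,
         carrier_lengths_kb = 16410.5),
    list(chromosome = "9",  position_kb = 14674.5, a = 10.6, d = 3.2,
         carrier_lengths_kb = 2500.0),
    list(chromosome = "10", position_kb = 21865.8, a = 14.8, d = 4.4,
         carrier_lengths_kb = 1467.0))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data module with defaults that
#' emulate a wild-rice SSSL screening study: a 12-chromosome genome of
#' 43 Mb chromosomes genotyped at 60 markers each, a library of 168 lines
#' including nine carriers of seven planted QTLs, a recipient baseline SER
#' of 29.6 percent, five cropping seasons with zero-mean season offsets,
#' line-by-season interaction sd 2 pp, panicle residual sd 5 pp and 10
#' panicles per line and season.
#'
#' @param seed integer RNG seed.
#' @param n_chromosomes,markers_per_chromosome,chromosome_length_kb genome
#'   and marker-map dimensions.
#' @param min_spacing_kb smallest admissible gap between adjacent markers.
#' @param n_lines library size (carriers included).
#' @param segment_length_kb length-2 range the background segment lengths
#'   are drawn from, uniformly.
#' @param planted_qtls list as returned by [default_planted_qtls()].
#' @param exclusive_carriers if TRUE (default) background segments are
#'   resampled away from planted loci, so each QTL's carrier set is exactly
#'   its designated carriers.
#' @param mu baseline (recipient) SER percent.
#' @param season_effects per-season fixed offsets (pp); their length sets
#'   the number of seasons.
#' @param interaction_sd sd (pp) of the line-by-season interaction.
#' @param residual_sd panicle-level residual sd (pp), normal mode.
#' @param n_panicles panicles per line and season.
#' @param spikelets_per_panicle Poisson mean spikelet count, binomial mode.
#' @param sse_fraction fraction of exserted spikelets scored as single
#'   exsertion, binomial mode.
#' @param count_mode \code{"normal"} (SER with Gaussian residual, clamped
#'   to [0, 100]) or \code{"binomial"} (spikelet counts, the biologically
#'   faithful observation model).
#' @param control_id recipient line id used in phenotype tables.
#' @return a \code{sslmap_sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 12L,
                       markers_per_chromosome = 60L,
                       chromosome_length_kb = 43000,
                       min_spacing_kb = 50,
                       n_lines = 168L,
                       segment_length_kb = c(1500, 12000),
                       planted_qtls = default_planted_qtls(),
                       exclusive_carriers = TRUE,
                       mu = 29.6,
                       season_effects = c(-2, -1, 0, 1, 2),
                       interaction_sd = 2,
                       residual_sd = 5,
                       n_panicles = 10L,
                       spikelets_per_panicle = 150,
                       sse_fraction = 0.75,
                       count_mode = c("normal", "binomial"),
                       control_id = "HJX74") {
  count_mode <- match.arg(count_mode)
  if (mu < 0 || mu > 100)
    stop_sslmap("mu must be in [0, 100]", class = "sslmap_config_error")
  if (interaction_sd < 0 || residual_sd < 0)
    stop_sslmap("sds must be >= 0", class = "sslmap_config_error")
  if (!length(season_effects))
    stop_sslmap("season_effects must be non-empty", class = "sslmap_config_error")
  for (q in planted_qtls)
    if (q$position_kb <= 0 || q$position_kb >= chromosome_length_kb)
      stop_sslmap("planted QTL position outside chromosome extent",
                  class = "sslmap_config_error")
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    chromosome_length_kb = chromosome_length_kb,
    min_spacing_kb = min_spacing_kb, n_lines = as.integer(n_lines),
    segment_length_kb = segment_length_kb, planted_qtls = planted_qtls,
    exclusive_carriers = isTRUE(exclusive_carriers), mu = mu,
    season_effects = season_effects, interaction_sd = interaction_sd,
    residual_sd = residual_sd, n_panicles = as.integer(n_panicles),
    spikelets_per_panicle = spikelets_per_panicle,
    sse_fraction = sse_fraction, count_mode = count_mode,
    control_id = control_id), class = "sslmap_sim_config")
}

#' Simulate a marker map
#'
#' Marker positions are laid out on a jittered regular grid: with m markers
#' on a chromosome of length L, marker i sits at \code{i L/(m+1)} plus a
#' uniform jitter of at most 45 percent of the grid gap, which keeps
#' positions strictly increasing with a guaranteed minimum spacing of a
#' tenth of the gap. Positions are rounded to 0.1 kb. Chromosome extents
#' run from 0 to L.
#'
#' @param config a [sim_config()]; only the map fields are used.
#' @param seed optional seed; set it for a standalone reproducible map.
#' @return a [marker_map()].
#' @export
simulate_marker_map <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$markers_per_chromosome
  if (m < 3L)
    stop_sslmap("markers_per_chromosome must be >= 3",
                class = "sslmap_config_error")
  L <- config$chromosome_length_kb
  gap <- L / (m + 1)
  if (0.1 * gap < config$min_spacing_kb)
    stop_sslmap("requested marker count too dense for min_spacing_kb ",
                config$min_spacing_kb, class = "sslmap_config_error")
  chroms <- as.character(seq_len(config$n_chromosomes))
  pieces <- lapply(chroms, function(chr) {
    pos <- round_kb(seq_len(m) * gap + stats::runif(m, -0.45, 0.45) * gap)
    data.frame(marker_id = sprintf("C%02dM%03d", as.integer(chr), seq_len(m)),
               chromosome = chr, position_kb = pos, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  ext <- data.frame(chromosome = chroms, start_kb = 0, end_kb = L,
                    stringsAsFactors = FALSE)
  marker_map(df$marker_id, df$chromosome, df$position_kb, chrom_extent = ext)
}

# markers of `map` on chromosome chr inside [start, end]
.markers_in <- function(map, chr, start, end) {
  sub <- map[map$chromosome == chr, , drop = FALSE]
  sub[sub$position_kb >= start & sub$position_kb <= end, , drop = FALSE]
}

#' Simulate an SSSL library
#'
#' Generates one donor segment per line. Designated carrier segments are
#' centered on their planted locus and, if needed, widened minimally so the
#' locus is flanked by donor-genotype markers — SSSL libraries are built by
#' marker-assisted selection, so a carrier whose locus is not bracketed by
#' markers of its segment would not have been selected. Background segments
#' get a random chromosome, length and position; segments containing no
#' marker are resampled (marker-invisible segments cannot enter a
#' marker-genotyped library), as are — under
#' \code{exclusive_carriers} — segments covering a planted locus.
#'
#' @param map a [marker_map()].
#' @param config a [sim_config()].
#' @param seed optional seed for standalone use.
#' @return list with \code{geno} (a [genotype_table()]), \code{truth}
#'   (list: \code{lines} data.frame with the planted segment coordinates,
#'   donor-run markers and carried QTL; \code{qtls} data.frame with
#'   position, effects and carrier lines; \code{n_resampled}).
#' @export
simulate_sssl_library <- function(map, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qtls <- config$planted_qtls
  carriers <- list()
  for (qi in seq_along(qtls)) {
    q <- qtls[[qi]]
    for (len in q$carrier_lengths_kb)
      carriers[[length(carriers) + 1L]] <-
        list(qtl = qi, chromosome = q$chromosome, position_kb = q$position_kb,
             length_kb = len)
  }
  if (length(carriers) > config$n_lines)
    stop_sslmap("n_lines smaller than the number of designated carriers",
                class = "sslmap_config_error")
  chroms <- unique(map$chromosome)
  qtl_pos <- lapply(chroms, function(chr) {
    unlist(lapply(qtls, function(q) if (q$chromosome == chr) q$position_kb))
  })
  names(qtl_pos) <- chroms

  n <- config$n_lines
  line_ids <- sprintf("SL%03d", seq_len(n))
  lines <- vector("list", n)
  n_resampled <- 0L

  for (i in seq_len(n)) {
    if (i <= length(carriers)) {
      cr <- carriers[[i]]
      ext <- chrom_extent(map, cr$chromosome)
      start <- max(ext[["start_kb"]], cr$position_kb - cr$length_kb / 2)
      end <- min(ext[["end_kb"]], cr$position_kb + cr$length_kb / 2)
      sub <- map[map$chromosome == cr$chromosome, , drop = FALSE]
      left <- sub$position_kb[sub$position_kb <= cr$position_kb]
      right <- sub$position_kb[sub$position_kb >= cr$position_kb]
      if (!length(left) || !length(right))
        stop_sslmap("planted locus outside the marker span of chromosome ",
                    cr$chromosome, class = "sslmap_config_error")
      # minimal widening: locus must be flanked by markers inside the segment
      if (!any(left >= start)) start <- max(left)
      if (!any(right <= end)) end <- min(right)
      lines[[i]] <- list(line_id = line_ids[i], chromosome = cr$chromosome,
                         seg_start_kb = start, seg_end_kb = end,
                         carrier_of = cr$qtl)
    } else {
      repeat {
        chr <- sample(chroms, 1L)
        len <- stats::runif(1, config$segment_length_kb[1],
                            config$segment_length_kb[2])
        ext <- chrom_extent(map, chr)
        if (len > ext[["end_kb"]] - ext[["start_kb"]]) {
          n_resampled <- n_resampled + 1L
          next
        }
        start <- stats::runif(1, ext[["start_kb"]], ext[["end_kb"]] - len)
        end <- start + len
        visible <- nrow(.markers_in(map, chr, start, end)) > 0L
        hits_qtl <- any(qtl_pos[[chr]] >= start & qtl_pos[[chr]] <= end)
        if (!visible || (config$exclusive_carriers && hits_qtl)) {
          n_resampled <- n_resampled + 1L
          next
        }
        lines[[i]] <- list(line_id = line_ids[i], chromosome = chr,
                           seg_start_kb = start, seg_end_kb = end,
                           carrier_of = NA_integer_)
        break
      }
    }
  }

  geno <- matrix(GENO_CALLS[["RECIPIENT"]], nrow = n, ncol = nrow(map),
                 dimnames = list(line_ids, map$marker_id))
  truth_lines <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- lines[[i]]
    inside <- .markers_in(map, ln$chromosome, ln$seg_start_kb, ln$seg_end_kb)
    geno[ln$line_id, inside$marker_id] <- GENO_CALLS[["DONOR"]]
    carried <- if (!is.na(ln$carrier_of)) ln$carrier_of else {
      hits <- which(vapply(qtls, function(q)
        q$chromosome == ln$chromosome &&
          q$position_kb >= ln$seg_start_kb &&
          q$position_kb <= ln$seg_end_kb, logical(1)))
      if (length(hits)) hits[1] else NA_integer_
    }
    truth_lines[[i]] <- data.frame(
      line_id = ln$line_id, chromosome = ln$chromosome,
      seg_start_kb = ln$seg_start_kb, seg_end_kb = ln$seg_end_kb,
      first_donor_marker = inside$marker_id[1],
      last_donor_marker = inside$marker_id[nrow(inside)],
      n_donor_markers = nrow(inside),
      carried_qtl = carried, stringsAsFactors = FALSE)
  }
  truth_lines <- do.call(rbind, truth_lines)
  empty_qtls <- data.frame(qtl = integer(), chromosome = character(),
                           position_kb = numeric(), a = numeric(),
                           d = numeric(), carrier_lines = character(),
                           stringsAsFactors = FALSE)
  truth_qtls <- do.call(rbind, lapply(seq_along(qtls), function(qi) {
    q <- qtls[[qi]]
    data.frame(qtl = qi, chromosome = q$chromosome,
               position_kb = q$position_kb, a = q$a, d = q$d,
               carrier_lines = paste(
                 truth_lines$line_id[!is.na(truth_lines$carried_qtl) &
                                       truth_lines$carried_qtl == qi],
                 collapse = ","),
               stringsAsFactors = FALSE)
  }))
  list(geno = genotype_table(geno, map),
       truth = list(lines = truth_lines, qtls = truth_qtls %||% empty_qtls,
                    n_resampled = n_resampled))
}

#' Simulate season-structured phenotypes for a library
#'
#' The latent line-by-season mean is
#' \deqn{p_{ij} = clamp(\mu + \sum_q 2 a_q [line_i\ carries\ q] + s_j +
#'   g_{ij},\ 0,\ 100)}
#' with season offsets \eqn{s_j} and interaction \eqn{g_{ij} \sim
#' N(0, \sigma_{int})}. In \code{"normal"} mode each panicle reports
#' \eqn{clamp(p_{ij} + \epsilon, 0, 100)} with \eqn{\epsilon \sim N(0,
#' \sigma_{res})}; in \code{"binomial"} mode each panicle gets a Poisson
#' spikelet count and a binomial number of exserted spikelets at rate
#' \eqn{p_{ij}/100}, split into single/dual exsertion by
#' \code{sse_fraction}. The recipient control line (no segment) is always
#' included.
#'
#' @param truth the \code{truth} element of [simulate_sssl_library()].
#' @param config a [sim_config()].
#' @param seed optional seed for standalone use.
#' @return long phenotype data.frame with \code{line_id, season_id,
#'   unit_id, ser_percent} (plus count columns in binomial mode).
#' @export
simulate_phenotypes <- function(truth, config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qtl_a <- truth$qtls$a
  lines <- c(config$control_id, truth$lines$line_id)
  shift <- c(0, vapply(seq_len(nrow(truth$lines)), function(i) {
    qi <- truth$lines$carried_qtl[i]
    if (is.na(qi)) 0 else 2 * qtl_a[qi]
  }, numeric(1)))
  seasons <- sprintf("S%d", seq_along(config$season_effects))
  rows <- vector("list", length(lines) * length(seasons))
  k <- 0L
  for (i in seq_along(lines)) {
    for (j in seq_along(seasons)) {
      g <- stats::rnorm(1, 0, config$interaction_sd)
      p_ij <- min(100, max(0, config$mu + shift[i] +
                             config$season_effects[j] + g))
      np <- config$n_panicles
      k <- k + 1L
      if (config$count_mode == "normal") {
        ser <- pmin(100, pmax(0, p_ij + stats::rnorm(np, 0, config$residual_sd)))
        rows[[k]] <- data.frame(line_id = lines[i], season_id = seasons[j],
                                unit_id = sprintf("P%02d", seq_len(np)),
                                ser_percent = ser, stringsAsFactors = FALSE)
      } else {
        nsp <- pmax(1L, stats::rpois(np, config$spikelets_per_panicle))
        exserted <- stats::rbinom(np, nsp, p_ij / 100)
        sse <- stats::rbinom(np, exserted, config$sse_fraction)
        rows[[k]] <- data.frame(line_id = lines[i], season_id = seasons[j],
                                unit_id = sprintf("P%02d", seq_len(np)),
                                n_spikelets = nsp, n_sse = sse,
                                n_dse = exserted - sse,
                                stringsAsFactors = FALSE)
      }
    }
  }
  add_ser(do.call(rbind, rows))
}

#' Simulate secondary recombinant lines within a parent segment
#'
#' Each secondary line's donor run is a contiguous sub-run of the parent's
#' marker run (a prefix, a suffix, or an interior block — one or two
#' breakpoints). The phenotypic resolution of substitution mapping is one
#' marker, so the QTL is anchored at the parent-run marker nearest the
#' planted locus, and a secondary line expresses the QTL iff its run
#' includes that marker. With \code{guarantee} (default) at least one
#' carrying and one non-carrying line are always produced.
#'
#' @param map a [marker_map()].
#' @param parent_segment the parent's row from [infer_segments()] (or the
#'   matching truth row with \code{first_donor_marker} /
#'   \code{last_donor_marker} and \code{chromosome}).
#' @param qtl_position_kb planted locus position.
#' @param n_lines number of secondary lines.
#' @param prefix line-id prefix, default \code{"SEC"}.
#' @param guarantee force at least one carrier and one non-carrier.
#' @param seed optional seed for standalone use.
#' @return list \code{geno} (secondary-line [genotype_table()]),
#'   \code{truth} (data.frame \code{line_id, first_marker, last_marker,
#'   carries}), \code{qtl_marker} (the anchoring marker id).
#' @export
simulate_secondary_lines <- function(map, parent_segment, qtl_position_kb,
                                     n_lines = 5L, prefix = "SEC",
                                     guarantee = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chr <- parent_segment$chromosome
  sub <- map[map$chromosome == chr, , drop = FALSE]
  i0 <- match(parent_segment$first_donor_marker, sub$marker_id)
  i1 <- match(parent_segment$last_donor_marker, sub$marker_id)
  if (is.na(i0) || is.na(i1) || i1 - i0 + 1L < 4L)
    stop_sslmap("parent run too short: need >= 4 markers",
                class = "sslmap_config_error")
  run <- i0:i1
  m <- length(run)
  q_rel <- which.min(abs(sub$position_kb[run] - qtl_position_kb))

  draw_run <- function() {
    kind <- sample(c("prefix", "suffix", "interior"), 1L)
    if (kind == "prefix") c(1L, sample(seq_len(m - 1L), 1L))
    else if (kind == "suffix") c(sample(2:m, 1L), m)
    else sort(sample(seq_len(m), 2L))
  }
  runs <- replicate(n_lines, draw_run(), simplify = FALSE)
  carries <- function(r) r[1] <= q_rel && q_rel <= r[2]
  if (guarantee && n_lines >= 2L) {
    has <- vapply(runs, carries, logical(1))
    if (!any(has)) runs[[1]] <- c(max(1L, q_rel - 1L), min(m, q_rel + 1L))
    has <- vapply(runs, carries, logical(1))
    if (all(has))
      runs[[n_lines]] <- if (q_rel > 1L) c(1L, q_rel - 1L) else c(q_rel + 1L, m)
  }
  ids <- sprintf("%s%02d", prefix, seq_len(n_lines))
  geno <- matrix(GENO_CALLS[["RECIPIENT"]], nrow = n_lines, ncol = nrow(map),
                 dimnames = list(ids, map$marker_id))
  truth <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    idx <- run[runs[[i]][1]]:run[runs[[i]][2]]
    geno[ids[i], sub$marker_id[idx]] <- GENO_CALLS[["DONOR"]]
    truth[[i]] <- data.frame(line_id = ids[i],
                             first_marker = sub$marker_id[idx[1]],
                             last_marker = sub$marker_id[idx[length(idx)]],
                             carries = carries(runs[[i]]),
                             stringsAsFactors = FALSE)
  }
  list(geno = genotype_table(geno, map), truth = do.call(rbind, truth),
       qtl_marker = sub$marker_id[run[q_rel]])
}

#' Simulate an F2 population at a focal marker
#'
#' Genotypes are multinomial with the Mendelian 1:2:1 expectation;
#' phenotype means are \eqn{\mu} (aa), \eqn{\mu + a + d} (Aa) and
#' \eqn{\mu + 2a} (AA) with Gaussian noise, clamped to [0, 100].
#'
#' @param n population size (>= 3).
#' @param a additive effect (pp).
#' @param d dominance deviation (pp).
#' @param mu recipient-homozygote mean SER.
#' @param sd residual sd (pp).
#' @param seed optional seed for standalone use.
#' @return data.frame \code{individual_id, genotype, ser_percent}; the
#'   class means used are stored in \code{attr(, "truth")}.
#' @export
simulate_f2 <- function(n = 80L, a = 10, d = 3, mu = 29.6, sd = 3,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 3L) stop_sslmap("n must be >= 3", class = "sslmap_config_error")
  geno <- sample(c("aa", "Aa", "AA"), n, replace = TRUE,
                 prob = c(0.25, 0.5, 0.25))
  means <- c(aa = mu, Aa = mu + a + d, AA = mu + 2 * a)
  ser <- pmin(100, pmax(0, means[geno] + stats::rnorm(n, 0, sd)))
  out <- data.frame(individual_id = sprintf("F2_%03d", seq_len(n)),
                    genotype = geno, ser_percent = unname(ser),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(a = a, d = d, mu = mu, sd = sd,
                             class_means = means)
  out
}

#' Simulate a complete study
#'
#' One call producing everything the pipeline consumes: marker map, SSSL
#' genotype table with ground truth, and the season-structured phenotype
#' table. All randomness is governed by \code{config$seed}, so identical
#' configurations reproduce identical outputs.
#'
#' @param config a [sim_config()].
#' @return list \code{map, geno, truth, pheno, config}.
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  map <- simulate_marker_map(config)
  lib <- simulate_sssl_library(map, config)
  pheno <- simulate_phenotypes(lib$truth, config)
  list(map = map, geno = lib$geno, truth = lib$truth, pheno = pheno,
       config = config)
}

#' Write simulation ground truth as JSON
#' @param truth truth list from [simulate_sssl_library()].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read simulation ground truth from JSON
#' @param path file written by [write_ground_truth()].
#' @return truth list.
#' @export
read_ground_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$lines <- as.data.frame(tr$lines, stringsAsFactors = FALSE)
  tr$qtls <- as.data.frame(tr$qtls, stringsAsFactors = FALSE)
  tr
}
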