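#' Axis definitions for the sensitivity study
#'
#' The study varies one population parameter at a time while holding the
#' others at stock values: population size (6x6, 20x20, 80x80 at density
#' 0.5), sex ratio (10x50, 30x30, 50x10 at density 0.5, i.e. equal total
#' size), and mating density (0.25, 0.5, 0.75 at 20x20). Level values
#' are encoded as total individuals (size axis), males/females (sex
#' ratio axis) and the density proportion.
#'
#' @return data.frame with columns `axis`, `level`, `n_males`,
#'   `n_females`, `density`
#' @export
study_axes <- function() {
  rbind(
    data.frame(axis = "size", level = c(12, 40, 160),
               n_males = c(6, 20, 80), n_females = c(6, 20, 80),
               density = 0.5),
    data.frame(axis = "sex_ratio", level = c(0.2, 1, 5),
               n_males = c(10, 30, 50), n_females = c(50, 30, 10),
               density = 0.5),
    data.frame(axis = "density", level = c(0.25, 0.5, 0.75),
               n_males = 20, n_females = 20,
               density = c(0.25, 0.5, 0.75))
  )
}

#' Run one axis of the sensitivity study
#'
#' For each level of the chosen axis, draws `reps` uniform random mating
#' networks (every individual mates at least once) and scores each with
#' [metric_report()]. Replicates on which a metric is undefined keep an
#' `NA` cell plus a reason code; they are dropped only from analyses
#' that involve that metric, never from the table.
#'
#' Per-replicate seeds derive deterministically from `base_seed` and the
#' (level, replicate) position, so any single replicate can be
#' regenerated in isolation.
#'
#' @param axis `"size"`, `"sex_ratio"` or `"density"`
#' @param reps replicates per level (the stock study uses 1000)
#' @param base_seed integer seed for the whole experiment
#' @return data.frame of class `experiment_result`, one row per
#'   replicate: `axis`, `level`, `replicate`, `seed`, the five metric
#'   columns (`r_newman_u`, `r_newman_d`, `nodf`, `scic_corr`,
#'   `scic_slope`, `NA` when undefined) and matching `*_reason` columns.
#' @export
run_axis_experiment <- function(axis = c("size", "sex_ratio", "density"),
                                reps = 1000L, base_seed = 1L) {
  axis <- match.arg(axis)
  stopifnot(reps >= 1L)
  levels <- study_axes()
  levels <- levels[levels$axis == axis, , drop = FALSE]
  out <- vector("list", nrow(levels) * reps)
  row <- 0L
  for (li in seq_len(nrow(levels))) {
    lv <- levels[li, ]
    for (rep in seq_len(reps)) {
      seed <- replicate_seed(base_seed, axis, li, rep)
      net <- random_mating_network(lv$n_males, lv$n_females, lv$density,
                                   seed = seed)
      rp <- metric_report(net)
      vals <- report_values(rp)
      reasons <- report_reasons(rp)
      row <- row + 1L
      out[[row]] <- data.frame(
        axis = axis, level = lv$level, replicate = rep, seed = seed,
        t(vals),
        r_newman_u_reason = reasons[["r_newman_u"]],
        r_newman_d_reason = reasons[["r_newman_d"]],
        scic_corr_reason = reasons[["scic_corr"]],
        scic_slope_reason = reasons[["scic_slope"]],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("experiment_result", "data.frame")
  res
}

# deterministic per-replicate seed; disjoint blocks per (axis, level) so
# no two replicates anywhere in a study share a seed; kept within 32 bits
replicate_seed <- function(base_seed, axis, level_index, rep) {
  axis_offset <- match(axis, c("size", "sex_ratio", "density")) - 1L
  (as.integer(base_seed) + (3L * axis_offset + level_index - 1L) * 1000003L +
     rep) %% 2147483647L
}

study_metrics <- c("r_newman_u", "r_newman_d", "nodf", "scic_corr", "scic_slope")

#' Correlation of each metric with its population parameter
#'
#' Spearman rank correlation between each metric and the axis level,
#' pooled over all non-`NA` replicates of all levels. Measures how
#' confounded a metric is by the population parameter: a useful
#' assortativity measure should be close to independent of size, sex
#' ratio and density.
#'
#' @param res an `experiment_result` from [run_axis_experiment()]
#' @return data.frame: `axis`, `metric`, `rho`, `n` (replicates used);
#'   `rho` is `NA` when a metric is constant or all-`NA`.
#' @export
metric_parameter_correlation <- function(res) {
  do.call(rbind, lapply(split(res, res$axis), function(part) {
    rows <- lapply(study_metrics, function(mname) {
      ok <- !is.na(part[[mname]])
      rho <- if (sum(ok) >= 2L && stats::sd(part[[mname]][ok]) > 0 &&
                 stats::sd(part$level[ok]) > 0)
        stats::cor(part$level[ok], part[[mname]][ok], method = "spearman")
      else NA_real_
      data.frame(axis = part$axis[1L], metric = mname, rho = rho,
                 n = sum(ok), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
}

#' Pairwise correlation between metrics at each level
#'
#' Pearson correlation between every pair of metrics at each level of
#' each axis, over pairwise-complete replicates. Measures whether the
#' metrics capture the same information about assortativity.
#'
#' @param res an `experiment_result` from [run_axis_experiment()]
#' @param min_pairs minimum complete pairs required; fewer gives `NA`
#' @return data.frame: `axis`, `level`, `metric1`, `metric2`, `r`, `n`
#' @export
metric_metric_correlation <- function(res, min_pairs = 3L) {
  parts <- split(res, list(res$axis, res$level), drop = TRUE)
  out <- lapply(parts, function(part) {
    combs <- utils::combn(study_metrics, 2L)
    rows <- lapply(seq_len(ncol(combs)), function(ci) {
      a <- part[[combs[1L, ci]]]; b <- part[[combs[2L, ci]]]
      ok <- !is.na(a) & !is.na(b)
      r <- if (sum(ok) >= min_pairs && stats::sd(a[ok]) > 0 &&
               stats::sd(b[ok]) > 0)
        stats::cor(a[ok], b[ok]) else NA_real_
      data.frame(axis = part$axis[1L], level = part$level[1L],
                 metric1 = combs[1L, ci], metric2 = combs[2L, ci],
                 r = r, n = sum(ok), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res2 <- do.call(rbind, out)
  rownames(res2) <- NULL
  res2[order(res2$axis, res2$level), ]
}

#' Null-model z-score for NODF
#'
#' NODF rises mechanically with mating density, so raw values from
#' networks of different density are not comparable. This transform
#' scores the observed NODF against the null distribution obtained from
#' uniform random networks with the same numbers of males and females,
#' the same edge count and the same minimum-degree-one constraint:
#' `z = (NODF_obs - mean(NODF_null)) / sd(NODF_null)`. Interpretation
#' shifts accordingly, from absolute nestedness to departure from random
#' mating at fixed density.
#'
#' @param net a [mating_network]
#' @param n_null number of null networks (>= 100)
#' @param seed integer seed for the null draws
#' @return the z value, or `NA` when the null distribution is degenerate
#'   (e.g. a complete matrix, whose null space is a single network)
#' @export
nodf_null_zscore <- function(net, n_null = 1000L, seed = NULL) {
  stopifnot(n_null >= 100L)
  net <- drop_unmated(net)
  m <- n_males(net); f <- n_females(net)
  E <- degrees(net)$n_edges
  obs <- nodf(net, detail = FALSE)
  if (!is.null(seed)) set.seed(seed)
  null_vals <- vapply(seq_len(n_null), function(i) {
    nodf(random_mating_network(m, f, E / (m * f)), detail = FALSE)
  }, numeric(1))
  s <- stats::sd(null_vals)
  if (is.na(s) || s == 0) return(NA_real_)
  (obs - mean(null_vals)) / s
}
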