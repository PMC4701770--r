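#' Metric values that may be undefined
#'
#' Correlation-type assortativity metrics are undefined on networks that
#' lack the variance they need (for example any strictly monogamous
#' population). Rather than silently returning `NaN`, metrics in this
#' package return a `metric_value`: either a number, or an explicit
#' undefined state with a machine-readable reason.
#'
#' @param value a numeric scalar, or `NA` when undefined
#' @param reason `NULL` when defined, else one of
#'   `"no-male-degree-variance"`, `"no-female-degree-variance"`,
#'   `"no-edge-end-variance"`, `"empty-network"`.
#' @return an object of class `metric_value`
#' @export
metric_value <- function(value, reason = NULL) {
  reasons <- c("no-male-degree-variance", "no-female-degree-variance",
               "no-edge-end-variance", "empty-network")
  if (!is.null(reason)) {
    reason <- match.arg(reason, reasons)
    value <- NA_real_
  } else if (is.na(value)) {
    stop("a defined metric_value needs a non-missing value")
  }
  structure(list(value = as.numeric(value), reason = reason),
            class = "metric_value")
}

#' @rdname metric_value
#' @param x a `metric_value`
#' @export
is_undefined <- function(x) !is.null(x$reason)

#' @export
print.metric_value <- function(x, ...) {
  if (is_undefined(x)) cat(sprintf("NA:%s\n", x$reason))
  else cat(format(x$value), "\n")
  invisible(x)
}

#' @export
format.metric_value <- function(x, digits = 3, ...) {
  if (is_undefined(x)) paste0("NA:", x$reason)
  else formatC(x$value, digits = digits, format = "f")
}

#' Degree pairs at the two ends of every edge
#'
#' The raw material of Newman's assortativity: for each edge, the mating
#' success (degree) of the male and of the female it connects. In directed
#' mode each copulation contributes one (male degree, female degree) pair,
#' viewed along the male's outgoing link. In undirected mode every link is
#' mutual and is read from both ends, so the list is the directed list
#' concatenated with its coordinate swap (2E pairs).
#'
#' @param net a [mating_network]
#' @param mode `"directed"` or `"undirected"`
#' @return two-column matrix (`j`, `k`) of degrees, one row per oriented
#'   edge
#' @export
edge_trait_pairs <- function(net, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  d <- degrees(net)
  if (d$n_edges < 1L) stop("empty network: no edges")
  cells <- which(net$incidence == 1L, arr.ind = TRUE)
  # order edges male-by-male for reproducibility of the pair list
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  pairs <- cbind(j = unname(d$male_degrees[cells[, 1L]]),
                 k = unname(d$female_degrees[cells[, 2L]]))
  if (mode == "undirected") pairs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
  pairs
}

# Pearson correlation in the population-moment form
#   r = (S_jk - S_j S_k / E) / sqrt((S_jj - S_j^2/E)(S_kk - S_k^2/E))
# Correlation is scale invariant, so this agrees with any consistent
# normalisation (sample or population); returns NA when a coordinate has
# zero variance.
moment_correlation <- function(j, k) {
  E <- length(j)
  num <- sum(j * k) - sum(j) * sum(k) / E
  vj <- sum(j^2) - sum(j)^2 / E
  vk <- sum(k^2) - sum(k)^2 / E
  if (vj <= 0 || vk <= 0) return(NA_real_)
  num / sqrt(vj * vk)
}

#' Newman's assortativity by mating success
#'
#' The Pearson correlation between the degrees at the two ends of an edge,
#' across all edges of the network. Positive values mean males with many
#' partners tend to mate with highly polyandrous females (assortative),
#' negative values the opposite (disassortative). The directed variant
#' counts each copulation once (male to female); the undirected variant
#' reads every link from both ends, which lets it respond to between-sex
#' differences in mean mating success even when one sex shows no variance.
#'
#' Individuals that never mated carry no edges and therefore never enter
#' the computation.
#'
#' @inheritParams edge_trait_pairs
#' @return a [metric_value] in `[-1, 1]`; undefined with reason
#'   `"no-edge-end-variance"` (undirected), or the per-sex reason
#'   (directed) when the degrees on one side of all edges are constant.
#' @examples
#' net <- mating_network(rbind(c(1, 1), c(1, 0)))
#' newman_assortativity(net, "directed")    # -0.5
#' @export
newman_assortativity <- function(net, mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  pairs <- edge_trait_pairs(net, mode)
  r <- moment_correlation(pairs[, 1L], pairs[, 2L])
  if (is.na(r)) {
    if (mode == "undirected") return(metric_value(NA, "no-edge-end-variance"))
    vj <- stats::var(pairs[, 1L]); vk <- stats::var(pairs[, 2L])
    if (is.na(vj)) vj <- 0              # single edge: both ends constant
    if (is.na(vk)) vk <- 0
    reason <- if (vj == 0 && vk == 0) "no-edge-end-variance"
              else if (vj == 0) "no-male-degree-variance"
              else "no-female-degree-variance"
    return(metric_value(NA, reason))
  }
  metric_value(r)
}

#' Nestedness by overlap and decreasing fill (NODF)
#'
#' A mating network is nested when the partners of individuals with low
#' mating success form subsets of the partners of individuals with higher
#' mating success -- the signature of disassortative mating. Rows and
#' columns are first ordered by decreasing degree; then for every ordered
#' pair (upper `i`, lower `j`) of rows, and likewise of columns:
#' decreasing fill `DF_ij` is 100 if the lower degree is strictly smaller
#' (ties give 0), percentage overlap `PO_ij` is the percentage of the
#' lower individual's partners shared with the upper, and the pair
#' nestedness is `N_ij = PO_ij` if `DF_ij = 100`, else 0. NODF is the sum
#' of `N_ij` over all row and column pairs divided by
#' `m(m-1)/2 + f(f-1)/2`, giving a 0-100 scale.
#'
#' Because tied degrees contribute 0 regardless of order, the result does
#' not depend on how ties are broken, nor on the input row/column order.
#' Unmated individuals are dropped before computation; a pair whose lower
#' member would have degree 0 is assigned `PO = 0` (division guard).
#'
#' @param net a [mating_network]
#' @param detail if `TRUE` (default) return per-pair `DF`, `PO`, `N`
#'   tables alongside the aggregate; `FALSE` returns just the number.
#' @return with `detail`, an object of class `nodf_detail`: `nodf`
#'   (aggregate), `row_order`/`col_order` (permutations of the original
#'   indices by decreasing degree), and data frames `row_pairs` and
#'   `col_pairs`; otherwise a single number in `[0, 100]`.
#' @examples
#' staircase <- mating_network(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0)))
#' nodf(staircase, detail = FALSE)   # 100: perfect nesting
#' @export
nodf <- function(net, detail = TRUE) {
  net <- drop_unmated(net)
  A <- net$incidence
  if (nrow(A) < 2L && ncol(A) < 2L)
    stop("NODF needs at least two rows or two columns")
  if (!detail) {
    return(nodf_sum(A, rowSums(A)) + nodf_sum(t(A), colSums(A)))
  }
  row_order <- order(-rowSums(A))
  col_order <- order(-colSums(A))
  B <- A[row_order, col_order, drop = FALSE]
  rp <- nodf_pairs(B, rowSums(B), net$male_ids[row_order])
  cp <- nodf_pairs(t(B), colSums(B), net$female_ids[col_order])
  denom <- pair_count(nrow(A)) + pair_count(ncol(A))
  structure(
    list(nodf = (sum(rp$N) + sum(cp$N)) / denom,
         row_order = row_order, col_order = col_order,
         row_pairs = rp, col_pairs = cp),
    class = "nodf_detail"
  )
}

pair_count <- function(n) n * (n - 1) / 2

# Aggregate contribution of all row pairs of A, already divided by the
# total pair-count denominator. Vectorised: shared-partner counts come
# from the overlap matrix A A^T.
nodf_sum <- function(A, deg) {
  m <- nrow(A)
  denom <- pair_count(m) + pair_count(ncol(A))
  if (m < 2L) return(0)
  ov <- tcrossprod(A)
  tot <- 0
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    lo <- if (deg[j] <= deg[i]) j else i
    hi <- if (lo == j) i else j
    if (deg[lo] < deg[hi] && deg[lo] > 0)
      tot <- tot + 100 * ov[hi, lo] / deg[lo]
  }
  unname(tot / denom)
}

# Per-pair DF/PO/N table for rows of B (B already sorted by decreasing
# row degree, so i < j means upper/lower).
nodf_pairs <- function(B, deg, ids) {
  m <- nrow(B)
  if (m < 2L) {
    return(data.frame(upper = character(), lower = character(),
                      DF = numeric(), PO = numeric(), N = numeric()))
  }
  ov <- tcrossprod(B)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  DF <- ifelse(deg[j] < deg[i], 100, 0)
  PO <- ifelse(deg[j] > 0, 100 * ov[cbind(i, j)] / deg[j], 0)
  data.frame(upper = ids[i], lower = ids[j], DF = DF, PO = PO,
             N = ifelse(DF == 100, PO, 0), stringsAsFactors = FALSE)
}

#' @export
print.nodf_detail <- function(x, ...) {
  cat(sprintf("NODF = %.3f (%d row pairs, %d column pairs)\n",
              x$nodf, nrow(x$row_pairs), nrow(x$col_pairs)))
  invisible(x)
}

#' Sperm competition intensity per male
#'
#' Under a fair-raffle null model of sperm competition (every competing
#' male's ejaculate has the same chance per ovum), a focal male's expected
#' paternity share with female `j` is `1/k_j`, the reciprocal of her
#' mating success. His mean share across partners is
#' `s_i = (1/M_i) * sum_j 1/k_j`, and his sperm competition intensity is
#' the harmonic mean of his partners' mating successes,
#' `SCI_i = 1/s_i` -- the effective number of competitors (including
#' himself) his ejaculates face. A male whose partners are all monandrous
#' has `SCI = 1`.
#'
#' In weighted mode each copulation counts as one raffle ticket:
#' `s_i = (1/M_i) * sum_j w_ij / W_j`, with `w_ij` the pair's copulation
#' count and `W_j` the female's total. Repeated copulation with a female
#' then raises the male's share with her above `1/k_j`.
#'
#' @param net a [mating_network]
#' @param weighted use copulation counts (requires a weighted network)
#' @return object of class `sci_result`: numeric vectors `sci` and
#'   `share` named by male id (`NA` for males that never mated, with
#'   ids in `undefined_males`), plus the `weighted` flag.
#' @examples
#' # focal male A: one monandrous partner, one partner with 3 mates
#' net <- from_edge_list(data.frame(
#'   male_id = c("A", "A", "B", "C"),
#'   female_id = c("x", "y", "y", "y")))
#' sperm_competition_intensity(net)$sci["A"]   # 1.5
#' @export
sperm_competition_intensity <- function(net, weighted = FALSE) {
  if (weighted && is.null(net$weights))
    stop("weighted SCI needs a network with copulation counts")
  d <- degrees(net)
  M <- d$male_degrees
  mated <- M > 0
  share <- rep(NA_real_, length(M))
  if (weighted) {
    W <- colSums(net$weights)
    ticket <- sweep(net$weights, 2L, pmax(W, 1L), "/")
    share[mated] <- (ticket %*% rep(1, ncol(ticket)))[mated] / M[mated]
  } else {
    invk <- ifelse(d$female_degrees > 0, 1 / d$female_degrees, 0)
    share[mated] <- (net$incidence %*% invk)[mated] / M[mated]
  }
  sci <- 1 / share
  names(sci) <- names(share) <- net$male_ids
  structure(
    list(sci = sci, share = share, weighted = weighted,
         undefined_males = net$male_ids[!mated]),
    class = "sci_result"
  )
}

#' @export
print.sci_result <- function(x, ...) {
  cat(sprintf("SCI (%s) for %d males", if (x$weighted) "weighted" else "unweighted",
              length(x$sci)), "\n")
  print(round(x$sci, 3))
  invisible(x)
}

#' Sperm competition intensity correlation (SCIC)
#'
#' The association, across mated males, between a male's mating success
#' `M_i` and the sperm competition intensity `SCI_i` faced by his
#' ejaculates. A positive SCIC means successful males also face the most
#' intense sperm competition, which flattens the male Bateman gradient; a
#' negative SCIC steepens it.
#'
#' Two standardisations are provided. `"correlation"` (default) is the
#' Pearson correlation of `(M_i, SCI_i)`, the form obtained when both
#' variables are z-scored as for selection gradients on phenotypic
#' traits. `"slope"` is the least-squares slope of mean-standardised SCI
#' on mean-standardised M (both divided by their means, the convention
#' used for Bateman gradients); this is the form that enters the
#' Bateman-gradient decomposition identity (see
#' [bateman_decomposition()]).
#'
#' @param net a [mating_network]
#' @param form `"correlation"` or `"slope"`
#' @param weighted passed to [sperm_competition_intensity()]
#' @return a [metric_value]; undefined with reason
#'   `"no-male-degree-variance"` when all mated males have equal `M`, or
#'   (correlation form only) `"no-female-degree-variance"` when `SCI` is
#'   constant, as happens whenever no female remates.
#' @export
scic <- function(net, form = c("correlation", "slope"), weighted = FALSE) {
  form <- match.arg(form)
  d <- degrees(net)
  mated <- d$male_degrees > 0
  if (sum(mated) < 2L) stop("SCIC needs at least 2 mated males")
  M <- d$male_degrees[mated]
  sci <- sperm_competition_intensity(net, weighted = weighted)$sci[mated]
  if (stats::var(M) == 0) return(metric_value(NA, "no-male-degree-variance"))
  if (form == "correlation") {
    if (stats::var(sci) == 0)
      return(metric_value(NA, "no-female-degree-variance"))
    metric_value(moment_correlation(M, sci))
  } else {
    slope <- ls_slope(sci / mean(sci), M / mean(M))
    metric_value(slope)
  }
}

# least-squares slope of y on x
ls_slope <- function(y, x) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Full metric report for a mating network
#'
#' Computes all assortativity metrics on the mated subnetwork -- Newman's
#' assortativity in undirected and directed form, NODF, and SCIC in both
#' correlation and slope form -- with explicit undefined states where a
#' metric's variance precondition fails. NODF is always defined (0 is a
#' valid value); the correlation-type metrics are undefined exactly when
#' the degrees they correlate show no variance.
#'
#' @param net a [mating_network]
#' @param weighted compute SCIC from copulation counts
#' @return object of class `metric_report`: [metric_value] fields
#'   `r_newman_u`, `r_newman_d`, `nodf`, `scic_corr`, `scic_slope`, plus
#'   the [degrees()] summary (of the mated subnetwork) and the mating
#'   density of the full network.
#' @export
metric_report <- function(net, weighted = FALSE) {
  density <- mating_density(net)
  net <- drop_unmated(net)
  d <- degrees(net)
  n_val <- if (n_males(net) >= 2L || n_females(net) >= 2L)
    metric_value(nodf(net, detail = FALSE)) else metric_value(0)
  sc_corr <- if (n_males(net) >= 2L) scic(net, "correlation", weighted)
             else metric_value(NA, "no-male-degree-variance")
  sc_slope <- if (n_males(net) >= 2L) scic(net, "slope", weighted)
              else metric_value(NA, "no-male-degree-variance")
  structure(
    list(r_newman_u = newman_assortativity(net, "undirected"),
         r_newman_d = newman_assortativity(net, "directed"),
         nodf = n_val, scic_corr = sc_corr, scic_slope = sc_slope,
         degrees = d, density = density, weighted = weighted),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report (density", sprintf("%.3f", x$density), ")\n")
  for (nm in c("r_newman_u", "r_newman_d", "nodf", "scic_corr", "scic_slope"))
    cat(sprintf("  %-11s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @rdname metric_report
#' @param x a `metric_report`
#' @export
report_values <- function(x) {
  vapply(x[c("r_newman_u", "r_newman_d", "nodf", "scic_corr", "scic_slope")],
         function(v) v$value, numeric(1))
}

#' @rdname metric_report
#' @export
report_reasons <- function(x) {
  vapply(x[c("r_newman_u", "r_newman_d", "nodf", "scic_corr", "scic_slope")],
         function(v) if (is_undefined(v)) v$reason else NA_character_,
         character(1))
}
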