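#' Uniform random mating network at fixed size and mating density
#'
#' Draws a binary mating network with exactly
#' `E = round(density * m * f)` edges in which every male and every
#' female mates at least once, uniformly over all incidence matrices
#' satisfying those constraints. Sampling is by rejection: `E` distinct
#' cells are drawn uniformly from the `m x f` grid and the draw is
#' discarded if any individual is left unmated. Conditioning a uniform
#' draw on an event preserves uniformity, so the accepted matrices are
#' exactly uniform on the constrained space; at the densities of
#' interest (>= 25%) rejections are rare.
#'
#' `round()` applies round-half-even; all the stock study configurations
#' give integer `E` so no rounding ambiguity arises.
#'
#' @param n_males,n_females population size per sex (>= 1)
#' @param density target mating density in `(0, 1]`; the implied `E` must
#'   satisfy `max(n_males, n_females) <= E <= n_males * n_females` or the
#'   constraint is infeasible
#' @param seed optional integer seed
#' @param max_rejections abort after this many rejected draws
#' @return a [mating_network] with attributes `rejections` (number of
#'   discarded draws) and `seed`
#' @examples
#' net <- random_mating_network(6, 6, 0.5, seed = 42)
#' degrees(net)$n_edges        # 18
#' min(degrees(net)$male_degrees)  # >= 1 by construction
#' @export
random_mating_network <- function(n_males, n_females, density,
                                  seed = NULL, max_rejections = 100000L) {
  stopifnot(n_males >= 1L, n_females >= 1L, density > 0, density <= 1)
  E <- round(density * n_males * n_females)
  if (E < max(n_males, n_females) || E > n_males * n_females)
    stop(sprintf(
      "infeasible: E = %d edges cannot give every one of %d males and %d females a mate",
      E, n_males, n_females))
  if (!is.null(seed)) set.seed(seed)
  ncell <- n_males * n_females
  rejections <- 0L
  repeat {
    cells <- sample.int(ncell, E)
    # cells are column-major indices into the m x f incidence matrix
    rows <- (cells - 1L) %% n_males + 1L
    cols <- (cells - 1L) %/% n_males + 1L
    if (length(unique.default(rows)) == n_males &&
        length(unique.default(cols)) == n_females) break
    rejections <- rejections + 1L
    if (rejections > max_rejections)
      stop(sprintf(
        "max_rejections exceeded: %d of %d draws rejected; density %.3f is too sparse for %d x %d",
        rejections, rejections + 1L, density, n_males, n_females))
  }
  A <- matrix(0L, n_males, n_females)
  A[cbind(rows, cols)] <- 1L
  net <- mating_network(A)
  attr(net, "rejections") <- rejections
  attr(net, "seed") <- seed
  net
}

#' Archetype mating networks
#'
#' A deterministic library of small model populations used throughout the
#' package's tests and documentation. For males and females to mate
#' assortatively by mating success, three conditions must hold at once:
#' some polyandry (mean female mating success > 1), variance in male
#' mating success, and variance in female mating success. The
#' `cond_*` archetypes each violate at least one condition, so every
#' correlation-type metric should return zero or be undefined on them;
#' the `assort_*` archetypes satisfy all three and realise positive or
#' negative assortment at a range of mating densities.
#'
#' @return named list of [mating_network] objects:
#' \describe{
#'   \item{monogamy}{each male mates one female (identity matrix)}
#'   \item{polygyny}{two harem-holding males, all females monandrous}
#'   \item{polygynandry}{a fully nested staircase: both sexes vary in
#'     mating success and females remate}
#'   \item{cond_monogamy, cond_polygyny_varM, cond_polyandry_novar,
#'     cond_even_polygynandry, cond_polygyny_skew, cond_polyandry_varF}{
#'     the six condition-violating model populations}
#'   \item{assort_sparse_disassortative, assort_disassortative,
#'     assort_dense_disassortative, assort_maximal_disassortative,
#'     assort_perfect_positive, assort_imperfect_positive}{six
#'     assorted populations; the `perfect_positive` one is a block
#'     structure whose directed assortativity and SCIC both equal 1}
#' }
#' @export
archetype_fixtures <- function() {
  inc <- function(...) mating_network(rbind(...))
  staircase <- function(n) {
    A <- matrix(0L, n, n)
    for (i in seq_len(n)) A[i, seq_len(n + 1L - i)] <- 1L
    mating_network(A)
  }
  # perfect positive assortment: complete 3x3 block plus an isolated pair
  block_pos <- matrix(0L, 4, 4)
  block_pos[1:3, 1:3] <- 1L; block_pos[4, 4] <- 1L
  # imperfect positive: two complete blocks plus one cross edge
  block_imp <- matrix(0L, 5, 5)
  block_imp[1:3, 1:3] <- 1L; block_imp[4:5, 4:5] <- 1L; block_imp[1, 4] <- 1L
  # sparse disassortative: one high-M male with monandrous partners, two
  # low-M males sharing one polyandrous female
  sparse_dis <- matrix(0L, 3, 4)
  sparse_dis[1, 1:3] <- 1L; sparse_dis[2:3, 4] <- 1L

  list(
    monogamy = inc(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    polygyny = inc(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1)),
    polygynandry = staircase(4),

    cond_monogamy = inc(c(1, 0, 0, 0), c(0, 1, 0, 0),
                        c(0, 0, 1, 0), c(0, 0, 0, 1)),
    cond_polygyny_varM = inc(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 0),
                             c(0, 0, 0, 0, 0, 1)),
    cond_polyandry_novar = inc(1, 1, 1),
    cond_even_polygynandry = mating_network(matrix(1L, 3, 3)),
    cond_polygyny_skew = inc(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 0, 0),
                             c(0, 0, 0, 0, 1, 0), c(0, 0, 0, 0, 0, 1)),
    cond_polyandry_varF = mating_network(t(rbind(c(1, 1, 1, 0, 0, 0),
                                                 c(0, 0, 0, 1, 1, 0),
                                                 c(0, 0, 0, 0, 0, 1)))),

    assort_sparse_disassortative = mating_network(sparse_dis),
    assort_disassortative = inc(c(1, 1, 1), c(1, 1, 1), c(1, 0, 0)),
    assort_dense_disassortative = staircase(6),
    assort_maximal_disassortative = inc(c(1, 1, 1), c(1, 1, 1), c(1, 1, 0)),
    assort_perfect_positive = mating_network(block_pos),
    assort_imperfect_positive = mating_network(block_imp)
  )
}
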