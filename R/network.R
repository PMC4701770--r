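#' Construct a bipartite mating network
#'
#' A `mating_network` is the universe every metric in this package operates
#' on: a bipartite graph whose two node sets are males and females and whose
#' edges are copulations. It is stored as an `m x f` binary incidence matrix
#' (males are rows, females are columns) with an optional parallel matrix of
#' copulation counts for weighted analyses.
#'
#' @param incidence m x f matrix of 0/1 (1 = the pair copulated at least
#'   once). A matrix of non-negative counts is also accepted when `weights`
#'   is missing: positive cells become edges and the counts become weights.
#' @param weights optional m x f matrix of non-negative integer copulation
#'   counts; must be positive exactly where `incidence` is 1.
#' @param male_ids,female_ids optional character vectors of unique node
#'   labels (lengths m and f). Default labels are `M1..Mm` / `F1..Ff`.
#' @return An object of class `mating_network` with elements `incidence`,
#'   `weights` (may be `NULL`), `male_ids`, `female_ids`.
#' @examples
#' net <- mating_network(rbind(c(1, 1), c(1, 0)))
#' degrees(net)
#' @export
mating_network <- function(incidence, weights = NULL,
                           male_ids = NULL, female_ids = NULL) {
  incidence <- as.matrix(incidence)
  if (nrow(incidence) < 1L || ncol(incidence) < 1L)
    stop("empty network: need at least one male and one female")
  if (any(is.na(incidence)) || any(incidence < 0))
    stop("incidence entries must be non-negative and non-missing")
  if (is.null(weights) && any(incidence > 1)) {
    weights <- incidence
    incidence <- (incidence > 0) + 0L
  }
  if (!all(incidence %in% c(0, 1)))
    stop("incidence entries must be 0 or 1")
  storage.mode(incidence) <- "integer"
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(incidence)))
      stop("weights must have the same dimensions as incidence")
    if (any(weights < 0) || any(weights != round(weights)))
      stop("weights must be non-negative integers")
    if (!all((weights > 0) == (incidence == 1L)))
      stop("weights must be positive exactly where incidence is 1")
    storage.mode(weights) <- "integer"
  }
  m <- nrow(incidence); f <- ncol(incidence)
  male_ids <- check_ids(male_ids, m, "M", "male_ids")
  female_ids <- check_ids(female_ids, f, "F", "female_ids")
  dimnames(incidence) <- list(male_ids, female_ids)
  if (!is.null(weights)) dimnames(weights) <- list(male_ids, female_ids)
  structure(
    list(incidence = incidence, weights = weights,
         male_ids = male_ids, female_ids = female_ids),
    class = "mating_network"
  )
}

check_ids <- function(ids, n, prefix, what) {
  if (is.null(ids)) return(paste0(prefix, seq_len(n)))
  ids <- as.character(ids)
  if (length(ids) != n) stop(sprintf("%s must have length %d", what, n))
  if (anyDuplicated(ids)) stop(sprintf("%s must be unique", what))
  if (any(!nzchar(ids))) stop(sprintf("%s must be non-empty strings", what))
  ids
}

#' @export
print.mating_network <- function(x, ...) {
  d <- degrees(x)
  cat(sprintf("mating_network: %d males x %d females, %d edges (density %.3f)%s\n",
              n_males(x), n_females(x), d$n_edges, mating_density(x),
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

#' @rdname mating_network
#' @param net a `mating_network`
#' @export
n_males <- function(net) nrow(net$incidence)

#' @rdname mating_network
#' @export
n_females <- function(net) ncol(net$incidence)

#' Build a mating network from an edge list
#'
#' Each row records one copulating pair. Duplicate (male, female) rows are
#' merged and their counts summed: repeated copulations between the same
#' pair are biologically meaningful and are kept as edge weights, not
#' errors. Node order follows first appearance in the input.
#'
#' @param rows a data.frame with columns `male_id`, `female_id` and
#'   optionally `count` (positive integers, default 1).
#' @return a [mating_network]; weighted iff any merged count exceeds 1.
#' @examples
#' from_edge_list(data.frame(male_id = c("A", "A", "B"),
#'                           female_id = c("x", "y", "x")))
#' @export
from_edge_list <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) stop("empty network: edge list has no rows")
  if (!all(c("male_id", "female_id") %in% names(rows)))
    stop("edge list needs columns male_id and female_id")
  male <- as.character(rows$male_id)
  female <- as.character(rows$female_id)
  if (any(is.na(male) | !nzchar(male) | is.na(female) | !nzchar(female)))
    stop("ids must be non-empty strings")
  count <- if ("count" %in% names(rows)) suppressWarnings(as.numeric(rows$count))
           else rep(1L, nrow(rows))
  bad <- which(is.na(count) | count <= 0 | count != round(count))
  if (length(bad))
    stop(sprintf("non-positive or non-integer count at row %d", bad[1L]))
  male_ids <- unique(male)
  female_ids <- unique(female)
  w <- matrix(0L, length(male_ids), length(female_ids))
  i <- match(male, male_ids); j <- match(female, female_ids)
  for (r in seq_along(i)) w[i[r], j[r]] <- w[i[r], j[r]] + as.integer(count[r])
  if (all(w %in% c(0L, 1L))) {
    mating_network(w, male_ids = male_ids, female_ids = female_ids)
  } else {
    mating_network((w > 0L) + 0L, weights = w,
                   male_ids = male_ids, female_ids = female_ids)
  }
}

#' Convert a mating network back to an edge list
#'
#' Inverse of [from_edge_list()]: one row per edge in row-major order of
#' first appearance, with the copulation count (1 for unweighted networks).
#'
#' @param net a [mating_network]
#' @return data.frame with columns `male_id`, `female_id`, `count`.
#' @export
to_edge_list <- function(net) {
  idx <- which(t(net$incidence) == 1L)       # row-major order over males
  j <- (idx - 1L) %% n_females(net) + 1L
  i <- (idx - 1L) %/% n_females(net) + 1L
  count <- if (is.null(net$weights)) rep(1L, length(i))
           else net$weights[cbind(i, j)]
  data.frame(male_id = net$male_ids[i], female_id = net$female_ids[j],
             count = count, stringsAsFactors = FALSE)
}

#' Degree (mating success) summary of a network
#'
#' An individual's node degree is its mating success M: the number of
#' distinct partners. Row sums give male degrees, column sums female
#' degrees; both sum to the edge count E.
#'
#' @param net a [mating_network]
#' @return list of class `degree_summary`: `male_degrees`, `female_degrees`
#'   (named integer vectors), `n_edges`, and per-sex `mean`/`var` of degree
#'   (variance is the sample variance across individuals of that sex).
#' @export
degrees <- function(net) {
  M <- rowSums(net$incidence)
  k <- colSums(net$incidence)
  structure(
    list(male_degrees = M, female_degrees = k, n_edges = sum(M),
         male_mean = mean(M), female_mean = mean(k),
         male_var = stats::var(M), female_var = stats::var(k)),
    class = "degree_summary"
  )
}

#' @export
print.degree_summary <- function(x, ...) {
  cat(sprintf("degrees: E = %d | males mean %.3f var %.3f | females mean %.3f var %.3f\n",
              x$n_edges, x$male_mean, x$male_var, x$female_mean, x$female_var))
  invisible(x)
}

#' Mating density of a network
#'
#' The fraction of all possible male-female pairs that actually mated:
#' `E / (m * f)`, the fill of the incidence matrix. A population of 10
#' males and 10 females in which 50 of the 100 possible pairs mated has
#' mating density 0.5.
#'
#' @param net a [mating_network]
#' @return a proportion in `[0, 1]`
#' @export
mating_density <- function(net) {
  sum(net$incidence) / (n_males(net) * n_females(net))
}

#' Read / write mating networks as CSV
#'
#' Two plain-text formats are supported. Edge list: header
#' `male_id,female_id,count` (`count` optional, default 1). Matrix: first
#' row holds female ids, first column male ids, cells are copulation
#' counts with 0 meaning no edge.
#'
#' @param path file path
#' @param format `"edgelist"` or `"matrix"`
#' @return `read_mating_network` returns a [mating_network];
#'   `write_mating_network` returns `path` invisibly.
#' @export
read_mating_network <- function(path, format = c("edgelist", "matrix")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    from_edge_list(utils::read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = "character"))
  } else {
    tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    w <- as.matrix(tab)
    mating_network(w, male_ids = rownames(tab), female_ids = colnames(tab))
  }
}

#' @rdname read_mating_network
#' @param net a [mating_network]
#' @export
write_mating_network <- function(net, path, format = c("edgelist", "matrix")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.csv(to_edge_list(net), path, row.names = FALSE, quote = FALSE)
  } else {
    w <- if (is.null(net$weights)) net$incidence else net$weights
    utils::write.csv(as.data.frame(w), path, quote = FALSE)
  }
  invisible(path)
}

# Drop individuals that never mated. Metrics operate on mated individuals
# only (non-maters carry no information about who mates with whom).
drop_unmated <- function(net) {
  keep_m <- rowSums(net$incidence) > 0L
  keep_f <- colSums(net$incidence) > 0L
  if (all(keep_m) && all(keep_f)) return(net)
  if (!any(keep_m) || !any(keep_f)) stop("empty network: no edges")
  mating_network(net$incidence[keep_m, keep_f, drop = FALSE],
                 weights = if (is.null(net$weights)) NULL
                           else net$weights[keep_m, keep_f, drop = FALSE],
                 male_ids = net$male_ids[keep_m],
                 female_ids = net$female_ids[keep_f])
}
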