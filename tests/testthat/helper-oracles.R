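# Independent oracles used across the suite. These deliberately share no
# code with the package: the NODF oracle is a literal double loop over
# row/column pairs, and correlation oracles go through stats::cor.

oracle_nodf <- function(A) {
  A <- A[order(-rowSums(A)), , drop = FALSE]
  A <- A[, order(-colSums(A)), drop = FALSE]
  m <- nrow(A); f <- ncol(A)
  tot <- 0
  if (m >= 2) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      Mi <- sum(A[i, ]); Mj <- sum(A[j, ])
      if (Mj < Mi && Mj > 0) tot <- tot + 100 * sum(A[i, ] & A[j, ]) / Mj
    }
  }
  if (f >= 2) {
    for (i in 1:(f - 1)) for (j in (i + 1):f) {
      ki <- sum(A[, i]); kj <- sum(A[, j])
      if (kj < ki && kj > 0) tot <- tot + 100 * sum(A[, i] & A[, j]) / kj
    }
  }
  tot / (m * (m - 1) / 2 + f * (f - 1) / 2)
}

# random binary matrix guaranteed to have at least one edge
random_incidence <- function(m, f, p = 0.5) {
  repeat {
    A <- matrix(rbinom(m * f, 1, p), m, f)
    if (sum(A) > 0) return(A)
  }
}

# the network behind the worked SCI example: focal male A has two
# partners, one monandrous and one with three mates in total
worked_sci_network <- function() {
  from_edge_list(data.frame(
    male_id = c("A", "A", "B", "C"),
    female_id = c("x", "y", "y", "y")))
}
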