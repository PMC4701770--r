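#' Fair-raffle paternity
#'
#' Distributes each female's ova among her mating partners under the
#' fair-raffle null model: every competing male has the same fertilisation
#' chance per ovum (per copulation, if the network is weighted). In
#' deterministic mode a male's reproductive success is his expected value,
#' `T_i = sum_j f_j * w_ij / W_j` over his partners (for unweighted
#' networks `w` is the incidence matrix, giving `f_j / k_j`). In
#' multinomial mode each female's `f_j` ova are assigned independently to
#' her partners with those probabilities, so `sum(T) = sum(f)` holds
#' exactly in both modes.
#'
#' @param net a [mating_network]
#' @param fecundities numeric vector of ova counts, length `n_females(net)`
#'   (recycled if scalar). Fecundity of an unmated female cannot be
#'   assigned and is dropped with a warning.
#' @param mode `"deterministic"` (expected values) or `"multinomial"`
#'   (sampled integer counts)
#' @param seed optional integer seed for multinomial sampling; recorded in
#'   the result for reproducibility
#' @return object of class `reproductive_outcome`: `T` (per-male
#'   reproductive success, named by male id), `fecundities`, `mode`,
#'   `seed`.
#' @examples
#' net <- from_edge_list(data.frame(
#'   male_id = c("A", "A", "B", "C"), female_id = c("x", "y", "y", "y")))
#' fair_raffle_paternity(net, 1)$T[["A"]]   # 1/1 + 1/3 = 4/3
#' @export
fair_raffle_paternity <- function(net, fecundities,
                                  mode = c("deterministic", "multinomial"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  f <- n_females(net)
  if (length(fecundities) == 1L) fecundities <- rep(fecundities, f)
  if (length(fecundities) != f)
    stop(sprintf("fecundities must have length %d", f))
  if (any(is.na(fecundities)) || any(fecundities < 0))
    stop("fecundities must be non-negative")
  w <- if (is.null(net$weights)) net$incidence else net$weights
  W <- colSums(w)
  unmated <- W == 0
  if (any(unmated & fecundities > 0)) {
    warning(sprintf("ignoring fecundity of %d unmated female(s): %s",
                    sum(unmated & fecundities > 0),
                    paste(net$female_ids[unmated & fecundities > 0],
                          collapse = ", ")))
    fecundities[unmated] <- 0
  }
  if (mode == "deterministic") {
    share <- sweep(w, 2L, pmax(W, 1L), "/")
    T_i <- drop(share %*% fecundities)
  } else {
    if (any(fecundities != round(fecundities)))
      stop("multinomial mode needs integer fecundities")
    if (!is.null(seed)) set.seed(seed)
    T_i <- numeric(n_males(net))
    for (j in which(W > 0 & fecundities > 0)) {
      draw <- stats::rmultinom(1L, fecundities[j], prob = w[, j])
      T_i <- T_i + drop(draw)
    }
  }
  names(T_i) <- net$male_ids
  structure(list(T = T_i, fecundities = fecundities, mode = mode,
                 seed = seed),
            class = "reproductive_outcome")
}

#' @export
print.reproductive_outcome <- function(x, ...) {
  cat(sprintf("reproductive_outcome (%s): %d males, total T = %g\n",
              x$mode, length(x$T), sum(x$T)))
  invisible(x)
}

#' Bateman gradient
#'
#' The slope of the least-squares regression of reproductive success `T`
#' on mating success `M` across males: the strength of precopulatory
#' sexual selection on mating success. The conventional
#' `"mean-relative"` standardisation divides both variables by their
#' means first, which makes gradients comparable across populations;
#' `"raw"` regresses the original values.
#'
#' @param T per-male reproductive success
#' @param M per-male mating success
#' @param standardization `"mean-relative"` or `"raw"`
#' @return the slope, or `NA` with a warning when `var(M) = 0`
#' @export
bateman_gradient <- function(T, M, standardization = c("mean-relative", "raw")) {
  standardization <- match.arg(standardization)
  stopifnot(length(T) == length(M))
  if (length(M) < 2L) stop("need at least 2 males")
  if (stats::var(M) == 0) {
    warning("Bateman gradient undefined: no variance in mating success")
    return(NA_real_)
  }
  if (standardization == "mean-relative") {
    T <- T / mean(T)
    M <- M / mean(M)
  }
  ls_slope(T, M)
}

#' Decompose the Bateman gradient into mating and sperm-competition parts
#'
#' When females remate, a male's reproductive success depends both on how
#' many females he mates (`M`) and on the sperm competition intensity his
#' ejaculates face (`SCI`). Fitting the two-predictor regression
#' `T_i = beta_M.SCI * M_i + beta_SCI.M * SCI_i + e_i` separates the two:
#' `beta_M.SCI` is the Bateman gradient controlling for sperm
#' competition, and `beta_SCI.M` (predicted negative by theory) is the
#' marginal cost of competition. Writing `scic_slope` for the simple
#' regression slope of `SCI` on `M`, ordinary least-squares algebra gives
#' the exact decomposition of the univariate gradient
#'
#'   `beta_M = beta_M.SCI + scic_slope * beta_SCI.M`
#'
#' which holds for any standardisation that rescales each variable by a
#' constant (both the raw and the mean-relative convention). The slope
#' form of SCIC -- not the correlation form -- is the term this identity
#' requires, and the identity gap is reported as a numerical check.
#'
#' @param T,M per-male reproductive and mating success
#' @param SCI per-male sperm competition intensity
#'   (see [sperm_competition_intensity()])
#' @param standardization `"mean-relative"` (divide each variable by its
#'   mean; default) or `"raw"`
#' @return object of class `bateman_decomposition`: `beta_M`,
#'   `beta_M_given_SCI`, `beta_SCI_given_M`, `scic_slope`, `residuals`
#'   (from the two-predictor fit), `identity_gap`,
#'   `sci_effect_negative` (is `beta_SCI_given_M < 0`, the theoretical
#'   prediction), and the standardisation used.
#' @export
bateman_decomposition <- function(T, M, SCI,
                                  standardization = c("mean-relative", "raw")) {
  standardization <- match.arg(standardization)
  stopifnot(length(T) == length(M), length(SCI) == length(M))
  if (length(M) < 3L) stop("need at least 3 males")
  if (stats::var(M) == 0) stop("undefined: no variance in mating success")
  if (standardization == "mean-relative") {
    T <- T / mean(T); M <- M / mean(M); SCI <- SCI / mean(SCI)
  }
  if (stats::var(SCI) == 0) {
    # degenerate but well-defined: the SCI term drops out
    beta_M <- ls_slope(T, M)
    fit <- T - mean(T) - beta_M * (M - mean(M))
    return(structure(
      list(beta_M = beta_M, beta_M_given_SCI = beta_M, beta_SCI_given_M = 0,
           scic_slope = 0, residuals = fit, identity_gap = 0,
           sci_effect_negative = FALSE, standardization = standardization),
      class = "bateman_decomposition"))
  }
  X <- cbind(1, M, SCI)
  XtX <- crossprod(X)
  if (rcond_2x2(M, SCI) < 1e-12)
    stop("undefined: M and SCI are collinear (correlation ",
         sprintf("%.6f", stats::cor(M, SCI)), ")")
  coef <- solve(XtX, crossprod(X, T))
  beta_M_given_SCI <- coef[2L]
  beta_SCI_given_M <- coef[3L]
  beta_M <- ls_slope(T, M)
  scic_slope <- ls_slope(SCI, M)
  structure(
    list(beta_M = beta_M,
         beta_M_given_SCI = beta_M_given_SCI,
         beta_SCI_given_M = beta_SCI_given_M,
         scic_slope = scic_slope,
         residuals = drop(T - X %*% coef),
         identity_gap = abs(beta_M - (beta_M_given_SCI +
                                      scic_slope * beta_SCI_given_M)),
         sci_effect_negative = beta_SCI_given_M < 0,
         standardization = standardization),
    class = "bateman_decomposition"
  )
}

# reciprocal condition proxy for the centred 2-predictor design:
# 1 - r^2 of the predictors
rcond_2x2 <- function(M, SCI) 1 - stats::cor(M, SCI)^2

#' @export
print.bateman_decomposition <- function(x, ...) {
  cat(sprintf("Bateman decomposition (%s standardisation)\n", x$standardization))
  cat(sprintf("  beta_M            %10.4f\n", x$beta_M))
  cat(sprintf("  beta_M.SCI        %10.4f\n", x$beta_M_given_SCI))
  cat(sprintf("  beta_SCI.M        %10.4f %s\n", x$beta_SCI_given_M,
              if (x$sci_effect_negative) "(negative, as theory predicts)" else ""))
  cat(sprintf("  SCIC slope        %10.4f\n", x$scic_slope))
  cat(sprintf("  identity gap      %10.2e\n", x$identity_gap))
  invisible(x)
}
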