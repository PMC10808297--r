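# Alpha diversity: observed richness, Chao1, Shannon (natural log).

#' Chao1 richness estimate
#'
#' Chao1 extrapolates observed richness from the counts of singletons and
#' doubletons: S_chao1 = S_obs + n1 (n1 - 1) / (2 (n2 + 1)), where n1 and
#' n2 are the numbers of taxa seen exactly once and exactly twice. The
#' +1 in the denominator is the bias-corrected form and keeps the estimate
#' finite when no doubletons occur. Zeros are ignored. The estimator is
#' only defined on raw integer counts (singleton/doubleton counting is
#' meaningless on rarefied or relative abundances), so non-integer input
#' is refused.
#'
#' @param counts nonnegative integer abundance vector with at least one
#'   positive entry.
#' @return estimated richness (>= observed richness).
#' @examples
#' chao1(c(5, 3, 1, 1, 2))  # 5.5
#' @export
chao1 <- function(counts) {
  .checkCounts(counts)
  if (any(counts != round(counts)))
    stop("chao1 is undefined on non-integer abundances; ",
         "supply raw counts, not proportions or rarefied means")
  pos <- counts[counts > 0]
  sobs <- length(pos)
  n1 <- sum(pos == 1)
  n2 <- sum(pos == 2)
  sobs + n1 * (n1 - 1) / (2 * (n2 + 1))
}

#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over the positive entries, with p_i = n_i / N.
#' Reported in nats; zero-count taxa contribute nothing.
#'
#' @param counts nonnegative abundance vector with at least one positive
#'   entry.
#' @return Shannon index, between 0 and ln(observed richness).
#' @examples
#' shannonIndex(c(10, 10, 10, 10))  # log(4)
#' @export
shannonIndex <- function(counts) {
  .checkCounts(counts)
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

.checkCounts <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative")
  if (all(counts == 0)) stop("all-zero abundance vector")
  invisible(counts)
}

#' Per-sample alpha diversity of a community table
#'
#' @param x a [CommunityExperiment-class].
#' @return data.frame with columns \code{sample_id}, \code{sobs},
#'   \code{chao1}, \code{shannon}. \code{chao1} is only defined on raw
#'   integer counts (see [chao1()]); on non-integer tables it is reported
#'   as NA with one warning rather than aborting the whole table.
#' @export
alphaDiversity <- function(x) {
  m <- counts(x)
  integerCounts <- all(m == round(m))
  if (!integerCounts)
    warning("non-integer abundances: chao1 reported as NA ",
            "(it is only defined on raw counts)")
  data.frame(
    sample_id = colnames(m),
    sobs = apply(m, 2, function(v) sum(v > 0)),
    chao1 = if (integerCounts) apply(m, 2, chao1) else NA_real_,
    shannon = apply(m, 2, shannonIndex),
    row.names = NULL, stringsAsFactors = FALSE)
}
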