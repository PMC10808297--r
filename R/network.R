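# Thresholded Spearman co-occurrence networks across kingdoms.

#' Join kingdom tables into one community object
#'
#' Intersects samples across the supplied tables, stacks the taxa, and
#' records each taxon's kingdom in \code{rowData} so that within- and
#' between-kingdom pairs are all eligible for edges. Clashing taxon names
#' are prefixed with their kingdom.
#'
#' @param tables named list of [CommunityExperiment-class] objects.
#' @return a [CommunityExperiment-class] with a \code{kingdom} rowData
#'   column.
#' @export
bindKingdoms <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L,
            !is.null(names(tables)), all(nzchar(names(tables))))
  common <- Reduce(intersect, lapply(tables, sampleNames))
  if (length(common) < 2L)
    stop("kingdom tables share fewer than 2 samples")
  mats <- lapply(tables, function(x) counts(x)[, common, drop = FALSE])
  taxa <- unlist(lapply(mats, rownames), use.names = FALSE)
  kings <- rep(names(tables), vapply(mats, nrow, 1L))
  if (anyDuplicated(taxa)) taxa <- paste(kings, taxa, sep = ":")
  m <- do.call(rbind, mats)
  rownames(m) <- taxa
  out <- communityExperiment(m, kingdom = "multi", taxaAsRows = TRUE)
  rowData(out)$kingdom <- kings
  out
}

#' Prevalence filter
#'
#' Keeps taxa detected (count above \code{detectionThreshold}) in at
#' least \code{minSamples} samples; the boundary is inclusive. Filtering
#' before correlation screening removes the rare taxa whose rank vectors
#' are dominated by zeros.
#'
#' @param x a [CommunityExperiment-class].
#' @param minSamples minimum number of samples with detection (>= 1).
#' @param detectionThreshold counts strictly above this value count as
#'   detection (default 0: any nonzero count).
#' @return the filtered [CommunityExperiment-class].
#' @export
prevalenceFilter <- function(x, minSamples = 3, detectionThreshold = 0) {
  stopifnot(minSamples >= 1)
  keep <- rowSums(counts(x) > detectionThreshold) >= minSamples
  if (!any(keep))
    stop("prevalence filter removed every taxon; no network possible")
  x[keep, ]
}

.spearmanP <- function(rho, n) {
  # rho-to-t transform, the common large-sample approximation
  p <- rep(0, length(rho))
  ok <- abs(rho) < 1
  t <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  p
}

#' Spearman co-occurrence edges
#'
#' Screens every unordered taxon pair of the table: Spearman's rho is
#' computed as Pearson correlation of mid-ranks (average ranks for
#' ties), and a pair becomes an edge iff |rho| > \code{rThreshold} and
#' p < \code{pThreshold} (both strict). Edge sign is the sign of rho.
#' With \code{pMethod = "t_approx"} (default) p-values use the rho-to-t
#' transform; \code{"exact_smalln"} uses the exact null distribution of
#' the rank statistic (exact for n < 10, high-order approximation
#' beyond, falling back to the t approximation when ties make the exact
#' distribution unavailable), recommended for very small sample numbers.
#' Constant taxa have undefined rho; their pairs are skipped with a
#' message. No multiple-testing correction is applied by default;
#' \code{adjust = "BH"} (or any [stats::p.adjust()] method) applies one
#' across all tested pairs before thresholding.
#'
#' @param x a [CommunityExperiment-class] (prevalence-filter first; a
#'   multi-kingdom object from [bindKingdoms()] yields kingdom-labelled
#'   edges).
#' @param rThreshold correlation-magnitude threshold (default 0.6).
#' @param pThreshold significance threshold (default 0.05).
#' @param pMethod \code{"t_approx"} or \code{"exact_smalln"}.
#' @param adjust multiple-testing method passed to [stats::p.adjust()];
#'   default \code{"none"}.
#' @return data.frame of retained edges with columns \code{source},
#'   \code{target}, \code{rho}, \code{p}, \code{sign},
#'   \code{kingdom_source}, \code{kingdom_target}; attribute
#'   \code{nPairsTested} records the number of screened pairs.
#' @export
spearmanEdges <- function(x, rThreshold = 0.6, pThreshold = 0.05,
                          pMethod = c("t_approx", "exact_smalln"),
                          adjust = "none") {
  pMethod <- match.arg(pMethod)
  m <- counts(x)
  n <- ncol(m)
  if (n < 3L) stop("need at least 3 samples to screen correlations")
  variable <- apply(m, 1, function(v) length(unique(v)) > 1L)
  if (any(!variable))
    message("spearmanEdges: skipping ", sum(!variable),
            " constant taxa (rho undefined): ",
            paste(utils::head(rownames(m)[!variable], 5), collapse = ", "))
  m <- m[variable, , drop = FALSE]
  taxa <- rownames(m)
  kings <- if ("kingdom" %in% names(rowData(x)))
    rowData(x)$kingdom[variable] else rep(NA_character_, nrow(m))
  ranks <- t(apply(m, 1, rank))
  rho <- stats::cor(t(ranks))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  p <- if (pMethod == "t_approx") .spearmanP(r, n) else
    vapply(seq_len(nrow(idx)), function(k) {
      suppressWarnings(stats::cor.test(m[idx[k, 1], ], m[idx[k, 2], ],
                                       method = "spearman",
                                       exact = TRUE)$p.value)
    }, numeric(1))
  p <- stats::p.adjust(p, method = adjust)
  keep <- abs(r) > rThreshold & p < pThreshold
  edges <- data.frame(
    source = taxa[idx[keep, 1]], target = taxa[idx[keep, 2]],
    rho = r[keep], p = p[keep],
    sign = ifelse(r[keep] > 0, "+", "-"),
    kingdom_source = kings[idx[keep, 1]],
    kingdom_target = kings[idx[keep, 2]],
    row.names = NULL, stringsAsFactors = FALSE)
  attr(edges, "nPairsTested") <- nrow(idx)
  attr(edges, "nSamples") <- n
  edges
}

#' Summary statistics of a co-occurrence network
#'
#' Counts nodes (only taxa incident to at least one retained edge),
#' total/positive/negative links, and the average degree 2L/N. An empty
#' edge list yields zeros and an undefined (NA) average degree.
#'
#' @param edges edge data.frame from [spearmanEdges()].
#' @return one-row data.frame with \code{n_nodes}, \code{total_links},
#'   \code{positive_links}, \code{negative_links}, \code{average_degree}.
#' @export
networkSummary <- function(edges) {
  nNodes <- length(unique(c(edges$source, edges$target)))
  pos <- sum(edges$sign == "+")
  neg <- sum(edges$sign == "-")
  data.frame(n_nodes = nNodes, total_links = pos + neg,
             positive_links = pos, negative_links = neg,
             average_degree = if (nNodes > 0) 2 * (pos + neg) / nNodes
                              else NA_real_)
}

#' Convert an edge list to an igraph graph
#'
#' @param edges edge data.frame from [spearmanEdges()].
#' @return an [igraph::graph] with \code{rho}, \code{p}, \code{sign} edge
#'   attributes and \code{kingdom} vertex attributes where known.
#' @export
asIgraph <- function(edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "rho", "p", "sign")], directed = FALSE)
  kk <- c(stats::setNames(edges$kingdom_source, edges$source),
          stats::setNames(edges$kingdom_target, edges$target))
  igraph::V(g)$kingdom <- unname(kk[igraph::V(g)$name])
  g
}

#' Write a network as GraphML
#'
#' @param edges edge data.frame from [spearmanEdges()].
#' @param path output .graphml path.
#' @return invisibly, \code{path}.
#' @export
writeGraphML <- function(edges, path) {
  igraph::write_graph(asIgraph(edges), path, format = "graphml")
  invisible(path)
}

#' Group-level signed associations
#'
#' Spearman associations among the six functional blocks of the
#' micro-food web: total bacteria, total fungi, and the four nematode
#' trophic groups (BF, FF, PP, OP), computed on per-sample group totals.
#' All 15 unordered pairs are reported (no self-pairs); pairs with a
#' constant total are NA. Thresholds are optional: by default every pair
#' is returned with its rho and p.
#'
#' @param bacteria,fungi [CommunityExperiment-class] tables.
#' @param nematodes a [NematodeCommunity-class].
#' @param pMethod as in [spearmanEdges()].
#' @param rThreshold,pThreshold optional; when both given, a
#'   \code{retained} column marks pairs passing the edge rule.
#' @return data.frame with \code{group1}, \code{group2}, \code{rho},
#'   \code{p}, \code{sign} (and \code{retained} if thresholds given).
#' @export
groupAssociations <- function(bacteria, fungi, nematodes,
                              pMethod = c("t_approx", "exact_smalln"),
                              rThreshold = NULL, pThreshold = NULL) {
  pMethod <- match.arg(pMethod)
  groups <- aggregateTrophicGroups(nematodes)
  common <- Reduce(intersect, list(sampleNames(bacteria), sampleNames(fungi),
                                   sampleNames(groups)))
  if (length(common) < 3L) stop("need at least 3 shared samples")
  tot <- rbind(bacteria = colSums(counts(bacteria)[, common, drop = FALSE]),
               fungi = colSums(counts(fungi)[, common, drop = FALSE]),
               counts(groups)[, common, drop = FALSE])
  n <- length(common)
  idx <- which(upper.tri(diag(nrow(tot))), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(idx)), function(k) {
    a <- tot[idx[k, 1], ]; b <- tot[idx[k, 2], ]
    if (length(unique(a)) < 2L || length(unique(b)) < 2L)
      return(c(NA_real_, NA_real_))
    r <- stats::cor(rank(a), rank(b))
    p <- if (pMethod == "t_approx") .spearmanP(r, n) else
      suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                       exact = TRUE)$p.value)
    c(r, p)
  })
  res <- do.call(rbind, res)
  out <- data.frame(group1 = rownames(tot)[idx[, 1]],
                    group2 = rownames(tot)[idx[, 2]],
                    rho = res[, 1], p = res[, 2],
                    sign = ifelse(is.na(res[, 1]), NA_character_,
                                  ifelse(res[, 1] > 0, "+", "-")),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(rThreshold) && !is.null(pThreshold))
    out$retained <- !is.na(out$rho) &
      abs(out$rho) > rThreshold & out$p < pThreshold
  out
}
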