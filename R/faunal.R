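# Nematode faunal analysis: weighted guild components, EI/SI/BI/CI,
# maturity indices, trophic diversity, faunal-profile quadrants.

#' Canonical guild weights of the faunal-analysis framework
#'
#' The Ferris (2001) parameterisation, the standard published weighting of
#' the enrichment/structure framework: the enrichment component weights
#' cp-1 bacterivores (Ba1) by 3.2 and cp-2 fungivores (Fu2) by 0.8; the
#' basal component weights Ba2 and Fu2 by 0.8; the structure component
#' weights free-living cp-3, cp-4 and cp-5 guilds (bacterivore, fungivore,
#' omnivore and carnivore alike) by 1.8, 3.2 and 5.0. Plant parasites
#' enter none of the three components. All weights are configuration, not
#' constants: pass a modified copy to [faunalIndices()] to match an
#' alternative parameterisation.
#'
#' @return list with numeric vectors \code{enrichment} (named by guild
#'   code), \code{basal} (named by guild code), and \code{structural}
#'   (named by c-p class \code{"3"}, \code{"4"}, \code{"5"}).
#' @export
ferrisWeights <- function() {
  list(enrichment = c(Ba1 = 3.2, Fu2 = 0.8),
       basal = c(Ba2 = 0.8, Fu2 = 0.8),
       structural = c(`3` = 1.8, `4` = 3.2, `5` = 5.0))
}

.FREE_LIVING_LETTERS <- c("Ba", "Fu", "Om", "Ca")

#' Weighted guild components of the nematode fauna
#'
#' For each sample, sums guild abundances into the enrichment (e), basal
#' (b) and structure (s) components of the faunal-analysis framework,
#' using the weights of [ferrisWeights()] by default. Also reports the
#' raw (unweighted) Ba1 and Fu2 abundances that the channel index needs.
#' Plant-parasitic taxa are excluded from all three components. A sample
#' with no free-living taxa yields all-zero components (and a warning):
#' its ratio indices will be undefined.
#'
#' @param x a [NematodeCommunity-class].
#' @param weights weight configuration, see [ferrisWeights()].
#' @return data.frame with columns \code{sample_id}, \code{e}, \code{b},
#'   \code{s}, \code{ba1}, \code{fu2}.
#' @export
guildComponents <- function(x, weights = ferrisWeights()) {
  stopifnot(is(x, "NematodeCommunity"))
  m <- counts(x)
  guild <- rowData(x)$guild
  letter <- substr(guild, 1, 2)
  cp <- rowData(x)$cp_class
  gsum <- function(sel) if (any(sel)) colSums(m[sel, , drop = FALSE]) else
    stats::setNames(numeric(ncol(m)), colnames(m))
  e <- b <- s <- stats::setNames(numeric(ncol(m)), colnames(m))
  for (g in names(weights$enrichment))
    e <- e + weights$enrichment[[g]] * gsum(guild == g)
  for (g in names(weights$basal))
    b <- b + weights$basal[[g]] * gsum(guild == g)
  for (cl in names(weights$structural))
    s <- s + weights$structural[[cl]] *
      gsum(letter %in% .FREE_LIVING_LETTERS & cp == as.integer(cl))
  free <- letter %in% .FREE_LIVING_LETTERS
  none <- colSums(m[free, , drop = FALSE]) == 0
  if (any(none))
    warning("no free-living nematodes in sample(s) ",
            paste(colnames(m)[none], collapse = ", "),
            "; faunal indices will be undefined there")
  data.frame(sample_id = colnames(m), e = e, b = b, s = s,
             ba1 = gsum(guild == "Ba1"), fu2 = gsum(guild == "Fu2"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ratios are mathematically in [0,100]; clamp floating-point spill
.ratioIndex <- function(num, den)
  ifelse(den > 0, pmin(100, pmax(0, 100 * num / den)), NA_real_)

#' Enrichment, structure and basal indices from guild components
#'
#' EI = 100 e/(e+b); SI = 100 s/(s+b); BI = 100 b/(e+s+b). An index whose
#' denominator is zero is undefined and reported as NA, never as 0: a
#' basal-only community (BI = 100) and a community with no basal fauna
#' (EI undefined) are different ecological statements.
#'
#' @param comp data.frame from [guildComponents()].
#' @return \code{comp} with added columns \code{EI}, \code{SI}, \code{BI}.
#' @export
enrichmentStructureBasal <- function(comp) {
  comp$EI <- .ratioIndex(comp$e, comp$e + comp$b)
  comp$SI <- .ratioIndex(comp$s, comp$s + comp$b)
  comp$BI <- .ratioIndex(comp$b, comp$e + comp$s + comp$b)
  comp
}

#' Channel index
#'
#' CI = 100 * 0.8 Fu2 / (3.2 Ba1 + 0.8 Fu2) (with the configured
#' enrichment weights): the share of the enrichment-opportunist fauna
#' that flows through the fungal decomposition channel. CI near 100 means
#' fungal-dominated decomposition, near 0 bacterial-dominated. Undefined
#' (NA) when both Ba1 and Fu2 are absent.
#'
#' @param comp data.frame from [guildComponents()].
#' @param weights weight configuration, see [ferrisWeights()].
#' @return numeric vector of CI values.
#' @export
channelIndex <- function(comp, weights = ferrisWeights()) {
  wB <- weights$enrichment[["Ba1"]]
  wF <- weights$enrichment[["Fu2"]]
  .ratioIndex(wF * comp$fu2, wB * comp$ba1 + wF * comp$fu2)
}

#' Maturity indices
#'
#' MI is the abundance-weighted mean c-p class of the free-living fauna
#' (proportions taken within free-living taxa); PPI the same over the
#' plant-parasitic fauna; PPI/MI their ratio. Each lies in [1, 5] when
#' defined; a missing fauna side propagates NA. By default cp-1
#' enrichment opportunists are included in MI; set
#' \code{includeCp1 = FALSE} for the tradition that computes MI on cp 2-5
#' only.
#'
#' @param x a [NematodeCommunity-class].
#' @param includeCp1 include cp-1 free-living taxa in MI?
#' @return data.frame with columns \code{sample_id}, \code{MI},
#'   \code{PPI}, \code{PPI_MI}.
#' @export
maturityIndices <- function(x, includeCp1 = TRUE) {
  stopifnot(is(x, "NematodeCommunity"))
  m <- counts(x)
  cp <- rowData(x)$cp_class
  free <- rowData(x)$trophic_group != "PP"
  if (!includeCp1) free <- free & cp > 1
  pp <- rowData(x)$trophic_group == "PP"
  wmean <- function(sel) {
    tot <- colSums(m[sel, , drop = FALSE])
    ifelse(tot > 0, colSums(m[sel, , drop = FALSE] * cp[sel]) / tot, NA_real_)
  }
  MI <- wmean(free)
  PPI <- wmean(pp)
  data.frame(sample_id = colnames(m), MI = MI, PPI = PPI,
             PPI_MI = PPI / MI, row.names = NULL, stringsAsFactors = FALSE)
}

#' Trophic diversity index
#'
#' Reciprocal Simpson dominance over the four trophic-group proportions:
#' TD = 1 / sum p_g^2. Ranges from 1 (a single group) to 4 (all four
#' groups equally abundant). The framework names the index without
#' printing a formula; the reciprocal-Simpson definition used here is the
#' common one (Heip's interpretation of trophic diversity) and is stated
#' wherever the value is reported.
#'
#' @param groups matrix of group abundances (groups x samples), e.g.
#'   \code{counts(aggregateTrophicGroups(x))}, or a single vector.
#' @return numeric vector of TD values per sample.
#' @export
trophicDiversity <- function(groups) {
  if (is.null(dim(groups))) groups <- matrix(groups, ncol = 1)
  apply(groups, 2, function(v) {
    .checkCounts(v)
    p <- v / sum(v)
    1 / sum(p^2)
  })
}

#' Faunal-profile quadrant of an (EI, SI) point
#'
#' The faunal profile divides the (SI, EI) plane into four quadrants at
#' the 50/50 lines: A (enriched, unstructured: EI >= 50, SI < 50),
#' B (enriched and structured: both >= 50), C (structured, resource-
#' limited: EI < 50, SI >= 50), D (basal/degraded: both < 50). The
#' boundary convention is that 50 counts as high. Undefined EI or SI
#' gives NA.
#'
#' @param EI,SI numeric vectors of equal length.
#' @return character vector of quadrant labels A/B/C/D (NA when
#'   undefined).
#' @export
classifyQuadrant <- function(EI, SI) {
  ifelse(is.na(EI) | is.na(SI), NA_character_,
         ifelse(EI >= 50,
                ifelse(SI >= 50, "B", "A"),
                ifelse(SI >= 50, "C", "D")))
}

#' All faunal indices of a nematode community
#'
#' One call computing, per sample: EI, SI, BI, CI, TD, MI, PPI, PPI/MI
#' and the faunal-profile quadrant. Undefined indices are NA.
#'
#' @param x a [NematodeCommunity-class].
#' @param weights guild weight configuration ([ferrisWeights()] default).
#' @param includeCp1 passed to [maturityIndices()].
#' @return data.frame keyed by \code{sample_id}.
#' @examples
#' \dontrun{
#' nc <- annotateNematodes(readCommunityTable("nematodes.tsv"))
#' faunalIndices(nc)
#' }
#' @export
faunalIndices <- function(x, weights = ferrisWeights(), includeCp1 = TRUE) {
  comp <- enrichmentStructureBasal(guildComponents(x, weights))
  mat <- maturityIndices(x, includeCp1 = includeCp1)
  g <- counts(aggregateTrophicGroups(x))
  # all-zero samples get NA rather than the hard error trophicDiversity()
  # raises on direct vector input
  td <- apply(g, 2, function(v)
    if (all(v == 0)) NA_real_ else trophicDiversity(v))
  data.frame(sample_id = comp$sample_id,
             EI = comp$EI, SI = comp$SI, BI = comp$BI,
             CI = channelIndex(comp, weights),
             TD = td, MI = mat$MI, PPI = mat$PPI, PPI_MI = mat$PPI_MI,
             quadrant = classifyQuadrant(comp$EI, comp$SI),
             row.names = NULL, stringsAsFactors = FALSE)
}
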