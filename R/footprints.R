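# Nematode metabolic footprints and the functional-footprint rhombus.

#' Metabolic footprint contribution of one taxon
#'
#' The carbon flux attributed to Nt individuals of a taxon with mean
#' individual fresh weight Wt (micrograms) and c-p class mt:
#' \deqn{Nt (0.1 Wt / mt + 0.273 Wt^{0.75})}
#' The first term approximates carbon lost to respiration (life-course
#' standardised by the c-p class), the second carbon fixed into
#' production; 0.1 and 0.273 are the standard conversion coefficients of
#' the footprint framework. Strictly increasing in Nt and Wt, strictly
#' decreasing in mt.
#'
#' @param Nt abundance (individuals; nonnegative).
#' @param Wt fresh weight in micrograms (> 0).
#' @param mt c-p class (integer 1..5).
#' @return footprint contribution(s); vectorised over equal-length inputs.
#' @examples
#' taxonFootprint(10, 1, 2)   # 3.23
#' taxonFootprint(1, 16, 4)   # 2.584
#' @export
taxonFootprint <- function(Nt, Wt, mt) {
  if (any(!is.finite(Nt)) || any(Nt < 0)) stop("Nt must be nonnegative")
  if (any(!is.finite(Wt)) || any(Wt <= 0)) stop("Wt must be positive")
  if (!all(mt %in% 1:5)) stop("mt must be a c-p class in 1..5")
  Nt * (0.1 * (Wt / mt) + 0.273 * Wt^0.75)
}

#' Per-sample metabolic footprints of a nematode community
#'
#' Sums [taxonFootprint()] over the taxa of each trophic group (BFMF,
#' FFMF, PPMF, OPMF), their total (TNMF), and the two functional
#' footprints: the enrichment footprint Fe over the enrichment-indicator
#' guilds (Ba1, Fu2 - the fauna that responds fastest to resource pulses)
#' and the structure footprint Fs over the free-living cp 3-5 guilds (the
#' higher-trophic-level fauna). Footprints need absolute abundances:
#' a table annotated as relative is refused unless \code{force = TRUE}.
#'
#' @param x a [NematodeCommunity-class] with absolute abundances.
#' @param force compute anyway on a relative-abundance table (the values
#'   are then footprints per unit of relative abundance, comparable only
#'   within one sample).
#' @return data.frame with columns \code{sample_id}, \code{BFMF},
#'   \code{FFMF}, \code{PPMF}, \code{OPMF}, \code{TNMF}, \code{Fe},
#'   \code{Fs}.
#' @export
groupFootprints <- function(x, force = FALSE) {
  stopifnot(is(x, "NematodeCommunity"))
  if (abundanceType(x) == "relative" && !force)
    stop("metabolic footprints require absolute abundances; this table is ",
         "annotated as relative. Re-annotate with abundance = 'absolute' ",
         "if counts are individuals/reads, or use force = TRUE.")
  m <- counts(x)
  rd <- rowData(x)
  fpPer <- taxonFootprint(1, rd$fresh_weight, rd$cp_class)  # per individual
  contrib <- m * fpPer                                      # taxa x samples
  gsum <- function(sel) colSums(contrib[sel, , drop = FALSE])
  grp <- rd$trophic_group
  letter <- substr(rd$guild, 1, 2)
  out <- data.frame(
    sample_id = colnames(m),
    BFMF = gsum(grp == "BF"), FFMF = gsum(grp == "FF"),
    PPMF = gsum(grp == "PP"), OPMF = gsum(grp == "OP"),
    row.names = NULL, stringsAsFactors = FALSE)
  out$TNMF <- out$BFMF + out$FFMF + out$PPMF + out$OPMF
  out$Fe <- gsum(rd$guild %in% c("Ba1", "Fu2"))
  out$Fs <- gsum(letter %in% .FREE_LIVING_LETTERS & rd$cp_class >= 3)
  out
}

#' Display scaling constant for functional-footprint diamonds
#'
#' The rhombus diagonals are Fe/k and Fs/k; with k = max(Fe, Fs)/50 over
#' the dataset, the largest diamond spans half of the 0-100 faunal plane.
#' The constant is display scaling only; reported areas always state k.
#'
#' @param Fe,Fs numeric vectors of footprints across the dataset.
#' @return a single positive k.
#' @export
autoFootprintK <- function(Fe, Fs) {
  k <- max(Fe, Fs, na.rm = TRUE) / 50
  if (!is.finite(k) || k <= 0) 1 else k
}

#' Functional-footprint rhombus
#'
#' Centres a rhombus at the faunal-profile point (SI, EI) with horizontal
#' vertices at SI +/- 0.5 Fs/k and vertical vertices at EI +/- 0.5 Fe/k;
#' its area Fe*Fs/(2 k^2) (product of the diagonals over two) is the
#' functional metabolic footprint of the community.
#'
#' @param SI,EI centre coordinates (defined faunal indices).
#' @param Fe,Fs enrichment and structure footprints (>= 0).
#' @param k display scaling constant (> 0); see [autoFootprintK()].
#' @return a [FootprintDiamond-class].
#' @examples
#' functionalFootprint(50, 50, Fe = 20, Fs = 10, k = 1)  # area 100
#' @export
functionalFootprint <- function(SI, EI, Fe, Fs, k = 1) {
  stopifnot(length(SI) == 1, length(EI) == 1)
  if (is.na(SI) || is.na(EI)) stop("SI and EI must be defined")
  if (!is.finite(k) || k <= 0) stop("k must be a positive scaling constant")
  if (Fe < 0 || Fs < 0) stop("Fe and Fs must be nonnegative")
  hx <- 0.5 * Fs / k
  hy <- 0.5 * Fe / k
  v <- rbind(left = c(SI - hx, EI), right = c(SI + hx, EI),
             bottom = c(SI, EI - hy), top = c(SI, EI + hy))
  colnames(v) <- c("x", "y")
  new("FootprintDiamond", center = c(SI = SI, EI = EI), k = k,
      Fe = Fe, Fs = Fs, vertices = v, area = Fe * Fs / (2 * k^2))
}

#' @rdname functionalFootprint
#' @param object a [FootprintDiamond-class].
#' @export
diamondArea <- function(object) object@area

#' @rdname functionalFootprint
#' @export
diamondVertices <- function(object) object@vertices

#' Diamonds for every sample of a results table
#'
#' Joins per-sample faunal indices and footprints, picks a common k
#' (\code{"auto"} = [autoFootprintK()] over the dataset) and returns the
#' per-sample diamond geometry.
#'
#' @param indices data.frame from [faunalIndices()].
#' @param footprints data.frame from [groupFootprints()].
#' @param k numeric constant or \code{"auto"}.
#' @return data.frame with \code{sample_id}, \code{SI}, \code{EI},
#'   \code{Fe}, \code{Fs}, \code{k}, \code{diamond_area}.
#' @export
footprintDiamonds <- function(indices, footprints, k = "auto") {
  d <- merge(indices[, c("sample_id", "SI", "EI")],
             footprints[, c("sample_id", "Fe", "Fs")],
             by = "sample_id", sort = FALSE)
  kk <- if (identical(k, "auto")) autoFootprintK(d$Fe, d$Fs) else k
  if (!is.numeric(kk) || kk <= 0) stop("k must be positive or 'auto'")
  d$k <- kk
  d$diamond_area <- ifelse(is.na(d$SI) | is.na(d$EI), NA_real_,
                           d$Fe * d$Fs / (2 * kk^2))
  d
}
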