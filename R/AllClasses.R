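#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata
NULL

#' Nematode trait database
#'
#' Holds genus-level nematode reference traits: feeding (trophic) group,
#' colonizer-persister (c-p) class, and mean individual fresh body weight.
#' These three traits drive every faunal index and metabolic-footprint
#' calculation in the package.
#'
#' Trophic groups use the four-letter-pair convention of soil nematode
#' ecology: \code{BF} bacterivores, \code{FF} fungivores, \code{PP}
#' plant-parasites, \code{OP} omnivores-predators. The c-p class is the
#' Bongers colonizer-persister score (1 = enrichment opportunist,
#' 5 = long-lived persister). Fresh weights are in micrograms per
#' individual.
#'
#' @slot data data.frame with columns \code{genus}, \code{trophic_group},
#'   \code{cp_class}, \code{fresh_weight} and optionally \code{op_subtype}
#'   (\code{"Om"} or \code{"Ca"}, distinguishing omnivores from carnivores
#'   within the OP group for guild coding).
#'
#' @seealso [readTraitTable()], [defaultTraits()], [lookupTrait()]
#' @export
setClass("NematodeTraits", representation(data = "data.frame"))

.TROPHIC_GROUPS <- c("BF", "FF", "PP", "OP")
.FEEDING_LETTER <- c(BF = "Ba", FF = "Fu", PP = "Pp", OP = "Om")

setValidity("NematodeTraits", function(object) {
  d <- object@data
  req <- c("genus", "trophic_group", "cp_class", "fresh_weight")
  if (!all(req %in% names(d)))
    return(paste("missing columns:", paste(setdiff(req, names(d)), collapse = ", ")))
  msgs <- character(0)
  if (anyDuplicated(tolower(trimws(d$genus))))
    msgs <- c(msgs, "duplicate genus names (case-insensitive)")
  if (!all(d$trophic_group %in% .TROPHIC_GROUPS))
    msgs <- c(msgs, "trophic_group must be one of BF, FF, PP, OP")
  if (!all(d$cp_class %in% 1:5))
    msgs <- c(msgs, "cp_class must be an integer in 1..5")
  if (!all(is.finite(d$fresh_weight)) || any(d$fresh_weight <= 0))
    msgs <- c(msgs, "fresh_weight must be positive and finite")
  if ("op_subtype" %in% names(d) &&
      !all(d$op_subtype %in% c("Om", "Ca", NA_character_)))
    msgs <- c(msgs, "op_subtype must be 'Om' or 'Ca'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Community count table for one kingdom
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay named
#' \code{"counts"}: a taxa-by-samples matrix of nonnegative abundances
#' (sequence reads or individual counts). Sample metadata (treatment,
#' replicate) live in \code{colData}; the kingdom label travels with the
#' object.
#'
#' @slot kingdom character scalar, e.g. \code{"bacteria"}, \code{"fungi"},
#'   \code{"nematodes"}; \code{NA} when unknown.
#'
#' @seealso [communityExperiment()], [readCommunityTable()]
#' @export
setClass("CommunityExperiment",
         contains = "SummarizedExperiment",
         representation(kingdom = "character"),
         prototype(kingdom = NA_character_))

setValidity("CommunityExperiment", function(object) {
  if (!"counts" %in% assayNames(object))
    return("must carry an assay named 'counts'")
  m <- assay(object, "counts")
  if (!is.numeric(m)) return("'counts' must be numeric")
  if (nrow(m) < 1L || ncol(m) < 1L) return("need at least 1 taxon and 1 sample")
  if (any(!is.finite(m)) || any(m < 0)) return("'counts' must be finite and nonnegative")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("taxa and samples must be named")
  if (anyDuplicated(rownames(m))) return("duplicate taxon names")
  if (anyDuplicated(colnames(m))) return("duplicate sample IDs")
  if (length(object@kingdom) != 1L) return("kingdom must be a single string")
  TRUE
})

#' Trait-annotated nematode community
#'
#' A [CommunityExperiment-class] whose taxa have all been matched to a
#' [NematodeTraits-class] database. Matched traits (\code{trophic_group},
#' \code{cp_class}, \code{fresh_weight}, \code{guild}) live in
#' \code{rowData}; genera that failed to match are dropped from the table
#' and recorded in \code{unmatched}. The \code{abundanceType} flag records
#' whether counts are absolute (individuals/reads usable as abundance) or
#' relative; metabolic footprints refuse relative tables.
#'
#' @slot unmatched character vector of input genera without trait records.
#' @slot abundanceType \code{"absolute"} or \code{"relative"}.
#'
#' @seealso [annotateNematodes()]
#' @export
setClass("NematodeCommunity",
         contains = "CommunityExperiment",
         representation(unmatched = "character", abundanceType = "character"),
         prototype(unmatched = character(0), abundanceType = "absolute"))

setValidity("NematodeCommunity", function(object) {
  rd <- rowData(object)
  req <- c("trophic_group", "cp_class", "fresh_weight", "guild")
  if (!all(req %in% names(rd)))
    return(paste("rowData must carry", paste(req, collapse = ", ")))
  if (!object@abundanceType %in% c("absolute", "relative"))
    return("abundanceType must be 'absolute' or 'relative'")
  TRUE
})

#' Functional-footprint rhombus
#'
#' The functional metabolic footprint of a nematode community drawn in the
#' faunal-profile plane: a rhombus centred at (SI, EI) whose horizontal
#' diagonal is the structure footprint Fs/k and whose vertical diagonal is
#' the enrichment footprint Fe/k, where k is a display scaling constant.
#' Its area, Fe*Fs/(2*k^2), summarises food-web carbon flux.
#'
#' @slot center numeric (SI, EI).
#' @slot k positive scaling constant.
#' @slot Fe,Fs enrichment and structure footprints.
#' @slot vertices 4x2 matrix: left, right, bottom, top.
#' @slot area rhombus area in plane units squared.
#'
#' @seealso [functionalFootprint()]
#' @export
setClass("FootprintDiamond",
         representation(center = "numeric", k = "numeric",
                        Fe = "numeric", Fs = "numeric",
                        vertices = "matrix", area = "numeric"))

#' Energy-flow reference triangle
#'
#' The fixed equilateral triangle used for ternary energy-flow plots:
#' base from (0,0) to (100,0), apex at (50, 86.6) (100*sin 60 degrees at
#' one decimal). Side midpoints and the centroid complete the seven-point
#' reference frame.
#'
#' @slot vertices 3x2 matrix with rows \code{left}, \code{right},
#'   \code{apex}.
#' @slot midpoints 3x2 matrix of side midpoints.
#' @slot centroid numeric length-2.
#'
#' @seealso [referenceTriangle()], [ternaryToCartesian()]
#' @export
setClass("EnergyTriangle",
         representation(vertices = "matrix", midpoints = "matrix",
                        centroid = "numeric"))

#' Synthetic community simulation configuration
#'
#' Validated parameter bundle for [simulateCommunities()]. See that
#' function for the meaning of each field.
#'
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
         representation(treatments = "character",
                        replicates = "integer",
                        taxaPerKingdom = "integer",
                        guildComposition = "matrix",
                        dispersion = "numeric",
                        librarySize = "numeric",
                        latentFactors = "list",
                        sampleNoiseSd = "numeric",
                        factorAmplitude = "numeric",
                        countNoise = "logical",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (length(object@treatments) < 1L || anyDuplicated(object@treatments))
    msgs <- c(msgs, "treatments must be unique, length >= 1")
  if (object@replicates < 1L) msgs <- c(msgs, "replicates must be >= 1")
  if (!all(c("bacteria", "fungi", "nematodes") %in% names(object@taxaPerKingdom)))
    msgs <- c(msgs, "taxaPerKingdom needs bacteria, fungi, nematodes")
  gc <- object@guildComposition
  if (nrow(gc) != length(object@treatments))
    msgs <- c(msgs, "guildComposition needs one row per treatment")
  if (any(gc < 0) || any(abs(rowSums(gc) - 1) > 1e-8))
    msgs <- c(msgs, "guildComposition rows must be nonnegative and sum to 1")
  if (is.null(colnames(gc)) ||
      !all(grepl("^(Ba|Fu|Om|Ca|Pp)[1-5]$", colnames(gc))))
    msgs <- c(msgs, "guildComposition columns must be guild codes like Ba1, Fu2, Om4, Pp3")
  if (object@dispersion <= 0) msgs <- c(msgs, "dispersion must be > 0")
  if (any(object@librarySize <= 0)) msgs <- c(msgs, "librarySize must be > 0")
  if (object@sampleNoiseSd < 0) msgs <- c(msgs, "sampleNoiseSd must be >= 0")
  if (object@factorAmplitude <= 0) msgs <- c(msgs, "factorAmplitude must be > 0")
  for (f in object@latentFactors) {
    if (!is.list(f) || is.null(f$taxa) || length(f$taxa) < 2L ||
        is.null(f$loading) || f$loading < 0 || f$loading > 1)
      msgs <- c(msgs, "each latent factor needs >= 2 taxa and loading in [0,1]")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
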