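#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("kingdom", function(x) standardGeneric("kingdom"))

#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @export
setGeneric("abundanceType", function(x) standardGeneric("abundanceType"))

#' @export
setGeneric("unmatchedTaxa", function(x) standardGeneric("unmatchedTaxa"))

#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))

#' @export
setGeneric("lookupTrait", function(db, genus) standardGeneric("lookupTrait"))

#' Accessors for community objects
#'
#' \code{counts()} returns the taxa-by-samples count matrix;
#' \code{kingdom()} the kingdom label; \code{taxonNames()} and
#' \code{sampleNames()} the dimension names; \code{abundanceType()} and
#' \code{unmatchedTaxa()} the annotation state of a
#' [NematodeCommunity-class]; \code{traitData()} the underlying
#' data.frame of a [NematodeTraits-class].
#'
#' @param x,object a [CommunityExperiment-class], [NematodeCommunity-class]
#'   or [NematodeTraits-class] as appropriate.
#' @return See details; \code{counts} returns a numeric matrix.
#' @aliases kingdom taxonNames sampleNames abundanceType unmatchedTaxa
#'   traitData counts,CommunityExperiment-method
#' @name community-accessors
NULL

#' @rdname community-accessors
#' @export
setMethod("counts", "CommunityExperiment", function(object) {
  assay(object, "counts")
})

#' @rdname community-accessors
#' @export
setMethod("kingdom", "CommunityExperiment", function(x) x@kingdom)

#' @rdname community-accessors
#' @export
setMethod("taxonNames", "CommunityExperiment", function(x) rownames(x))

#' @rdname community-accessors
#' @export
setMethod("sampleNames", "CommunityExperiment", function(x) colnames(x))

#' @rdname community-accessors
#' @export
setMethod("abundanceType", "NematodeCommunity", function(x) x@abundanceType)

#' @rdname community-accessors
#' @export
setMethod("unmatchedTaxa", "NematodeCommunity", function(x) x@unmatched)

#' @rdname community-accessors
#' @export
setMethod("traitData", "NematodeTraits", function(x) x@data)

setMethod("show", "CommunityExperiment", function(object) {
  cat(sprintf("CommunityExperiment [%s]: %d taxa x %d samples\n",
              ifelse(is.na(object@kingdom), "unknown kingdom", object@kingdom),
              nrow(object), ncol(object)))
  callNextMethod()
})

setMethod("show", "NematodeCommunity", function(object) {
  cat(sprintf("NematodeCommunity (%s abundances): %d matched taxa, %d unmatched; %d samples\n",
              object@abundanceType, nrow(object), length(object@unmatched),
              ncol(object)))
})

setMethod("show", "NematodeTraits", function(object) {
  d <- object@data
  cat(sprintf("NematodeTraits: %d genera (%s)\n", nrow(d),
              paste(sprintf("%s=%d", names(table(d$trophic_group)),
                            as.integer(table(d$trophic_group))), collapse = ", ")))
})

setMethod("show", "FootprintDiamond", function(object) {
  cat(sprintf("FootprintDiamond: center (SI=%.2f, EI=%.2f), Fe=%.3f, Fs=%.3f, k=%.3g, area=%.3f\n",
              object@center[1], object@center[2], object@Fe, object@Fs,
              object@k, object@area))
})

setMethod("show", "EnergyTriangle", function(object) {
  cat("EnergyTriangle: apex", paste(object@vertices["apex", ], collapse = ", "),
      "| base (0,0)-(100,0)\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d treatments x %d replicates, taxa (B/F/N) = %d/%d/%d, seed=%d\n",
              length(object@treatments), object@replicates,
              object@taxaPerKingdom[["bacteria"]],
              object@taxaPerKingdom[["fungi"]],
              object@taxaPerKingdom[["nematodes"]], object@seed))
})
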