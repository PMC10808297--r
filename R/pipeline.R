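# One-call orchestration: tables in, results bundle + manifest out.

.writeTSV <- function(d, path) {
  old <- options(OutDec = ".", scipen = 15)
  on.exit(options(old))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  path
}

#' Run the full micro-food-web analysis
#'
#' Orchestrates every stage over one dataset: alpha diversity per
#' kingdom, nematode faunal indices, metabolic footprints and the
#' functional-footprint diamond, ternary energy-flow coordinates,
#' cross-kingdom co-occurrence network and its summary, and per-treatment
#' means. Writes \code{diversity.tsv}, \code{indices.tsv},
#' \code{footprints.tsv}, \code{ternary.tsv}, \code{edges.tsv},
#' \code{stats.tsv}, \code{treatment_summary.tsv} and
#' \code{manifest.json} into \code{outdir}. Stages that cannot run are
#' skipped with an explicit manifest entry, never silently: footprints
#' (and everything downstream of them) are skipped when counts are
#' relative; missing traits abort with the blocked stage named. The
#' manifest records inputs, their MD5 hashes, configuration, per-stage
#' row counts and warnings; rerunning with identical inputs and
#' configuration reproduces the outputs byte for byte.
#'
#' @param outdir output directory (created if needed).
#' @param bacteria,fungi [CommunityExperiment-class] tables (either may
#'   be NULL; the network stage then uses what is available).
#' @param nematodes a [CommunityExperiment-class] of nematode genera, or
#'   NULL to skip the nematode stages.
#' @param traits a [NematodeTraits-class]; required when
#'   \code{nematodes} is given.
#' @param abundance abundance semantics of the nematode table, passed to
#'   [annotateNematodes()].
#' @param k diamond scaling constant or \code{"auto"}.
#' @param minPrevalence,rThreshold,pThreshold,pMethod network stage
#'   parameters, see [spearmanEdges()].
#' @param simConfig alternatively, a [SimulationConfig-class]: the
#'   pipeline simulates its own inputs with [simulateCommunities()].
#' @return invisibly, a list of all stage results plus the manifest.
#' @export
runPipeline <- function(outdir,
                        bacteria = NULL, fungi = NULL, nematodes = NULL,
                        traits = NULL,
                        abundance = c("absolute", "relative"),
                        k = "auto",
                        minPrevalence = 3, rThreshold = 0.6,
                        pThreshold = 0.05, pMethod = "t_approx",
                        simConfig = NULL) {
  abundance <- match.arg(abundance)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warningsLog <- character(0)
  skipped <- list()
  note <- function(w) warningsLog <<- c(warningsLog, w)

  if (!is.null(simConfig)) {
    sim <- simulateCommunities(simConfig)
    bacteria <- sim$bacteria; fungi <- sim$fungi
    nematodes <- sim$nematodes; traits <- sim$traits
  }
  if (!is.null(nematodes) && is.null(traits))
    stop("stage 'faunal_indices' blocked: nematode table given without a ",
         "trait table")

  results <- list()

  # --- diversity -----------------------------------------------------
  kingdomTables <- Filter(Negate(is.null),
                          list(bacteria = bacteria, fungi = fungi,
                               nematodes = nematodes))
  div <- withCallingHandlers(
    do.call(rbind, lapply(names(kingdomTables), function(nm) {
      cbind(kingdom = nm, alphaDiversity(kingdomTables[[nm]]))
    })),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  results$diversity <- div
  .writeTSV(div, file.path(outdir, "diversity.tsv"))

  # --- faunal indices / footprints / energy flow ---------------------
  if (!is.null(nematodes)) {
    nc <- withCallingHandlers(
      annotateNematodes(nematodes, traits, abundance = abundance),
      message = function(m) { note(conditionMessage(m)); invokeRestart("muffleMessage") })
    idx <- withCallingHandlers(
      faunalIndices(nc),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    results$indices <- idx
    .writeTSV(idx, file.path(outdir, "indices.tsv"))

    if (abundanceType(nc) == "absolute") {
      fp <- groupFootprints(nc)
      dia <- footprintDiamonds(idx, fp, k = k)
      fpOut <- merge(fp, dia[, c("sample_id", "k", "diamond_area")],
                     by = "sample_id", sort = FALSE)
      results$footprints <- fpOut
      .writeTSV(fpOut, file.path(outdir, "footprints.tsv"))

      tern <- ternaryToCartesian(channelFractions(fp))
      results$ternary <- tern
      .writeTSV(tern, file.path(outdir, "ternary.tsv"))
    } else {
      skipped$footprints <- "relative abundances: metabolic footprints need absolute counts"
      skipped$energy_flow <- "skipped with footprints"
      note("footprint and energy-flow stages skipped (relative abundances)")
    }
  } else {
    skipped$faunal_indices <- "no nematode table supplied"
  }

  # --- co-occurrence network ----------------------------------------
  netTables <- kingdomTables
  if (length(netTables) >= 1L &&
      ncol(counts(netTables[[1L]])) >= max(3L, minPrevalence)) {
    merged <- bindKingdoms(netTables)
    filtered <- prevalenceFilter(merged, minSamples = minPrevalence)
    edges <- withCallingHandlers(
      spearmanEdges(filtered, rThreshold = rThreshold,
                    pThreshold = pThreshold, pMethod = pMethod),
      message = function(m) { note(conditionMessage(m)); invokeRestart("muffleMessage") })
    results$edges <- edges
    .writeTSV(edges, file.path(outdir, "edges.tsv"))
    stats <- networkSummary(edges)
    results$stats <- stats
    .writeTSV(stats, file.path(outdir, "stats.tsv"))
  } else {
    skipped$network <- "too few samples for correlation screening"
    note("network stage skipped (too few samples)")
  }

  # --- per-treatment summaries --------------------------------------
  treatmentOf <- function(ids) {
    cd <- as.data.frame(colData(kingdomTables[[1L]]))
    if ("treatment" %in% names(cd)) cd$treatment[match(ids, rownames(cd))]
    else rep(NA_character_, length(ids))
  }
  summarise <- function(d) {
    tr <- treatmentOf(d$sample_id)
    if (all(is.na(tr))) return(NULL)
    num <- names(d)[vapply(d, is.numeric, TRUE)]
    do.call(rbind, lapply(split(seq_len(nrow(d)), tr), function(i) {
      v <- d[i, num, drop = FALSE]
      data.frame(treatment = tr[i[1]],
                 variable = num,
                 mean = vapply(v, function(col) mean(col, na.rm = TRUE), 1),
                 se = vapply(v, function(col) {
                   col <- col[!is.na(col)]
                   if (length(col) > 1) stats::sd(col) / sqrt(length(col)) else NA_real_
                 }, 1),
                 row.names = NULL)
    }))
  }
  summ <- do.call(rbind, Filter(Negate(is.null), lapply(
    Filter(Negate(is.null),
           results[intersect(c("indices", "footprints"), names(results))]),
    summarise)))
  if (!is.null(summ)) {
    results$treatment_summary <- summ
    .writeTSV(summ, file.path(outdir, "treatment_summary.tsv"))
  }

  # --- manifest ------------------------------------------------------
  outputs <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "microfoodweb",
    version = as.character(utils::packageVersion("microfoodweb")),
    config = list(abundance = abundance, k = k,
                  minPrevalence = minPrevalence, rThreshold = rThreshold,
                  pThreshold = pThreshold, pMethod = pMethod,
                  seed = if (!is.null(simConfig)) simConfig@seed else NULL),
    inputs = lapply(kingdomTables, function(x)
      list(taxa = nrow(x), samples = ncol(x), kingdom = kingdom(x))),
    stage_rows = lapply(results, nrow),
    skipped_stages = skipped,
    warnings = warningsLog,
    output_hashes = as.list(tools::md5sum(outputs)))
  names(manifest$output_hashes) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}
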