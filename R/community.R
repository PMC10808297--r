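# Reading, writing, and trait-binding of sample x genus community tables.

#' Build a community object from a count matrix
#'
#' @param counts numeric matrix of nonnegative abundances. By default rows
#'   are samples and columns taxa (the on-disk orientation); set
#'   \code{taxaAsRows = TRUE} if the matrix is already taxa-by-samples.
#' @param kingdom kingdom label carried by the object.
#' @param sampleData optional data.frame of per-sample metadata with a
#'   \code{sample_id} column (one row per sample).
#' @param taxaAsRows orientation flag, see \code{counts}.
#' @return a [CommunityExperiment-class].
#' @export
communityExperiment <- function(counts, kingdom = NA_character_,
                                sampleData = NULL, taxaAsRows = FALSE) {
  m <- as.matrix(counts)
  if (!taxaAsRows) m <- t(m)
  storage.mode(m) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  if (!is.null(sampleData)) {
    if (!"sample_id" %in% names(sampleData))
      stop("sampleData needs a 'sample_id' column")
    i <- match(colnames(m), sampleData$sample_id)
    if (anyNA(i))
      stop("metadata missing for samples: ",
           paste(colnames(m)[is.na(i)], collapse = ", "))
    cd <- S4Vectors::DataFrame(sampleData[i, , drop = FALSE],
                               row.names = colnames(m))
  }
  se <- SummarizedExperiment(assays = S4Vectors::SimpleList(counts = m),
                             colData = cd)
  new("CommunityExperiment", se, kingdom = kingdom)
}

.inferSep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a delimited community count table
#'
#' Reads a rectangular TSV/CSV whose first column holds sample IDs and
#' whose remaining columns are taxa (or the transpose, with
#' \code{taxaAsRows = TRUE}). Ragged rows and negative entries are
#' rejected. The result is orientation-normalised regardless of the file
#' layout.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (\code{.csv} comma, otherwise tab) unless \code{sep} is given.
#' @param taxaAsRows set \code{TRUE} when rows are taxa and columns samples.
#' @param kingdom kingdom label to attach.
#' @param sep field delimiter override.
#' @return a [CommunityExperiment-class].
#' @export
readCommunityTable <- function(path, taxaAsRows = FALSE,
                               kingdom = NA_character_, sep = NULL) {
  sep <- sep %||% .inferSep(path)
  nf <- utils::count.fields(path, sep = sep, quote = "", comment.char = "#")
  if (length(unique(nf)) != 1L)
    stop("ragged table: rows have ", paste(sort(unique(nf)), collapse = "/"),
         " fields in ", path)
  d <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                         comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric abundance entries in ", path)
  if (any(m < 0)) stop("negative abundance in ", path)
  rownames(m) <- ids
  communityExperiment(m, kingdom = kingdom, taxaAsRows = taxaAsRows)
}

#' Write a community table in the canonical dialect
#'
#' Canonical on-disk form: tab-separated, UTF-8, samples as rows, "."
#' decimal separator, no quoting. Reading a written file reproduces the
#' object, and rewriting a freshly read file is byte-identical.
#'
#' @param x a [CommunityExperiment-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCommunityTable <- function(x, path) {
  m <- t(counts(x))
  d <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  old <- options(OutDec = ".", scipen = 15)
  on.exit(options(old))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV/CSV with columns \code{sample_id}, \code{treatment},
#' \code{replicate}.
#'
#' @param path file path.
#' @param sep delimiter override (inferred from extension by default).
#' @return data.frame.
#' @export
readSampleMetadata <- function(path, sep = NULL) {
  sep <- sep %||% .inferSep(path)
  d <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  req <- c("sample_id", "treatment", "replicate")
  if (!all(req %in% names(d)))
    stop("metadata needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in metadata")
  d
}

#' Read a BIOM-format community table
#'
#' Thin wrapper over \pkg{biomformat} exposing BIOM files (JSON or HDF5
#' flavour) through the same [CommunityExperiment-class] contract as the
#' delimited readers.
#'
#' @param path BIOM file.
#' @param kingdom kingdom label to attach.
#' @return a [CommunityExperiment-class].
#' @export
readBiomTable <- function(path, kingdom = NA_character_) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("readBiomTable requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))  # observations (taxa) x samples
  communityExperiment(m, kingdom = kingdom, taxaAsRows = TRUE)
}

#' Bind a nematode community to its trait database
#'
#' Matches each genus (case-insensitive) against the trait database.
#' Matched taxa keep their counts and gain \code{trophic_group},
#' \code{cp_class}, \code{fresh_weight} and \code{guild} columns in
#' \code{rowData}; unmatched genera are excluded from all downstream index
#' math (never imputed) and recorded in the object, with a message
#' reporting the unmatched fraction. A table with no matched genus at all
#' is an error, since every index would be vacuous.
#'
#' @param x a [CommunityExperiment-class] of nematode genera.
#' @param db a [NematodeTraits-class]; defaults to the packaged reference.
#' @param abundance \code{"absolute"} if counts can be treated as absolute
#'   abundances (required by metabolic footprints), \code{"relative"}
#'   otherwise. There is no default heuristic: the caller must assert the
#'   semantics.
#' @return a [NematodeCommunity-class].
#' @export
annotateNematodes <- function(x, db = defaultTraits(),
                              abundance = c("absolute", "relative")) {
  abundance <- match.arg(abundance)
  d <- traitData(db)
  i <- match(.normGenus(taxonNames(x)), .normGenus(d$genus))
  unmatched <- taxonNames(x)[is.na(i)]
  if (all(is.na(i)))
    stop("no genus in the table matches the trait database; ",
         "faunal analysis would be vacuous")
  if (length(unmatched))
    message(sprintf("annotateNematodes: %d/%d genera without traits excluded (%.1f%%): %s",
                    length(unmatched), nrow(x),
                    100 * length(unmatched) / nrow(x),
                    paste(unmatched, collapse = ", ")))
  keep <- !is.na(i)
  sub <- x[keep, ]
  ii <- i[keep]
  rowData(sub)$trophic_group <- d$trophic_group[ii]
  rowData(sub)$cp_class <- d$cp_class[ii]
  rowData(sub)$fresh_weight <- d$fresh_weight[ii]
  rowData(sub)$guild <- guildCode(
    d$trophic_group[ii], d$cp_class[ii],
    if ("op_subtype" %in% names(d)) d$op_subtype[ii] else NULL)
  new("NematodeCommunity", sub, kingdom = x@kingdom,
      unmatched = unmatched, abundanceType = abundance)
}

#' Sum a nematode community into its four trophic groups
#'
#' Collapses the matched taxa of an annotated nematode table into the four
#' trophic groups (BF, FF, PP, OP). Per-sample totals over the groups
#' equal the totals over matched genera, and the result is invariant to
#' taxon order.
#'
#' @param x a [NematodeCommunity-class].
#' @return a [CommunityExperiment-class] with four "taxa" BF, FF, PP, OP.
#' @export
aggregateTrophicGroups <- function(x) {
  stopifnot(is(x, "NematodeCommunity"))
  m <- counts(x)
  g <- factor(rowData(x)$trophic_group, levels = .TROPHIC_GROUPS)
  agg <- rowsum(m, g)  # drops absent levels
  out <- matrix(0, 4L, ncol(m),
                dimnames = list(.TROPHIC_GROUPS, colnames(m)))
  out[rownames(agg), ] <- agg
  communityExperiment(out, kingdom = "nematode_trophic_groups",
                      taxaAsRows = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
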