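# Nematode trait reference: loading, lookup, guild coding.

.normGenus <- function(x) tolower(trimws(x))

#' Read a nematode trait table
#'
#' Reads a tab-separated trait table with header columns \code{genus},
#' \code{trophic_group}, \code{cp_class}, \code{fresh_weight} and an
#' optional \code{op_subtype} column (\code{Om}/\code{Ca}) that refines
#' the guild letter of omnivore-predator genera. Lines starting with
#' \code{#} are comments. All trait invariants (c-p class in 1..5,
#' positive weight, unique genera, valid trophic group) are enforced at
#' load time; violations raise errors naming the offending line.
#'
#' @param path path to a UTF-8 TSV file.
#' @return a [NematodeTraits-class] database.
#' @examples
#' db <- defaultTraits()
#' lookupTrait(db, "Acrobeloides")
#' @export
readTraitTable <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("trait table needs a header and at least one row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  req <- c("genus", "trophic_group", "cp_class", "fresh_weight")
  if (!all(req %in% header))
    stop("trait table header must contain: ", paste(req, collapse = ", "))
  ncols <- length(header)
  rows <- fields[-1L]
  bad <- which(lengths(rows) != ncols)
  if (length(bad))
    stop("malformed trait row at line ", lineNo[-1L][bad[1L]],
         ": expected ", ncols, " fields, got ", lengths(rows)[bad[1L]])
  d <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(d) <- header
  cp <- suppressWarnings(as.numeric(d$cp_class))
  fw <- suppressWarnings(as.numeric(d$fresh_weight))
  if (anyNA(cp) || any(cp != round(cp)))
    stop("non-integer cp_class at line ",
         lineNo[-1L][which(is.na(cp) | cp != round(cp))[1L]])
  if (any(!cp %in% 1:5))
    stop("cp_class outside 1-5 at line ", lineNo[-1L][which(!cp %in% 1:5)[1L]])
  if (anyNA(fw) || any(fw <= 0))
    stop("fresh_weight must be a positive number; offending line ",
         lineNo[-1L][which(is.na(fw) | fw <= 0)[1L]])
  dup <- which(duplicated(.normGenus(d$genus)))
  if (length(dup))
    stop("duplicate genus '", d$genus[dup[1L]], "' at line ", lineNo[-1L][dup[1L]])
  d$genus <- trimws(d$genus)
  d$trophic_group <- trimws(d$trophic_group)
  d$cp_class <- as.integer(cp)
  d$fresh_weight <- fw
  if ("op_subtype" %in% names(d)) {
    d$op_subtype <- trimws(d$op_subtype)
    d$op_subtype[d$op_subtype %in% c("", "NA")] <- NA_character_
  }
  new("NematodeTraits", data = d)
}

#' Write a trait database back to its canonical TSV dialect
#'
#' @param db a [NematodeTraits-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeTraitTable <- function(db, path) {
  utils::write.table(traitData(db), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged nematode trait reference
#'
#' Loads the trait table shipped with the package: 30 common soil nematode
#' genera with trophic group, c-p class, and mean individual fresh weight
#' (micrograms). Feeding-group and c-p assignments follow the standard
#' colonizer-persister literature; fresh weights are implementer-compiled
#' reference values in the style of the Nemaplex expert-system tables and
#' are meant to be replaced by users who maintain their own compilation
#' ([readTraitTable()] accepts any file in the same dialect).
#'
#' @return a [NematodeTraits-class].
#' @export
defaultTraits <- function() {
  readTraitTable(system.file("extdata", "nematode_traits.tsv",
                             package = "microfoodweb", mustWork = TRUE))
}

#' Look up the trait record of a genus
#'
#' Matching is case-insensitive after trimming; there is no fuzzy
#' matching. An unknown genus raises a condition of class
#' \code{"genusMissError"} so callers can convert misses into
#' exclude-and-log behaviour rather than silent zeros.
#'
#' @param db a [NematodeTraits-class].
#' @param genus a single genus name.
#' @return one-row data.frame with the trait record.
#' @export
setMethod("lookupTrait", c("NematodeTraits", "character"), function(db, genus) {
  stopifnot(length(genus) == 1L)
  i <- match(.normGenus(genus), .normGenus(db@data$genus))
  if (is.na(i))
    stop(structure(class = c("genusMissError", "error", "condition"),
                   list(message = paste0("genus '", genus, "' not in trait database"),
                        call = sys.call(-1))))
  db@data[i, , drop = FALSE]
})

#' Guild code of a trophic group / c-p class combination
#'
#' Concatenates the feeding-letter pair with the c-p digit: BF -> Ba,
#' FF -> Fu, PP -> Pp, OP -> Om (or Ca when \code{opSubtype} marks a
#' genus as a carnivore). E.g. a cp-1 bacterivore is \code{Ba1}, a cp-2
#' fungivore \code{Fu2}. Enumerating all four groups over the five c-p
#' classes yields 20 distinct codes.
#'
#' @param trophicGroup character vector in \code{BF, FF, PP, OP}.
#' @param cpClass integer vector in 1..5.
#' @param opSubtype optional character vector (\code{"Om"}/\code{"Ca"}/NA)
#'   overriding the OP letter per element.
#' @return character vector of guild codes.
#' @examples
#' guildCode(c("BF", "FF", "OP"), c(1, 2, 4))  # "Ba1" "Fu2" "Om4"
#' @export
guildCode <- function(trophicGroup, cpClass, opSubtype = NULL) {
  stopifnot(all(trophicGroup %in% .TROPHIC_GROUPS), all(cpClass %in% 1:5))
  letter <- .FEEDING_LETTER[trophicGroup]
  if (!is.null(opSubtype)) {
    ca <- trophicGroup == "OP" & !is.na(opSubtype) & opSubtype == "Ca"
    letter[ca] <- "Ca"
  }
  paste0(letter, cpClass)
}

.guildsOf <- function(db) {
  d <- db@data
  guildCode(d$trophic_group, d$cp_class,
            if ("op_subtype" %in% names(d)) d$op_subtype else NULL)
}
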