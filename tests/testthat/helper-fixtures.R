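# In-code fixture builders shared across test files.

guildTraitTable <- function(guilds, weights = NULL) {
  letter <- substr(guilds, 1, 2)
  cp <- as.integer(substr(guilds, 3, 3))
  group <- c(Ba = "BF", Fu = "FF", Om = "OP", Ca = "OP", Pp = "PP")[letter]
  new("NematodeTraits", data = data.frame(
    genus = paste0("G", guilds),
    trophic_group = unname(group),
    cp_class = cp,
    fresh_weight = if (is.null(weights)) rep(1, length(guilds)) else weights,
    op_subtype = ifelse(letter == "Ca", "Ca",
                        ifelse(group == "OP", "Om", NA_character_)),
    stringsAsFactors = FALSE))
}

# Build an annotated nematode community from per-guild abundances.
# `abund`: matrix samples x guilds (or named vector for one sample);
# one synthetic genus per guild, fresh weight 1 unless given.
ncFromGuilds <- function(abund, weights = NULL, abundance = "absolute") {
  if (is.null(dim(abund))) abund <- matrix(abund, nrow = 1,
                                           dimnames = list("S1", names(abund)))
  guilds <- colnames(abund)
  db <- guildTraitTable(guilds, weights)
  m <- abund
  colnames(m) <- paste0("G", guilds)
  ce <- communityExperiment(m, kingdom = "nematodes")
  suppressMessages(annotateNematodes(ce, db, abundance = abundance))
}

randomGuildMatrix <- function(nSamples, guilds, maxCount = 50) {
  m <- matrix(sample(0:maxCount, nSamples * length(guilds), replace = TRUE),
              nrow = nSamples,
              dimnames = list(sprintf("S%03d", seq_len(nSamples)), guilds))
  m
}

smallCommunityFile <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  m <- matrix(c(5, 0, 3, 2,
                1, 4, 0, 7,
                2, 2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"),
                              c("Acrobeloides", "Filenchus",
                                "Helicotylenchus", "Eudorylaimus")))
  path <- file.path(dir, "toy.tsv")
  writeCommunityTable(communityExperiment(m), path)
  list(path = path, matrix = m)
}
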