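# Synthetic community generator: negative-binomial counts around
# treatment-specific guild compositions, with planted latent-factor
# correlation structure.

#' Default nematode guild composition across a phosphorus gradient
#'
#' Per-treatment target proportions of the five guilds the generator
#' populates (Ba1, Ba2, Fu2, Om4, Pp3). The four-treatment default moves
#' the enrichment fauna from fungal-channel dominance (large Fu2 share,
#' channel index above 60) under no/low phosphorus to bacterial-channel
#' dominance (large Ba1 share, channel index far below 60) under high
#' phosphorus, the canonical pattern for increasing nutrient input. For
#' other treatment counts the schedule is interpolated linearly between
#' the two ends and renormalised.
#'
#' @param treatments character vector of treatment labels.
#' @return matrix (treatments x guilds) of proportions summing to 1 per
#'   row.
#' @export
defaultGuildComposition <- function(treatments = c("CK", "P60", "P120", "P180")) {
  cols <- c("Ba1", "Ba2", "Fu2", "Om4", "Pp3")
  four <- rbind(c(0.050, 0.150, 0.500, 0.150, 0.150),
                c(0.055, 0.170, 0.450, 0.165, 0.160),
                c(0.060, 0.190, 0.400, 0.180, 0.170),
                c(0.350, 0.250, 0.100, 0.150, 0.150))
  nT <- length(treatments)
  m <- if (nT == 4L) four else {
    w <- if (nT == 1L) 0 else seq(0, 1, length.out = nT)
    t(vapply(w, function(a) (1 - a) * four[1, ] + a * four[4, ],
             numeric(5)))
  }
  m <- m / rowSums(m)
  dimnames(m) <- list(treatments, cols)
  m
}

#' Build a validated simulation configuration
#'
#' Defaults emulate a 4-treatment x 3-replicate phosphorus-addition
#' design with genus-level tables for three kingdoms, overdispersed
#' (negative-binomial) counts, and a nematode guild gradient (see
#' [defaultGuildComposition()]).
#'
#' @param treatments treatment labels.
#' @param replicates replicates per treatment.
#' @param taxaPerKingdom named integer vector (\code{bacteria},
#'   \code{fungi}, \code{nematodes}).
#' @param guildComposition treatments-by-guilds proportion matrix; column
#'   names are guild codes (feeding letter pair + c-p digit).
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed; 5 gives the mild overdispersion typical of replicated
#'   amplicon counts).
#' @param librarySize named numeric vector of mean total counts per
#'   sample and kingdom.
#' @param latentFactors list of planted factors, each
#'   \code{list(taxa = c(...), loading = rho)}: the named taxa (IDs such
#'   as \code{"Bacteria007"} or \code{"Nematode03"}, any kingdom mix)
#'   share a latent sample factor inducing monotone association;
#'   \code{loading} is the target pairwise rank (Spearman) correlation of
#'   the latent abundances (count noise attenuates the realised value
#'   toward it from below).
#' @param sampleNoiseSd per-taxon log-scale biological noise SD.
#' @param factorAmplitude log-scale amplitude of planted factor taxa
#'   (1.5 log units: order-of-magnitude abundance swings, typical of
#'   strongly covarying genera).
#' @param countNoise draw negative-binomial counts (\code{TRUE}) or
#'   return the latent means unchanged (\code{FALSE}, useful for
#'   noise-free checks).
#' @param seed integer seed; all randomness flows from it.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(treatments = c("CK", "P60", "P120", "P180"),
                             replicates = 3,
                             taxaPerKingdom = c(bacteria = 100L, fungi = 60L,
                                                nematodes = 25L),
                             guildComposition = defaultGuildComposition(treatments),
                             dispersion = 5,
                             librarySize = c(bacteria = 20000, fungi = 10000,
                                             nematodes = 2000),
                             latentFactors = list(),
                             sampleNoiseSd = 0.6,
                             factorAmplitude = 1.5,
                             countNoise = TRUE,
                             seed = 1) {
  new("SimulationConfig",
      treatments = as.character(treatments),
      replicates = as.integer(replicates),
      taxaPerKingdom = stats::setNames(as.integer(taxaPerKingdom),
                                       names(taxaPerKingdom)),
      guildComposition = guildComposition,
      dispersion = as.numeric(dispersion),
      librarySize = librarySize,
      latentFactors = latentFactors,
      sampleNoiseSd = as.numeric(sampleNoiseSd),
      factorAmplitude = as.numeric(factorAmplitude),
      countNoise = countNoise,
      seed = as.integer(seed))
}

.GUILD_TO_GROUP <- c(Ba = "BF", Fu = "FF", Om = "OP", Ca = "OP", Pp = "PP")
.GROUP_MEANLOG_WEIGHT <- c(BF = log(0.45), FF = log(0.15),
                           OP = log(1.5), PP = log(0.30))

# latent log-noise matrix for one kingdom; factor taxa get correlated
# noise with pairwise latent rank correlation = loading, variance-
# standardised so expected counts are unbiased. Factor sample scores are
# drawn once per simulation (factorScores) and shared across kingdoms so
# cross-kingdom factors induce cross-kingdom association.
.noiseMatrix <- function(taxa, nSamples, cfg, factorScores) {
  z <- matrix(stats::rnorm(length(taxa) * nSamples, 0, cfg@sampleNoiseSd),
              nrow = length(taxa), dimnames = list(taxa, NULL))
  varZ <- rep(cfg@sampleNoiseSd^2, length(taxa))
  for (k in seq_along(cfg@latentFactors)) {
    f <- cfg@latentFactors[[k]]
    hit <- match(intersect(f$taxa, taxa), taxa)
    if (!length(hit)) next
    # loading is the target rank correlation; Greiner's relation converts
    # it to the Pearson correlation of the underlying normals
    rhoP <- min(1, 2 * sin(pi * f$loading / 6))
    for (i in hit) {
      eps <- stats::rnorm(nSamples)
      z[i, ] <- cfg@factorAmplitude *
        (sqrt(rhoP) * factorScores[[k]] + sqrt(1 - rhoP) * eps)
      varZ[i] <- cfg@factorAmplitude^2
    }
  }
  z - varZ / 2  # exp(z) has mean 1 row-wise
}

.drawCounts <- function(expected, noise, cfg) {
  mu <- expected * exp(noise)
  if (!cfg@countNoise) return(mu)
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg@dispersion),
                nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(cnt) <- "double"
  cnt
}

#' Simulate bacteria, fungi and nematode community tables
#'
#' Draws genus-level count tables for the three kingdoms around a
#' treatment design. Nematode taxa are assigned to the guilds of
#' \code{guildComposition} (round-robin, so every populated guild has at
#' least one taxon) with fixed within-guild abundance weights; expected
#' counts are \code{librarySize * proportion}. Bacterial and fungal taxa
#' get fixed log-normal base abundances. Counts are negative-binomial
#' around log-normally perturbed means (mean-corrected so expected totals
#' match \code{librarySize}); planted latent factors give the named taxa
#' correlated log-means with pairwise correlation \code{loading}, which
#' Spearman screening can recover. Output is bit-reproducible from
#' \code{seed}.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements \code{bacteria}, \code{fungi},
#'   \code{nematodes} ([CommunityExperiment-class] objects carrying the
#'   design in \code{colData}), \code{traits}
#'   ([NematodeTraits-class] for the simulated genera), \code{metadata}
#'   (data.frame), \code{expected} (list of noise-free expected count
#'   matrices, taxa x samples), and \code{config}.
#' @examples
#' sim <- simulateCommunities(simulationConfig(seed = 42))
#' sim$nematodes
#' @export
simulateCommunities <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  cfg <- config
  gc <- cfg@guildComposition
  guilds <- colnames(gc)
  nNema <- cfg@taxaPerKingdom[["nematodes"]]
  if (nNema < length(guilds)) {
    covered <- unique(rep(guilds, length.out = nNema))
    missing <- setdiff(guilds[colSums(gc) > 0], covered)
    if (length(missing))
      stop("infeasible composition: no taxa available for guild(s) ",
           paste(missing, collapse = ", "))
  }
  treatments <- rep(cfg@treatments, each = cfg@replicates)
  repl <- rep(seq_len(cfg@replicates), times = length(cfg@treatments))
  samples <- paste(treatments, repl, sep = "_")
  metadata <- data.frame(sample_id = samples, treatment = treatments,
                         replicate = repl, stringsAsFactors = FALSE)
  nS <- length(samples)

  withr::with_seed(cfg@seed, {
    # --- nematodes: guild-structured expected counts ------------------
    taxGuild <- rep(guilds, length.out = nNema)
    nemaTaxa <- sprintf("Nematode%02d", seq_len(nNema))
    within <- stats::rgamma(nNema, shape = 2)
    for (g in guilds) {
      sel <- taxGuild == g
      within[sel] <- within[sel] / sum(within[sel])
    }
    relNema <- gc[treatments, taxGuild, drop = FALSE]
    relNema <- t(relNema) * within           # taxa x samples
    dimnames(relNema) <- list(nemaTaxa, samples)
    expNema <- cfg@librarySize[["nematodes"]] * relNema

    grp <- unname(.GUILD_TO_GROUP[substr(taxGuild, 1, 2)])
    traits <- new("NematodeTraits", data = data.frame(
      genus = nemaTaxa,
      trophic_group = grp,
      cp_class = as.integer(substr(taxGuild, 3, 3)),
      fresh_weight = stats::rlnorm(nNema, .GROUP_MEANLOG_WEIGHT[grp], 0.5),
      op_subtype = ifelse(substr(taxGuild, 1, 2) == "Ca", "Ca",
                          ifelse(grp == "OP", "Om", NA_character_)),
      stringsAsFactors = FALSE))

    # --- bacteria / fungi: fixed log-normal base profiles -------------
    baseExpected <- function(prefix, nTax, lib) {
      taxa <- sprintf("%s%03d", prefix, seq_len(nTax))
      w <- stats::rlnorm(nTax, 0, 1.25)
      rel <- w / sum(w)
      e <- matrix(lib * rel, nrow = nTax, ncol = nS,
                  dimnames = list(taxa, samples))
      e
    }
    expBact <- baseExpected("Bacteria", cfg@taxaPerKingdom[["bacteria"]],
                            cfg@librarySize[["bacteria"]])
    expFung <- baseExpected("Fungi", cfg@taxaPerKingdom[["fungi"]],
                            cfg@librarySize[["fungi"]])

    factorScores <- lapply(cfg@latentFactors,
                           function(f) stats::rnorm(nS))
    cntBact <- .drawCounts(expBact, .noiseMatrix(rownames(expBact), nS, cfg,
                                                 factorScores), cfg)
    cntFung <- .drawCounts(expFung, .noiseMatrix(rownames(expFung), nS, cfg,
                                                 factorScores), cfg)
    cntNema <- .drawCounts(expNema, .noiseMatrix(rownames(expNema), nS, cfg,
                                                 factorScores), cfg)
  })

  asCE <- function(m, kingdom)
    communityExperiment(m, kingdom = kingdom, sampleData = metadata,
                        taxaAsRows = TRUE)
  list(bacteria = asCE(cntBact, "bacteria"),
       fungi = asCE(cntFung, "fungi"),
       nematodes = asCE(cntNema, "nematodes"),
       traits = traits, metadata = metadata,
       expected = list(bacteria = expBact, fungi = expFung,
                       nematodes = expNema),
       config = cfg)
}

#' Simulate a phosphorus-gradient scenario with known ground truth
#'
#' Wraps [simulateCommunities()] in the gradient schedule of
#' [defaultGuildComposition()]: the Fu2 share decreases and the Ba1 share
#' increases monotonically across the treatment sequence, so the channel
#' index decreases and the energy-flow point moves from the fungal toward
#' the bacterial vertex in expectation. The schedule is validated for
#' monotonicity (a custom non-monotone \code{guildComposition} is a
#' configuration error). Ground-truth per-treatment channel fractions,
#' computed from the noise-free expected tables, are returned for
#' recovery tests.
#'
#' @param config a [SimulationConfig-class]; defaults to
#'   \code{simulationConfig(seed = seed)}.
#' @param seed convenience seed used when \code{config} is not supplied.
#' @return As [simulateCommunities()], plus \code{truth}: a list with
#'   \code{channelFractions} (per-treatment expected f_bact/f_fung/
#'   f_plant), \code{CI} (per-treatment expected channel index), and the
#'   \code{guildComposition} schedule.
#' @export
simulatePhosphorusGradient <- function(config = simulationConfig(seed = seed),
                                       seed = 1) {
  stopifnot(is(config, "SimulationConfig"))
  if (length(config@treatments) < 2L)
    stop("a gradient needs at least 2 treatments")
  gc <- config@guildComposition
  fu2 <- gc[, "Fu2"]
  ba1 <- gc[, "Ba1"]
  if (any(diff(fu2) > 1e-12) || any(diff(ba1) < -1e-12))
    stop("non-monotone channel schedule: Fu2 must not increase and Ba1 ",
         "must not decrease along the treatment sequence")
  if (config@replicates == 1L)
    warning("single replicate per treatment: network inference on ",
            "per-treatment tables is not possible")
  sim <- simulateCommunities(config)

  ncExp <- annotateNematodes(
    communityExperiment(sim$expected$nematodes, kingdom = "nematodes",
                        taxaAsRows = TRUE),
    sim$traits, abundance = "absolute")
  fpExp <- groupFootprints(ncExp)
  frExp <- channelFractions(fpExp)
  byTreat <- sim$metadata$treatment[match(frExp$sample_id,
                                          sim$metadata$sample_id)]
  truthFrac <- unique(data.frame(treatment = byTreat,
                                 frExp[, c("f_bact", "f_fung", "f_plant")],
                                 row.names = NULL))
  w <- ferrisWeights()$enrichment
  truthCI <- 100 * w[["Fu2"]] * fu2 / (w[["Ba1"]] * ba1 + w[["Fu2"]] * fu2)
  sim$truth <- list(channelFractions = truthFrac,
                    CI = stats::setNames(truthCI, config@treatments),
                    guildComposition = gc)
  sim
}
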