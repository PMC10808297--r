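smallCfg <- function(...) {
  simulationConfig(taxaPerKingdom = c(bacteria = 12L, fungi = 8L,
                                      nematodes = 10L),
                   librarySize = c(bacteria = 3000, fungi = 2000,
                                   nematodes = 1000), ...)
}

test_that("a fixed seed reproduces tables bit for bit", {
  s1 <- simulateCommunities(smallCfg(seed = 99))
  s2 <- simulateCommunities(smallCfg(seed = 99))
  expect_identical(counts(s1$bacteria), counts(s2$bacteria))
  expect_identical(counts(s1$fungi), counts(s2$fungi))
  expect_identical(counts(s1$nematodes), counts(s2$nematodes))
  expect_identical(traitData(s1$traits), traitData(s2$traits))
  s3 <- simulateCommunities(smallCfg(seed = 100))
  expect_false(identical(counts(s3$nematodes), counts(s1$nematodes)))
})

test_that("the design has the configured shape and metadata", {
  sim <- simulateCommunities(smallCfg(seed = 1))
  expect_equal(ncol(counts(sim$nematodes)), 12)  # 4 treatments x 3 reps
  expect_equal(nrow(counts(sim$bacteria)), 12)
  expect_equal(sort(unique(sim$metadata$treatment)),
               sort(c("CK", "P60", "P120", "P180")))
  expect_equal(colData(sim$nematodes)$treatment, sim$metadata$treatment)
})

test_that("a guild given zero proportion yields zero counts everywhere", {
  gc <- defaultGuildComposition()
  gc[, "Pp3"] <- 0
  gc <- gc / rowSums(gc)
  sim <- simulateCommunities(smallCfg(seed = 5, guildComposition = gc))
  nc <- suppressMessages(annotateNematodes(sim$nematodes, sim$traits))
  pp <- rowData(nc)$trophic_group == "PP"
  expect_true(any(pp))  # taxa exist but never occur
  expect_true(all(counts(nc)[pp, ] == 0))
})

test_that("infeasible compositions and bad factors are configuration errors", {
  expect_error(simulateCommunities(
    simulationConfig(taxaPerKingdom = c(bacteria = 5L, fungi = 5L,
                                        nematodes = 3L))),
    "infeasible")
  expect_error(simulationConfig(latentFactors = list(list(taxa = "only1",
                                                          loading = 0.5))))
  expect_error(simulationConfig(latentFactors = list(
    list(taxa = c("a", "b"), loading = 1.2))))
})

test_that("a loading-1 factor with no count noise gives identical ranks and rho 1", {
  cfg <- smallCfg(seed = 17, treatments = "T", replicates = 10,
                  countNoise = FALSE,
                  latentFactors = list(list(taxa = c("Bacteria001",
                                                     "Bacteria002"),
                                            loading = 1)))
  sim <- simulateCommunities(cfg)
  m <- counts(sim$bacteria)
  expect_equal(rank(m["Bacteria001", ]), rank(m["Bacteria002", ]))
  e <- suppressMessages(spearmanEdges(sim$bacteria))
  hit <- e[e$source == "Bacteria001" & e$target == "Bacteria002", ]
  expect_equal(hit$rho, 1)
})

test_that("faunal indices on noise-free expected tables match closed-form values", {
  cfg <- smallCfg(seed = 23)
  sim <- simulateCommunities(cfg)
  ncExp <- suppressMessages(annotateNematodes(
    communityExperiment(sim$expected$nematodes, taxaAsRows = TRUE),
    sim$traits))
  idx <- faunalIndices(ncExp)
  gc <- cfg@guildComposition
  w <- ferrisWeights()
  tr <- sim$metadata$treatment[match(idx$sample_id, sim$metadata$sample_id)]
  for (t in rownames(gc)) {
    e <- w$enrichment[["Ba1"]] * gc[t, "Ba1"] + w$enrichment[["Fu2"]] * gc[t, "Fu2"]
    b <- w$basal[["Ba2"]] * gc[t, "Ba2"] + w$basal[["Fu2"]] * gc[t, "Fu2"]
    s <- w$structural[["4"]] * gc[t, "Om4"]
    ci <- 100 * w$enrichment[["Fu2"]] * gc[t, "Fu2"] /
      (w$enrichment[["Ba1"]] * gc[t, "Ba1"] + w$enrichment[["Fu2"]] * gc[t, "Fu2"])
    rows <- idx[tr == t, ]
    expect_equal(rows$EI, rep(100 * e / (e + b), nrow(rows)), tolerance = 1e-9)
    expect_equal(rows$SI, rep(100 * s / (s + b), nrow(rows)), tolerance = 1e-9)
    expect_equal(rows$CI, rep(ci, nrow(rows)), tolerance = 1e-9)
  }
})

test_that("mean library size stays within 2 SE of the configured value", {
  sims <- lapply(1:20, function(s) simulateCommunities(smallCfg(seed = 700 + s)))
  tot <- unlist(lapply(sims, function(s) colSums(counts(s$nematodes))))
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - 1000), 2 * se + 1e-9)
})

test_that("the gradient scenario validates its schedule and reports ground truth", {
  g <- simulatePhosphorusGradient(smallCfg(seed = 31))
  expect_named(g$truth, c("channelFractions", "CI", "guildComposition"))
  expect_equal(length(g$truth$CI), 4)
  expect_true(all(diff(g$truth$CI) < 0))
  expect_equal(nrow(g$truth$channelFractions), 4)
  # planted pattern: expected fungal fraction decreases, bacterial increases
  cf <- g$truth$channelFractions
  cf <- cf[match(c("CK", "P60", "P120", "P180"), cf$treatment), ]
  expect_true(all(diff(cf$f_fung) < 0))
  expect_true(all(diff(cf$f_bact) > 0))

  bad <- defaultGuildComposition()
  bad[, "Fu2"] <- rev(bad[, "Fu2"])
  bad <- bad / rowSums(bad)
  expect_error(simulatePhosphorusGradient(smallCfg(guildComposition = bad)),
               "monotone")
  expect_warning(simulatePhosphorusGradient(smallCfg(seed = 2, replicates = 1)),
                 "replicate")
})
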