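ceFromMatrix <- function(m) communityExperiment(m, taxaAsRows = TRUE)

test_that("prevalence filter keeps taxa at the inclusive boundary", {
  m <- rbind(inThree = c(2, 2, 3, 0, 0, 0, 0, 0, 0, 0, 0, 0),
             inTwo = c(1, 2, rep(0, 10)),
             never = rep(0, 12),
             always = rep(1, 12))
  colnames(m) <- sprintf("S%02d", 1:12)
  kept <- taxonNames(prevalenceFilter(ceFromMatrix(m), minSamples = 3))
  expect_setequal(kept, c("inThree", "always"))
  expect_error(prevalenceFilter(ceFromMatrix(m), minSamples = 13), "no network")
  # detection threshold option
  kept2 <- taxonNames(prevalenceFilter(ceFromMatrix(m), minSamples = 3,
                                       detectionThreshold = 1))
  expect_setequal(kept2, "inThree")
})

test_that("perfect monotone and antitone pairs give signed unit-rho edges", {
  base <- c(3, 1, 4, 1.5, 5, 9, 2.6, 7)
  m <- rbind(a = base, b = 2 * base + 1, c = 10 - base)
  colnames(m) <- sprintf("S%d", 1:8)
  e <- spearmanEdges(ceFromMatrix(m))
  key <- paste(e$source, e$target)
  expect_setequal(key, c("a b", "a c", "b c"))
  expect_equal(e$rho[key == "a b"], 1)
  expect_equal(e$sign[key == "a c"], "-")
  expect_equal(e$rho[key == "a c"], -1)
  expect_true(all(e$p == 0))
})

test_that("constant taxa are skipped with a message, not silently dropped pairs", {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6), flat = rep(2, 6), b = c(2, 3, 4, 5, 6, 7))
  colnames(m) <- sprintf("S%d", 1:6)
  expect_message(e <- spearmanEdges(ceFromMatrix(m)), "constant")
  expect_setequal(c(e$source, e$target), c("a", "b"))
})

test_that("retained edge sets equal the brute-force oracle on random tables", {
  withr::local_seed(202)
  for (i in 1:50) {
    m <- matrix(rpois(8 * 15, 6) + round(rnorm(8 * 15), 2), nrow = 15)
    m <- abs(m)
    dimnames(m) <- list(sprintf("t%02d", 1:15), sprintf("s%d", 1:8))
    e <- suppressMessages(spearmanEdges(ceFromMatrix(m)))
    got <- sort(apply(cbind(e$source, e$target), 1,
                      function(r) paste(sort(r), collapse = "|")))
    expect_identical(got, bruteEdgeSet(m, 0.6, 0.05))
  }
})

test_that("edges are invariant to taxon order", {
  withr::local_seed(303)
  m <- matrix(rpois(10 * 12, 5), nrow = 10,
              dimnames = list(sprintf("t%02d", 1:10), sprintf("s%d", 1:12)))
  e1 <- suppressMessages(spearmanEdges(ceFromMatrix(m)))
  perm <- sample(10)
  e2 <- suppressMessages(spearmanEdges(ceFromMatrix(m[perm, ])))
  keyOf <- function(e) sort(apply(cbind(e$source, e$target), 1,
                                  function(r) paste(sort(r), collapse = "|")))
  expect_identical(keyOf(e1), keyOf(e2))
})

test_that("at n = 3 with the t approximation only |rho| = 1 passes p < 0.05", {
  ref <- c(1, 2, 3)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    m <- rbind(a = ref, b = p)
    colnames(m) <- c("s1", "s2", "s3")
    e <- spearmanEdges(ceFromMatrix(m), rThreshold = 0)
    rho <- bruteSpearmanRho(ref, p)
    if (abs(rho) == 1) expect_equal(nrow(e), 1) else expect_equal(nrow(e), 0)
  }
})

test_that("network summary counts incident nodes and signed links", {
  edges <- data.frame(
    source = c("a", "a", "b", "c", "d"),
    target = c("b", "c", "c", "d", "e"),
    rho = c(0.9, 0.8, 0.7, -0.8, -0.9),
    p = rep(0.001, 5),
    sign = c("+", "+", "+", "-", "-"))
  s <- networkSummary(edges)
  expect_equal(s$n_nodes, 5)
  expect_equal(s$total_links, 5)
  expect_equal(s$positive_links, 3)
  expect_equal(s$negative_links, 2)
  expect_equal(s$average_degree, 2)

  s0 <- networkSummary(edges[0, ])
  expect_equal(s0$total_links, 0)
  expect_true(is.na(s0$average_degree))
})

test_that("kingdom labels travel through bindKingdoms into edges", {
  withr::local_seed(404)
  base <- matrix(rpois(4 * 8, 5), nrow = 4,
                 dimnames = list(paste0("b", 1:4), sprintf("s%d", 1:8)))
  fun <- rbind(f1 = base[1, ] + rpois(8, 1), f2 = rpois(8, 5))
  merged <- bindKingdoms(list(bacteria = ceFromMatrix(base),
                              fungi = ceFromMatrix(fun)))
  expect_equal(nrow(merged), 6)
  expect_setequal(unique(rowData(merged)$kingdom), c("bacteria", "fungi"))
  e <- suppressMessages(spearmanEdges(merged, rThreshold = 0.3))
  if (nrow(e) > 0)
    expect_true(all(e$kingdom_source %in% c("bacteria", "fungi")))
})

test_that("group-level associations recover a planted fungal-FF coupling", {
  withr::local_seed(515)
  cfg <- simulationConfig(
    treatments = "T", replicates = 12,
    taxaPerKingdom = c(bacteria = 8L, fungi = 6L, nematodes = 10L),
    librarySize = c(bacteria = 5000, fungi = 4000, nematodes = 1500),
    latentFactors = list(list(taxa = c(sprintf("Fungi%03d", 1:6),
                                       sprintf("Nematode%02d", c(3, 8))),
                              loading = 0.95)),
    seed = 515)
  sim <- simulateCommunities(cfg)
  # Nematode03/08 fall in the Fu2 guild under the default round-robin
  nc <- suppressMessages(annotateNematodes(sim$nematodes, sim$traits))
  expect_true(all(rowData(nc)$guild[match(c("Nematode03", "Nematode08"),
                                          taxonNames(nc))] == "Fu2"))
  ga <- groupAssociations(sim$bacteria, sim$fungi, nc)
  expect_equal(nrow(ga), 15)
  expect_false(any(ga$group1 == ga$group2))
  ff <- ga[(ga$group1 == "fungi" & ga$group2 == "FF") |
           (ga$group1 == "FF" & ga$group2 == "fungi"), ]
  expect_equal(ff$sign, "+")
  expect_gt(ff$rho, 0.5)
})

test_that("GraphML export and igraph conversion keep attributes", {
  edges <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      rho = c(0.9, -0.8), p = c(0.01, 0.02),
                      sign = c("+", "-"),
                      kingdom_source = c("bacteria", "fungi"),
                      kingdom_target = c("fungi", "nematodes"))
  g <- asIgraph(edges)
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::E(g)$sign, c("+", "-"))
  f <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(edges, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
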