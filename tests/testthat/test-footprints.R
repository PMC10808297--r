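test_that("taxon footprint matches hand evaluation of the composite formula", {
  expect_equal(taxonFootprint(0, 5, 2), 0)
  expect_equal(taxonFootprint(10, 1, 2), 3.23)        # 10*(0.05 + 0.273)
  expect_equal(taxonFootprint(1, 16, 4), 2.584)       # 0.4 + 0.273*8
  expect_error(taxonFootprint(1, 0, 2), "positive")
  expect_error(taxonFootprint(1, 1, 6), "c-p")
  expect_error(taxonFootprint(-1, 1, 2))
})

test_that("taxon footprint is monotone in abundance and weight, antitone in c-p", {
  withr::local_seed(21)
  for (i in 1:200) {
    N <- runif(1, 0.1, 100); W <- runif(1, 0.05, 20); m <- sample(1:4, 1)
    expect_gt(taxonFootprint(N + 1, W, m), taxonFootprint(N, W, m))
    expect_gt(taxonFootprint(N, W + 0.5, m), taxonFootprint(N, W, m))
    expect_gt(taxonFootprint(N, W, m), taxonFootprint(N, W, m + 1))
  }
})

test_that("group footprints partition the total and respect guild membership", {
  # single bacterivore with Nt = 10, Wt = 1, cp = 2
  nc <- ncFromGuilds(c(Ba2 = 10), weights = 1)
  fp <- groupFootprints(nc)
  expect_equal(fp$BFMF, 3.23)
  expect_equal(fp$TNMF, 3.23)
  expect_equal(fp$FFMF + fp$PPMF + fp$OPMF, 0)

  # one enrichment-indicator and one structure taxon: Fe and Fs separate
  nc2 <- ncFromGuilds(c(Ba1 = 10, Om4 = 4), weights = c(1, 16))
  fp2 <- groupFootprints(nc2)
  expect_equal(fp2$Fe, 10 * (0.1 / 1 + 0.273))  # the Ba1 term alone
  expect_equal(fp2$Fs, 4 * 2.584)               # the Om4 term alone
  expect_equal(fp2$TNMF, fp2$BFMF + fp2$FFMF + fp2$PPMF + fp2$OPMF)
})

test_that("footprints are additive, order-invariant, and conserved on random draws", {
  withr::local_seed(33)
  guilds <- c("Ba1", "Ba2", "Fu2", "Om4", "Ca5", "Pp3")
  for (i in 1:200) {
    m <- randomGuildMatrix(3, guilds)
    w <- runif(length(guilds), 0.1, 8)
    fp <- groupFootprints(ncFromGuilds(m, weights = w))
    expect_equal(fp$TNMF, fp$BFMF + fp$FFMF + fp$PPMF + fp$OPMF,
                 tolerance = 1e-12)
    perm <- sample(ncol(m))
    fp2 <- groupFootprints(ncFromGuilds(m[, perm, drop = FALSE],
                                        weights = w[perm]))
    expect_equal(fp2, fp, tolerance = 1e-12)
  }
})

test_that("relative-abundance tables are refused unless forced", {
  m <- c(Ba1 = 0.6, Fu2 = 0.4)
  ncRel <- ncFromGuilds(m, abundance = "relative")
  expect_error(groupFootprints(ncRel), "absolute")
  expect_s3_class(groupFootprints(ncRel, force = TRUE), "data.frame")
})

test_that("the functional-footprint rhombus has the stated vertices and area", {
  d <- functionalFootprint(50, 50, Fe = 20, Fs = 10, k = 1)
  v <- diamondVertices(d)
  expect_equal(unname(v["left", ]), c(45, 50))
  expect_equal(unname(v["right", ]), c(55, 50))
  expect_equal(unname(v["bottom", ]), c(50, 40))
  expect_equal(unname(v["top", ]), c(50, 60))
  expect_equal(diamondArea(d), 100)

  expect_equal(diamondArea(functionalFootprint(30, 70, Fe = 0, Fs = 9)), 0)
  # doubling k halves each half-diagonal and quarters the area
  d2 <- functionalFootprint(50, 50, Fe = 20, Fs = 10, k = 2)
  expect_equal(diamondArea(d2), 25)
  expect_equal(diamondVertices(d2)["left", "x"], 47.5)
  expect_error(functionalFootprint(50, 50, 1, 1, k = 0), "positive")
})

test_that("shoelace area of the vertex polygon equals Fe*Fs/(2 k^2)", {
  withr::local_seed(55)
  for (i in 1:200) {
    Fe <- runif(1, 0, 300); Fs <- runif(1, 0, 300); k <- runif(1, 0.1, 10)
    d <- functionalFootprint(runif(1, 0, 100), runif(1, 0, 100), Fe, Fs, k)
    v <- diamondVertices(d)
    poly <- v[c("left", "bottom", "right", "top"), ]
    expect_equal(shoelace(poly), Fe * Fs / (2 * k^2), tolerance = 1e-12)
    expect_equal(diamondArea(d), Fe * Fs / (2 * k^2), tolerance = 1e-12)
  }
})

test_that("auto-k spans the faunal plane and flows through footprintDiamonds", {
  expect_equal(autoFootprintK(c(10, 200), c(50, 80)), 4)
  nc <- ncFromGuilds(rbind(S1 = c(Ba1 = 10, Om4 = 5, Pp3 = 2),
                           S2 = c(Ba1 = 3, Om4 = 9, Pp3 = 1)))
  idx <- faunalIndices(nc)
  fp <- groupFootprints(nc)
  dd <- footprintDiamonds(idx, fp)
  expect_equal(dd$k, rep(autoFootprintK(fp$Fe, fp$Fs), 2))
  expect_equal(dd$diamond_area, dd$Fe * dd$Fs / (2 * dd$k^2))
})
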