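test_that("guild components match hand-weighted sums", {
  c1 <- guildComponents(ncFromGuilds(c(Ba1 = 50, Ba2 = 50)))
  expect_equal(c(c1$e, c1$b, c1$s), c(160, 40, 0))

  c2 <- guildComponents(ncFromGuilds(c(Fu2 = 10)))
  expect_equal(c(c2$e, c2$b, c2$s), c(8, 8, 0))  # Fu2 in both e and b

  c3 <- suppressWarnings(guildComponents(ncFromGuilds(c(Pp3 = 30))))
  expect_equal(c(c3$e, c3$b, c3$s), c(0, 0, 0))
  expect_warning(guildComponents(ncFromGuilds(c(Pp3 = 30))), "free-living")
})

test_that("EI/SI/BI follow the ratio definitions with NA on zero denominators", {
  comp <- enrichmentStructureBasal(
    guildComponents(ncFromGuilds(c(Ba1 = 50, Ba2 = 50))))
  expect_equal(c(comp$EI, comp$SI, comp$BI), c(80, 0, 20))

  onlyBa1 <- enrichmentStructureBasal(guildComponents(ncFromGuilds(c(Ba1 = 9))))
  expect_equal(onlyBa1$EI, 100)
  expect_true(is.na(onlyBa1$SI))  # s + b = 0
  expect_equal(onlyBa1$BI, 0)

  empty <- enrichmentStructureBasal(
    suppressWarnings(guildComponents(ncFromGuilds(c(Pp3 = 5)))))
  expect_true(all(is.na(c(empty$EI, empty$SI, empty$BI))))
})

test_that("channel index separates fungal from bacterial decomposition", {
  ci <- function(x) channelIndex(guildComponents(x))
  expect_equal(ci(ncFromGuilds(c(Ba1 = 10, Fu2 = 10))), 20)  # 100*8/40
  expect_equal(ci(ncFromGuilds(c(Fu2 = 4))), 100)
  expect_equal(ci(ncFromGuilds(c(Ba1 = 4))), 0)
  expect_true(is.na(suppressWarnings(ci(ncFromGuilds(c(Om4 = 4))))))
})

test_that("maturity indices are abundance-weighted mean c-p classes", {
  mi <- maturityIndices(ncFromGuilds(c(Ba2 = 3, Om4 = 1)))
  expect_equal(mi$MI, 2.5)  # (2*3 + 4*1)/4
  expect_true(is.na(mi$PPI))
  expect_true(is.na(mi$PPI_MI))

  both <- maturityIndices(ncFromGuilds(c(Ba2 = 3, Om4 = 1, Pp3 = 7)))
  expect_equal(both$PPI, 3)
  expect_equal(both$PPI_MI, 3 / 2.5)

  nocp1 <- maturityIndices(ncFromGuilds(c(Ba1 = 10, Ba2 = 5, Ba3 = 5)),
                           includeCp1 = FALSE)
  expect_equal(nocp1$MI, 2.5)
})

test_that("trophic diversity spans 1 (single group) to 4 (even groups)", {
  expect_equal(unname(trophicDiversity(c(5, 5, 5, 5))), 4)
  expect_equal(unname(trophicDiversity(c(9, 0, 0, 0))), 1)
  expect_equal(unname(trophicDiversity(c(3, 3, 0, 0))), 2)
  expect_error(trophicDiversity(c(0, 0, 0, 0)))
})

test_that("quadrant classification partitions the plane with >= 50 as high", {
  expect_identical(classifyQuadrant(60, 40), "A")
  expect_identical(classifyQuadrant(40, 60), "C")
  expect_identical(classifyQuadrant(50, 50), "B")
  expect_identical(classifyQuadrant(49.9, 49.9), "D")
  expect_identical(classifyQuadrant(NA, 60), NA_character_)
  # exactly one label for any defined point
  withr::local_seed(5)
  q <- classifyQuadrant(runif(500, 0, 100), runif(500, 0, 100))
  expect_true(all(q %in% c("A", "B", "C", "D")))
})

test_that("percentage indices stay in [0,100] over random communities", {
  withr::local_seed(42)
  guilds <- c("Ba1", "Ba2", "Ba3", "Fu2", "Fu4", "Om4", "Ca5", "Pp2", "Pp3")
  m <- randomGuildMatrix(10000, guilds, maxCount = 30)
  idx <- suppressWarnings(faunalIndices(ncFromGuilds(m)))
  for (col in c("EI", "SI", "BI", "CI")) {
    v <- idx[[col]]
    expect_true(all(v[!is.na(v)] >= 0 & v[!is.na(v)] <= 100))
  }
  expect_true(all(idx$TD[!is.na(idx$TD)] >= 1 - 1e-12))
  ok <- !is.na(idx$MI)
  expect_true(all(idx$MI[ok] >= 1 & idx$MI[ok] <= 5))
})

test_that("EI is scale-invariant and responds monotonically to guild additions", {
  base <- c(Ba1 = 7, Ba2 = 12, Fu2 = 9, Om4 = 3, Pp3 = 5)
  ei <- function(x) enrichmentStructureBasal(guildComponents(ncFromGuilds(x)))$EI
  si <- function(x) enrichmentStructureBasal(guildComponents(ncFromGuilds(x)))$SI
  expect_equal(ei(base * 17), ei(base))
  for (add in c(1, 5, 20)) {
    up <- base; up["Ba1"] <- up["Ba1"] + add
    expect_gte(ei(up), ei(base))
    up2 <- base; up2["Om4"] <- up2["Om4"] + add
    expect_gte(si(up2), si(base))
  }
})

test_that("MI lies within the c-p range of the free-living taxa present", {
  withr::local_seed(9)
  for (i in 1:100) {
    m <- randomGuildMatrix(1, c("Ba1", "Ba2", "Fu2", "Om4", "Ca5"))
    if (all(m == 0)) m[1] <- 1
    cp <- as.integer(substr(colnames(m), 3, 3))
    present <- m[1, ] > 0
    mi <- maturityIndices(ncFromGuilds(m))$MI
    expect_gte(mi, min(cp[present]))
    expect_lte(mi, max(cp[present]))
  }
})

test_that("configurable weights override the canonical parameterisation", {
  w <- ferrisWeights()
  w$enrichment[["Ba1"]] <- 1
  comp <- guildComponents(ncFromGuilds(c(Ba1 = 10, Ba2 = 10)), weights = w)
  expect_equal(comp$e, 10)
  expect_equal(channelIndex(guildComponents(
    ncFromGuilds(c(Ba1 = 10, Fu2 = 10)), w), w), 100 * 8 / 18)
})
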