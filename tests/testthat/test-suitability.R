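test_that("favourability classification is boundary-exact and idempotent", {
  got <- classifyEi(c(0, 5, 10, 10.01, 15, 20, 20.0001, 25, 100))
  expect_equal(as.character(got),
               c("unfavourable", "marginal", "marginal", "favourable",
                 "favourable", "favourable", "highly_favourable",
                 "highly_favourable", "highly_favourable"))
  # classification is a pure function: repeated application agrees
  ei <- c(0, 1e-12, 5, 10, 10 + 1e-12, 20, 20 + 1e-12, 99)
  expect_identical(classifyEi(ei), classifyEi(ei))
  expect_error(classifyEi(-1), "\\[0, 100\\]")
  expect_error(classifyEi(101), "\\[0, 100\\]")
  expect_true(is.na(classifyEi(NA_real_)))
})

test_that("area summary reproduces hand-computed class areas and shares", {
  # 4-cell single-row grid with cos(lat) areas, mixed classes
  spec <- GridSpec(100, 40, 1, 4, 1)
  g <- uniformGrid(spec, constantClimate())
  sg <- runGrid(g, defaultFornicatusParams())
  sg@ei <- c(0, 5, 15, 25)
  sg@eiClass <- classifyEi(sg@ei)
  a <- cellAreas(spec)
  s <- areaSummary(sg)
  expect_equal(s$area_km2, as.numeric(a))       # one cell per class
  expect_equal(sum(s$area_km2), sum(a))
  pot <- sum(a[2:4])
  expect_equal(s$pct_potential[2:4], 100 * a[2:4] / pot)
  expect_true(is.na(s$pct_potential[1]))

  # uniform class: the whole potential distribution
  sg@ei <- rep(25, 4); sg@eiClass <- classifyEi(sg@ei)
  s2 <- areaSummary(sg)
  expect_equal(s2$pct_potential[4], 100)
  expect_equal(s2$area_km2[1:3], rep(0, 3))
})

test_that("published class areas give the published potential-distribution shares", {
  # a grid engineered to hold 2.55 / 0.50 / 0.71 million km^2 in the
  # three favourable classes reproduces the printed shares of the
  # potential distribution (67.8 / 13.2 / 19.0 percent)
  spec <- GridSpec(0, -0.5, 1, 376, 1)   # equatorial row: equal-area cells
  area1 <- cellAreas(spec)[1]
  n <- round(c(255, 50, 71) / 376 * 376)  # cells per class out of 376
  ei <- rep(c(25, 15, 5), times = n)
  g <- uniformGrid(spec, constantClimate())
  sg <- runGrid(g, defaultFornicatusParams())
  sg@ei <- ei; sg@eiClass <- classifyEi(ei)
  s <- areaSummary(sg)
  shares <- s$pct_potential[match(c("highly_favourable", "favourable",
                                    "marginal"), s$class)]
  expect_equal(shares, c(67.8, 13.2, 19.0), tolerance = 0.05)
})

test_that("limiting-factor masks allow multi-membership and exclude suitable cells", {
  spec <- testSpec(8)
  sg <- runGrid(generateSyntheticRegion(spec, 42), defaultFornicatusParams())
  masks <- limitingFactorMap(sg)
  expect_named(masks, c("GEN_LT_1", "CS_GE_100", "TI_ZERO", "MI_ZERO"))
  flagged <- sort(unique(unlist(masks)))
  # every flagged cell has EI zero; every suitable cell is in no mask
  expect_true(all(sg@ei[flagged] == 0))
  expect_length(intersect(which(sg@ei > 0), flagged), 0L)
  # on this cold-plateau grid the generation and cold-stress masks overlap
  expect_gt(length(intersect(masks$GEN_LT_1, masks$CS_GE_100)), 0L)
})

test_that("every zero-EI cell is explained by a flag or a lethal non-cold stress", {
  spec <- testSpec(10)
  sg <- runGrid(generateSyntheticRegion(spec, 9), defaultFornicatusParams())
  res <- sg@results
  zero <- res[res$ei == 0, ]
  explained <- zero$GEN_LT_1 | zero$CS_GE_100 | zero$TI_ZERO | zero$MI_ZERO |
    zero$ds >= 100 | zero$hs >= 100 | zero$ws >= 100 | zero$giA == 0
  expect_true(all(explained))
})

test_that("impact index follows half-up rounding on area fractions", {
  spec <- GridSpec(100, 30, 1, 3, 1)   # one row: equal-area cells
  expect_equal(impactIndex(integer(0), 1:3, spec), 0L)
  expect_equal(impactIndex(1:3, 1:3, spec), 10L)
  expect_equal(impactIndex(1L, 1:3, spec), 3L)      # round(10/3)
  # half the area: exactly 5 under half-up rounding
  spec2 <- GridSpec(100, 30, 1, 4, 1)
  expect_equal(impactIndex(1:2, 1:4, spec2), 5L)
  expect_error(impactIndex(1L, integer(0), spec), "non-empty")
  # monotone in the affected fraction
  idx <- vapply(1:4, function(k) impactIndex(seq_len(k), 1:4, spec2),
                integer(1))
  expect_true(all(diff(idx) >= 0))
})

test_that("EI difference summarizes per-cell change", {
  spec <- testSpec(6)
  sg <- runGrid(generateSyntheticRegion(spec, 3), defaultFornicatusParams())
  same <- eiDifference(sg, sg)
  expect_true(all(same$delta == 0))
  expect_equal(same$summary$maxIncrease, 0)

  up <- sg; up@ei <- pmin(100, sg@ei + 3); up@eiClass <- classifyEi(up@ei)
  d <- eiDifference(sg, up)
  expect_equal(d$summary$mean, mean(pmin(100, sg@ei + 3) - sg@ei))
  expect_error(eiDifference(sg, runGrid(generateSyntheticRegion(testSpec(5), 3),
                                        defaultFornicatusParams())),
               "share one GridSpec")
})

test_that("range shift is exact under translation and undefined when absent", {
  spec <- GridSpec(100, 30, 0.5, 4, 6)
  g <- uniformGrid(spec, constantClimate())
  base <- runGrid(g, defaultFornicatusParams())
  expect_equal(rangeShift(base, base), 0)

  # paint a highly-favourable block, then the same block one row north
  paint <- function(sg, rows) {
    ei <- rep(0, nCells(spec))
    cells <- as.vector(outer(1:4, (rows - 1) * 4, `+`))
    ei[cells] <- 30
    sg@ei <- ei; sg@eiClass <- classifyEi(ei)
    sg
  }
  cur <- paint(base, 2:3)
  fut <- paint(base, 3:4)
  # one 0.5-degree row north; area weights (cos lat) perturb the
  # centroid displacement only in the fourth decimal
  expect_equal(rangeShift(cur, fut), 0.5, tolerance = 1e-3)

  none <- paint(base, integer(0))
  expect_warning(sh <- rangeShift(cur, none), "absent")
  expect_true(is.na(sh))
})

test_that("occurrence validation scores points against containing cells", {
  spec <- GridSpec(100, 30, 1, 5, 4)
  g <- uniformGrid(spec, constantClimate())
  sg <- runGrid(g, defaultFornicatusParams())
  ei <- rep(30, nCells(spec)); ei[1] <- 0
  sg@ei <- ei; sg@eiClass <- classifyEi(ei)

  cc <- cellCenters(spec)
  pts <- data.frame(lon = cc$lon[1:20], lat = cc$lat[1:20])
  res <- validateOccurrences(pts, sg)
  expect_equal(res$percentSuitable, 95)     # 19 of 20 in suitable cells
  expect_equal(res$nUsed, 20L)
  expect_equal(as.character(res$table$class[1]), "unfavourable")

  resAll <- validateOccurrences(pts[2:20, ], sg)
  expect_equal(resAll$percentSuitable, 100)

  # a point outside the extent is excluded and reduces the denominator
  out <- rbind(pts, data.frame(lon = 0, lat = 0))
  expect_warning(resOut <- validateOccurrences(out, sg), "excluded")
  expect_equal(resOut$nUsed, 20L)
  expect_equal(resOut$nExcluded, 1L)
  expect_error(validateOccurrences(data.frame(lon = 0, lat = 0), sg),
               "inside the grid")
})

test_that("points on interior edges resolve to the south-west cell", {
  spec <- GridSpec(100, 30, 1, 3, 3)
  # (101, 31) is the corner between cells 1,2,4,5 -> south-west cell 1
  expect_equal(ecoclimex:::pointToCell(spec, 101, 31), 1L)
  expect_equal(ecoclimex:::pointToCell(spec, 100, 30), 1L)   # SW corner
  expect_equal(ecoclimex:::pointToCell(spec, 103, 33), 9L)   # NE corner
  expect_true(is.na(ecoclimex:::pointToCell(spec, 99.99, 31)))
})

test_that("latitude-band regions partition the grid", {
  spec <- testSpec(10)
  bands <- latBandRegions(spec, 5)
  expect_length(bands, 5L)
  expect_equal(sort(unname(unlist(bands))), seq_len(nCells(spec)))
})
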