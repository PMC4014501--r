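# Per-structure parameter catalogue: geometry, shape, appendages,
# neighborhood, channel features, record assembly.

test_that("geometry: center of mass, edge distances, quantile radius", {
  one <- matrix(0, 5, 5); one[3, 3] <- 1
  g1 <- structureGeometry(one)
  expect_equal(unname(g1$center), c(3, 3))
  expect_equal(g1$D, 0)
  expect_equal(g1$radius, 0)

  disk <- diskMask(50)
  gd <- structureGeometry(disk, m = 0.25)
  expect_gte(gd$radius, 48)
  expect_lte(gd$radius, 50)
  expect_true(all(gd$D >= 0))
  expect_equal(length(gd$D), nrow(gd$edge))
  expect_true(gd$radius >= min(gd$D) && gd$radius <= max(gd$D))

  # 10x10 square: brute-force distance enumeration over the 36 edge pixels
  sq <- rectMask(10, 10, pad = 3)
  gs <- structureGeometry(sq)
  edge <- which(sq == 1 &
    (rbind(0, sq[-nrow(sq), ]) == 0 | rbind(sq[-1, ], 0) == 0 |
     cbind(0, sq[, -ncol(sq)]) == 0 | cbind(sq[, -1], 0) == 0))
  expect_equal(length(edge), 36)
  cy <- mean((which(sq == 1) - 1) %% nrow(sq) + 1)
  cx <- mean((which(sq == 1) - 1) %/% nrow(sq) + 1)
  bfD <- sqrt(((edge - 1) %% nrow(sq) + 1 - cy)^2 +
              ((edge - 1) %/% nrow(sq) + 1 - cx)^2)
  expect_equal(sort(gs$D), sort(bfD))
  expect_equal(max(gs$D), max(bfD))
})

test_that("shape features rank disks, rectangles and appendaged bodies", {
  p <- segmentationParams()
  disk <- diskMask(50)
  gd <- structureGeometry(disk)
  bd <- bodyAppendages(disk, p)
  sd_ <- shapeFeatures(disk, gd, bd$body, p)
  expect_equal(unname(sd_["Area"]), sum(disk))
  expect_gte(sd_["Roundness"], 95)
  expect_lte(sd_["Roughness"], 2)
  expect_lt(abs(sd_["RoundDiff"]), 2)

  rect <- rectMask(100, 10, pad = 3)
  gr <- structureGeometry(rect)
  sr <- shapeFeatures(rect, gr, NULL, p)
  expect_lt(sr["Roundness"], sd_["Roundness"] - 20)

  m <- diskWithProtrusions(40, c(35, 35, 35))
  gm <- structureGeometry(m)
  bm <- bodyAppendages(m, p)
  sm <- shapeFeatures(m, gm, bm$body, p)
  expect_gt(sm["RoundDiff"], 0)    # body rounder than the whole

  # isoperimetric alternative stays in range and ranks the same way
  p2 <- segmentationParams(roundnessMethod = "isoperimetric")
  r1 <- shapeFeatures(disk, gd, NULL, p2)["Roundness"]
  r2 <- shapeFeatures(rect, gr, NULL, p2)["Roundness"]
  expect_true(r1 <= 100 && r2 >= 0 && r2 < r1)
})

test_that("appendage features recover planted lengths and ratios", {
  disk <- diskMask(40)
  ba <- bodyAppendages(disk)
  expect_equal(unname(appendageFeatures(ba$body, ba$appendages)),
               c(0, 0, 0, 0))

  m <- diskWithProtrusions(40, c(20, 30, 40))
  ba3 <- bodyAppendages(m)
  af <- appendageFeatures(ba3$body, ba3$appendages)
  expect_equal(unname(af["AppNumber"]), 3)
  expect_gte(af["MaxApp"], 36); expect_lte(af["MaxApp"], 44)
  expect_gte(af["MedApp"], 27); expect_lte(af["MedApp"], 33)

  # AppIndex is appendage area over body area
  body <- rectMask(50, 60, pad = 30)            # 3000 px body
  apps <- list(seq_len(600))                    # 600 px appendage area
  expect_equal(unname(appendageFeatures(body, apps)["AppIndex"]), 0.2)
})

test_that("neighbor features: closest centers, touching labels, CellRatio", {
  f <- matrix(0, 300, 300)
  f <- placeIn(f, diskMask(30), 100, 40)
  f <- placeIn(f, diskMask(30), 100, 160)   # centers 120 px apart
  lab <- segmentStructures(f)
  centers <- t(vapply(1:2, function(i) {
    idx <- which(lab == i)
    c(mean((idx - 1) %/% 300 + 1), mean((idx - 1) %% 300 + 1))
  }, numeric(2)))
  nb <- neighborFeatures(lab, centers)
  expect_true(all(abs(nb$Closest - 120) <= 1))
  expect_equal(nb$Neighbors, c(0, 0))           # separated disks
  expect_equal(nb$SharedBound, c(0, 0))

  # single structure: sentinel distance
  single <- matrix(0L, 672, 512)
  single[1:10, 1:10] <- 1L                      # 100-px structure
  nb1 <- neighborFeatures(single, cbind(5, 5))
  expect_equal(nb1$Closest, -1)
  expect_equal(nb1$Neighbors, 0)
  expect_equal(nb1$CellRatio, 100 * 100 / (672 * 512))

  # touching labels share a boundary
  two <- matrix(0L, 20, 20)
  two[5:15, 3:9] <- 1L; two[5:15, 10:16] <- 2L
  nbt <- neighborFeatures(two, rbind(c(6, 10), c(13, 10)))
  expect_equal(nbt$Neighbors, c(1, 1))
  expect_true(all(nbt$SharedBound >= 11))
})

test_that("channel features: density, dots, hollowness contrasts", {
  struct <- rectMask(40, 50, pad = 2)
  g <- structureGeometry(struct)
  const <- matrix(120, nrow(struct), ncol(struct))
  cells0 <- matrix(0L, nrow(struct), ncol(struct))
  cf <- channelFeatures(struct, const, cells0, g)
  expect_equal(unname(cf["Density"]), 120)
  expect_equal(unname(cf["Deviation"]), 0)
  expect_equal(unname(cf["Hollowness"]), 0)

  # 5 planted 20-px dots in a 2000-px structure: exact counts
  struct2 <- rectMask(40, 50, pad = 2)
  expect_equal(sum(struct2), 2000)
  chan <- matrix(10, nrow(struct2), ncol(struct2))
  for (k in 0:4) chan[10:13, (5 + k * 9):(9 + k * 9)] <- 220  # 4x5 = 20 px
  cells <- segmentCells(struct2, chan)
  expect_equal(max(cells), 5)
  cf2 <- channelFeatures(struct2, chan, cells, structureGeometry(struct2))
  expect_equal(unname(cf2["CellNumber"]), 5)
  expect_equal(unname(cf2["AveArea"]), 20)
  expect_equal(unname(cf2["AreaRatio"]), 5)

  # bright annulus (rim 200, core 10) scores hollow; filled disk does not
  disk <- diskMask(30)
  gd <- structureGeometry(disk)
  n <- nrow(disk); c0 <- (n + 1) / 2
  rad2 <- outer((1:n - c0)^2, (1:n - c0)^2, "+")
  annulus <- matrix(200, n, n)
  annulus[rad2 <= (0.55 * 30)^2] <- 10
  expect_gte(channelFeatures(disk, annulus, matrix(0L, n, n),
                             gd)["Hollowness"], 80)
  filled <- matrix(200, n, n)
  expect_lte(channelFeatures(disk, filled, matrix(0L, n, n),
                             gd)["Hollowness"], 1)
})

test_that("the catalogue has 19 named parameters and stable columns", {
  cat_ <- morphometryCatalog()
  expect_equal(nrow(cat_), 19)
  expect_equal(sum(cat_$perChannel), 5)
  cols <- recordColumns()
  expect_length(cols, 14 + 10)
  expect_true(all(c("Area", "Roundness", "AppIndex", "AreaRatioR",
                    "CellNumberG", "CellRatio") %in% cols))
  # the two internal quantities are not in the result schema
  expect_false(any(c("Radius", "CenterOfMass", "cx", "cy") %in% cols))
})

test_that("record assembly yields one complete row per structure", {
  sim <- makeField(phenotypeSpec(nStructures = 3, fieldSize = c(320, 448),
                                 seed = 17))
  fld <- analyzeField(sim$stack, imageId = "img1")
  r <- records(fld)
  expect_equal(nrow(r), 3)
  expect_identical(names(r), c("ImageId", "StructureId", recordColumns()))
  # no red dots planted: the red channel reports no cells
  expect_equal(r$CellNumberR, rep(0, 3))
  expect_equal(r$AveAreaR, rep(0, 3))
  expect_true(all(r$AveAreaG * r$CellNumberG <= r$Area + 1e-9))
})

test_that("percentage features stay in [0, 100] across random phenotypes", {
  pctCols <- c("Roundness", "FiltRound", "Roughness", "CellRatio",
               "AreaRatioR", "AreaRatioG", "HollownessR", "HollownessG")
  n <- 0
  for (sd in 1:8) {
    sim <- makeField(phenotypeSpec(
      nStructures = 5, fieldSize = c(384, 512), redDotRate = 2,
      hollowFraction = 0.5, deformAmplitude = 0.1,
      roughnessAmplitude = 0.05, seed = sd))
    r <- records(analyzeField(sim$stack, imageId = "x"))
    n <- n + nrow(r)
    for (cc in pctCols)
      expect_true(all(r[[cc]] >= 0 & r[[cc]] <= 100), label = cc)
    expect_true(all(r$Area > 0))
    expect_true(all(r[c("AppNumber", "Neighbors", "CellNumberR",
                        "CellNumberG")] >= 0))
  }
  expect_gte(n, 35)
})

test_that("features scale and rotate the way lengths and areas must", {
  m <- diskWithProtrusions(30, c(25, 30))
  p <- segmentationParams()
  measure <- function(mask) {
    g <- structureGeometry(mask)
    ba <- bodyAppendages(mask, p)
    c(shapeFeatures(mask, g, ba$body, p),
      appendageFeatures(ba$body, ba$appendages), radius = g$radius)
  }
  f1 <- measure(m)
  up <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  f2 <- measure(up)
  expect_equal(unname(f2["Area"] / f1["Area"]), 4, tolerance = 0.01)
  expect_equal(unname(f2["radius"] / f1["radius"]), 2, tolerance = 0.05)
  expect_equal(unname(f2["MaxApp"] / f1["MaxApp"]), 2, tolerance = 0.05)
  expect_lt(abs(f2["Roundness"] - f1["Roundness"]), 3)

  rot <- t(m)[ncol(m):1, ]                     # exact 90-degree rotation
  f3 <- measure(rot)
  expect_lt(abs(f3["Roundness"] - f1["Roundness"]), 3)
  expect_lt(abs(f3["Roughness"] - f1["Roughness"]), 3)
  expect_lt(abs(f3["AppIndex"] - f1["AppIndex"]) /
            max(f1["AppIndex"], 1e-9), 0.05)
})

test_that("red-channel area ratio recovers planted dead-cell fractions", {
  for (cfg in list(list(rate = 0, rad = 2.5), list(rate = 3, rad = 3),
                   list(rate = 8, rad = 4), list(rate = 14, rad = 5))) {
    sim <- makeField(phenotypeSpec(
      nStructures = 5, fieldSize = c(384, 512), radiusMean = 30,
      radiusSd = 3, appendageCountRange = c(0, 0), deformAmplitude = 0.03,
      redDotRate = cfg$rate, dotRadius = cfg$rad, seed = 31 + cfg$rate))
    fld <- analyzeField(sim$stack, imageId = "x")
    tt <- sim$truth$table
    expect_equal(nStructures(fld), nrow(tt))
    mm <- matchToTruth(fld, tt)
    trueArea <- tabulate(sim$truth$labels[sim$truth$labels > 0], nrow(tt))
    planted <- 100 * tt$dotArea[mm] / trueArea[mm]
    expect_true(all(abs(records(fld)$AreaRatioR - planted) <= 2))
  }
})
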