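test_that("the frame of an axis-aligned rectangle has its closed form", {
  mask <- matrix(1, 20, 10) # height 20 (y), width 10 (x)
  fr <- computeFrame(mask)
  expect_equal(frameArea(fr), 200)
  expect_equal(unname(frameCentroid(fr)), c(4.5, 9.5))
  expect_equal(unname(boundingRect(fr)), c(0, 0, 10, 20))
  expect_equal(brAnt(fr), c(x = 0, y = 20))
  expect_equal(brPost(fr), c(x = 10, y = 0))
  expect_error(computeFrame(matrix(0, 5, 5)), "empty")
})

test_that("mask centroids equal the explicit pixel-loop mean", {
  set.seed(61)
  for (i in 1:100) {
    mask <- matrix(rbinom(15 * 12, 1, 0.4), 15, 12)
    if (!any(mask > 0)) next
    fr <- computeFrame(mask)
    px <- which(mask > 0, arr.ind = TRUE)
    sx <- 0; sy <- 0
    for (j in seq_len(nrow(px))) {
      sx <- sx + px[j, 2] - 1; sy <- sy + px[j, 1] - 1
    }
    expect_equal(unname(frameCentroid(fr)),
                 unname(c(sx / nrow(px), sy / nrow(px))))
    expect_equal(frameArea(fr), nrow(px))
  }
})

test_that("translation moves the centroid identically and keeps the area", {
  mask <- matrix(0, 30, 30); mask[5:12, 3:20] <- 1
  big <- matrix(0, 40, 40); big[15:22, 10:27] <- 1 # shifted by (7, 10)
  f1 <- computeFrame(mask); f2 <- computeFrame(big)
  expect_equal(frameArea(f1), frameArea(f2))
  expect_equal(frameCentroid(f2) - frameCentroid(f1), c(x = 7, y = 10))
})

test_that("polygon frames use the shoelace area and polygon centroid", {
  poly <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 20, 20))
  fr <- computeFrame(poly)
  expect_equal(frameArea(fr), 200)
  expect_equal(unname(frameCentroid(fr)), c(5, 10))
  expect_equal(unname(boundingRect(fr)), c(0, 0, 10, 20))
})

test_that("standardisation evaluates the printed formulas exactly", {
  fr <- new("MuscleFrame", centroid = c(x = 50, y = 30), area = 200,
            boundingRect = c(x = 10, y = 20, width = 90, height = 30))
  # the worked example: point (54, 28) -> dX 4, dY 2, std (2, 1)
  sc <- standardizeCoords(cbind(54, 28), fr)
  expect_identical(sc$dX, 4)
  expect_identical(sc$dY, 2)
  expect_identical(sc$std_dX, 2)
  expect_identical(sc$std_dY, 1)
  expect_equal(as.character(classifySubdomain(sc)), "postero-dorsal")
  # the centroid itself maps to the origin
  sc0 <- standardizeCoords(cbind(50, 30), fr)
  expect_identical(c(sc0$std_dX, sc0$std_dY), c(0, 0))
  # image-down points (y > centroid) are antero-ventral side: dY < 0
  scd <- standardizeCoords(cbind(50, 35), fr)
  expect_lt(scd$dY, 0)
})

test_that("standardisation agrees with an independent evaluation", {
  set.seed(62)
  for (i in 1:100) {
    cen <- runif(2, 10, 90); area <- runif(1, 50, 500)
    fr <- new("MuscleFrame", centroid = c(x = cen[1], y = cen[2]),
              area = area, boundingRect = c(0, 0, 100, 100))
    p <- runif(2, 0, 100)
    sc <- standardizeCoords(cbind(p[1], p[2]), fr)
    expect_equal(sc$std_dX, (p[1] - cen[1]) * 100 / area)
    expect_equal(sc$std_dY, -(p[2] - cen[2]) * 100 / area)
  }
})

test_that("translating mask and point together leaves std coordinates fixed", {
  mask <- matrix(0, 50, 50); mask[10:20, 5:40] <- 1
  big <- matrix(0, 60, 60); big[25:35, 17:52] <- 1 # shift (12, 15)
  s1 <- standardizeCoords(cbind(20, 12), computeFrame(mask))
  s2 <- standardizeCoords(cbind(32, 27), computeFrame(big))
  expect_equal(s1$std_dX, s2$std_dX)
  expect_equal(s1$std_dY, s2$std_dY)
})

test_that("uniform rescaling by s scales std coordinates by 1/s", {
  mask <- matrix(0, 40, 60); mask[10:19, 10:39] <- 1 # 10 x 30
  mask2 <- matrix(0, 80, 120); mask2[20:39, 20:79] <- 1 # scaled by 2
  f1 <- computeFrame(mask); f2 <- computeFrame(mask2)
  expect_equal(frameArea(f2), 4 * frameArea(f1))
  p1 <- standardizeCoords(cbind(35, 12), f1)
  # the corresponding point at doubled coordinates relative to the centroid
  cen1 <- frameCentroid(f1); cen2 <- frameCentroid(f2)
  p2xy <- cen2 + 2 * (c(35, 12) - cen1)
  p2 <- standardizeCoords(rbind(p2xy), f2)
  expect_equal(p2$std_dX, p1$std_dX / 2)
  expect_equal(p2$std_dY, p1$std_dY / 2)
})

test_that("subdomain classification is total, unique and prioritised", {
  cases <- data.frame(
    std_dX = c(0, 0, 2, 2, 0, 1, 1, -3),
    std_dY = c(0, -2, 1, -2, -1, 0, -1, -3))
  got <- classifySubdomain(cases)
  expect_equal(as.character(got),
               c("central", "antero-ventral", "postero-dorsal",
                 "antero-ventral", # AV takes priority over PD
                 "central",        # boundary std_dY = -1 falls central
                 "central",        # boundary std_dX = +1 falls central
                 "central",        # both boundaries
                 "antero-ventral"))
  expect_false(any(is.na(got)))
  # exhaustive: a grid of coordinates receives exactly one label each
  grid <- expand.grid(std_dX = seq(-3, 3, by = 0.25),
                      std_dY = seq(-3, 3, by = 0.25))
  labs <- classifySubdomain(grid)
  expect_equal(length(labs), nrow(grid))
  expect_false(any(is.na(labs)))
  expect_error(classifySubdomain(cases, avCut = 2, pdCut = 1), "avCut")
})

test_that("repartition percentages sum to 100 with expected values", {
  allCentral <- factor(rep("central", 7),
                       levels = c("antero-ventral", "central",
                                  "postero-dorsal"))
  expect_equal(unname(repartition(allCentral)), c(0, 100, 0),
               ignore_attr = TRUE)
  one <- factor(c("antero-ventral", "central", "postero-dorsal"),
                levels = levels(allCentral))
  expect_equal(unname(repartition(one)), rep(100 / 3, 3),
               ignore_attr = TRUE)
  expect_equal(sum(repartition(one)), 100)
  expect_error(repartition(factor(character(),
                                  levels = levels(allCentral))), "empty")
})

test_that("uniform points over the angled template match the area oracle", {
  tmpl <- muscleTemplate("da3_angled")
  mask <- rasterisePolygon(tmpl$polygon, tmpl$imageSize)
  fr <- computeFrame(mask)
  # oracle: exhaustive classification of every mask pixel (area fractions)
  px <- which(mask > 0, arr.ind = TRUE)
  scAll <- standardizeCoords(cbind(px[, 2] - 1, px[, 1] - 1), fr)
  oracle <- unname(repartition(classifySubdomain(scAll)))
  # Monte-Carlo sample of uniform points over the same outline
  set.seed(63)
  n <- 4000
  pts <- matrix(NA_real_, 0, 2)
  bb <- apply(tmpl$polygon, 2, range)
  while (nrow(pts) < n) {
    cand <- cbind(runif(n, bb[1, 1], bb[2, 1]),
                  runif(n, bb[1, 2], bb[2, 2]))
    keep <- vapply(seq_len(n), function(i)
      oracleInside(cand[i, ], tmpl$polygon), TRUE)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n), ]
  got <- unname(repartition(classifySubdomain(standardizeCoords(pts, fr))))
  for (k in 1:3) {
    se <- 100 * sqrt(oracle[k] / 100 * (1 - oracle[k] / 100) / n)
    expect_lt(abs(got[k] - oracle[k]), 3 * se)
  }
})

test_that("an already aligned fibre needs no rotation", {
  mask <- matrix(0, 50, 100); mask[20:30, 10:90] <- 1
  out <- orientAndCrop(mask)
  expect_lt(abs(out$angle), 1)
  expect_equal(dim(out$mask), c(11, 81))
  # crop equals the rotated mask's bounding rectangle: mask touches edges
  expect_gt(sum(out$mask[1, ]), 0)
  expect_gt(sum(out$mask[nrow(out$mask), ]), 0)
  expect_gt(sum(out$mask[, 1]), 0)
  expect_gt(sum(out$mask[, ncol(out$mask)]), 0)
})

test_that("a known 30-degree rotation is recovered within a degree", {
  # build a rectangle rotated by +30 degrees (image coordinates)
  h <- 160; w <- 160
  th <- 30 * pi / 180
  cen <- c(80, 80)
  mask <- matrix(0, h, w)
  for (row in 1:h) for (col in 1:w) {
    rel <- c(col - 1 - cen[1], row - 1 - cen[2])
    u <- cos(th) * rel[1] + sin(th) * rel[2]
    v <- -sin(th) * rel[1] + cos(th) * rel[2]
    if (abs(u) <= 55 && abs(v) <= 8) mask[row, col] <- 1
  }
  out <- orientAndCrop(mask)
  expect_equal(abs(out$angle), 30, tolerance = 1 / 30)
  # after rotation the fibre is flat: height much smaller than width
  expect_gt(ncol(out$mask) / nrow(out$mask), 4)
})

test_that("a nearly circular region warns and keeps the identity rotation", {
  mask <- matrix(0, 41, 41)
  for (row in 1:41) for (col in 1:41)
    if ((row - 21)^2 + (col - 21)^2 <= 15^2) mask[row, col] <- 1
  expect_warning(out <- orientAndCrop(mask), "degenerate")
  expect_equal(out$angle, 0)
})
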