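test_that("projections match the definition on simple stacks", {
  s1 <- array(matrix(1:12, 3, 4), c(3, 4, 1))
  expect_equal(projectStack(s1, "sum"), matrix(1:12, 3, 4),
               ignore_attr = TRUE)
  s2 <- array(0, c(2, 2, 2)); s2[, , 1] <- 1; s2[, , 2] <- 2
  expect_equal(projectStack(s2, "sum"), matrix(3, 2, 2), ignore_attr = TRUE)
  expect_equal(projectStack(s2, "max"), matrix(2, 2, 2), ignore_attr = TRUE)
  expect_error(projectStack(array(0, c(0, 2, 2))), "non-empty")
})

test_that("projections equal the per-pixel loop oracle on random stacks", {
  set.seed(41)
  for (i in 1:100) {
    d <- c(sample(3:8, 2, replace = TRUE), sample(2:5, 1))
    s <- array(rpois(prod(d), 20), d)
    expect_equal(projectStack(s, "sum"), oracleProject(s, "sum"),
                 ignore_attr = TRUE)
    expect_equal(projectStack(s, "max"), oracleProject(s, "max"),
                 ignore_attr = TRUE)
  }
})

test_that("thresholding is strict and logs the applied value", {
  z <- matrix(0, 5, 5)
  m <- thresholdDots(z, 10)
  expect_true(all(m == 0))
  img <- matrix(0, 10, 10); img[3:5, 3:5] <- 100
  m <- thresholdDots(img, 10)
  expect_equal(sum(m), 9)
  expect_equal(attr(m, "threshold"), 10)
  # ties at the threshold are background
  img2 <- matrix(c(10, 11), 1, 2)
  expect_equal(as.vector(thresholdDots(img2, 10)), c(0, 1))
  expect_error(thresholdDots(z, "otsu"), "constant image")
  expect_error(thresholdDots(z, "background_2sd"), "constant image")
})

test_that("particle labelling matches a flood-fill oracle on random masks", {
  set.seed(42)
  for (i in 1:100) {
    m <- matrix(rbinom(16 * 16, 1, 0.35), 16, 16)
    regions <- labelParticles(m, minArea = 1)
    oracle <- oracleLabel(m)
    expect_equal(length(regions), max(oracle))
    # identical pixel partitions (region sets, order-independent)
    got <- sort(vapply(regions, function(r)
      paste(sort(r$pixels[, 1] * 100 + r$pixels[, 2]), collapse = ","), ""))
    want <- sort(vapply(seq_len(max(oracle)), function(k) {
      px <- which(oracle == k, arr.ind = TRUE)
      paste(sort(px[, 1] * 100 + px[, 2]), collapse = ",")
    }, ""))
    expect_identical(got, want)
  }
})

test_that("particle labelling counts, filters and orders deterministically", {
  expect_equal(labelParticles(matrix(0, 5, 5)), list())
  m <- matrix(0, 10, 12)
  m[2:4, 2:4] <- 1; m[7:9, 8:10] <- 1
  regions <- labelParticles(m, minArea = 1)
  expect_equal(length(regions), 2L)
  expect_equal(vapply(regions, function(r) r$area, 0L), c(9L, 9L))
  # ordering: top-most first
  expect_lt(regions[[1]]$centroid["y"], regions[[2]]$centroid["y"])
  # minimum area filter
  m[1, 12] <- 1
  expect_equal(length(labelParticles(m, minArea = 2)), 2L)
  expect_equal(length(labelParticles(m, minArea = 1)), 3L)
})

test_that("muscle intersection retains exactly centroid-inside dots", {
  mask <- matrix(0, 10, 10); mask[3:8, 3:8] <- 1
  inDot <- list(id = 1L, pixels = cbind(5, 5), centroid = c(x = 4, y = 4),
                area = 1L)
  outDot <- list(id = 2L, pixels = cbind(1, 1), centroid = c(x = 0, y = 0),
                 area = 1L)
  kept <- intersectWithMuscle(list(inDot, outDot), mask)
  expect_equal(length(kept), 1L)
  expect_equal(kept[[1]]$muscle, 1L)
  expect_error(
    intersectWithMuscle(list(list(id = 1L, pixels = cbind(50, 50),
                                  centroid = c(x = 49, y = 49), area = 1L)),
                        mask), "grid")
})

test_that("muscle intersection agrees with a containment oracle on many dots", {
  tmpl <- muscleTemplate("band")
  mask <- rasterisePolygon(tmpl$polygon, tmpl$imageSize)
  set.seed(43)
  xs <- runif(700, 0, tmpl$imageSize[2] - 1)
  ys <- runif(700, 0, tmpl$imageSize[1] - 1)
  # avoid pixels whose centre sits exactly on the outline, where any two
  # correct containment definitions may legitimately disagree
  clear <- fibreFISH:::distanceToBoundary(cbind(round(xs), round(ys)),
                                          tmpl$polygon) > 0.5
  xs <- xs[clear][1:500]; ys <- ys[clear][1:500]
  regions <- lapply(1:500, function(i) list(
    id = i, pixels = cbind(round(ys[i]) + 1, round(xs[i]) + 1),
    centroid = c(x = xs[i], y = ys[i]), area = 1L))
  kept <- intersectWithMuscle(regions, mask)
  keptIds <- vapply(kept, function(r) r$id, 0L)
  oracle <- vapply(1:500, function(i)
    oracleInside(c(round(xs[i]), round(ys[i])), tmpl$polygon), TRUE)
  expect_identical(sort(keptIds), which(oracle))
})

test_that("the Z filter keeps in-plane dots and drops out-of-plane decoys", {
  stack <- array(0, c(40, 40, 8))
  stack <- addSpot(stack, 10, 10, 5000, zWeights = c(0, 0, 0, 1, 1, 1, 0, 0))
  stack <- addSpot(stack, 30, 30, 5000, zWeights = c(1, rep(0, 7))) # decoy
  proj <- projectStack(stack, "sum")
  regions <- labelParticles(thresholdDots(proj, 2), minArea = 2)
  expect_equal(length(regions), 2L)
  kept <- zFilter(regions, zExtent = c(4, 6), stack, tolerance = 1)
  expect_equal(length(kept), 1L)
  expect_equal(unname(kept[[1]]$centroid["x"]), 10, tolerance = 0.5)
  expect_true(kept[[1]]$z_peak %in% 4:6)
})

test_that("decoy spots planted by the generator are all removed", {
  cfg <- testConfig(pOn = 1, nuclei15 = 4)
  set.seed(44)
  fb <- simulateFibre(cfg, 15)
  ch <- fb$channels$dot_g1
  # plant a decoy above the fibre (slice 1; the fibre occupies 2..5) at a
  # spot clear of every true dot, with zero Z-filter tolerance
  ch <- addSpot(ch, 180, 25, 20000, zWeights = c(1, rep(0, 5)))
  d0 <- quantifyStack(fb$channels$dot_g1, fb$masks$muscle, c(2, 5),
                      threshold = 2, zTolerance = 0)
  d1 <- quantifyStack(ch, fb$masks$muscle, c(2, 5), threshold = 2,
                      zTolerance = 0)
  expect_equal(nrow(d0), 4L)
  expect_equal(nrow(d1), nrow(d0)) # decoy dropped, true dots kept
})

test_that("integrated density and region mean equal loop oracles", {
  expect_equal(measureIntDen(matrix(1, 5, 5), cbind(1:5, 1:5)), 5)
  expect_equal(measureIntDen(matrix(0, 5, 5), cbind(1:3, 1)), 0)
  expect_equal(measureMuscleMean(matrix(7, 4, 4), matrix(1, 4, 4)), 7)
  half <- matrix(c(0, 10), 10, 10)
  expect_equal(measureMuscleMean(half, matrix(1, 10, 10)), 5)
  expect_error(measureIntDen(matrix(1, 5, 5),
                             matrix(numeric(0), 0, 2)), "empty")
  expect_error(measureMuscleMean(matrix(1, 5, 5), matrix(0, 5, 5)), "empty")
  set.seed(45)
  for (i in 1:100) {
    img <- matrix(runif(100, 0, 50), 10, 10)
    n <- sample(1:20, 1)
    px <- unique(cbind(sample(1:10, n, TRUE), sample(1:10, n, TRUE)))
    expect_equal(measureIntDen(img, px), oracleRegionSum(img, px))
    expect_equal(measureMuscleMean(img, px), oracleRegionMean(img, px))
  }
})

test_that("fibre quantification recovers well-separated ground-truth dots", {
  cfg <- testConfig(pOn = 0.7, nuclei15 = 8, cv = 0.2)
  set.seed(46)
  for (f in 1:10) {
    fb <- simulateFibre(cfg, 15)
    q <- quantifyFibre(fb, cfg)
    k <- sum(fb$states[, "g1"])
    expect_equal(q$fibres$n_dots, k)
    expect_equal(q$fibres$n_nuclei, 8L)
    expect_equal(q$fibres$total_intden, sum(q$dots$intden))
    if (k > 0) {
      # match each detected dot to the nearest true dot; IntDen within 5%
      tr <- fb$truth$dots
      for (i in seq_len(nrow(q$dots))) {
        j <- which.min((tr$dot_x - q$dots$x[i])^2 +
                         (tr$dot_y - q$dots$y[i])^2)
        expect_lt(abs(q$dots$intden[i] - tr$dot_intensity[j]) /
                    tr$dot_intensity[j], 0.05)
        # retained centroids lie inside the muscle mask
        expect_equal(fb$masks$muscle[round(q$dots$y[i]) + 1,
                                     round(q$dots$x[i]) + 1], 1)
      }
    }
  }
})

test_that("a fibre with zero ON nuclei quantifies to zero dots", {
  cfg <- testConfig(pOn = 0)
  set.seed(47)
  fb <- simulateFibre(cfg, 15)
  q <- quantifyFibre(fb, cfg)
  expect_equal(q$fibres$n_dots, 0L)
  expect_equal(q$fibres$total_intden, 0)
})

test_that("an FC-restricted gene yields one dot per fibre", {
  cfg <- presetConfig("kr_stage13")
  set.seed(48)
  for (f in 1:10) {
    fb <- simulateFibre(cfg, 13)
    q <- quantifyFibre(fb, cfg)
    expect_equal(q$fibres$n_dots, 1L)
  }
})

test_that("raising the threshold never increases the dot count", {
  cfg <- testConfig(pOn = 0.8, nuclei15 = 8, cv = 0.3)
  set.seed(49)
  for (f in 1:5) {
    fb <- simulateFibre(cfg, 15)
    counts <- vapply(c(2, 10, 50, 200, 1000, 5000), function(t) {
      nrow(quantifyStack(fb$channels$dot_g1, fb$masks$muscle,
                         c(2, 5), threshold = t))
    }, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the permissive profile counts small and weak dots", {
  # a dim dot below the standard threshold
  stack <- array(0, c(40, 40, 6))
  stack <- addSpot(stack, 20, 20, 30, zWeights = c(0, 1, 1, 1, 1, 0))
  mask <- matrix(1, 40, 40)
  std <- quantifyStack(stack, mask, c(2, 5), threshold = 50,
                       profile = "standard")
  perm <- quantifyStack(stack, mask, c(2, 5), profile = "permissive")
  expect_equal(nrow(std), 0L)
  expect_equal(nrow(perm), 1L)
})
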