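discImage <- function(centres, r, size = c(60, 80), value = 120) {
  img <- matrix(0, size[1], size[2])
  for (k in seq_len(nrow(centres))) {
    for (row in 1:size[1]) for (col in 1:size[2]) {
      if ((col - 1 - centres[k, 1])^2 + (row - 1 - centres[k, 2])^2 <= r^2)
        img[row, col] <- value
    }
  }
  img
}

test_that("disjoint nuclei segment to one mask each", {
  img <- discImage(rbind(c(15, 15), c(45, 30), c(65, 15)), r = 7)
  nuc <- segmentNuclei(img)
  expect_s4_class(nuc, "NucleusSet")
  expect_equal(nrow(nucleusInfo(nuc)), 3L)
  # centroids near the disc centres
  info <- nucleusInfo(nuc)
  expect_equal(sort(round(info$x)), c(15, 45, 65), tolerance = 1)
})

test_that("touching nuclei are split by the watershed", {
  # two discs of radius 8 overlapping ~20% of their area
  img <- discImage(rbind(c(30, 25), c(42, 25)), r = 8)
  nuc <- segmentNuclei(img)
  expect_equal(nrow(nucleusInfo(nuc)), 2L)
})

test_that("an empty nuclear channel warns and returns no nuclei", {
  expect_warning(nuc <- segmentNuclei(matrix(0, 20, 20)), "no nuclei")
  expect_equal(nrow(nucleusInfo(nuc)), 0L)
})

test_that("segmentation of simulated fibres recovers the nucleus count", {
  cfg <- testConfig(pOn = 0.5)
  set.seed(51)
  for (f in 1:10) {
    fb <- simulateFibre(cfg, 14)
    nuc <- segmentNuclei(projectStack(fb$channels$nuclei, "max"))
    expect_equal(nrow(nucleusInfo(nuc)), nrow(nucleusCentres(fb$geometry)))
  }
})

test_that("dot assignment follows containment, then bounded distance", {
  img <- discImage(rbind(c(20, 20), c(50, 20)), r = 7)
  nuc <- segmentNuclei(img)
  info <- nucleusInfo(nuc)
  idAt <- function(x) info$nucleus_id[which.min(abs(info$x - x))]
  dots <- data.frame(x = c(20, 50, 20, 70), y = c(20, 20, 29, 50))
  out <- assignDots(dots, nuc)
  expect_equal(out$nucleus_id[1], idAt(20)) # containment
  expect_equal(out$nucleus_id[2], idAt(50))
  expect_equal(out$nucleus_id[3], idAt(20)) # nearest within range
  expect_true(is.na(out$nucleus_id[4]))     # beyond max distance
})

test_that("assignment accuracy reaches 99% on simulated dots", {
  cfg <- testConfig(pOn = 0.8, nuclei15 = 8)
  set.seed(52)
  good <- 0L; total <- 0L
  while (total < 1000) {
    fb <- simulateFibre(cfg, 15)
    nuc <- segmentNuclei(projectStack(fb$channels$nuclei, "max"))
    q <- quantifyFibre(fb, cfg, nuclei = nuc)
    d <- assignDots(q$dots, nuc)
    tr <- fb$truth$dots
    info <- nucleusInfo(nuc)
    for (i in seq_len(nrow(d))) {
      j <- which.min((tr$dot_x - d$x[i])^2 + (tr$dot_y - d$y[i])^2)
      trueXY <- nucleusCentres(fb$geometry)[tr$nucleus_id[j], ]
      # the segmented nucleus matching the true owner
      trueSeg <- info$nucleus_id[
        which.min((info$x - trueXY[1])^2 + (info$y - trueXY[2])^2)]
      total <- total + 1L
      if (!is.na(d$nucleus_id[i]) && d$nucleus_id[i] == trueSeg)
        good <- good + 1L
    }
  }
  expect_gte(good / total, 0.99)
})

test_that("co-transcription counts partition the nuclei and derive fractions", {
  st <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE,
                 TRUE, FALSE, TRUE, FALSE, TRUE), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  # states: both, a only, b only, neither, b only
  ct <- tabulateCotranscription(st, c("a", "b"))
  expect_equal(ct$n_both, 1L)
  expect_equal(ct$n_a_only, 1L)
  expect_equal(ct$n_b_only, 2L)
  expect_equal(ct$n_neither, 1L)
  expect_equal(ct$n_a_only + ct$n_b_only + ct$n_both + ct$n_neither,
               ct$n_total)
  expect_equal(ct$active, 4 / 5)
  expect_equal(ct$co_given_active, 1 / 4)
  expect_error(tabulateCotranscription(st[0, , drop = FALSE], c("a", "b")),
               "zero nuclei")
})

test_that("the four-way partition always sums to the nucleus total", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    st <- matrix(runif(2 * n) < 0.5, ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
    ct <- tabulateCotranscription(st, c("a", "b"))
    expect_equal(ct$n_a_only + ct$n_b_only + ct$n_both + ct$n_neither, n)
    expect_gte(ct$active, 0); expect_lte(ct$active, 1)
  }
})

test_that("tabulated fractions converge to the joint law", {
  cfg <- generatorConfig(
    "jt", "DA3",
    genes = list(burstSpec("duf", 0.5), burstSpec("col", 0.5)),
    jointTables = list(jointBurstTable(c("duf", "col"), 0.4, 0.2, 0.2, 0.2)))
  g <- gridGeometry(10000)
  set.seed(54)
  st <- sampleTranscriptionStates(g, cfg)
  ct <- tabulateCotranscription(st, c("duf", "col"))
  expect_lt(abs(ct$active - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  expect_lt(abs(ct$co_given_active - 0.5),
            3 * sqrt(0.25 / (0.8 * 10000)))
})

test_that("exclusion-model data never co-transcribe; independent data do", {
  cfg <- generatorConfig(
    "ex", "DA3",
    genes = list(burstSpec("sns", 0.5, exclusionGroup = "g"),
                 burstSpec("col", 0.5, exclusionGroup = "g")))
  g <- gridGeometry(5000)
  set.seed(55)
  st <- sampleTranscriptionStates(g, cfg)
  expect_equal(exclusionCheck(st, c("sns", "col")), 0L)
  # independently bursting genes at p = 0.5 co-occur with near certainty
  ind <- matrix(runif(200) < 0.5, ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  expect_gt(exclusionCheck(ind, c("x", "y")), 0L)
  empty <- matrix(logical(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  expect_equal(exclusionCheck(empty, c("x", "y")), 0L)
})

test_that("lineage classification and counting follow the mask and labels", {
  img <- discImage(rbind(c(20, 20), c(50, 20)), r = 7)
  nuc <- segmentNuclei(img)
  lineageImg <- discImage(rbind(c(20, 20)), r = 7, value = 100) +
    discImage(rbind(c(50, 20)), r = 7, value = 20)
  lin <- classifyLineage(nuc, lineageImg, threshold = 60)
  info <- nucleusInfo(nuc)
  expect_equal(lin[order(info$x)], c("labelled", "unlabelled"))
  mask <- matrix(1, nrow(img), ncol(img))
  expect_equal(countLabelledNuclei(nuc, lin, mask),
               c(n_labelled = 1L, n_total = 2L))
  expect_equal(countLabelledNuclei(nuc, rep("unlabelled", 2), mask),
               c(n_labelled = 0L, n_total = 2L))
  expect_equal(countLabelledNuclei(nuc, rep("labelled", 2), mask),
               c(n_labelled = 2L, n_total = 2L))
  # restriction to the muscle: mask covering only the left nucleus
  half <- matrix(0, nrow(img), ncol(img)); half[, 1:35] <- 1
  expect_equal(unname(countLabelledNuclei(nuc, lin, half)["n_total"]), 1L)
})
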