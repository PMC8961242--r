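# helper: an empty intensity field with a planted ellipsoidal bright blob
blobVolume <- function(shape = c(40, 40, 20), centers = list(),
                       radii = list(), value = 10) {
  v <- array(0, shape)
  for (i in seq_along(centers)) {
    cc <- centers[[i]]; r <- radii[[i]]
    idx <- as.matrix(expand.grid(1:shape[1], 1:shape[2], 1:shape[3]))
    d <- sweep(idx, 2, cc)
    sel <- rowSums(sweep(d, 2, r, `/`)^2) <= 1
    v[idx[sel, , drop = FALSE]] <- value
  }
  v
}

test_that("uniform grey matter yields no candidates", {
  set.seed(1)
  v <- array(rnorm(30^3, 5, 0.5), c(30, 30, 30))
  gm <- array(TRUE, dim(v))
  expect_equal(nrow(detectCandidates(v, gm, zThresh = 6)), 0)
})

test_that("a planted 5 mm2 blob is detected exactly once", {
  gm <- array(TRUE, c(40, 40, 20))
  v <- blobVolume(centers = list(c(20, 20, 10)),
                  radii = list(c(1.6, 1.6, 1)))   # disc ~8 voxels/slice
  set.seed(2)
  v <- v + array(rnorm(length(v), 0, 0.01), dim(v))
  rec <- detectCandidates(v, gm, zThresh = 5, minAreaMm2 = 3)
  expect_equal(nrow(rec), 1)
  expect_gt(rec$area_mm2, 5)
  expect_equal(rec$centroid_x, 20, tolerance = 0.5)
})

test_that("blobs under the axial area rule are rejected", {
  gm <- array(TRUE, c(40, 40, 20))
  # two voxels per axial slice = 2 mm^2 at 1 mm spacing
  v <- array(0, c(40, 40, 20))
  v[20:21, 20, 5:9] <- 10
  set.seed(3)
  v <- v + array(rnorm(length(v), 0, 0.01), dim(v))
  rec <- detectCandidates(v, gm, zThresh = 5, minAreaMm2 = 3)
  expect_equal(nrow(rec), 0)
  # same blob with larger in-plane footprint survives
  v[19:22, 19:21, 5:9] <- 10
  rec2 <- detectCandidates(v, gm, zThresh = 5, minAreaMm2 = 3)
  expect_equal(nrow(rec2), 1)
})

test_that("area and centroid scale with voxel spacing", {
  gm <- array(TRUE, c(30, 30, 12))
  v <- array(0, dim(gm)); v[10:13, 10:13, 5:6] <- 10
  set.seed(4)
  v <- v + array(rnorm(length(v), 0, 0.01), dim(v))
  rec <- detectCandidates(v, gm, spacing = c(2, 2, 3), zThresh = 5)
  expect_equal(rec$area_mm2, 16 * 4)          # 16 voxels * 2mm * 2mm
  expect_equal(rec$centroid_x, 11.5 * 2, tolerance = 0.02)
  expect_equal(rec$centroid_z, 5.5 * 3, tolerance = 0.02)
})

test_that("matching: identical, disjoint, and ambiguous sets", {
  mk <- function(xyz, source, subject = "s1") {
    data.frame(subject_id = subject,
               lesion_id = seq_len(nrow(xyz)),
               centroid_x = xyz[, 1], centroid_y = xyz[, 2],
               centroid_z = xyz[, 3], area_mm2 = 5,
               volume_mm3 = 10, type = "intracortical", lobe = "frontal",
               source = source, stringsAsFactors = FALSE)
  }
  pts <- cbind(runif(4, 0, 50), runif(4, 0, 50), runif(4, 0, 50))
  a <- mk(pts, "aDIR"); c1 <- mk(pts, "cDIR")
  m <- matchLesions(a, c1, tolMm = 1)
  expect_equal(c(m@tp, m@fp, m@fn), c(4L, 0L, 0L))
  far <- mk(pts + 100, "cDIR")
  m2 <- matchLesions(a, far, tolMm = 5)
  expect_equal(c(m2@tp, m2@fp, m2@fn), c(0L, 4L, 4L))
  expect_error(matchLesions(a, mk(pts, "cDIR", subject = "s2")), "subjects")
})

test_that("greedy matching equals exhaustive assignment: ambiguous fixture", {
  # 3 aDIR vs 2 cDIR with one ambiguous pair: a1 and a2 both lie within
  # tolerance of c1, a3 matches c2, a2 has no second partner
  A <- rbind(c(0, 0, 0), c(3, 0, 0), c(20, 0, 0))
  C <- rbind(c(1, 0, 0), c(21, 0, 0))
  m <- matchLesions(recFromPoints(A, "aDIR"), recFromPoints(C, "cDIR"),
                    tolMm = 5)
  expect_equal(m@tp, bruteBestMatch(A, C, 5))
  expect_equal(c(m@tp, m@fp, m@fn), c(2L, 1L, 0L))
  # the closer of the ambiguous pair wins
  expect_true(all(m@pairs$a_id != 2))
})

test_that("greedy matching equals exhaustive assignment on separated instances", {
  # random instances whose lesions are well separated relative to the
  # matching radius (the regime the radius criterion formalizes); both
  # routes must find the planted correspondence
  set.seed(6)
  for (trial in 1:15) {
    nc <- sample(3:5, 1)
    # cDIR lesions at least 4*tol apart, aDIR = jittered subset + clutter
    tol <- 4
    repeat {
      C <- matrix(runif(nc * 3, 0, 80), nc)
      if (nc == 1 || min(dist(C)) > 4 * tol) break
    }
    keep <- sort(sample(seq_len(nc), sample(2:nc, 1)))
    A <- C[keep, , drop = FALSE] +
      matrix(runif(length(keep) * 3, -1, 1), ncol = 3)
    extra <- matrix(runif(3, 120, 150), 1)
    A <- rbind(A, extra)
    got <- matchLesions(recFromPoints(A, "aDIR"),
                        recFromPoints(C, "cDIR"), tolMm = tol)
    expect_equal(got@tp, bruteBestMatch(A, C, tol),
                 label = sprintf("greedy vs exhaustive, trial %d", trial))
    expect_equal(got@tp, length(keep))
  }
})

test_that("precision/recall: published-count identities and degenerate cases", {
  mk <- function(tp, fp, fn, subject = "s1")
    new("MatchResult", subject = subject,
        pairs = if (tp > 0) data.frame(a_id = seq_len(tp),
                                       c_id = seq_len(tp),
                                       dist_mm = 0)
                else data.frame(a_id = integer(), c_id = integer(),
                                dist_mm = numeric()),
        tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn))
  pr <- precisionRecall(list(mk(528, 98, 168)))
  expect_equal(round(unname(pr$pooled["precision"]), 2), 0.84)
  expect_equal(round(unname(pr$pooled["recall"]), 2), 0.76)
  # degenerate subject: zero precision denominator is excluded, recall 0
  pr2 <- precisionRecall(list(mk(0, 0, 5), mk(2, 2, 2, "s2")))
  expect_true(is.na(pr2$perSubject$precision[1]))
  expect_equal(pr2$perSubject$recall[1], 0)
  expect_equal(unname(pr2$meanSd["precision_mean"]), 0.5)
  expect_error(precisionRecall(list(mk(0, 0, 0))), "zero denominators")
  # pooled values invariant under subject order
  pr3 <- precisionRecall(list(mk(2, 2, 2, "s2"), mk(0, 0, 5)))
  expect_equal(pr3$pooled, pr2$pooled)
})

test_that("tabulation reproduces column percentages and conserves totals", {
  set.seed(7)
  lobes <- c("frontal", "temporal", "parietal", "occipital")
  types <- c("intracortical", "juxtacortical", "mixed")
  nA <- 30; nC <- 28
  aRec <- data.frame(subject_id = "s1", lesion_id = 1:nA,
                     centroid_x = runif(nA, 0, 100),
                     centroid_y = runif(nA, 0, 100),
                     centroid_z = runif(nA, 0, 100), area_mm2 = 5,
                     volume_mm3 = 1,
                     type = sample(types, nA, TRUE),
                     lobe = sample(lobes, nA, TRUE), source = "aDIR")
  cRec <- data.frame(subject_id = "s1", lesion_id = 1:nC,
                     centroid_x = runif(nC, 0, 100),
                     centroid_y = runif(nC, 0, 100),
                     centroid_z = runif(nC, 0, 100), area_mm2 = 5,
                     volume_mm3 = 1,
                     type = sample(types, nC, TRUE),
                     lobe = sample(lobes, nC, TRUE), source = "cDIR")
  m <- matchLesions(aRec, cRec, tolMm = 20)
  tab <- tabulateLesions(aRec, cRec, list(m))
  expect_equal(sum(tab$lobe$both), m@tp)
  expect_equal(sum(tab$lobe$aOnly), m@fp)
  expect_equal(sum(tab$lobe$cOnly), m@fn)
  expect_equal(sum(tab$type$both), m@tp)
  expect_equal(tab$lobe$both_pct,
               round(100 * tab$lobe$both / sum(tab$lobe$both), 1))
  # matched pairs take lobe/type from the conventional-DIR member
  cMatched <- cRec[cRec$lesion_id %in% m@pairs$c_id, ]
  expect_equal(sum(tab$type$both[tab$type$level == "intracortical"]),
               sum(cMatched$type == "intracortical"))
  bad <- aRec; bad$lobe[1] <- "insular"
  expect_error(tabulateLesions(bad, cRec, list(m)), "unknown lobe")
})

test_that("empty inputs tabulate to an all-zero table", {
  empty <- data.frame(subject_id = character(), lesion_id = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      centroid_z = numeric(), area_mm2 = numeric(),
                      volume_mm3 = numeric(), type = character(),
                      lobe = character(), source = character())
  m <- matchLesions(empty, empty)
  tab <- tabulateLesions(empty, empty, list(m))
  expect_true(all(tab$lobe[, c("both", "aOnly", "cOnly")] == 0))
})

test_that("planted lesions are recovered end-to-end from noisy DIR", {
  # simulated artificial DIR = analytic DIR + mild noise; the detector and
  # matcher should recover nearly all planted lesions with >= 5 mm2
  # cross-section
  recovered <- 0; planted <- 0
  for (seed in c(51, 52, 53)) {
    ph <- makeTissuePhantom(c(48, 48, 48), nLesions = 6,
                            lesionRadiusRange = c(1.6, 2.4), seed = seed)
    truthDIR <- simulateSequence(ph, defaultSequenceParams("DIR"),
                                 noiseSd = 0)
    noisy <- normalizeIntensity(
      simulateSequence(ph, defaultSequenceParams("DIR"), noiseSd = 0.05,
                       seed = seed + 1), brainMask(ph))@data
    gm <- tissueLabels(ph) == 2L
    rec <- detectCandidates(noisy, gm, zThresh = 3, subject = "s1",
                            source = "aDIR")
    meta <- lesionMeta(ph)
    for (i in meta$lesion_id) {
      les <- lesionMask(ph) == i
      area <- max(apply(les, 3, sum))
      if (area < 5) next
      planted <- planted + 1
      cen <- colMeans(arrayInd(which(les), dim(les)))
      d <- sqrt((rec$centroid_x - cen[1])^2 + (rec$centroid_y - cen[2])^2 +
                  (rec$centroid_z - cen[3])^2)
      if (length(d) && min(d) <= 5) recovered <- recovered + 1
    }
  }
  expect_gte(planted, 8)
  expect_gte(recovered / planted, 0.9)
})
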