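LESION_TYPES <- c("intracortical", "juxtacortical", "mixed")
LOBES <- c("frontal", "temporal", "parietal", "occipital")

#' Detect hyperintense lesion candidates on a DIR volume
#'
#' Automated stand-in for a human rater: voxels brighter than
#' `mean + zThresh * sd` of the normal-appearing grey-matter intensity are
#' grouped into 26-connected components; components that neither overlap
#' nor touch (1-voxel dilation) the grey-matter mask are dropped, as are
#' components whose largest in-plane (axial) cross-section is below
#' `minAreaMm2`, mirroring the operational rule that a cortical lesion
#' must measure at least 3 mm2. The grey-matter statistics use the plain
#' mean/sd over the whole grey-matter mask, which is slightly conservative
#' when lesions occupy part of it.
#'
#' @param dirVolume numeric 3D array (any monotone intensity scale).
#' @param gmMask logical 3D array of normal-appearing grey matter.
#' @param spacing voxel size (mm).
#' @param zThresh hyperintensity threshold in grey-matter SD units.
#' @param minAreaMm2 minimum largest axial cross-section (mm^2).
#' @param subject subject identifier stored in the records.
#' @param source detection source label (`"aDIR"` or `"cDIR"`).
#' @param lobeMap optional integer 3D array of lobe codes (1-4, order
#'   frontal, temporal, parietal, occipital) sampled at the centroid;
#'   when absent the lobe is derived from the centroid's axial angle
#'   about the mask centre, matching the phantom's angular parcellation.
#' @return data.frame of lesion records: `subject_id`, `lesion_id`,
#'   centroid (mm), `area_mm2`, `volume_mm3`, `type`, `lobe`, `source`.
#' @export
detectCandidates <- function(dirVolume, gmMask, spacing = c(1, 1, 1),
                             zThresh = 3, minAreaMm2 = 3,
                             subject = "s1", source = "aDIR",
                             lobeMap = NULL) {
  stopifnot3d(dirVolume)
  stopifnot(identical(dim(dirVolume), dim(gmMask)))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (!any(gmMask)) stop("grey-matter mask is empty")
  gmVals <- dirVolume[gmMask]
  thr <- mean(gmVals) + zThresh * sd(gmVals)
  hyper <- dirVolume > thr
  lab <- .labelComponents3d(as.logical(hyper), dim(dirVolume))
  nComp <- attr(lab, "n")
  empty <- data.frame(
    subject_id = character(), lesion_id = integer(), centroid_x = numeric(),
    centroid_y = numeric(), centroid_z = numeric(), area_mm2 = numeric(),
    volume_mm3 = numeric(), type = character(), lobe = character(),
    source = character(), stringsAsFactors = FALSE)
  if (nComp == 0L) return(empty)
  dims <- dim(dirVolume)
  gmGrown <- dilate1(gmMask)
  vox <- prod(spacing)
  ctrMask <- colMeans(arrayInd(which(gmMask), dims))
  recs <- empty
  id <- 0L
  for (cc in seq_len(nComp)) {
    lin <- which(lab == cc)
    if (!any(gmGrown[lin])) next
    coord <- arrayInd(lin, dims)
    # largest axial (xy-plane) cross-section in mm^2
    area <- max(tabulate(coord[, 3], nbins = dims[3])) *
      spacing[1] * spacing[2]
    if (area < minAreaMm2) next
    id <- id + 1L
    cen <- colMeans(coord)
    # fraction of the component inside or immediately adjacent to
    # normal-appearing grey matter decides its type class
    inGM <- mean(gmGrown[lin])
    type <- if (inGM >= 0.85) "intracortical"
      else if (inGM <= 0.45) "juxtacortical" else "mixed"
    lobe <- if (!is.null(lobeMap)) {
      LOBES[lobeMap[round(cen[1]), round(cen[2]), round(cen[3])]]
    } else {
      az <- atan2((cen[2] - ctrMask[2]) * spacing[2],
                  (cen[1] - ctrMask[1]) * spacing[1]) * 180 / pi
      if (az >= -45 && az < 45) "frontal"
      else if (az >= 45 && az < 135) "temporal"
      else if (az >= -135 && az < -45) "parietal"
      else "occipital"
    }
    recs <- rbind(recs, data.frame(
      subject_id = subject, lesion_id = id,
      centroid_x = cen[1] * spacing[1], centroid_y = cen[2] * spacing[2],
      centroid_z = cen[3] * spacing[3], area_mm2 = area,
      volume_mm3 = length(lin) * vox, type = type, lobe = lobe,
      source = source, stringsAsFactors = FALSE))
  }
  recs
}

# one-voxel 6-connected dilation
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

#' Match lesions between two detection sets of one subject
#'
#' Greedy one-to-one matching on ascending centroid distance: the closest
#' still-unmatched pair is accepted while its distance is at most `tolMm`;
#' leftover records from the artificial-DIR set count as false positives,
#' leftovers from the conventional-DIR set as false negatives.
#'
#' @param aRecords,cRecords lesion record data.frames (see
#'   [detectCandidates()]) from the same single subject.
#' @param tolMm matching radius (mm).
#' @return a [MatchResult-class].
#' @export
matchLesions <- function(aRecords, cRecords, tolMm = 5) {
  subj <- unique(c(aRecords$subject_id, cRecords$subject_id))
  if (length(subj) > 1L)
    stop("records mix subjects: ", paste(subj, collapse = ", "))
  if (length(subj) == 0L) subj <- "s1"
  na <- nrow(aRecords); nc <- nrow(cRecords)
  pairs <- data.frame(a_id = integer(), c_id = integer(),
                      dist_mm = numeric())
  if (na > 0L && nc > 0L) {
    am <- as.matrix(aRecords[, c("centroid_x", "centroid_y", "centroid_z")])
    cm <- as.matrix(cRecords[, c("centroid_x", "centroid_y", "centroid_z")])
    D <- outer(rowSums(am^2), rowSums(cm^2), `+`) - 2 * am %*% t(cm)
    D <- sqrt(pmax(D, 0))
    usedA <- logical(na); usedC <- logical(nc)
    ord <- order(D)
    for (o in ord) {
      if (D[o] > tolMm) break
      i <- (o - 1L) %% na + 1L
      j <- (o - 1L) %/% na + 1L
      if (usedA[i] || usedC[j]) next
      usedA[i] <- TRUE; usedC[j] <- TRUE
      pairs <- rbind(pairs, data.frame(
        a_id = aRecords$lesion_id[i], c_id = cRecords$lesion_id[j],
        dist_mm = D[o]))
    }
  }
  new("MatchResult", subject = subj, pairs = pairs,
      tp = nrow(pairs), fp = na - nrow(pairs), fn = nc - nrow(pairs))
}

#' Precision and recall over per-subject match results
#'
#' Per-subject precision `tp / (tp + fp)` and recall `tp / (tp + fn)`,
#' together with pooled values computed on the summed counts and the mean
#' and SD over subjects. Subjects with a zero denominator are excluded
#' from the corresponding mean (with a note attribute), not treated as 0.
#'
#' @param matches list of [MatchResult-class] objects (one per subject),
#'   or a single one.
#' @return list with `perSubject` (data.frame), `pooled`
#'   (precision/recall on summed counts), `meanSd`.
#' @export
precisionRecall <- function(matches) {
  if (is(matches, "MatchResult")) matches <- list(matches)
  stopifnot(length(matches) >= 1L)
  tab <- do.call(rbind, lapply(matches, function(m)
    data.frame(subject = m@subject, tp = m@tp, fp = m@fp, fn = m@fn)))
  tab$precision <- ifelse(tab$tp + tab$fp > 0, tab$tp / (tab$tp + tab$fp),
                          NA_real_)
  tab$recall <- ifelse(tab$tp + tab$fn > 0, tab$tp / (tab$tp + tab$fn),
                       NA_real_)
  if (all(is.na(tab$precision)) && all(is.na(tab$recall)))
    stop("all subjects have zero denominators")
  pooledP <- with(tab, if (sum(tp + fp) > 0) sum(tp) / sum(tp + fp)
                  else NA_real_)
  pooledR <- with(tab, if (sum(tp + fn) > 0) sum(tp) / sum(tp + fn)
                  else NA_real_)
  res <- list(
    perSubject = tab,
    pooled = c(precision = pooledP, recall = pooledR),
    meanSd = c(precision_mean = mean(tab$precision, na.rm = TRUE),
               precision_sd = sd(tab$precision[!is.na(tab$precision)]),
               recall_mean = mean(tab$recall, na.rm = TRUE),
               recall_sd = sd(tab$recall[!is.na(tab$recall)])))
  excl <- sum(is.na(tab$precision)) + sum(is.na(tab$recall))
  if (excl > 0)
    attr(res, "note") <- sprintf(
      "%d zero-denominator subject value(s) excluded from the means", excl)
  res
}

#' Tabulate matched and unmatched lesions by lobe and type
#'
#' Builds the three-column contingency summary of a reading session:
#' lesions detected on both images (matched pairs), artificial-DIR-only
#' detections, and conventional-DIR-only detections, broken down by lobe
#' and by lesion type with percentages of each column total (1 decimal).
#' A matched pair inherits lobe and type from its conventional-DIR member.
#'
#' @param aRecords,cRecords lesion record data.frames (possibly several
#'   subjects concatenated).
#' @param matches list of per-subject [MatchResult-class] objects.
#' @return list of data.frames `lobe` and `type` with columns `both`,
#'   `aOnly`, `cOnly` and matching percentage columns.
#' @export
tabulateLesions <- function(aRecords, cRecords, matches) {
  if (is(matches, "MatchResult")) matches <- list(matches)
  badT <- setdiff(unique(c(aRecords$type, cRecords$type)), LESION_TYPES)
  badL <- setdiff(unique(c(aRecords$lobe, cRecords$lobe)), LOBES)
  if (length(badT)) stop("unknown lesion type: ", paste(badT, collapse = ", "))
  if (length(badL)) stop("unknown lobe: ", paste(badL, collapse = ", "))
  key <- function(df) paste(df$subject_id, df$lesion_id)
  both <- aOnly <- cOnly <-
    data.frame(type = character(), lobe = character())
  for (m in matches) {
    aS <- aRecords[aRecords$subject_id == m@subject, , drop = FALSE]
    cS <- cRecords[cRecords$subject_id == m@subject, , drop = FALSE]
    both <- rbind(both, cS[cS$lesion_id %in% m@pairs$c_id,
                           c("type", "lobe")])
    aOnly <- rbind(aOnly, aS[!aS$lesion_id %in% m@pairs$a_id,
                             c("type", "lobe")])
    cOnly <- rbind(cOnly, cS[!cS$lesion_id %in% m@pairs$c_id,
                             c("type", "lobe")])
  }
  count <- function(vals, levels) {
    n <- table(factor(vals, levels = levels))
    as.integer(n)
  }
  mk <- function(field, levels) {
    nB <- count(both[[field]], levels)
    nA <- count(aOnly[[field]], levels)
    nC <- count(cOnly[[field]], levels)
    pct <- function(n) round(100 * n / max(sum(n), 1L), 1)
    data.frame(level = levels, both = nB, aOnly = nA, cOnly = nC,
               both_pct = pct(nB), aOnly_pct = pct(nA),
               cOnly_pct = pct(nC), stringsAsFactors = FALSE)
  }
  list(lobe = mk("lobe", LOBES), type = mk("type", LESION_TYPES))
}
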