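# AHA 16-segment model: circumferential sectors, longitudinal thirds,
# segment <-> imaging-plane (meridian) bookkeeping.
#
# Circumferential convention (fixed, documented): angles increase from the
# A4C wall-1 plane, which images the (infero)septum. Anatomical sector
# centers on this axis:
#   0 = inferoseptal, 60 = anteroseptal, 120 = anterior, 180 = anterolateral,
#   240 = inferolateral, 300 = inferior.
# Views are rotated 0/60/120 degrees about the long axis: A4C images
# 0/180, APLAX 60/240, A2C 120/300, so each view's wall pair matches the
# standard anatomy (A4C: septum + anterolateral wall; APLAX: anteroseptum +
# inferolateral wall; A2C: anterior + inferior wall).
#
# Longitudinal levels use the convention 0 = base, 1 = apex.

.viewAzimuth <- c(A4C = 0, APLAX = 60, A2C = 120)

# angle of the meridian imaged by (view, wall)
.meridianAngle <- function(view, wall) {
  unname(.viewAzimuth[view] + if (wall == 1L) 0 else 180)
}

# basal/mid sector centers by segment id
.sectorCenter <- c(`1` = 120, `2` = 60, `3` = 0, `4` = 300, `5` = 240,
                   `6` = 180, `7` = 120, `8` = 60, `9` = 0, `10` = 300,
                   `11` = 240, `12` = 180,
                   # apical (90-degree sectors)
                   `13` = 120, `14` = 30, `15` = 300, `16` = 210)

#' Segment names of the AHA 16-segment model
#'
#' @return named character vector, names are segment ids 1..16.
#' @export
segmentNames <- function() {
  c(`1` = "basal anterior", `2` = "basal anteroseptal",
    `3` = "basal inferoseptal", `4` = "basal inferior",
    `5` = "basal inferolateral", `6` = "basal anterolateral",
    `7` = "mid anterior", `8` = "mid anteroseptal",
    `9` = "mid inferoseptal", `10` = "mid inferior",
    `11` = "mid inferolateral", `12` = "mid anterolateral",
    `13` = "apical anterior", `14` = "apical septal",
    `15` = "apical inferior", `16` = "apical lateral")
}

# signed angular difference a - b wrapped to [-180, 180)
.angDiff <- function(a, b) {
  ((a - b + 180) %% 360) - 180
}

#' Map a mesh position to its AHA segment
#'
#' Longitudinal thirds (basal/mid/apical) by level; basal and mid thirds are
#' split into six 60-degree circumferential sectors, the apical third into
#' four 90-degree sectors (no apical cap).
#'
#' @param levelFrac longitudinal level, 0 = base, 1 = apex (vectorised).
#' @param angleDeg circumferential angle in degrees (vectorised), on the
#'   package's circumferential axis (0 = inferoseptal plane).
#' @return integer segment ids 1..16.
#' @export
segmentAt <- function(levelFrac, angleDeg) {
  n <- max(length(levelFrac), length(angleDeg))
  levelFrac <- rep_len(levelFrac, n)
  angleDeg <- rep_len(angleDeg, n)
  stopifnot(all(levelFrac >= 0 & levelFrac <= 1))
  third <- ifelse(levelFrac < 1 / 3, "basal",
                  ifelse(levelFrac < 2 / 3, "mid", "apical"))
  out <- integer(n)
  for (i in seq_len(n)) {
    ids <- switch(third[i], basal = 1:6, mid = 7:12, apical = 13:16)
    half <- if (third[i] == "apical") 45 else 30
    d <- abs(.angDiff(angleDeg[i], .sectorCenter[as.character(ids)]))
    # sector membership is half-open [center - half, center + half)
    inside <- .angDiff(angleDeg[i], .sectorCenter[as.character(ids)]) >= -half &
      .angDiff(angleDeg[i], .sectorCenter[as.character(ids)]) < half
    out[i] <- if (any(inside)) ids[which(inside)[1L]] else ids[which.min(d)]
  }
  out
}

# For strain extraction: which meridians (view, wall) contribute to each
# segment, and the segment's longitudinal span in arc-from-apex fraction
# u (u = 1 - level). Basal/mid sectors are centered on a single imaged
# meridian; apical 90-degree sectors contain one or two meridians.
.segmentMeridians <- function() {
  m <- list(
    `1`  = 120, `2`  = 60,  `3`  = 0,   `4`  = 300, `5`  = 240, `6`  = 180,
    `7`  = 120, `8`  = 60,  `9`  = 0,   `10` = 300, `11` = 240, `12` = 180,
    `13` = 120, `14` = c(0, 60), `15` = 300, `16` = c(180, 240))
  lapply(m, function(a) {
    data.frame(
      view = vapply(a, function(x) {
        names(.viewAzimuth)[match(x %% 180, .viewAzimuth)]
      }, character(1)),
      wall = ifelse(a < 180, 1L, 2L),
      angle = a)
  })
}

# arc-from-apex span [uLo, uHi] of a segment's third; the apical span starts
# above the discarded apex-most fraction of the apical third
.segmentSpanU <- function(segmentId, apicalDiscardFrac = 0.25) {
  third <- ifelse(segmentId <= 6L, 0L, ifelse(segmentId <= 12L, 1L, 2L))
  switch(as.character(third),
    `0` = c(2 / 3, 1),
    `1` = c(1 / 3, 2 / 3),
    `2` = c(apicalDiscardFrac / 3, 1 / 3))
}

#' Coronary territory map of the 16-segment model
#'
#' Segments 1, 2, 7, 8, 13, 14 form the LAD territory, 5, 6, 11, 12, 16 the
#' CX territory and 3, 4, 9, 10, 15 the RCA territory. The partition property
#' (three disjoint sets covering 1..16, sizes 6/5/5) is asserted on creation.
#'
#' @return named list of integer segment-id vectors `LAD`, `CX`, `RCA`.
#' @export
territoryMap <- function() {
  map <- list(LAD = c(1L, 2L, 7L, 8L, 13L, 14L),
              CX  = c(5L, 6L, 11L, 12L, 16L),
              RCA = c(3L, 4L, 9L, 10L, 15L))
  all16 <- sort(unlist(map, use.names = FALSE))
  stopifnot(identical(all16, 1:16),
            lengths(map) == c(6L, 5L, 5L))
  map
}

#' Label mesh subsegments with AHA segments and the apical discard mask
#'
#' Each lattice cell (between adjacent longitudinal levels and circumferential
#' angles) is assigned a segment by its center, and its 3D area at the first
#' mesh frame is computed. Cells in the apex-most `apicalDiscardFrac` of the
#' apical third's longitudinal extent are marked `discard = TRUE` and are
#' excluded from all segment statistics downstream.
#'
#' @param mesh a [Mesh3D-class].
#' @param apicalDiscardFrac discarded apex-most fraction of the apical third
#'   (default 0.25).
#' @param frame frame index at which cell areas are measured (default 1).
#' @return data.frame with one row per cell: `levelIdx`, `angleIdx`,
#'   `level` (0 = base, 1 = apex), `angle` (deg), `segment`, `discard`,
#'   `areaMm2`.
#' @export
assignSegments <- function(mesh, apicalDiscardFrac = 0.25, frame = 1L) {
  stopifnot(is(mesh, "Mesh3D"))
  u <- mesh@apexFrac
  ang <- mesh@angles
  L <- length(u); C <- length(ang)
  nodes <- mesh@nodes[frame, , , , drop = TRUE]  # [level, angle, 3]
  dim(nodes) <- c(L, C, 3L)
  lv <- rep(seq_len(L - 1L), times = C)
  an <- rep(seq_len(C), each = L - 1L)
  an2 <- an %% C + 1L  # wrap circumferentially
  uC <- (u[lv] + u[lv + 1L]) / 2
  dAng <- .angDiff(ang[an2], ang[an]) / 2
  angC <- (ang[an] + dAng) %% 360
  level <- 1 - uC
  seg <- segmentAt(level, angC)
  discard <- level > 1 - apicalDiscardFrac / 3
  # quad area: two triangles (p1 p2 p3) + (p1 p3 p4)
  p1 <- nodes[cbind(rep(lv, 3L), rep(an, 3L), rep(1:3, each = length(lv)))]
  dim(p1) <- c(length(lv), 3L)
  p2 <- nodes[cbind(rep(lv + 1L, 3L), rep(an, 3L), rep(1:3, each = length(lv)))]
  dim(p2) <- c(length(lv), 3L)
  p3 <- nodes[cbind(rep(lv + 1L, 3L), rep(an2, 3L), rep(1:3, each = length(lv)))]
  dim(p3) <- c(length(lv), 3L)
  p4 <- nodes[cbind(rep(lv, 3L), rep(an2, 3L), rep(1:3, each = length(lv)))]
  dim(p4) <- c(length(lv), 3L)
  area <- .triArea(p1, p2, p3) + .triArea(p1, p3, p4)
  data.frame(levelIdx = lv, angleIdx = an, level = level, angle = angC,
             segment = seg, discard = discard, areaMm2 = area)
}

# rowwise triangle areas for n x 3 point matrices
.triArea <- function(a, b, c) {
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}
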