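# Papillary-muscle modelling: statistics-driven specs, the
# cylinder-plus-paraboloid solid, and merging a PM into the LV endocardium.

.PM_STATS <- list(
  APM = list(lenN = c(33.6, 5.3), diamN = c(8.9, 1.7),
             tipAngle = c(19.9, 6.3), tipDist = c(24.1, 3.1),
             azimuthDeg = 240, attachZfrac = 0.40, angleSign = 1),
  PPM = list(lenN = c(27.6, 5.5), diamN = c(8.3, 1.9),
             tipAngle = c(27.8, 12.2), tipDist = c(21.7, 3.8),
             azimuthDeg = 120, attachZfrac = 0.40, angleSign = -1))

#' Paraboloid cap height of the papillary-muscle profile
#'
#' z(r) = L - 4 * 0.4 * L * r^2 / d^2: the cap spans z in [0.6 L, L] for
#' r in [d/2, 0], capping the cylinder that makes up 60% of the PM length.
#'
#' @param r radial coordinate (mm), 0 at the PM axis.
#' @param L PM length (mm).
#' @param d PM diameter (mm).
#' @return height above the PM base (mm).
#' @export
pmParaboloidHeight <- function(r, L, d) {
  L - 4 * 0.4 * L * r^2 / d^2
}

# PM radius at axial station s in [0, L].
.pmRadius <- function(s, L, d) {
  ifelse(s <= 0.6 * L, d / 2, (d / 2) * sqrt(pmax(0, (L - s) / (0.4 * L))))
}

#' Draw papillary-muscle parameters from the printed statistics
#'
#' Length and diameter are Gaussian in normalized units (percent of LV
#' length), tip angle and tip distance in absolute units; all draws are
#' truncated at three standard deviations and redrawn until d < L.
#'
#' @param lvLength LV length of the target heart (mm).
#' @param side "APM" or "PPM".
#' @param fixed if TRUE all standard deviations are forced to zero
#'   (population-mean PM).
#' @return a \linkS4class{PMSpec}. Uses the current RNG stream; wrap in a
#'   seeded context for reproducibility.
#' @export
samplePmSpec <- function(lvLength, side = c("APM", "PPM"), fixed = FALSE) {
  side <- match.arg(side)
  if (lvLength <= 0) stop("lvLength must be positive")
  st <- .PM_STATS[[side]]
  sd0 <- function(ms) if (fixed) c(ms[1], 0) else ms
  for (attempt in seq_len(100)) {
    L <- rnormTrunc(1, sd0(st$lenN)[1], sd0(st$lenN)[2],
                    positive = TRUE) / 100 * lvLength
    d <- rnormTrunc(1, sd0(st$diamN)[1], sd0(st$diamN)[2],
                    positive = TRUE) / 100 * lvLength
    ang <- rnormTrunc(1, sd0(st$tipAngle)[1], sd0(st$tipAngle)[2],
                      positive = TRUE)
    tdist <- rnormTrunc(1, sd0(st$tipDist)[1], sd0(st$tipDist)[2],
                        positive = TRUE)
    if (d < L && ang < 90) {
      return(new("PMSpec", side = side, length = L, diameter = d,
                 attachmentPoint = c(0, 0, 0), attachmentTriangle = 0L,
                 tipAngle = ang, tipDistance = tdist,
                 paraboloidFraction = 0.4))
    }
  }
  stop("could not draw a valid PM spec in 100 attempts")
}

# Ring layout of a PM cross-section: centre + three rings (8/16/32 points)
# at radius fractions 1/3, 2/3, 1.
.pmDiscLayout <- function() {
  list(counts = c(8L, 16L, 32L), fracs = c(1 / 3, 2 / 3, 1))
}

# Triangulation of the disc layout (indices 1 = centre, then rings).
.pmDiscTriangles <- function() {
  lay <- .pmDiscLayout()
  tris <- NULL
  ringStart <- c(2L, 2L + lay$counts[1], 2L + lay$counts[1] + lay$counts[2])
  # centre fan to ring 1
  n1 <- lay$counts[1]
  r1 <- ringStart[1] + 0:(n1 - 1)
  tris <- rbind(tris, cbind(1L, r1, r1[c(2:n1, 1)]))
  # ring-to-ring strips (outer ring has twice the points, aligned 2:1)
  for (k in 1:2) {
    ni <- lay$counts[k]
    no <- lay$counts[k + 1]
    ri <- ringStart[k] + 0:(ni - 1)
    ro <- ringStart[k + 1] + 0:(no - 1)
    nxt <- function(v, n, s) v[(s %% n) + 1]
    for (i in 0:(ni - 1)) {
      inA <- ri[i + 1]
      inB <- nxt(ri, ni, i + 1 - 1 + 1)
      oA <- ro[2 * i + 1]
      oB <- nxt(ro, no, 2 * i + 1)
      oC <- nxt(ro, no, 2 * i + 2)
      tris <- rbind(tris,
                    c(inA, oA, oB),
                    c(inA, oB, inB),
                    c(inB, oB, oC))
    }
  }
  tris
}

# Points of one station disc in the PM local frame (axis along +w).
.pmStationPoints <- function(origin, w, u, v, s, L, d) {
  lay <- .pmDiscLayout()
  R <- .pmRadius(s, L, d)
  pts <- matrix(origin + s * w, 1, 3, byrow = TRUE)
  for (k in seq_along(lay$counts)) {
    n <- lay$counts[k]
    beta <- 2 * pi * (0:(n - 1)) / n
    r <- R * lay$fracs[k]
    ring <- sweep(outer(cos(beta), u * r) + outer(sin(beta), v * r), 2,
                  origin + s * w, "+")
    pts <- rbind(pts, ring)
  }
  pts
}

#' Build the closed lateral surface of a papillary muscle
#'
#' Cylinder of height 0.6 L and diameter d capped by the paraboloid
#' z(r) = L - 4 * 0.4 * L * r^2 / d^2; open at the base (z = 0), axis along
#' +z in the PM-local frame.
#'
#' @param spec a \linkS4class{PMSpec}.
#' @return list with \code{vertices}, \code{triangles} (outward-oriented)
#'   and \code{baseRing} (indices of the open base ring, outer ring of the
#'   z = 0 station).
#' @export
buildPmSurface <- function(spec) {
  L <- spec@length
  d <- spec@diameter
  if (!(L > 0 && d > 0 && d < L)) stop("degenerate PM spec")
  nO <- .pmDiscLayout()$counts[3]
  # axial stations: cylinder part + refined cap
  sCyl <- seq(0, 0.6 * L, length.out = max(4, ceiling(0.6 * L / 2.5) + 1))
  sCap <- 0.6 * L + 0.4 * L * (seq(0, 1, length.out = 7)[-1])^1.0
  sCap <- sCap[sCap < L - 1e-9]
  ss <- c(sCyl, sCap)
  verts <- NULL
  ringIdx <- list()
  for (s in ss) {
    R <- .pmRadius(s, L, d)
    beta <- 2 * pi * (0:(nO - 1)) / nO
    ring <- cbind(R * cos(beta), R * sin(beta), rep(s, nO))
    ringIdx[[length(ringIdx) + 1]] <- nrow(verts %||% matrix(0, 0, 3)) +
      seq_len(nO)
    verts <- rbind(verts, ring)
  }
  tip <- c(0, 0, L)
  verts <- rbind(verts, tip)
  tipIdx <- nrow(verts)
  ip1 <- c(2:nO, 1L)
  tris <- NULL
  for (m in seq_len(length(ss) - 1)) {
    a <- ringIdx[[m]]
    b <- ringIdx[[m + 1]]
    tris <- rbind(tris,
                  cbind(a, a[ip1], b[ip1]),
                  cbind(a, b[ip1], b))
  }
  last <- ringIdx[[length(ringIdx)]]
  tris <- rbind(tris, cbind(last, last[ip1], tipIdx))
  list(vertices = verts, triangles = tris, baseRing = ringIdx[[1]],
       tipIndex = tipIdx)
}

#' Analytic papillary-muscle volume
#'
#' Cylinder plus paraboloid cap: pi (d/2)^2 (0.6 L) + (pi/2) (d/2)^2 (0.4 L).
#'
#' @param spec a \linkS4class{PMSpec}.
#' @return volume (mm^3).
#' @export
pmAnalyticVolume <- function(spec) {
  r <- spec@diameter / 2
  pi * r^2 * 0.6 * spec@length + (pi / 2) * r^2 * 0.4 * spec@length
}

# LV long axis of a surface: origin at the apex, unit direction to the
# mitral centre, plus an orthonormal in-plane basis.
.lvAxis <- function(surface) {
  apex <- surface@vertices[surface@landmarks[["lvApex"]], ]
  mc <- .mitralCentre(surface)
  w <- normalize(mc - apex)
  # in-plane basis chosen so the azimuth reduces to atan2(y, x) when the
  # axis is +z (the septal azimuth is 0 by construction)
  ref <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize(ref - w * sum(ref * w))
  v <- crossProd3(w, u)
  list(origin = apex, dir = w, u = u, v = v)
}

.axisCoords <- function(p, axis) {
  rel <- if (is.matrix(p)) sweep(p, 2, axis$origin) else
    matrix(p - axis$origin, 1)
  z <- as.numeric(rel %*% axis$dir)
  x <- as.numeric(rel %*% axis$u)
  y <- as.numeric(rel %*% axis$v)
  cbind(az = atan2(y, x), r = sqrt(x^2 + y^2), z = z)
}

# Resolve the PM placement on a surface: attachment vertex, tip point and
# axis. tipAngle is honoured exactly; tipDistance is softened when the
# implied chord exceeds the PM length.
.resolvePmPlacement <- function(surface, spec, azimuthDeg = NULL,
                                attachZfrac = NULL, tipDistanceRelax = 0.1) {
  st <- .PM_STATS[[spec@side]]
  azimuthDeg <- azimuthDeg %||% st$azimuthDeg
  attachZfrac <- attachZfrac %||% st$attachZfrac
  axis <- .lvAxis(surface)
  endoV <- sort(unique(as.vector(
    surface@triangles[surface@region == .REGION[["LV_ENDO"]], ])))
  ac <- .axisCoords(surface@vertices[endoV, , drop = FALSE], axis)
  lvLen <- lvLength(surface)
  targetZ <- attachZfrac * lvLen
  want <- azimuthDeg * pi / 180
  score <- (abs(.wrapAngle(ac[, "az"] - want)) * 20)^2 +
    (ac[, "z"] - targetZ)^2
  va <- endoV[which.min(score)]
  p0 <- surface@vertices[va, ]
  a0 <- .axisCoords(p0, axis)
  alphaT <- a0[1, "az"] + st$angleSign * spec@tipAngle * pi / 180
  rt <- spec@tipDistance
  h2 <- function(rt) a0[1, "r"]^2 + rt^2 -
    2 * a0[1, "r"] * rt * cos(st$angleSign * spec@tipAngle * pi / 180)
  # soften the tip distance if the horizontal chord exceeds 90% of L
  while (sqrt(h2(rt)) > 0.9 * spec@length && rt > 0.5)
    rt <- rt * 0.97
  zt <- a0[1, "z"] + sqrt(spec@length^2 - h2(rt))
  tip <- axis$origin + axis$dir * zt + (axis$u * cos(alphaT) +
                                          axis$v * sin(alphaT)) * rt
  # penetration check: the tip must stay inside the cavity; pull the tip
  # toward the axis (within the allowed relaxation) if it would not
  tipAt <- function(rt) {
    zt <- a0[1, "z"] + sqrt(max(spec@length^2 - h2(rt), 0))
    axis$origin + axis$dir * zt + (axis$u * cos(alphaT) +
                                     axis$v * sin(alphaT)) * rt
  }
  penetrates <- function(tip) {
    d2 <- colSums((t(surface@vertices[endoV, , drop = FALSE]) - tip)^2)
    near <- endoV[which.min(d2)]
    rNear <- .axisCoords(surface@vertices[near, ], axis)[1, "r"]
    .axisCoords(tip, axis)[1, "r"] > rNear + 0.75
  }
  rtMin <- (1 - tipDistanceRelax) * spec@tipDistance
  while (penetrates(tip) && rt * 0.95 >= rtMin) {
    rt <- rt * 0.95
    tip <- tipAt(rt)
  }
  if (penetrates(tip))
    stop("PM tip penetrating the opposite wall: placement error")
  list(vertex = va, point = p0, tip = tip,
       axisDir = normalize(tip - p0), axis = axis, tipRadius = rt)
}

# Ordered boundary loop (vertex cycle) of a set of removed triangles.
.holeLoop <- function(triangles, removed) {
  edges <- function(t) rbind(t[, c(1, 2)], t[, c(2, 3)], t[, c(3, 1)])
  eAll <- edges(triangles[removed, , drop = FALSE])
  key <- paste(pmin(eAll[, 1], eAll[, 2]), pmax(eAll[, 1], eAll[, 2]))
  cnt <- table(key)
  boundaryKey <- names(cnt)[cnt == 1L]
  if (!length(boundaryKey)) stop("PM footprint removal produced no boundary")
  bk <- do.call(rbind, strsplit(boundaryKey, " "))
  be <- cbind(as.integer(bk[, 1]), as.integer(bk[, 2]))
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  start <- be[1, 1]
  loop <- c(start)
  prev <- -1L
  cur <- start
  repeat {
    nb <- adj[[as.character(cur)]]
    nxt <- nb[nb != prev][1]
    if (is.na(nxt)) stop("open PM footprint boundary")
    if (nxt == start) break
    loop <- c(loop, nxt)
    prev <- cur
    cur <- nxt
    if (length(loop) > 10000) stop("failed to close PM footprint boundary")
  }
  loop
}

# Stitch two closed loops into a triangle band. Both loops are given as
# cyclic vertex sequences with a normalized parameter in [0, 1) (cumulative
# arc length for the hole boundary, azimuth fraction for the PM base ring);
# a two-pointer merge walks both in parameter order.
.stitchLoops <- function(idxA, tA, idxB, tB) {
  oa <- order(tA)
  ob <- order(tB)
  A <- idxA[oa]
  B <- idxB[ob]
  aa <- tA[oa]
  bb <- tB[ob]
  na <- length(A)
  nb <- length(B)
  at <- function(v, n, k) v[(k - 1L) %% n + 1L]
  tAt <- function(v, n, k) v[(k - 1L) %% n + 1L] + ((k - 1L) %/% n)
  tris <- NULL
  i <- 1L
  j <- 1L
  while (i <= na || j <= nb) {
    aNext <- if (i <= na) tAt(aa, na, i + 1L) else Inf
    bNext <- if (j <= nb) tAt(bb, nb, j + 1L) else Inf
    if (aNext <= bNext) {
      tris <- rbind(tris, c(at(A, na, i), at(A, na, i + 1L), at(B, nb, j)))
      i <- i + 1L
    } else {
      tris <- rbind(tris, c(at(B, nb, j), at(A, na, i), at(B, nb, j + 1L)))
      j <- j + 1L
    }
  }
  tris
}

#' Merge a papillary muscle into the LV endocardium
#'
#' Positions the PM solid with its base at the statistically chosen
#' attachment point, tilts it so that the tip honours the tip-angle (exact)
#' and tip-distance (soft) statistics, removes the endocardial triangles in
#' the attachment footprint and stitches the PM base ring to the hole
#' boundary, yielding a single watertight surface. PM triangles are
#' labelled APM or PPM.
#'
#' @param surface a \linkS4class{VentricularSurface}.
#' @param spec a \linkS4class{PMSpec}.
#' @param azimuthDeg,attachZfrac optional overrides of the attachment site
#'   (azimuth about the LV axis in degrees; height as a fraction of LV
#'   length).
#' @param tipDistanceRelax allowed fractional reduction of the tip
#'   distance when the nominal placement would cross the opposite wall.
#' @return the merged \linkS4class{VentricularSurface}; the resolved
#'   placement is recorded in \code{meta$pmSpecs}.
#' @export
attachPm <- function(surface, spec, azimuthDeg = NULL, attachZfrac = NULL,
                     tipDistanceRelax = 0.1) {
  pl <- .resolvePmPlacement(surface, spec, azimuthDeg, attachZfrac,
                            tipDistanceRelax)
  w <- pl$axisDir
  pb <- planeBasis(w)
  pm <- buildPmSurface(spec)
  # map PM-local (x,y,z) into world: base at attachment point
  world <- pm$vertices[, 1] %o% pb$u + pm$vertices[, 2] %o% pb$v +
    pm$vertices[, 3] %o% w
  world <- sweep(world, 2, pl$point, "+")

  verts <- surface@vertices
  tris <- surface@triangles
  region <- surface@region
  # remove endo triangles in the footprint (centroid within ~1.15 r of the
  # PM axis near the base); shrink the footprint and retry if the hole
  # boundary is not a simple loop
  cent <- (verts[tris[, 1], ] + verts[tris[, 2], ] + verts[tris[, 3], ]) / 3
  rel <- sweep(cent, 2, pl$point)
  axial <- as.numeric(rel %*% w)
  perp2 <- rowSums(rel^2) - axial^2
  loop <- NULL
  for (shrink in c(1.15, 1.0, 0.85, 0.7)) {
    rf <- shrink * spec@diameter / 2
    inFoot <- region == .REGION[["LV_ENDO"]] & perp2 < rf^2 &
      abs(axial) < spec@diameter
    if (!any(inFoot)) next
    loopTry <- tryCatch(.holeLoop(tris, inFoot), error = function(e) NULL)
    if (!is.null(loopTry) && !anyDuplicated(loopTry)) {
      loop <- loopTry
      break
    }
  }
  if (is.null(loop)) stop("PM attachment footprint has no simple boundary")

  off <- nrow(verts)
  verts <- rbind(verts, world)
  pmTris <- pm$triangles + off
  baseRing <- pm$baseRing + off
  tipIdx <- pm$tipIndex + off

  angOf <- function(idx) {
    rel <- sweep(verts[idx, , drop = FALSE], 2, pl$point)
    atan2(as.numeric(rel %*% pb$v), as.numeric(rel %*% pb$u))
  }
  # orient the hole loop counter-clockwise about the PM axis and
  # parameterize both loops in [0, 1)
  angL <- angOf(loop)
  wind <- sum(.wrapAngle(diff(c(angL, angL[1]))))
  if (wind < 0) {
    loop <- rev(loop)
    angL <- angOf(loop)
  }
  segLen <- sqrt(rowSums((verts[c(loop[-1], loop[1]), , drop = FALSE] -
                          verts[loop, , drop = FALSE])^2))
  tLoop <- (cumsum(c(0, segLen[-length(segLen)]))) / sum(segLen)
  angR <- angOf(baseRing)
  tRing <- ((angR - angL[1]) / (2 * pi)) %% 1
  band <- .stitchLoops(loop, tLoop, baseRing, tRing)

  regCode <- .REGION[[spec@side]]
  keep <- !inFoot
  newTris <- rbind(tris[keep, , drop = FALSE], pmTris, band)
  newReg <- c(region[keep], rep(regCode, nrow(pmTris)),
              rep(regCode, nrow(band)))

  # orient the two added sheets (PM lateral surface and stitch band) so
  # the wall-material volume grows by close to the analytic PM volume
  v0 <- enclosedVolume(surface@vertices, tris[keep, , drop = FALSE])
  nk <- sum(keep)
  pmRows <- nk + seq_len(nrow(pmTris))
  bandRows <- nk + nrow(pmTris) + seq_len(nrow(band))
  target <- v0 + pmAnalyticVolume(spec)
  bestTris <- NULL
  bestErr <- Inf
  for (fp in c(FALSE, TRUE)) for (fb in c(FALSE, TRUE)) {
    tt <- newTris
    if (fp) tt[pmRows, c(2, 3)] <- tt[pmRows, c(3, 2)]
    if (fb) tt[bandRows, c(2, 3)] <- tt[bandRows, c(3, 2)]
    err <- abs(enclosedVolume(verts, tt) - target)
    if (err < bestErr) {
      bestErr <- err
      bestTris <- tt
    }
  }
  newTris <- bestTris

  out <- surface
  out@vertices <- verts
  out@triangles <- newTris
  out@region <- as.integer(newReg)
  rec <- list(spec = spec, attachmentPoint = pl$point,
              attachmentVertex = pl$vertex, tip = pl$tip,
              axisDir = w, tipVertex = tipIdx, tipRadius = pl$tipRadius)
  out@meta$pmSpecs <- c(out@meta$pmSpecs %||% list(), list(rec))
  # record the resolved attachment fields on the PMSpec
  spec@attachmentPoint <- pl$point
  tri0 <- which(inFoot)[1]
  spec@attachmentTriangle <- as.integer(tri0)
  out@meta$pmSpecs[[length(out@meta$pmSpecs)]]$spec <- spec
  out
}

#' Enclosed LV cavity volume
#'
#' Volume bounded by the LV endocardium (including merged papillary
#' muscles), capped at the base by a fan to the mitral-valve centre.
#'
#' @param surface a \linkS4class{VentricularSurface}.
#' @return volume (mm^3).
#' @export
lvCavityVolume <- function(surface) {
  sel <- surface@region %in% c(.REGION[["LV_ENDO"]], .REGION[["APM"]],
                               .REGION[["PPM"]])
  tris <- surface@triangles[sel, , drop = FALSE]
  # boundary loop(s) of the endo sheet = basal ring; cap with a fan
  eAll <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- paste(pmin(eAll[, 1], eAll[, 2]), pmax(eAll[, 1], eAll[, 2]))
  cnt <- table(key)
  bKey <- names(cnt)[cnt == 1L]
  mc <- surface@landmarks[["mitralCentre"]]
  bk <- do.call(rbind, strsplit(bKey, " "))
  be <- cbind(as.integer(bk[, 1]), as.integer(bk[, 2]))
  # orient boundary edges as they appear in the sheet (so the cap matches)
  eDir <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  keyDir <- paste(pmin(eDir[, 1], eDir[, 2]), pmax(eDir[, 1], eDir[, 2]))
  dirMap <- eDir[match(bKey, keyDir), , drop = FALSE]
  cap <- cbind(dirMap[, 2], dirMap[, 1], mc)
  vol <- enclosedVolume(surface@vertices, rbind(tris, cap))
  abs(vol)
}
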