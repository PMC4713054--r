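# Tetrahedral meshing of the myocardial wall.
#
# Surfaces produced by the package's shape model carry their parametric
# provenance, so the wall is meshed by structured extrusion between the
# endocardial and epicardial sheets (with the papillary muscles added as
# structured blocks snapped onto the endocardial layer). Generic closed
# surfaces are meshed with a star-shaped "onion layer" scheme (scaled
# copies of the boundary toward the centroid), which reproduces the
# enclosed volume exactly for star-shaped domains such as the test cube.

#' Tetrahedralize a ventricular (or generic closed) surface
#'
#' @param surface a \linkS4class{VentricularSurface}.
#' @param targetVertices approximate vertex count of the resulting mesh
#'   (default 70000; the result is within about 20% of the target).
#' @return a \linkS4class{VolumeMesh} with per-vertex labels, transmural
#'   coordinate, endo/epi flags and lumped nodal volumes.
#' @export
tetrahedralize <- function(surface, targetVertices = 70000L) {
  if (isTRUE(surface@meta$parametric)) {
    .meshParametricHeart(surface, targetVertices)
  } else {
    .meshStarShaped(surface, targetVertices)
  }
}

.meshParametricHeart <- function(surface, targetVertices) {
  meta <- surface@meta
  cfg <- meta$cfg
  f <- targetVertices / 70000
  nT <- max(24L, round(140 * sqrt(f)))
  nP <- max(18L, round(100 * sqrt(f)))
  ne <- 3L
  neRV <- 2L
  th <- 2 * pi * (seq_len(nT) - 1) / nT
  uu <- seq_len(nP) / nP
  ee <- (0:ne) / ne

  grid <- expand.grid(i = seq_len(nT), j = seq_len(nP))
  gTheta <- th[grid$i]
  gU <- uu[grid$j]
  rv <- .rvProfile(gTheta, gU, cfg)
  inrv <- rv$f > 1e-3
  inrvM <- matrix(FALSE, nT, nP)
  inrvM[cbind(grid$i, grid$j)] <- inrv

  pos <- NULL
  par <- NULL
  apexIdx <- integer(ne + 1L)
  lvIdx <- array(NA_integer_, c(nT, nP, ne + 1L))
  add <- function(p, pr) {
    start <- nrow(pos %||% matrix(0, 0, 3))
    pos <<- rbind(pos, p)
    par <<- rbind(par, pr)
    start + seq_len(nrow(p))
  }
  for (k in 0:ne) {
    apexIdx[k + 1L] <- add(.lvPoints(0, 0, ee[k + 1L], cfg),
                           data.frame(kind = "apex", theta = 0, u = 0,
                                      eEff = ee[k + 1L], isRV = FALSE))
    ids <- add(.lvPoints(gTheta, gU, ee[k + 1L], cfg),
               data.frame(kind = "lv", theta = gTheta, u = gU,
                          eEff = ee[k + 1L], isRV = FALSE))
    lvIdx[cbind(grid$i, grid$j, k + 1L)] <- ids
  }
  # RV shell: new nodes where the cavity exists, otherwise collapse onto
  # the LV epicardial node (conformal pinch seam)
  rvIdx <- array(NA_integer_, c(nT, nP, neRV + 1L))
  epiPos <- .lvPoints(gTheta, gU, 1, cfg)
  rdir <- cbind(cos(gTheta), sin(gTheta), 0)
  sel <- which(inrv)
  for (l in 0:neRV) {
    layer <- lvIdx[, , ne + 1L] # default: collapsed to epi
    if (length(sel)) {
      off <- rv$depth[sel] + (l / neRV) * rv$thick[sel]
      ids <- add(epiPos[sel, , drop = FALSE] + off * rdir[sel, , drop = FALSE],
                 data.frame(kind = "rv", theta = gTheta[sel], u = gU[sel],
                            eEff = l / neRV, isRV = TRUE))
      layer[cbind(grid$i[sel], grid$j[sel])] <- ids
    }
    rvIdx[, , l + 1L] <- layer
  }

  # deform to the sampled shape (+ optional rescale)
  pos <- .applySampleTransform(pos, par, cfg, meta)

  # --- tetrahedra -----------------------------------------------------
  ip1 <- c(2:nT, 1L)
  tets <- vector("list", 8L)
  tn <- 0L
  pushTets <- function(t) {
    tn <<- tn + 1L
    tets[[tn]] <<- t
  }
  for (k in 1:ne) {
    a <- lvIdx[, , k]
    b <- lvIdx[, , k + 1L]
    # apex cap wedges (ring j = 1)
    w6 <- cbind(apexIdx[k], a[, 1], a[ip1, 1],
                apexIdx[k + 1L], b[, 1], b[ip1, 1])
    pushTets(wedgeGridToTets(w6))
    # ring hexes
    h8 <- cbind(as.vector(a[, -nP]), as.vector(a[ip1, -nP]),
                as.vector(a[ip1, -1]), as.vector(a[, -1]),
                as.vector(b[, -nP]), as.vector(b[ip1, -nP]),
                as.vector(b[ip1, -1]), as.vector(b[, -1]))
    pushTets(hexGridToTets(h8))
  }
  cellAny <- inrvM | inrvM[ip1, ] | cbind(inrvM[, -1], FALSE) |
    cbind(inrvM[, -1], FALSE)[ip1, ]
  cellSel <- as.vector(cellAny[, -nP])
  for (l in 1:neRV) {
    a <- rvIdx[, , l]
    b <- rvIdx[, , l + 1L]
    h8 <- cbind(as.vector(a[, -nP]), as.vector(a[ip1, -nP]),
                as.vector(a[ip1, -1]), as.vector(a[, -1]),
                as.vector(b[, -nP]), as.vector(b[ip1, -nP]),
                as.vector(b[ip1, -1]), as.vector(b[, -1]))
    pushTets(hexGridToTets(h8[cellSel, , drop = FALSE]))
  }

  # --- vertex bookkeeping ---------------------------------------------
  nvWall <- nrow(pos)
  label <- integer(nvWall)
  septal <- abs(.wrapAngle(par$theta)) < cfg$rvSpan & par$kind %in%
    c("lv", "apex")
  label[par$kind %in% c("lv", "apex")] <- .VLABEL[["LV_WALL"]]
  label[septal & par$u > cfg$rvApexU] <- .VLABEL[["SEPTUM"]]
  label[par$kind == "rv"] <- .VLABEL[["RV_WALL"]]
  eCoord <- par$eEff
  endo <- logical(nvWall)
  epi <- logical(nvWall)
  lvEndoMask <- logical(nvWall)
  rvEndoMask <- logical(nvWall)
  lvK0 <- c(apexIdx[1L], as.vector(lvIdx[, , 1L]))
  endo[lvK0] <- TRUE
  lvEndoMask[lvK0] <- TRUE
  lvKe <- as.vector(lvIdx[, , ne + 1L])
  inrvVec <- as.vector(inrvM)
  septalFace <- lvKe[inrvVec]
  endo[septalFace] <- TRUE
  rvEndoMask[septalFace] <- TRUE
  epi[setdiff(c(apexIdx[ne + 1L], lvKe), septalFace)] <- TRUE
  rvActual <- which(par$kind == "rv")
  rvL0 <- rvActual[par$eEff[rvActual] == 0]
  rvLn <- rvActual[par$eEff[rvActual] == 1]
  endo[rvL0] <- TRUE
  rvEndoMask[rvL0] <- TRUE
  epi[rvLn] <- TRUE

  # endocardial normals (toward the cavity) from the transmural stacks
  normals <- matrix(NA_real_, nvWall, 3)
  stackN <- function(at, nb) rowNormalize(pos[at, , drop = FALSE] -
                                            pos[nb, , drop = FALSE])
  normals[lvK0, ] <- stackN(lvK0, c(apexIdx[2L], as.vector(lvIdx[, , 2L])))
  normals[septalFace, ] <- stackN(septalFace,
                                  as.vector(lvIdx[, , ne])[inrvVec])
  rvL0grid <- which(rvIdx[, , 1L] != lvIdx[, , ne + 1L], arr.ind = TRUE)
  if (nrow(rvL0grid)) {
    a0 <- rvIdx[, , 1L][rvL0grid]
    a1 <- rvIdx[, , 2L][rvL0grid]
    normals[a0, ] <- rowNormalize(pos[a0, , drop = FALSE] -
                                    pos[a1, , drop = FALSE])
  }

  # --- papillary muscles ----------------------------------------------
  pmInfo <- list()
  pmSpecs <- meta$pmSpecs %||% list()
  if (length(pmSpecs)) {
    endoGrid <- makePointGrid(pos[lvK0, , drop = FALSE], cell = 6)
    for (rec in pmSpecs) {
      blk <- .pmVolumeBlock(rec, pos, lvK0, endoGrid)
      ids <- add(blk$newPos, blk$newPar)
      # remap block-local indices: negatives index newPos, positives are
      # existing vertex ids
      mapIdx <- function(v) {
        out <- v
        neg <- v < 0
        out[neg] <- ids[-v[neg]]
        out
      }
      pushTets(matrix(mapIdx(blk$tets), ncol = 4))
      lab <- .VLABEL[[rec$spec@side]]
      label[ids] <- lab
      eCoord[ids] <- 0
      endo[ids] <- TRUE
      lvEndoMask[ids] <- TRUE
      normals <- rbind(normals, blk$normals)
      pmInfo[[rec$spec@side]] <- list(tipVertex = mapIdx(blk$tipLocal),
                                      axisDir = rec$axisDir,
                                      attachmentPoint = rec$attachmentPoint,
                                      vertexIds = ids,
                                      surfIds = mapIdx(blk$surfLocal))
    }
  }
  # pad per-vertex vectors added after the wall stage
  nvAll <- nrow(pos)
  pad <- function(v, fill) {
    v[is.na(v)] <- fill
    c(v, rep(fill, nvAll - length(v)))
  }
  label <- pad(label, .VLABEL[["LV_WALL"]])
  eCoord <- pad(eCoord, 0)
  endo <- pad(endo, FALSE)
  epi <- pad(epi, FALSE)
  lvEndoMask <- pad(lvEndoMask, FALSE)
  rvEndoMask <- pad(rvEndoMask, FALSE)

  tetsM <- do.call(rbind, tets[seq_len(tn)])
  tetsM <- cleanTets(pos, tetsM)
  nodalVolume <- lumpNodalVolumes(pos, tetsM)

  # landmark vertices
  nearestIn <- function(mask, p) {
    cand <- which(mask)
    cand[which.min(colSums((t(pos[cand, , drop = FALSE]) - p)^2))]
  }
  sl <- surface@landmarks
  sv <- surface@vertices
  axisDir <- normalize(sv[sl[["mitralCentre"]], ] - sv[sl[["lvApex"]], ])
  lmk <- list(
    hisVertex = nearestIn(lvEndoMask, sv[sl[["hisOrigin"]], ]),
    avVertex = nearestIn(rvEndoMask, sv[sl[["avNode"]], ]),
    lvApexVertex = nearestIn(lvEndoMask, sv[sl[["lvApex"]], ]),
    rvApexVertex = if (any(par$kind == "rv"))
      nearestIn(rvEndoMask & par$kind == "rv" &
                  .rvProfile(par$theta, par$u, cfg)$f > 0.25,
                sv[sl[["rvApex"]], ]) else NA_integer_,
    mitralPoint = sv[sl[["mitralCentre"]], ],
    apexPoint = sv[sl[["lvApex"]], ],
    lvAxisDir = axisDir)

  new("VolumeMesh", vertices = pos, tets = tetsM,
      label = as.integer(label), e = as.numeric(eCoord),
      endo = endo, epi = epi, nodalVolume = nodalVolume,
      meta = list(parametric = TRUE, cfg = cfg, weights = meta$weights,
                  scale = meta$scale %||% 1,
                  dims = list(nTheta = nT, nPhi = nP, ne = ne, neRV = neRV),
                  lvIdx = lvIdx, apexIdx = apexIdx, rvIdx = rvIdx,
                  inRV = inrvM, param = par, normals = normals,
                  lvEndoMask = lvEndoMask, rvEndoMask = rvEndoMask,
                  landmarks = lmk, pm = pmInfo))
}

# Structured PM block in world coordinates. Base disc nodes are snapped to
# existing endocardial vertices (returned as positive ids); interior nodes
# are new (negative local ids into newPos).
.pmVolumeBlock <- function(rec, pos, endoIds, endoGrid) {
  spec <- rec$spec
  L <- spec@length
  d <- spec@diameter
  w <- rec$axisDir
  pb <- planeBasis(w)
  p0 <- rec$attachmentPoint
  lay <- .pmDiscLayout()
  nPer <- 1L + sum(lay$counts)
  hs <- max(1.8, L / 12)
  ss <- unique(c(seq(0, 0.6 * L, by = hs), seq(0.6 * L, L, length.out = 5)))
  ss <- ss[ss < L - 1e-6]
  discTri <- .pmDiscTriangles()
  newPos <- NULL
  newPar <- NULL
  stIdx <- list()
  nNew <- 0L
  for (m in seq_along(ss)) {
    pts <- .pmStationPoints(p0, w, pb$u, pb$v, ss[m], L, d)
    if (m == 1L) {
      # snap base disc onto endocardial vertices
      ids <- vapply(seq_len(nrow(pts)), function(r) {
        hit <- gridNearest(endoGrid, pts[r, ])
        endoIds[hit$index]
      }, numeric(1))
      stIdx[[m]] <- as.integer(ids)
    } else {
      newPos <- rbind(newPos, pts)
      newPar <- rbind(newPar, data.frame(
        kind = "pm", theta = 0, u = 0, eEff = 0, isRV = FALSE)[rep(1, nrow(pts)), ])
      stIdx[[m]] <- -(nNew + seq_len(nrow(pts)))
      nNew <- nNew + nrow(pts)
    }
  }
  tip <- p0 + L * w
  newPos <- rbind(newPos, tip)
  newPar <- rbind(newPar, data.frame(kind = "pm", theta = 0, u = 0,
                                     eEff = 0, isRV = FALSE))
  tipLocal <- -(nNew + 1L)
  nNew <- nNew + 1L

  tets <- NULL
  for (m in seq_len(length(ss) - 1L)) {
    a <- stIdx[[m]]
    b <- stIdx[[m + 1L]]
    w6 <- cbind(a[discTri[, 1]], a[discTri[, 2]], a[discTri[, 3]],
                b[discTri[, 1]], b[discTri[, 2]], b[discTri[, 3]])
    tets <- rbind(tets, wedgeGridToTets(w6))
  }
  last <- stIdx[[length(ss)]]
  tets <- rbind(tets, cbind(last[discTri[, 1]], last[discTri[, 2]],
                            last[discTri[, 3]], tipLocal))
  # radial normals for the new nodes (PM lateral surface direction)
  rel <- sweep(newPos, 2, p0)
  ax <- as.numeric(rel %*% w)
  radial <- rel - ax %o% w
  rn <- sqrt(rowSums(radial^2))
  normals <- ifelse(rn > 1e-9, 1, NA) * radial / pmax(rn, 1e-9)
  normals[is.na(normals[, 1]), ] <- matrix(pb$u, sum(is.na(normals[, 1])),
                                           3, byrow = TRUE)
  # local ids of lateral-surface nodes (outer ring of each station + tip)
  outerLocal <- integer(0)
  lay2 <- .pmDiscLayout()
  nPerStation <- 1L + sum(lay2$counts)
  outRing <- (1L + sum(lay2$counts[1:2])) + seq_len(lay2$counts[3])
  for (m in 2:length(ss)) {
    base <- (m - 2L) * nPerStation
    outerLocal <- c(outerLocal, -(base + outRing))
  }
  outerLocal <- c(outerLocal, tipLocal)
  list(newPos = newPos, newPar = newPar, tets = tets, tipLocal = tipLocal,
       normals = normals, surfLocal = outerLocal)
}

# Star-shaped fallback mesher: onion layers toward the centroid.
.meshStarShaped <- function(surface, targetVertices) {
  v <- surface@vertices
  tr <- surface@triangles
  if (!isClosedManifold(tr) && any(edgeUseCounts(tr) %% 2 != 0))
    stop("tetrahedralization requires a closed surface")
  nv <- nrow(v)
  ctr <- colMeans(v[sort(unique(as.vector(tr))), , drop = FALSE])
  nLayers <- max(1L, round(targetVertices / nv) - 1L)
  pos <- NULL
  layerIdx <- list()
  for (l in nLayers:1) {
    s <- l / nLayers
    layerIdx[[l]] <- nrow(pos %||% matrix(0, 0, 3)) + seq_len(nv)
    pos <- rbind(pos, sweep(sweep(v, 2, ctr) * s, 2, ctr, "+"))
  }
  pos <- rbind(pos, ctr)
  ctrIdx <- nrow(pos)
  tets <- NULL
  if (nLayers > 1) {
    for (l in nLayers:2) {
      a <- layerIdx[[l]]
      b <- layerIdx[[l - 1]]
      w6 <- cbind(a[tr[, 1]], a[tr[, 2]], a[tr[, 3]],
                  b[tr[, 1]], b[tr[, 2]], b[tr[, 3]])
      tets <- rbind(tets, wedgeGridToTets(w6))
    }
  }
  inner <- layerIdx[[1]]
  tets <- rbind(tets, cbind(inner[tr[, 1]], inner[tr[, 2]], inner[tr[, 3]],
                            ctrIdx))
  tets <- cleanTets(pos, tets, minVol = 1e-14)
  nvAll <- nrow(pos)
  new("VolumeMesh", vertices = pos, tets = tets,
      label = rep(.VLABEL[["LV_WALL"]], nvAll),
      e = rep(0, nvAll), endo = rep(FALSE, nvAll),
      epi = c(rep(TRUE, nv), rep(FALSE, nvAll - nv)),
      nodalVolume = lumpNodalVolumes(pos, tets),
      meta = list(parametric = FALSE))
}
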