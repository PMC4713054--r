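# Three-stage L-system growth of the endocardial Purkinje networks.
#
# Stage 1 is landmark-driven: geodesic bundle/fascicle paths on the
# endocardial vertex graph (His origin -> apex with a trifurcation at two
# thirds of the path in the LV; AV node -> RV apex with a bifurcation in
# the RV), smoothed on-surface. Stages 2 and 3 are rule-based Y-branching
# with Gaussian branch lengths and angles (Table-style per-stage
# parameters), surface-projected steps, avoidance of the existing network
# (LV stage 2), fusion into loops within a capture radius (stage 2), and
# an acyclic PMJ-densification stage stratified over the AHA 17 segments.

#' Growth parameters for one ventricle
#'
#' Per-stage branch length mean/sd (mm), branch angle mean/sd (deg),
#' segments per branch and branch budget, plus avoidance and loop-capture
#' radii (mm).
#'
#' @param side "LV" or "RV".
#' @return a named list of growth parameters.
#' @export
growthParams <- function(side = c("LV", "RV")) {
  side <- match.arg(side)
  if (side == "LV") {
    list(side = "LV",
         stage2 = list(len = 6, lenSd = 0.3, ang = 60, angSd = 40,
                       segments = 10L, maxBranches = 300L),
         stage3 = list(len = 1, lenSd = 0.03, ang = 60, angSd = 40,
                       segments = 5L, maxBranches = 600L),
         avoidanceRadius = 1, loopCaptureRadius = 0.5,
         velocity = 3.5, basalMargin = 20)
  } else {
    list(side = "RV",
         stage2 = list(len = 4, lenSd = 0.3, ang = 60, angSd = 20,
                       segments = 10L, maxBranches = 800L),
         stage3 = list(len = 1, lenSd = 0.03, ang = 60, angSd = 40,
                       segments = 5L, maxBranches = 1000L),
         avoidanceRadius = 0, # RV fibres do not avoid each other
         loopCaptureRadius = 0.5,
         velocity = 3.5, basalMargin = 20)
  }
}

.checkGrowthParams <- function(p) {
  for (st in c("stage2", "stage3")) {
    s <- p[[st]]
    if (s$len <= 0 || s$ang <= 0) stop("growth means must be positive")
  }
  invisible(p)
}

# ---------------------------------------------------------------------------
# network builder (preallocated, with a spatial bucket index)

.newBuilder <- function(bboxLo, bboxHi, capacity = 50000L, cell = 2) {
  env <- new.env(parent = emptyenv())
  env$pos <- matrix(NA_real_, capacity, 3)
  env$role <- character(capacity)
  env$nearVert <- rep(NA_integer_, capacity)
  env$branch <- integer(capacity)
  env$stage <- integer(capacity)
  env$n <- 0L
  env$eFrom <- integer(capacity * 2L)
  env$eTo <- integer(capacity * 2L)
  env$eVel <- numeric(capacity * 2L)
  env$en <- 0L
  env$grid <- flatGrid(bboxLo, bboxHi, cell)
  env
}

.bAddNode <- function(b, p, role, nearVert = NA_integer_, branch = 0L,
                      stage = 1L) {
  i <- b$n + 1L
  if (i > nrow(b$pos)) { # grow
    b$pos <- rbind(b$pos, matrix(NA_real_, nrow(b$pos), 3))
    b$role <- c(b$role, character(length(b$role)))
    b$nearVert <- c(b$nearVert, rep(NA_integer_, length(b$nearVert)))
    b$branch <- c(b$branch, integer(length(b$branch)))
    b$stage <- c(b$stage, integer(length(b$stage)))
  }
  b$pos[i, ] <- p
  b$role[i] <- role
  b$nearVert[i] <- nearVert
  b$branch[i] <- branch
  b$stage[i] <- stage
  b$n <- i
  fgAdd(b$grid, p, i)
  i
}

.bAddEdge <- function(b, i, j, vel) {
  e <- b$en + 1L
  if (e > length(b$eFrom)) {
    b$eFrom <- c(b$eFrom, integer(length(b$eFrom)))
    b$eTo <- c(b$eTo, integer(length(b$eTo)))
    b$eVel <- c(b$eVel, numeric(length(b$eVel)))
  }
  b$eFrom[e] <- i
  b$eTo[e] <- j
  b$eVel[e] <- vel
  b$en <- e
  e
}

# node ids within radius r of p (r must be <= grid cell)
.bNear <- function(b, p, r) {
  cand <- .fgBlock(b$grid, p, 1L)
  if (!length(cand)) return(integer(0))
  d2 <- (b$pos[cand, 1] - p[1])^2 + (b$pos[cand, 2] - p[2])^2 +
    (b$pos[cand, 3] - p[3])^2
  cand[d2 <= r * r]
}

# ---------------------------------------------------------------------------
# endocardial vertex graphs from the structured mesh

.lvEndoGraph <- function(mesh) {
  meta <- mesh@meta
  d <- meta$dims
  nT <- d$nTheta
  nP <- d$nPhi
  lv0 <- meta$lvIdx[, , 1L]
  ip1 <- c(2:nT, 1L)
  e1 <- cbind(as.vector(lv0), as.vector(lv0[ip1, ]))
  e2 <- cbind(as.vector(lv0[, -nP]), as.vector(lv0[, -1]))
  e3 <- cbind(as.vector(lv0[, -nP]), as.vector(lv0[ip1, -1]))
  e4 <- cbind(as.vector(lv0[ip1, -nP]), as.vector(lv0[, -1]))
  apex <- meta$apexIdx[1L]
  e5 <- cbind(rep(apex, nT), lv0[, 1])
  rbind(e1, e2, e3, e4, e5)
}

.rvEndoGraph <- function(mesh) {
  meta <- mesh@meta
  d <- meta$dims
  nT <- d$nTheta
  nP <- d$nPhi
  inrv <- meta$inRV
  rv0 <- meta$rvIdx[, , 1L] # collapsed columns already map to septal epi
  sep <- meta$lvIdx[, , d$ne + 1L]
  ip1 <- c(2:nT, 1L)
  quadEdges <- function(m, maskCell) {
    e1 <- cbind(as.vector(m), as.vector(m[ip1, ]))
    k1 <- inrv | inrv[ip1, ]
    e2 <- cbind(as.vector(m[, -nP]), as.vector(m[, -1]))
    k2 <- (inrv | cbind(inrv[, -1], FALSE))[, -nP]
    e3 <- cbind(as.vector(m[, -nP]), as.vector(m[ip1, -1]))
    e4 <- cbind(as.vector(m[ip1, -nP]), as.vector(m[, -1]))
    k3 <- (inrv | cbind(inrv[, -1], FALSE)[ip1, ])[, -nP]
    rbind(e1[as.vector(k1), , drop = FALSE],
          e2[as.vector(k2), , drop = FALSE],
          e3[as.vector(k3), , drop = FALSE],
          e4[as.vector(k3), , drop = FALSE])
  }
  rbind(quadEdges(rv0), quadEdges(sep))
}

.compactGraph <- function(mesh, rawEdges) {
  rawEdges <- rawEdges[rawEdges[, 1] != rawEdges[, 2], , drop = FALSE]
  vids <- sort(unique(as.vector(rawEdges)))
  map <- integer(max(vids))
  map[vids] <- seq_along(vids)
  el <- cbind(map[rawEdges[, 1]], map[rawEdges[, 2]])
  pos <- mesh@vertices
  len <- sqrt(rowSums((pos[rawEdges[, 1], , drop = FALSE] -
                       pos[rawEdges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- len
  list(g = g, vids = vids, map = map)
}

.geodesic <- function(cg, fromVert, toVert) {
  p <- igraph::shortest_paths(cg$g, from = cg$map[fromVert],
                              to = cg$map[toVert],
                              weights = igraph::E(cg$g)$weight,
                              output = "vpath")
  cg$vids[as.integer(p$vpath[[1]])]
}

# two rounds of on-surface Laplacian smoothing of a polyline given as mesh
# vertex positions (endpoints fixed); returns free points + their nearest
# projection vertices.
.smoothPath <- function(path, mesh, projGrid, projIds) {
  pts <- mesh@vertices[path, , drop = FALSE]
  normals <- mesh@meta$normals
  for (rep in 1:2) {
    if (nrow(pts) < 3) break
    mid <- (pts[-c(1, 2), , drop = FALSE] +
              pts[-c(nrow(pts) - 1, nrow(pts)), , drop = FALSE] +
              2 * pts[-c(1, nrow(pts)), , drop = FALSE]) / 4
    for (r in seq_len(nrow(mid))) {
      hit <- gridNearest(projGrid, mid[r, ])
      v <- projIds[hit$index]
      nrm <- normals[v, ]
      mid[r, ] <- mid[r, ] - nrm * sum((mid[r, ] - mesh@vertices[v, ]) * nrm)
    }
    pts[-c(1, nrow(pts)), ] <- mid
  }
  near <- vapply(seq_len(nrow(pts)), function(r)
    projIds[gridNearest(projGrid, pts[r, ])$index], numeric(1))
  list(pts = pts, near = as.integer(near))
}

# append a polyline to the builder, returning the id of its last node
.addPolyline <- function(b, pts, near, role, vel, startId, stage = 1L) {
  prev <- startId
  for (r in seq_len(nrow(pts))) {
    id <- .bAddNode(b, pts[r, ], role, near[r], stage = stage)
    if (!is.null(prev)) .bAddEdge(b, prev, id, vel)
    prev <- id
  }
  prev
}

# ---------------------------------------------------------------------------
# rule-based Y-branching engine (stages 2 and 3); the per-segment stepping
# runs in compiled code (.grow_branches), the builder receives the results
# in bulk.

.growStage <- function(b, tips, st, stage, pr, avoidR, loopR, vel, stats,
                       spawnTips = (stage == 2L)) {
  if (!length(tips) || st$maxBranches < 1L) return(invisible(NULL))
  tipMat <- do.call(rbind, tips)
  fusable <- as.integer(!b$role[seq_len(b$n)] %in%
                          c("BUNDLE", "HIS_ORIGIN", "AV_NODE"))
  res <- .grow_branches(b$pos[seq_len(b$n), , drop = FALSE],
                        b$branch[seq_len(b$n)], fusable, tipMat,
                        pr$pts, pr$nrm, pr$cap,
                        st$len, st$lenSd, st$ang, st$angSd,
                        as.integer(st$segments), as.integer(st$maxBranches),
                        avoidR, if (stage == 2L) loopR else 0,
                        spawnTips, as.integer(b$nBranchCounter %||% 0L))
  nNew <- nrow(res$pos)
  if (nNew) {
    while (b$n + nNew > nrow(b$pos)) { # grow storage
      b$pos <- rbind(b$pos, matrix(NA_real_, nrow(b$pos), 3))
      b$role <- c(b$role, character(length(b$role)))
      b$nearVert <- c(b$nearVert, rep(NA_integer_, length(b$nearVert)))
      b$branch <- c(b$branch, integer(length(b$branch)))
      b$stage <- c(b$stage, integer(length(b$stage)))
    }
    ids <- b$n + seq_len(nNew)
    b$pos[ids, ] <- res$pos
    b$role[ids] <- "FASCICLE"
    b$nearVert[ids] <- pr$ids[res$nearVert]
    b$branch[ids] <- res$branch
    b$stage[ids] <- stage
    b$n <- b$n + nNew
  }
  ne <- nrow(res$edges)
  if (ne) {
    while (b$en + ne > length(b$eFrom)) {
      b$eFrom <- c(b$eFrom, integer(length(b$eFrom)))
      b$eTo <- c(b$eTo, integer(length(b$eTo)))
      b$eVel <- c(b$eVel, numeric(length(b$eVel)))
    }
    eix <- b$en + seq_len(ne)
    b$eFrom[eix] <- res$edges[, 1]
    b$eTo[eix] <- res$edges[, 2]
    b$eVel[eix] <- vel
    b$en <- b$en + ne
  }
  b$nBranchCounter <- res$branchCounter
  stats$len <- c(stats$len, res$len)
  stats$ang <- c(stats$ang, res$ang)
  invisible(NULL)
}

# AHA 17-segment id from axis coordinates (axial fraction + azimuth)
.ahaSegment <- function(az, tfrac) {
  seg <- integer(length(az))
  sext <- (floor(((az %% (2 * pi)) / (2 * pi)) * 6) %% 6) + 1
  quad <- (floor(((az %% (2 * pi)) / (2 * pi)) * 4) %% 4) + 1
  basal <- tfrac > 2 / 3
  mid <- tfrac > 1 / 3 & !basal
  apical <- tfrac > 0.12 & !basal & !mid
  seg[basal] <- sext[basal]
  seg[mid] <- 6 + sext[mid]
  seg[apical] <- 12 + quad[apical]
  seg[seg == 0] <- 17
  seg
}

# ---------------------------------------------------------------------------

# Projection bundle: surface points, cavity-facing normals and the clamp
# distance that keeps growth tips near the sampled surface.
.mkProjector <- function(mesh, ids) {
  pts <- mesh@vertices[ids, , drop = FALSE]
  nrm <- mesh@meta$normals[ids, , drop = FALSE]
  smp <- pts[seq(1, nrow(pts), length.out = min(150, nrow(pts))), ,
             drop = FALSE]
  nn <- vapply(seq_len(nrow(smp)), function(r) {
    d2 <- colSums((t(pts) - smp[r, ])^2)
    sqrt(sort(d2, partial = 2)[2])
  }, numeric(1))
  list(pts = pts, nrm = nrm, ids = ids, cap = 1.3 * stats::median(nn))
}

.finishNetwork <- function(b, meta) {
  n <- b$n
  pos <- b$pos[seq_len(n), , drop = FALSE]
  role <- b$role[seq_len(n)]
  ed <- data.frame(from = b$eFrom[seq_len(b$en)], to = b$eTo[seq_len(b$en)],
                   velocity = b$eVel[seq_len(b$en)])
  ed$length <- sqrt(rowSums((pos[ed$from, , drop = FALSE] -
                             pos[ed$to, , drop = FALSE])^2))
  ed$blocked <- FALSE
  ed <- ed[, c("from", "to", "length", "velocity", "blocked")]
  # terminals of stages 2-3 become PMJs
  deg <- tabulate(c(ed$from, ed$to), nbins = n)
  stage <- b$stage[seq_len(n)]
  isPmj <- deg == 1L & stage >= 2L
  role[isPmj] <- "PMJ"
  pmjVertex <- rep(NA_integer_, n)
  pmjVertex[isPmj] <- b$nearVert[seq_len(n)][isPmj]
  meta$stage <- stage
  new("PurkinjeNetwork", nodes = pos, edges = ed, role = role,
      pmjVertex = pmjVertex, meta = meta)
}

#' Grow the left-ventricular Purkinje network
#'
#' Stage 1: a bundle fiber from the His origin toward the LV apex along
#' the septal endocardium, trifurcating at two thirds of the geodesic path
#' into fascicles toward the posterior PM, the anterior PM and the apex;
#' after reaching its landmark each fascicle turns toward the base and
#' stops 20 mm short of the basal plane (fascicles run beneath the PMs on
#' the retained endocardial sheet). Stage 2: Y-structures from the stage-1
#' endpoints (branch length 6 +/- 0.3 mm, angle 60 +/- 40 deg, 10
#' segments, at most 300 branches), extending onto the PMs, with early
#' termination near foreign fibres (avoidance) or fusion within the
#' loop-capture radius. Stage 3: small Y-structures (1 +/- 0.03 mm, 5
#' segments, at most 600 branches) seeded at random network points
#' stratified over the AHA 17 segments; acyclic; terminals become PMJs.
#'
#' @param mesh a parametric \linkS4class{VolumeMesh} with PMs.
#' @param params from [growthParams()]("LV").
#' @param seed integer seed (full network is deterministic given it).
#' @return a \linkS4class{PurkinjeNetwork}.
#' @export
growLvNetwork <- function(mesh, params = growthParams("LV"), seed = 1L) {
  .checkGrowthParams(params)
  meta <- mesh@meta
  if (!isTRUE(meta$parametric)) stop("mesh lacks parametric landmarks")
  lmk <- meta$landmarks
  withSeed(seed, {
    projIds <- unique(c(which(meta$lvEndoMask & mesh@label <
                                .VLABEL[["APM"]]),
                        unlist(lapply(meta$pm, `[[`, "surfIds"))))
    pr <- .mkProjector(mesh, projIds)
    projGrid <- makePointGrid(pr$pts, cell = 4)
    cg <- .compactGraph(mesh, .lvEndoGraph(mesh))
    bb <- apply(mesh@vertices, 2, range)
    b <- .newBuilder(bb[1, ], bb[2, ])

    # stage 1: His -> apex with trifurcation at 2/3 arc length
    pathHA <- .geodesic(cg, lmk$hisVertex, lmk$lvApexVertex)
    seg <- sqrt(rowSums((mesh@vertices[pathHA[-1], , drop = FALSE] -
                         mesh@vertices[pathHA[-length(pathHA)], ,
                                       drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    kTri <- which.min(abs(arc - 2 / 3 * arc[length(arc)]))
    proxPath <- pathHA[seq_len(kTri)]
    sp <- .smoothPath(proxPath, mesh, projGrid, projIds)
    av <- .bAddNode(b, mesh@vertices[lmk$avVertex, ], "AV_NODE",
                    lmk$avVertex)
    his <- .bAddNode(b, sp$pts[1, ], "HIS_ORIGIN", sp$near[1])
    .bAddEdge(b, av, his, params$velocity)
    trif <- .addPolyline(b, sp$pts[-1, , drop = FALSE], sp$near[-1],
                         "BUNDLE", params$velocity, his)
    leftBundleNodes <- c(his, setdiff(seq_len(b$n), c(av, his)))
    leftBundleEdges <- 2:b$en # all edges after av-his

    # fascicles: trifurcation -> {PPM, APM, apex}, then toward the base
    baseN <- lmk$lvAxisDir
    baseP <- lmk$mitralPoint
    distToBase <- function(v) sum((baseP - mesh@vertices[v, ]) * baseN)
    endoPos <- mesh@vertices[cg$vids, , drop = FALSE]
    vertNear <- function(p) cg$vids[which.min(colSums((t(endoPos) - p)^2))]
    freeWallAz <- pi # opposite the septal azimuth
    axis <- list(origin = lmk$apexPoint, dir = baseN)
    pbA <- planeBasis(baseN)
    basalTarget <- function(fromV) {
      p <- mesh@vertices[fromV, ]
      rel <- p - axis$origin
      r <- sqrt(max(sum(rel^2) - sum(rel * baseN)^2, 0))
      # near the apex the azimuth is degenerate: the apical fascicle then
      # turns up the free wall (opposite the septum)
      azf <- if (r < 5) freeWallAz else
        atan2(sum(rel * pbA$v), sum(rel * pbA$u))
      lvLen <- sqrt(sum((baseP - axis$origin)^2))
      tgt <- axis$origin + baseN * (0.95 * lvLen) +
        (pbA$u * cos(azf) + pbA$v * sin(azf)) * max(r, 10)
      vertNear(tgt)
    }
    trifVert <- pathHA[kTri]
    endpoints <- integer(0)
    tipsDir <- list()
    targets <- list(
      PPM = vertNear(meta$pm$PPM$attachmentPoint %||%
                       mesh@vertices[lmk$lvApexVertex, ]),
      APM = vertNear(meta$pm$APM$attachmentPoint %||%
                       mesh@vertices[lmk$lvApexVertex, ]),
      APEX = lmk$lvApexVertex)
    for (nm in names(targets)) {
      pth <- .geodesic(cg, trifVert, targets[[nm]])
      # continue toward the base, stopping short of the basal plane
      cont <- .geodesic(cg, targets[[nm]], basalTarget(targets[[nm]]))
      keep <- vapply(cont, distToBase, numeric(1)) > params$basalMargin
      full <- c(pth, cont[keep][-1])
      if (length(full) < 2) next
      spF <- .smoothPath(full, mesh, projGrid, projIds)
      endId <- .addPolyline(b, spF$pts[-1, , drop = FALSE], spF$near[-1],
                            "FASCICLE", params$velocity, trif)
      endpoints <- c(endpoints, endId)
      nlast <- nrow(spF$pts)
      d <- spF$pts[nlast, ] - spF$pts[max(1, nlast - 2), ]
      tipsDir[[length(tipsDir) + 1L]] <- normalize(d)
    }

    # stage 2
    stats <- new.env(parent = emptyenv())
    stats$len <- numeric(0)
    stats$ang <- numeric(0)
    tips <- lapply(seq_along(endpoints), function(k)
      c(endpoints[k], tipsDir[[k]], 0L, 0L))
    .growStage(b, tips, params$stage2, 2L, pr, params$avoidanceRadius,
               params$loopCaptureRadius, params$velocity, stats)
    s2 <- list(len = stats$len, ang = stats$ang)

    # stage 3: seeds on the existing network, AHA-17 stratified
    stats$len <- numeric(0)
    stats$ang <- numeric(0)
    .seedStage3(b, mesh, params, pr, stats)
    s3 <- list(len = stats$len, ang = stats$ang)

    .finishNetwork(b, meta = list(
      side = "LV", leftBundleNodes = leftBundleNodes,
      leftBundleEdges = leftBundleEdges,
      branchStats = list(stage2 = s2, stage3 = s3),
      hisNode = his, avNode = av, seed = seed))
  })
}

.seedStage3 <- function(b, mesh, params, pr, stats, endoIds = NULL) {
  st <- params$stage3
  lmk <- mesh@meta$landmarks
  axisO <- lmk$apexPoint
  axisD <- lmk$lvAxisDir
  pb <- planeBasis(axisD)
  lvLen <- sqrt(sum((lmk$mitralPoint - axisO)^2))
  # seeds live on the peripheral network only: the proximal bundle is
  # insulated conduction tissue without Purkinje-muscle junctions
  pool <- which(!b$role[seq_len(b$n)] %in%
                  c("BUNDLE", "HIS_ORIGIN", "AV_NODE"))
  rel <- sweep(b$pos[pool, , drop = FALSE], 2, axisO)
  az <- atan2(as.numeric(rel %*% pb$v), as.numeric(rel %*% pb$u))
  tfrac <- as.numeric(rel %*% axisD) / lvLen
  segId <- .ahaSegment(az, tfrac)
  # seed budget per segment proportional to segment endocardial area
  # (approximated by endocardial vertex counts)
  endoIds <- endoIds %||% which(mesh@meta$lvEndoMask)
  relE <- sweep(mesh@vertices[endoIds, , drop = FALSE], 2, axisO)
  azE <- atan2(as.numeric(relE %*% pb$v), as.numeric(relE %*% pb$u))
  tE <- as.numeric(relE %*% axisD) / lvLen
  segE <- .ahaSegment(azE, tE)
  w <- tabulate(segE, 17)
  w <- w / sum(w)
  nSeeds <- pmax(0L, round(w * st$maxBranches / 2))
  nrmAt <- function(nodeId) {
    v <- b$nearVert[nodeId]
    if (is.na(v)) c(0, 0, 1) else mesh@meta$normals[v, ]
  }
  tips <- list()
  for (s17 in seq_len(17)) {
    cand <- pool[segId == s17]
    if (!length(cand) || nSeeds[s17] == 0L) next
    take <- if (length(cand) == 1L) rep(cand, nSeeds[s17]) else
      sample(cand, nSeeds[s17], replace = TRUE)
    for (nodeId in take) {
      nrm <- nrmAt(nodeId)
      ref <- planeBasis(nrm)$u
      dir <- rotateAbout(ref, nrm, stats::runif(1, 0, 2 * pi))
      tips[[length(tips) + 1L]] <- c(nodeId, dir, 0L, 0L)
    }
  }
  .growStage(b, tips, st, 3L, pr, 0, 0, params$velocity, stats,
             spawnTips = FALSE)
  invisible(length(tips))
}

#' Grow the right-ventricular Purkinje network
#'
#' The bundle runs from the AV node toward the RV apex on the septal RV
#' endocardium, splitting in two at two thirds of the way (one branch to
#' the apex, the other crossing to the RV free wall). Stage 2 starts from
#' those two endpoints only and the fibres do not avoid each other; stage
#' 3 is as in the LV with the RV branch budget.
#'
#' @param mesh a parametric \linkS4class{VolumeMesh}.
#' @param params from [growthParams()]("RV").
#' @param seed integer seed.
#' @return a \linkS4class{PurkinjeNetwork}.
#' @export
growRvNetwork <- function(mesh, params = growthParams("RV"), seed = 1L) {
  .checkGrowthParams(params)
  meta <- mesh@meta
  if (!isTRUE(meta$parametric)) stop("mesh lacks parametric landmarks")
  lmk <- meta$landmarks
  withSeed(seed, {
    projIds <- which(meta$rvEndoMask)
    pr <- .mkProjector(mesh, projIds)
    projGrid <- makePointGrid(pr$pts, cell = 4)
    cg <- .compactGraph(mesh, .rvEndoGraph(mesh))
    bb <- apply(mesh@vertices, 2, range)
    b <- .newBuilder(bb[1, ], bb[2, ])

    pathAR <- .geodesic(cg, lmk$avVertex, lmk$rvApexVertex)
    seg <- sqrt(rowSums((mesh@vertices[pathAR[-1], , drop = FALSE] -
                         mesh@vertices[pathAR[-length(pathAR)], ,
                                       drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    kSplit <- which.min(abs(arc - 2 / 3 * arc[length(arc)]))
    proxPath <- pathAR[seq_len(kSplit)]
    sp <- .smoothPath(proxPath, mesh, projGrid, projIds)
    av <- .bAddNode(b, sp$pts[1, ], "AV_NODE", sp$near[1])
    split <- .addPolyline(b, sp$pts[-1, , drop = FALSE], sp$near[-1],
                          "BUNDLE", params$velocity, av)
    rightBundleEdges <- seq_len(b$en)

    # free-wall target: RV endocardial vertex farthest from the septum
    splitVert <- pathAR[kSplit]
    rvPos <- mesh@vertices[cg$vids, , drop = FALSE]
    fwTarget <- cg$vids[which.max(rvPos[, 1])]
    endpoints <- integer(0)
    tipsDir <- list()
    for (tgt in c(lmk$rvApexVertex, fwTarget)) {
      pth <- .geodesic(cg, splitVert, tgt)
      if (length(pth) < 2) next
      spF <- .smoothPath(pth, mesh, projGrid, projIds)
      endId <- .addPolyline(b, spF$pts[-1, , drop = FALSE], spF$near[-1],
                            "FASCICLE", params$velocity, split)
      endpoints <- c(endpoints, endId)
      nlast <- nrow(spF$pts)
      tipsDir[[length(tipsDir) + 1L]] <-
        normalize(spF$pts[nlast, ] - spF$pts[max(1, nlast - 2), ])
    }

    stats <- new.env(parent = emptyenv())
    stats$len <- numeric(0)
    stats$ang <- numeric(0)
    tips <- lapply(seq_along(endpoints), function(k)
      c(endpoints[k], tipsDir[[k]], 0L, 0L))
    .growStage(b, tips, params$stage2, 2L, pr, params$avoidanceRadius,
               params$loopCaptureRadius, params$velocity, stats)
    s2 <- list(len = stats$len, ang = stats$ang)
    stats$len <- numeric(0)
    stats$ang <- numeric(0)
    .seedStage3(b, mesh, params, pr, stats, endoIds = projIds)
    s3 <- list(len = stats$len, ang = stats$ang)

    .finishNetwork(b, meta = list(
      side = "RV", rightBundleEdges = rightBundleEdges,
      branchStats = list(stage2 = s2, stage3 = s3),
      avNode = av, seed = seed))
  })
}

#' Merge the LV and RV networks at their shared AV-node anchor
#'
#' @param lv,rv networks from [growLvNetwork()] and [growRvNetwork()].
#' @param tol coincidence tolerance (mm) for the shared anchor nodes.
#' @return a single \linkS4class{PurkinjeNetwork}; left-bundle tagging is
#'   preserved for block targeting.
#' @export
mergeNetworks <- function(lv, rv, tol = 1e-6) {
  nLv <- nrow(lv@nodes)
  avLv <- lv@meta$avNode
  avRv <- rv@meta$avNode
  if (sqrt(sum((lv@nodes[avLv, ] - rv@nodes[avRv, ])^2)) > tol)
    stop("duplicate anchor nodes collide beyond tolerance")
  mapRv <- seq_len(nrow(rv@nodes)) + nLv
  mapRv[avRv] <- avLv
  keepRv <- setdiff(seq_len(nrow(rv@nodes)), avRv)
  # reindex kept RV nodes contiguously
  newIds <- integer(nrow(rv@nodes))
  newIds[keepRv] <- nLv + seq_along(keepRv)
  newIds[avRv] <- avLv
  nodes <- rbind(lv@nodes, rv@nodes[keepRv, , drop = FALSE])
  role <- c(lv@role, rv@role[keepRv])
  pmjV <- c(lv@pmjVertex, rv@pmjVertex[keepRv])
  edRv <- rv@edges
  edRv$from <- newIds[edRv$from]
  edRv$to <- newIds[edRv$to]
  edges <- rbind(lv@edges, edRv)
  meta <- lv@meta
  meta$side <- "BIV"
  meta$rightBundleEdges <- rv@meta$rightBundleEdges + nrow(lv@edges)
  meta$nLvNodes <- nLv
  meta$branchStats <- list(LV = lv@meta$branchStats,
                           RV = rv@meta$branchStats)
  meta$stage <- c(lv@meta$stage, rv@meta$stage[keepRv])
  new("PurkinjeNetwork", nodes = nodes, edges = edges, role = role,
      pmjVertex = pmjV, meta = meta)
}

#' Apply a complete left bundle branch block
#'
#' Sets \code{blocked = TRUE} on the left-bundle edge immediately distal
#' to the false-tendon take-off (or immediately distal to the His origin
#' when no FT is present). Blocked edges carry infinite travel time in
#' both directions.
#'
#' @param network a \linkS4class{PurkinjeNetwork} with tagged left bundle.
#' @param ftOriginNode optional node id of the FT take-off; must lie on
#'   the left bundle.
#' @return the network with the block applied.
#' @export
applyLbbb <- function(network, ftOriginNode = NULL) {
  lbe <- network@meta$leftBundleEdges
  if (is.null(lbe) || !length(lbe)) stop("left bundle not tagged")
  ed <- network@edges
  if (is.null(ftOriginNode)) {
    blockEdge <- lbe[1]
  } else {
    onBundle <- ftOriginNode %in% c(ed$from[lbe], ed$to[lbe])
    if (!onBundle) stop("FT origin not on the left bundle")
    # edge immediately distal: the bundle edge leaving the FT origin
    # farther from the His origin
    after <- lbe[ed$from[lbe] == ftOriginNode]
    blockEdge <- if (length(after)) after[1] else lbe[length(lbe)]
  }
  network@edges$blocked[blockEdge] <- TRUE
  network@meta$blockEdge <- blockEdge
  network
}

#' Remove any conduction block
#'
#' @param network a \linkS4class{PurkinjeNetwork}.
#' @return the network with all blocked flags cleared.
#' @export
clearBlock <- function(network) {
  network@edges$blocked <- FALSE
  network@meta$blockEdge <- NULL
  network
}
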