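# False tendon: a fast-conducting free-running fiber from the left bundle
# branch to the APM tip, PPM tip or a ventricular free-wall point, ending
# either in a direct connection to the closest Purkinje node or in a small
# "delta" tree of ten branches whose terminals couple to the myocardium
# like ordinary PMJs.

#' False-tendon configuration constructor
#'
#' @param endpoint "APM_TIP", "PPM_TIP" or "VFW".
#' @param termination "DIRECT" or "DELTA".
#' @param vfwPoint free-wall endocardial point (mm); required for "VFW"
#'   unless the default mid-height lateral point is wanted (then NA).
#' @return an \linkS4class{FTConfig}.
#' @export
ftConfig <- function(endpoint = c("APM_TIP", "PPM_TIP", "VFW"),
                     termination = c("DIRECT", "DELTA"),
                     vfwPoint = c(NA_real_, NA_real_, NA_real_)) {
  endpoint <- match.arg(endpoint)
  termination <- match.arg(termination)
  new("FTConfig", endpoint = endpoint, termination = termination,
      vfwPoint = as.numeric(vfwPoint),
      deltaSegmentLength = 0.2, deltaSegmentSd = 0.1,
      deltaBranchAngle = 60.0, deltaAngleSd = 1.0, deltaBranches = 10L)
}

# default VFW endpoint: mid-height lateral free wall
.defaultVfwVertex <- function(mesh) {
  lmk <- mesh@meta$landmarks
  axisO <- lmk$apexPoint
  axisD <- lmk$lvAxisDir
  pb <- planeBasis(axisD)
  lvLen <- sqrt(sum((lmk$mitralPoint - axisO)^2))
  cand <- which(mesh@meta$lvEndoMask & mesh@label == .VLABEL[["LV_WALL"]])
  rel <- sweep(mesh@vertices[cand, , drop = FALSE], 2, axisO)
  az <- atan2(as.numeric(rel %*% pb$v), as.numeric(rel %*% pb$u))
  zf <- as.numeric(rel %*% axisD) / lvLen
  score <- abs(.wrapAngle(az - pi)) + 4 * abs(zf - 0.5)
  cand[which.min(score)]
}

# free-wall vertices eligible as random FT attachment points (population
# P3): LV free wall, mid region, never septum or PM
.vfwCandidates <- function(mesh) {
  lmk <- mesh@meta$landmarks
  axisO <- lmk$apexPoint
  axisD <- lmk$lvAxisDir
  lvLen <- sqrt(sum((lmk$mitralPoint - axisO)^2))
  cand <- which(mesh@meta$lvEndoMask & mesh@label == .VLABEL[["LV_WALL"]])
  rel <- sweep(mesh@vertices[cand, , drop = FALSE], 2, axisO)
  zf <- as.numeric(rel %*% axisD) / lvLen
  cand[zf > 0.25 & zf < 0.75]
}

#' Insert a false tendon into the Purkinje network
#'
#' The FT leaves the left bundle at a configurable arc-length fraction
#' (default midpoint), runs as a straight chord of 20 segments through the
#' cavity to the configured endpoint at the Purkinje conduction velocity,
#' and terminates either directly (one extra segment to the closest
#' Purkinje node) or in a ten-branch delta tree that does not connect to
#' the main network (its terminals are PMJs with the standard antegrade
#' delay). There is no extra delay where the FT joins the bundle.
#'
#' @param network a merged \linkS4class{PurkinjeNetwork}.
#' @param mesh the matching \linkS4class{VolumeMesh}.
#' @param config an \linkS4class{FTConfig}.
#' @param seed integer seed (used by the delta-tree growth).
#' @param takeOffFraction arc-length fraction along the proximal left
#'   bundle for the FT origin.
#' @return the network with the FT added; bookkeeping (origin node, added
#'   node/edge ranges) in \code{meta$ft}.
#' @export
addFalseTendon <- function(network, mesh, config, seed = 1L,
                           takeOffFraction = 0.5) {
  lbe <- network@meta$leftBundleEdges
  if (is.null(lbe) || !length(lbe)) stop("network has no tagged left bundle")
  ed <- network@edges
  # ordered bundle node chain (from His): from/to laid down sequentially
  chain <- c(ed$from[lbe[1]], ed$to[lbe])
  arc <- c(0, cumsum(ed$length[lbe]))
  origin <- chain[which.min(abs(arc - takeOffFraction * arc[length(arc)]))]

  endPoint <- switch(config@endpoint,
    APM_TIP = {
      pm <- mesh@meta$pm$APM
      if (is.null(pm)) stop("mesh has no APM: endpoint unreachable")
      list(p = mesh@vertices[pm$tipVertex, ], v = pm$tipVertex)
    },
    PPM_TIP = {
      pm <- mesh@meta$pm$PPM
      if (is.null(pm)) stop("mesh has no PPM: endpoint unreachable")
      list(p = mesh@vertices[pm$tipVertex, ], v = pm$tipVertex)
    },
    VFW = {
      if (all(is.finite(config@vfwPoint))) {
        cand <- which(mesh@meta$lvEndoMask)
        d2 <- colSums((t(mesh@vertices[cand, , drop = FALSE]) -
                         config@vfwPoint)^2)
        v <- cand[which.min(d2)]
      } else {
        v <- .defaultVfwVertex(mesh)
      }
      list(p = mesh@vertices[v, ], v = v)
    })

  n0 <- nrow(network@nodes)
  e0 <- nrow(network@edges)
  p0 <- network@nodes[origin, ]
  p1 <- endPoint$p
  nSeg <- 20L
  tt <- seq_len(nSeg) / nSeg
  pts <- sweep(outer(tt, p1 - p0), 2, p0, "+")
  # keep the chord inside the cavity: if a waypoint leaves the wall-bounded
  # region (farther from the LV axis than the local endocardium), reroute
  # through one interior waypoint pulled toward the axis
  lmk <- mesh@meta$landmarks
  axisO <- lmk$apexPoint
  axisD <- lmk$lvAxisDir
  radial <- function(p) {
    rel <- p - axisO
    rel - axisD * sum(rel * axisD)
  }
  endoIds <- which(mesh@meta$lvEndoMask)
  endoGrid <- makePointGrid(mesh@vertices[endoIds, , drop = FALSE], cell = 5)
  outside <- vapply(seq_len(nSeg - 1L), function(r) {
    hit <- gridNearest(endoGrid, pts[r, ])
    v <- endoIds[hit$index]
    sqrt(sum(radial(pts[r, ])^2)) > sqrt(sum(radial(mesh@vertices[v, ])^2))
  }, logical(1))
  if (any(outside)) {
    warning("FT chord exits the cavity; rerouting via an interior waypoint")
    mid <- (p0 + p1) / 2
    mid <- mid - 0.35 * radial(mid)
    half <- seq_len(nSeg / 2) / (nSeg / 2)
    pts <- rbind(sweep(outer(half, mid - p0), 2, p0, "+"),
                 sweep(outer(half, p1 - mid), 2, mid, "+"))
  }

  nodes <- rbind(network@nodes, pts)
  role <- c(network@role, rep("FT_NODE", nrow(pts)))
  pmjV <- c(network@pmjVertex, rep(NA_integer_, nrow(pts)))
  ids <- n0 + seq_len(nrow(pts))
  vel <- network@edges$velocity[lbe[1]]
  newE <- data.frame(from = c(origin, ids[-length(ids)]), to = ids,
                     velocity = vel, blocked = FALSE)
  ftEnd <- ids[length(ids)]

  deltaStats <- NULL
  if (config@termination == "DIRECT") {
    # one extra segment to the closest point of the peripheral Purkinje
    # system (never the insulated bundle or the anchor nodes)
    d2 <- colSums((t(network@nodes) - p1)^2)
    d2[network@role %in% c("HIS_ORIGIN", "AV_NODE", "BUNDLE")] <- Inf
    d2[origin] <- Inf
    target <- which.min(d2)
    newE <- rbind(newE, data.frame(from = ftEnd, to = target,
                                   velocity = vel, blocked = FALSE))
  } else {
    # delta tree: ten branches from the endpoint, not connected to the
    # main network; terminals couple to the myocardium as PMJs
    withSeed(childSeed(seed, 977L), {
      nrm <- normalize(radial(p1))
      dlt <- .growDelta(p1, -nrm, config)
      deltaStats <- dlt$segLen
      dIds <- ftEnd + seq_len(nrow(dlt$pos))
      nodes <- rbind(nodes, dlt$pos)
      role <- c(role, rep("FT_NODE", nrow(dlt$pos)))
      pmjV <- c(pmjV, rep(NA_integer_, nrow(dlt$pos)))
      mapId <- function(i) ifelse(i == 0L, ftEnd, ftEnd + i)
      newE <- rbind(newE, data.frame(from = mapId(dlt$edges[, 1]),
                                     to = mapId(dlt$edges[, 2]),
                                     velocity = vel, blocked = FALSE))
      # terminals become delay-coupled PMJs
      deg <- tabulate(c(mapId(dlt$edges[, 1]), mapId(dlt$edges[, 2])),
                      nbins = length(role))
      term <- dIds[deg[dIds] == 1L]
      role[term] <- "PMJ"
      endoGrid2 <- endoGrid
      for (tmi in term) {
        hit <- gridNearest(endoGrid2, nodes[tmi, ])
        pmjV[tmi] <- endoIds[hit$index]
      }
    })
  }

  dimnames(nodes) <- NULL
  newE$length <- sqrt(rowSums((nodes[newE$from, , drop = FALSE] -
                               nodes[newE$to, , drop = FALSE])^2))
  newE <- newE[, c("from", "to", "length", "velocity", "blocked")]
  out <- network
  out@nodes <- nodes
  out@role <- role
  out@pmjVertex <- pmjV
  out@edges <- rbind(network@edges, newE)
  out@meta$ft <- list(config = config, originNode = origin,
                      nodeRange = c(n0 + 1L, nrow(nodes)),
                      edgeRange = c(e0 + 1L, nrow(out@edges)),
                      endVertex = endPoint$v, deltaSegLen = deltaStats)
  out@meta$stage <- c(network@meta$stage %||% integer(n0),
                      rep(0L, nrow(nodes) - n0))
  out
}

# small binary tree with Gaussian segment lengths/angles; returns local
# coordinates relative to the root (edge index 0 = root)
.growDelta <- function(root, dir0, config) {
  nb <- config@deltaBranches
  segPerBranch <- 3L
  pos <- NULL
  edges <- NULL
  segLen <- numeric(0)
  tips <- list(list(id = 0L, dir = normalize(dir0)))
  nBranches <- 0L
  nid <- 0L
  while (nBranches < nb && length(tips)) {
    pick <- sample.int(length(tips), 1)
    tip <- tips[[pick]]
    tips[[pick]] <- NULL
    ang <- stats::rnorm(1, config@deltaBranchAngle, config@deltaAngleSd) *
      pi / 180
    pb <- planeBasis(tip$dir)
    for (sgn in c(1, -1)) {
      if (nBranches >= nb) break
      nBranches <- nBranches + 1L
      dir <- rotateAbout(tip$dir, pb$u, sgn * ang / 2)
      p <- if (tip$id == 0L) root else pos[tip$id, ]
      prev <- tip$id
      for (sgm in seq_len(segPerBranch)) {
        sl <- rnormTrunc(1, config@deltaSegmentLength,
                         config@deltaSegmentSd, k = 1.9)
        segLen <- c(segLen, sl)
        p <- p + dir * sl
        nid <- nid + 1L
        pos <- rbind(pos, p)
        edges <- rbind(edges, c(prev, nid))
        prev <- nid
      }
      tips[[length(tips) + 1L]] <- list(id = prev, dir = dir)
    }
  }
  list(pos = pos, edges = edges, segLen = segLen)
}

#' Remove a previously added false tendon
#'
#' @param network a network whose last modification was [addFalseTendon()].
#' @return the original network (nodes, edges and roles restored).
#' @export
removeFalseTendon <- function(network) {
  ft <- network@meta$ft
  if (is.null(ft)) stop("network has no false tendon")
  keepN <- seq_len(ft$nodeRange[1] - 1L)
  keepE <- seq_len(ft$edgeRange[1] - 1L)
  out <- network
  out@nodes <- network@nodes[keepN, , drop = FALSE]
  out@role <- network@role[keepN]
  out@pmjVertex <- network@pmjVertex[keepN]
  out@edges <- network@edges[keepE, , drop = FALSE]
  rownames(out@edges) <- NULL
  out@meta$ft <- NULL
  out@meta$stage <- network@meta$stage[keepN]
  out
}

#' Enumerate false-tendon configurations
#'
#' The six canonical configurations (three endpoints x direct/delta) with
#' the default free-wall point, plus optional random free-wall attachment
#' locations for the location-sensitivity population.
#'
#' @param mesh a \linkS4class{VolumeMesh}.
#' @param nVfwPoints number of additional random VFW locations (each
#'   produced with both terminations).
#' @param seed integer seed for the random locations.
#' @return list of \linkS4class{FTConfig} objects.
#' @export
enumerateFtConfigs <- function(mesh, nVfwPoints = 0L, seed = 1L) {
  base <- list()
  for (ep in c("APM_TIP", "PPM_TIP", "VFW"))
    for (tm in c("DIRECT", "DELTA"))
      base[[length(base) + 1L]] <- ftConfig(ep, tm)
  if (nVfwPoints > 0L) {
    cand <- .vfwCandidates(mesh)
    withSeed(childSeed(seed, 31L), {
      pick <- sample(cand, nVfwPoints, replace = length(cand) < nVfwPoints)
      for (v in pick)
        for (tm in c("DIRECT", "DELTA"))
          base[[length(base) + 1L]] <- ftConfig("VFW", tm,
                                                mesh@vertices[v, ])
    })
  }
  base
}
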