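# Synthetic statistical shape model of the biventricular anatomy.
#
# The mean shape is a parametric biventricular surface: the LV wall is the
# region between two coaxial truncated prolate ellipsoids (endocardium and
# epicardium, shared basal plane), and the RV is a crescent-section chamber
# wrapped onto one side of the LV (the shared wall is the septum). Ten
# smooth analytic deformation fields (global scale, long-axis elongation,
# wall thickness, septal curvature, apical sharpness, basal dilation, RV
# volume, eccentricity, anterior-posterior skew, torsion) are
# orthonormalized into the mode matrix of a point-distribution model
# x = xbar + P' b.

.atlasConfig <- function(config = list()) {
  cfg <- list(
    lvLength = 98,      # apex to mitral-valve centre, mm (population mean)
    aEndo = 27,         # LV endocardial short semi-axis, mm
    cEndo = 70,         # LV endocardial long semi-axis, mm
    wall = 10,          # LV wall thickness, mm
    rvSpan = 70 * pi / 180, # RV half-span about the septal azimuth (rad)
    rvDepth = 22,       # max RV cavity depth, mm
    rvWall = 4,         # max RV free-wall thickness, mm
    rvApexU = 0.12,     # RV cavity starts above this normalized height
    rvFullU = 0.45,     # ... and reaches full depth here
    nTheta = 48,        # azimuthal landmark resolution
    nPhi = 40,          # meridional landmark resolution
    nModes = 10L,
    boundType = "sd",   # "sd": |b_i| <= 3 sqrt(lambda_i); "lambda": 3 lambda_i
    modeSdMm = c(NA, 5, 2.5, 2.5, 2, 2, 3, 1.5, 1.2, 1.0),
    lvLengthSd = 8.5    # Table-2 LV length spread driven by mode 1
  )
  cfg[names(config)] <- config
  if (cfg$lvLength <= 0 || cfg$aEndo <= 0 || cfg$cEndo <= 0 ||
      cfg$wall <= 0 || cfg$rvDepth <= 0 || cfg$rvWall <= 0)
    stop("invalid atlas config: dimensions must be positive")
  # geometry is laid out so that apex (endo) sits at z = 0 and the basal
  # plane at z = lvLength
  cfg$zBase <- cfg$lvLength
  cfg$zCentre <- cfg$cEndo
  cfg
}

.wrapAngle <- function(theta) {
  ((theta + pi) %% (2 * pi)) - pi
}

.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# LV wall point at azimuth theta, normalized meridional coordinate u
# (0 apex, 1 base) and transmural coordinate e (0 endo, 1 epi).
.lvPoints <- function(theta, u, e, cfg) {
  a <- cfg$aEndo + cfg$wall * e
  cc <- cfg$cEndo + cfg$wall * e
  phiMax <- acos(pmax(-1, (cfg$zCentre - cfg$zBase) / cc))
  phi <- u * phiMax
  cbind(a * sin(phi) * cos(theta),
        a * sin(phi) * sin(theta),
        cfg$zCentre - cc * cos(phi))
}

# RV shape functions: cavity depth and free-wall thickness at (theta, u).
.rvProfile <- function(theta, u, cfg) {
  tw <- .wrapAngle(theta)
  ft <- ifelse(abs(tw) < cfg$rvSpan, cos(pi * tw / (2 * cfg$rvSpan))^2, 0)
  fu <- .smoothstep((u - cfg$rvApexU) / (cfg$rvFullU - cfg$rvApexU))
  f <- ft * fu
  list(f = f, depth = cfg$rvDepth * f, thick = cfg$rvWall * sqrt(f))
}

.inRV <- function(theta, u, cfg, eps = 1e-3) {
  .rvProfile(theta, u, cfg)$f > eps
}

# ---------------------------------------------------------------------------
# Mean-shape surface at a given grid resolution. Returns node positions,
# per-node parametric records, triangulation with region labels, landmarks.
# The same builder runs at landmark resolution (for the ShapeModel) and is
# reused by the structured volume mesher through .deformPoints().

.buildMeanSurface <- function(cfg, nTheta = cfg$nTheta, nPhi = cfg$nPhi) {
  th <- 2 * pi * (seq_len(nTheta) - 1) / nTheta
  uu <- seq_len(nPhi) / nPhi

  grid <- expand.grid(i = seq_len(nTheta), j = seq_len(nPhi))
  gTheta <- th[grid$i]
  gU <- uu[grid$j]
  rv <- .rvProfile(gTheta, gU, cfg)
  inrv <- rv$f > 1e-3

  # endo apex + endo grid
  apexEndo <- 1L
  posL <- rbind(.lvPoints(0, 0, 0, cfg), .lvPoints(gTheta, gU, 0, cfg))
  parL <- data.frame(
    kind = c("apexEndo", rep("endo", nrow(grid))),
    i = c(0L, grid$i), j = c(0L, grid$j),
    theta = c(0, gTheta), u = c(0, gU),
    eEff = 0, isRV = FALSE)
  endoIdx <- matrix(seq_len(nrow(grid)) + 1L, nTheta, nPhi)

  # epi apex + epi grid (always present; inside the RV span this sheet is
  # the septal face of the RV cavity)
  off <- nrow(posL)
  posL <- rbind(posL, .lvPoints(0, 0, 1, cfg), .lvPoints(gTheta, gU, 1, cfg))
  parL <- rbind(parL, data.frame(
    kind = c("apexEpi", rep("epi", nrow(grid))),
    i = c(0L, grid$i), j = c(0L, grid$j),
    theta = c(0, gTheta), u = c(0, gU),
    eEff = 1, isRV = FALSE))
  apexEpi <- off + 1L
  epiIdx <- matrix(seq_len(nrow(grid)) + off + 1L, nTheta, nPhi)

  # RV shell nodes (inner = cavity side, outer = epicardial side) where the
  # cavity exists; radial offsets from the LV epicardial sheet
  rdir <- cbind(cos(gTheta), sin(gTheta), 0)
  epiPos <- .lvPoints(gTheta, gU, 1, cfg)
  rvInIdx <- matrix(NA_integer_, nTheta, nPhi)
  rvOutIdx <- matrix(NA_integer_, nTheta, nPhi)
  sel <- which(inrv)
  if (length(sel)) {
    off <- nrow(posL)
    posL <- rbind(posL, epiPos[sel, , drop = FALSE] +
                    rv$depth[sel] * rdir[sel, , drop = FALSE])
    parL <- rbind(parL, data.frame(
      kind = "rvIn", i = grid$i[sel], j = grid$j[sel],
      theta = gTheta[sel], u = gU[sel], eEff = 0, isRV = TRUE))
    rvInIdx[cbind(grid$i[sel], grid$j[sel])] <- off + seq_along(sel)
    off <- nrow(posL)
    posL <- rbind(posL, epiPos[sel, , drop = FALSE] +
                    (rv$depth[sel] + rv$thick[sel]) * rdir[sel, , drop = FALSE])
    parL <- rbind(parL, data.frame(
      kind = "rvOut", i = grid$i[sel], j = grid$j[sel],
      theta = gTheta[sel], u = gU[sel], eEff = 1, isRV = TRUE))
    rvOutIdx[cbind(grid$i[sel], grid$j[sel])] <- off + seq_along(sel)
  }

  # mitral-valve centre: explicit landmark vertex (not referenced by the
  # triangulation; it marks the centre of the basal LV opening)
  posL <- rbind(posL, c(0, 0, cfg$zBase))
  parL <- rbind(parL, data.frame(kind = "mitral", i = 0L, j = 0L, theta = 0,
                                 u = 1, eEff = 0, isRV = FALSE))
  mitralIdx <- nrow(posL)

  inrvM <- matrix(FALSE, nTheta, nPhi)
  inrvM[cbind(grid$i, grid$j)] <- inrv
  # outer surface map: RV outer sheet where the cavity exists, LV epi
  # elsewhere
  outerIdx <- ifelse(is.na(rvOutIdx), epiIdx, rvOutIdx)
  # RV cavity inner sheet map (falls back to the epi node so the free-wall
  # sheet seals onto the septal face at the cavity rim)
  innerIdx <- ifelse(is.na(rvInIdx), epiIdx, rvInIdx)

  ip1 <- c(2:nTheta, 1L)
  tris <- list()
  regs <- list()
  addTris <- function(t, r) {
    tris[[length(tris) + 1L]] <<- t
    regs[[length(regs) + 1L]] <<- rep.int(r, nrow(t))
  }
  quadSheet <- function(idxM, flip = FALSE) {
    a <- idxM[, -nPhi, drop = FALSE]
    b <- idxM[ip1, -nPhi, drop = FALSE]
    cc <- idxM[ip1, -1, drop = FALSE]
    d <- idxM[, -1, drop = FALSE]
    t1 <- cbind(as.vector(a), as.vector(b), as.vector(cc))
    t2 <- cbind(as.vector(a), as.vector(cc), as.vector(d))
    t <- rbind(t1, t2)
    if (flip) t <- t[, c(1, 3, 2)]
    t
  }
  fan <- function(centre, ring, flip = FALSE) {
    t <- cbind(centre, ring, ring[ip1])
    if (flip) t <- t[, c(1, 3, 2)]
    t
  }

  # Sheets of the wall-solid boundary:
  #  - LV endocardium: full grid at e = 0, facing the LV cavity
  #  - LV epicardial sheet: full grid at e = 1; outside the RV span it is
  #    exposed epicardium, inside it is the septal face of the RV cavity
  #  - RV inner / outer sheets over cells with at least one cavity node
  #    (rim corners fall back to the epi node, pinching the shell closed)
  #  - basal annuli (endo->epi and RV inner->outer) at u = 1
  # The pinch seam makes a few edges 4-valent (watertight, manifold per
  # region).
  cellRV <- inrvM | inrvM[ip1, ] | cbind(inrvM[, -1], FALSE)[ip1, ] |
    cbind(inrvM[, -1], FALSE)
  cellSel <- rep(as.vector(cellRV[, -nPhi]), 2L)

  addTris(fan(apexEndo, endoIdx[, 1], flip = TRUE), .REGION[["LV_ENDO"]])
  addTris(quadSheet(endoIdx, flip = TRUE), .REGION[["LV_ENDO"]])

  addTris(fan(apexEpi, epiIdx[, 1]), .REGION[["EPI"]])
  epiSheet <- quadSheet(epiIdx)
  epiReg <- ifelse(cellSel, .REGION[["RV_ENDO"]], .REGION[["EPI"]])
  tris[[length(tris) + 1L]] <- epiSheet
  regs[[length(regs) + 1L]] <- epiReg

  fw <- quadSheet(innerIdx, flip = TRUE)
  addTris(fw[cellSel, , drop = FALSE], .REGION[["RV_ENDO"]])
  ow <- quadSheet(outerIdx)
  addTris(ow[cellSel, , drop = FALSE], .REGION[["EPI"]])

  # basal caps at u = 1 (degenerate strips filtered below)
  baseStrip <- function(ringA, ringB, flip = FALSE) {
    t1 <- cbind(ringA, ringB, ringB[ip1])
    t2 <- cbind(ringA, ringB[ip1], ringA[ip1])
    t <- rbind(t1, t2)
    if (flip) t <- t[, c(1, 3, 2)]
    t
  }
  addTris(baseStrip(endoIdx[, nPhi], epiIdx[, nPhi]), .REGION[["BASE"]])
  addTris(baseStrip(innerIdx[, nPhi], outerIdx[, nPhi]), .REGION[["BASE"]])

  triangles <- do.call(rbind, tris)
  region <- unlist(regs)
  degen <- triangles[, 1] == triangles[, 2] |
    triangles[, 1] == triangles[, 3] | triangles[, 2] == triangles[, 3]
  triangles <- triangles[!degen, , drop = FALSE]
  region <- region[!degen]

  # landmarks
  vz <- posL[, 3]
  nearestNode <- function(idxPool, target) {
    d2 <- colSums((t(posL[idxPool, , drop = FALSE]) - target)^2)
    idxPool[which.min(d2)]
  }
  hisT <- 0.90 * cfg$zBase
  avT <- 0.95 * cfg$zBase
  septalEndo <- endoIdx[1, ] # theta = 0 column
  his <- nearestNode(septalEndo, c(cfg$aEndo, 0, hisT))
  septalEpi <- epiIdx[1, ]
  av <- nearestNode(septalEpi, c(cfg$aEndo + cfg$wall, 0, avT))
  # RV apex: lowest point of the true cavity pocket (not the pinch seam)
  rvNodes <- which(parL$kind == "rvIn")
  if (length(rvNodes)) {
    pocket <- rvNodes[.rvProfile(parL$theta[rvNodes], parL$u[rvNodes],
                                 cfg)$f > 0.25]
    if (length(pocket)) rvNodes <- pocket
  }
  rvApex <- if (length(rvNodes)) rvNodes[which.min(vz[rvNodes])] else
    NA_integer_
  landmarks <- c(lvApex = apexEndo, mitralCentre = mitralIdx,
                 hisOrigin = his, avNode = av, rvApex = rvApex)

  list(pos = posL, param = parL, triangles = triangles, region = region,
       landmarks = landmarks,
       maps = list(endo = endoIdx, epi = epiIdx, rvIn = rvInIdx,
                   rvOut = rvOutIdx, inRV = inrvM, theta = th, u = uu))
}

# ---------------------------------------------------------------------------
# Raw analytic deformation fields evaluated at arbitrary nodes. `par` must
# provide theta, u, eEff, isRV, kind; RV nodes move with the epicardial
# sheet they are extruded from so the fields stay smooth across the seam.

.rawFields <- function(pos, par, cfg) {
  n <- nrow(pos)
  zb <- cfg$zBase
  theta <- par$theta
  u <- par$u
  tw <- .wrapAngle(theta)
  rhat <- cbind(cos(theta), sin(theta), 0)
  centre <- c(0, 0, cfg$zCentre)
  radial <- rowNormalize(sweep(pos, 2, centre))
  mitral <- par$kind == "mitral"
  rv <- .rvProfile(theta, u, cfg)

  f <- vector("list", 10L)
  f[[1]] <- sweep(pos, 2, c(0, 0, zb))                       # global scale
  f[[2]] <- cbind(0, 0, pos[, 3] - zb)                       # elongation
  f[[3]] <- radial * (2 * ifelse(par$isRV, 1, par$eEff) - 1) # wall thickness
  f[[4]] <- cbind(exp(-(tw / 0.7)^2) * sin(pi * u), 0, 0)    # septal bulge
  f[[5]] <- cbind(0, 0, -(1 - u)^2)                          # apical sharpness
  f[[6]] <- rhat * u^2                                       # basal dilation
  f[[7]] <- rhat * ifelse(par$isRV, rv$f, 0)                 # RV volume
  f[[8]] <- cbind(pos[, 1], -pos[, 2], 0) / 50               # eccentricity
  f[[9]] <- cbind(0, u - 0.5, 0)                             # A-P skew
  f[[10]] <- u * cbind(-pos[, 2], pos[, 1], 0) / 50          # torsion
  for (k in seq_along(f)) f[[k]][mitral, ] <- 0
  f
}

# Displacement of arbitrary nodes for mode weights b, through the stored
# Gram-Schmidt combination matrix (modes = Rmat %*% rawFields).
.deformPoints <- function(pos, par, cfg, Rmat, b) {
  if (!length(b) || all(b == 0)) return(pos)
  w <- as.numeric(t(Rmat) %*% b) # weight per raw field
  f <- .rawFields(pos, par, cfg)
  disp <- matrix(0, nrow(pos), 3)
  for (k in seq_along(f)) if (w[k] != 0) disp <- disp + w[k] * f[[k]]
  pos + disp
}

.applySampleTransform <- function(pos, par, cfg, meta) {
  pos <- .deformPoints(pos, par, cfg, meta$Rmat, meta$weights)
  s <- meta$scale %||% 1
  if (s != 1) {
    mc <- meta$scaleCentre
    pos <- sweep(sweep(pos, 2, mc) * s, 2, mc, "+")
  }
  pos
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------

#' Build the synthetic statistical shape model
#'
#' Constructs the parametric mean biventricular surface and ten smooth,
#' orthonormalized deformation modes. The mean-shape LV length (apex to
#' mitral-valve centre) equals the configured population mean (98.0 mm by
#' default) and mode 1 is scaled so that one standard deviation of its
#' weight changes the LV length by the configured population spread.
#'
#' @param config named list overriding entries of the default atlas
#'   configuration (mean LV length, wall thickness, RV size, grid
#'   resolution, per-mode deformation scales, bound interpretation).
#' @param seed integer; the construction is deterministic given
#'   \code{(config, seed)}.
#' @return a \linkS4class{ShapeModel}.
#' @export
buildSyntheticAtlas <- function(config = list(), seed = 1L) {
  cfg <- .atlasConfig(config)
  geo <- .buildMeanSurface(cfg)
  n <- nrow(geo$pos)
  raw <- .rawFields(geo$pos, geo$param, cfg)
  nModes <- cfg$nModes
  # Gram-Schmidt over flattened 3n vectors; keep the combination matrix so
  # the same modes can be evaluated analytically at volume-mesh nodes.
  FviaRows <- do.call(rbind, lapply(raw, function(m) as.numeric(t(m))))
  Rmat <- matrix(0, nModes, length(raw))
  P <- matrix(0, nModes, 3L * n)
  for (m in seq_len(nModes)) {
    v <- FviaRows[m, ]
    coef <- numeric(length(raw))
    coef[m] <- 1
    if (m > 1) {
      pr <- P[seq_len(m - 1), , drop = FALSE] %*% v
      v <- v - as.numeric(t(pr) %*% P[seq_len(m - 1), , drop = FALSE])
      coef <- coef - as.numeric(t(pr) %*% Rmat[seq_len(m - 1), , drop = FALSE])
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) stop("degenerate deformation field basis")
    P[m, ] <- v / nv
    Rmat[m, ] <- coef / nv
  }

  # eigenvalues: mode 1 from the LV-length sensitivity, the others from
  # per-node displacement targets
  lmk <- geo$landmarks
  dispAt <- function(m, idx) P[m, (3 * (idx - 1) + 1):(3 * idx)]
  axis <- normalize(geo$pos[lmk[["mitralCentre"]], ] -
                    geo$pos[lmk[["lvApex"]], ])
  g1 <- abs(sum((dispAt(1, lmk[["lvApex"]]) -
                 dispAt(1, lmk[["mitralCentre"]])) * axis))
  sdv <- numeric(nModes)
  sdv[1] <- cfg$lvLengthSd / g1
  for (m in 2:nModes) {
    pn <- matrix(P[m, ], ncol = 3, byrow = TRUE)
    sdv[m] <- cfg$modeSdMm[m] / max(sqrt(rowSums(pn^2)))
  }
  lambda <- sdv^2
  ord <- order(lambda, decreasing = TRUE)
  lambda <- lambda[ord]
  P <- P[ord, , drop = FALSE]
  Rmat <- Rmat[ord, , drop = FALSE]
  # enforce strict decrease
  for (m in 2:nModes) if (lambda[m] >= lambda[m - 1])
    lambda[m] <- lambda[m - 1] * (1 - 1e-9)

  new("ShapeModel",
      meanShape = as.numeric(t(geo$pos)),
      modes = P, eigenvalues = lambda,
      topology = list(triangles = geo$triangles, region = geo$region),
      landmarks = geo$landmarks,
      meta = list(cfg = cfg, param = geo$param, Rmat = Rmat,
                  maps = geo$maps, seed = seed))
}

.modelBounds <- function(model) {
  cfg <- model@meta$cfg
  if (identical(cfg$boundType, "lambda")) 3 * model@eigenvalues
  else 3 * sqrt(model@eigenvalues)
}

.surfaceFromPositions <- function(model, pos, weights, scale = 1,
                                  scaleCentre = NULL) {
  meta <- list(parametric = TRUE, cfg = model@meta$cfg,
               param = model@meta$param, Rmat = model@meta$Rmat,
               maps = model@meta$maps, weights = weights, scale = scale,
               scaleCentre = scaleCentre, pmSpecs = list())
  new("VentricularSurface", vertices = pos,
      triangles = model@topology$triangles,
      region = as.integer(model@topology$region),
      landmarks = model@landmarks, meta = meta)
}

#' Draw one shape from the model (x = xbar + P' b)
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param b numeric weight vector of length equal to the number of modes;
#'   each \code{b_i} must lie within the model bounds (by default plus or
#'   minus three standard deviations, 3 sqrt(lambda_i)).
#' @return a \linkS4class{ShapeSample}.
#' @export
sampleShape <- function(model, b) {
  nModes <- nrow(model@modes)
  if (length(b) != nModes) stop("b must have one weight per mode")
  bound <- .modelBounds(model)
  if (any(abs(b) > bound + 1e-9))
    stop("shape weights outside the allowable bounds of the model")
  x <- model@meanShape + as.numeric(t(model@modes) %*% b)
  pos <- matrix(x, ncol = 3, byrow = TRUE)
  surf <- .surfaceFromPositions(model, pos, weights = b)
  new("ShapeSample", weights = as.numeric(b), surface = surf)
}

#' Sample a virtual population of ventricular shapes
#'
#' Mode weights are drawn independently from zero-mean Gaussians with
#' variance lambda_i, truncated at the model bounds (a uniform-in-bounds
#' alternative is available via \code{distribution}).
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param count number of shapes (>= 1).
#' @param seed integer seed; the population is reproducible given the seed.
#' @param distribution "gaussian" (default) or "uniform".
#' @return list of \linkS4class{ShapeSample} objects.
#' @export
randomPopulation <- function(model, count, seed = 1L,
                             distribution = c("gaussian", "uniform")) {
  distribution <- match.arg(distribution)
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  nModes <- nrow(model@modes)
  bound <- .modelBounds(model)
  sdv <- sqrt(model@eigenvalues)
  withSeed(seed, {
    lapply(seq_len(count), function(k) {
      b <- if (distribution == "gaussian") {
        vapply(seq_len(nModes), function(m)
          rnormTrunc(1, 0, sdv[m], k = bound[m] / sdv[m]), numeric(1))
      } else {
        stats::runif(nModes, -bound, bound)
      }
      sampleShape(model, b)
    })
  })
}

#' Rescale a surface to a target LV length
#'
#' Uniform isotropic scaling about the mitral-valve centre so that the
#' apex-to-mitral-centre distance equals \code{targetLength}.
#'
#' @param surface a \linkS4class{VentricularSurface}.
#' @param targetLength target LV length (mm, > 0).
#' @return the scaled \linkS4class{VentricularSurface}.
#' @export
scaleToLvLength <- function(surface, targetLength) {
  if (targetLength <= 0) stop("targetLength must be positive")
  cur <- lvLength(surface)
  s <- targetLength / cur
  mc <- .mitralCentre(surface)
  v <- sweep(sweep(surface@vertices, 2, mc) * s, 2, mc, "+")
  surface@vertices <- v
  surface@meta$scale <- (surface@meta$scale %||% 1) * s
  surface@meta$scaleCentre <- surface@meta$scaleCentre %||% mc
  surface
}
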