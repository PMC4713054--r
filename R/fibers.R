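# Rule-based myocardial fiber orientation (Streeter): helix angle linear
# in the transmural coordinate, papillary-muscle fibers along the PM axis.

#' Assign myocardial fiber orientations
#'
#' The helix angle varies linearly across the wall,
#' alpha(e) = alphaEndo + e (alphaEpi - alphaEndo), and the fiber is the
#' local circumferential direction rotated by alpha(e) in the tangent
#' plane. Papillary-muscle vertices are aligned to the PM long axis. The
#' per-tet direction is the sign-aligned normalized mean of its vertex
#' directions.
#'
#' @param mesh a \linkS4class{VolumeMesh} from [tetrahedralize()] (requires
#'   endo/epi correspondence, i.e. a parametric mesh).
#' @param alphaEndo,alphaEpi helix angles at endo- and epicardium
#'   (degrees; classic Streeter values +60/-60 by default).
#' @return a \linkS4class{FiberField}.
#' @export
assignFibers <- function(mesh, alphaEndo = 60, alphaEpi = -60) {
  if (!isTRUE(mesh@meta$parametric))
    stop("assignFibers requires a mesh with endo/epi correspondence")
  meta <- mesh@meta
  pos <- mesh@vertices
  par <- meta$param
  d <- meta$dims
  nT <- d$nTheta
  nP <- d$nPhi
  ne <- d$ne
  neRV <- d$neRV
  lvIdx <- meta$lvIdx
  apexIdx <- meta$apexIdx
  rvIdx <- meta$rvIdx
  nv <- nrow(pos)
  fib <- matrix(0, nv, 3)

  ip1 <- c(2:nT, 1L)
  im1 <- c(nT, 1:(nT - 1L))
  alpha <- (alphaEndo + mesh@e * (alphaEpi - alphaEndo)) * pi / 180

  layerFibers <- function(idxM, alphaVec) {
    # circumferential and longitudinal tangents by central differences
    ec <- pos[idxM[ip1, ], , drop = FALSE] - pos[idxM[im1, ], , drop = FALSE]
    jn <- cbind(idxM[, c(2:nP, nP)])
    jp <- cbind(idxM[, c(1, 1:(nP - 1L))])
    el <- pos[jn, , drop = FALSE] - pos[jp, , drop = FALSE]
    ec <- rowNormalize(ec)
    nrm <- rowNormalize(cbind(
      ec[, 2] * el[, 3] - ec[, 3] * el[, 2],
      ec[, 3] * el[, 1] - ec[, 1] * el[, 3],
      ec[, 1] * el[, 2] - ec[, 2] * el[, 1]))
    el2 <- rowNormalize(cbind(
      nrm[, 2] * ec[, 3] - nrm[, 3] * ec[, 2],
      nrm[, 3] * ec[, 1] - nrm[, 1] * ec[, 3],
      nrm[, 1] * ec[, 2] - nrm[, 2] * ec[, 1]))
    a <- alphaVec[as.vector(idxM)]
    cos(a) * ec + sin(a) * el2
  }

  for (k in 0:ne) {
    idxM <- lvIdx[, , k + 1L]
    fib[as.vector(idxM), ] <- layerFibers(idxM, alpha)
    # apex node: copy from the first ring neighbour
    fib[apexIdx[k + 1L], ] <- fib[idxM[1, 1], ]
  }
  for (l in 0:neRV) {
    idxM <- rvIdx[, , l + 1L]
    own <- which(idxM != lvIdx[, , ne + 1L]) # actual RV nodes
    if (length(own)) {
      lf <- layerFibers(idxM, alpha)
      ids <- as.vector(idxM)[own]
      fib[ids, ] <- lf[own, , drop = FALSE]
    }
  }
  # papillary muscles: fiber along the PM long axis
  for (pm in meta$pm) {
    fib[pm$vertexIds, ] <- matrix(pm$axisDir, length(pm$vertexIds), 3,
                                  byrow = TRUE)
  }
  fib <- rowNormalize(fib)

  # per-tet sign-aligned average
  tets <- mesh@tets
  f1 <- fib[tets[, 1], , drop = FALSE]
  algn <- function(fk) {
    s <- sign(rowSums(fk * f1))
    s[s == 0] <- 1
    fk * s
  }
  tf <- f1 + algn(fib[tets[, 2], , drop = FALSE]) +
    algn(fib[tets[, 3], , drop = FALSE]) +
    algn(fib[tets[, 4], , drop = FALSE])
  tf <- rowNormalize(tf)

  new("FiberField", vertexFibers = fib, tetFibers = tf, e = mesh@e)
}
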