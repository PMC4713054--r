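# Activation-time solvers: exact shortest-time on the 1-D Purkinje graph,
# anisotropic Eikonal on the tetrahedral myocardium (fast-iterative local
# solver, compiled), and the delayed two-way coupling at the PMJs.

#' Source set constructor
#'
#' @param id vertex (or network-node) indices.
#' @param time prescribed activation times (ms, >= 0).
#' @return data.frame with columns \code{id}, \code{time}.
#' @export
sourceSet <- function(id, time) {
  if (length(id) != length(time)) stop("id and time lengths differ")
  if (!length(id)) stop("empty source set")
  if (any(time < 0)) stop("source times must be >= 0")
  data.frame(id = as.integer(id), time = as.numeric(time))
}

#' Exact shortest-time solve on the Purkinje network
#'
#' Edge travel time is length/velocity; blocked edges are excluded (full
#' conduction block). Solved as a single-source shortest path problem with
#' a virtual super-source (equivalent to Dijkstra from every source with
#' its prescribed time).
#'
#' @param network a \linkS4class{PurkinjeNetwork}.
#' @param sources a [sourceSet()] on network node ids.
#' @return numeric per-node activation times (ms; +Inf if unreachable).
#' @export
solveNetwork <- function(network, sources) {
  k <- nrow(network@nodes)
  if (!nrow(sources)) stop("empty source set")
  if (any(sources$id < 1L | sources$id > k)) stop("source id out of range")
  ed <- network@edges[!network@edges$blocked, , drop = FALSE]
  super <- k + 1L
  el <- rbind(cbind(ed$from, ed$to),
              cbind(rep(super, nrow(sources)), sources$id))
  wts <- c(ed$length / ed$velocity, sources$time)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < super) g <- igraph::add_vertices(g, super -
                                                             igraph::vcount(g))
  d <- igraph::distances(g, v = super, weights = wts, algorithm = "dijkstra")
  as.numeric(d)[seq_len(k)]
}

# Packed inverse conduction tensors per tet: M = A F^-2 A' =
# (1/vt^2) I + (1/vl^2 - 1/vt^2) f f'.
.tetTensorInv <- function(fibers, config) {
  f <- fibers@tetFibers
  iT <- 1 / config@vTransversal^2
  dL <- 1 / config@vLongitudinal^2 - iT
  cbind(iT + dL * f[, 1]^2, dL * f[, 1] * f[, 2], dL * f[, 1] * f[, 3],
        iT + dL * f[, 2]^2, dL * f[, 2] * f[, 3], iT + dL * f[, 3]^2)
}

#' Anisotropic Eikonal solve on the myocardium
#'
#' Per-tet conduction tensor with the longitudinal speed along the
#' (averaged) fiber direction and the transversal speed across it; vertex
#' times from a monotone fast-iterative front propagation whose local
#' update minimizes t(y) + |x - y| in the tensor metric over the opposite
#' face of each incident tetrahedron.
#'
#' @param mesh a \linkS4class{VolumeMesh}.
#' @param fibers the matching \linkS4class{FiberField}.
#' @param sources a [sourceSet()] on mesh vertex ids.
#' @param config a \linkS4class{ConductionConfig}.
#' @return numeric per-vertex activation times (ms; +Inf where unreached).
#' @export
solveMyocardium <- function(mesh, fibers, sources, config = conductionConfig()) {
  if (!nrow(sources)) stop("empty source set")
  nv <- nrow(mesh@vertices)
  if (any(sources$id < 1L | sources$id > nv)) stop("source id out of range")
  vols <- tetVolumes(mesh@vertices, mesh@tets)
  if (any(abs(vols) < 1e-9)) stop("degenerate tetrahedra in mesh")
  Minv <- .tetTensorInv(fibers, config)
  out <- .fim_solve(mesh@vertices, mesh@tets - 1L, Minv,
                    sources$id - 1L, sources$time,
                    config@solverTolerance, numeric(0))
  unreached <- !is.finite(out)
  if (any(unreached))
    warning(sum(unreached), " vertices unreached (disconnected components)")
  out
}

#' Coupled Purkinje-myocardium activation solve
#'
#' Fixed-point iteration of the two domains coupled at the PMJs with
#' asymmetric delays: network times from the His origin, myocardial
#' sources at PMJ vertices (+6 ms by default), network re-solve with
#' retrograde sources at the PMJ nodes (+1 ms), until no time changes by
#' more than the coupling tolerance.
#'
#' @param mesh a \linkS4class{VolumeMesh}.
#' @param fibers the matching \linkS4class{FiberField}.
#' @param network a \linkS4class{PurkinjeNetwork} with PMJ-to-vertex map.
#' @param config a \linkS4class{ConductionConfig}.
#' @param onsetTime activation time prescribed at the His origin (ms).
#' @return an \linkS4class{ActivationMap} (myocardium + network).
#' @export
coupledSolve <- function(mesh, fibers, network, config = conductionConfig(),
                         onsetTime = 0) {
  his <- which(network@role == "HIS_ORIGIN")
  if (!length(his)) stop("network has no HIS_ORIGIN node")
  pmj <- which(network@role == "PMJ" & !is.na(network@pmjVertex))
  baseSrc <- sourceSet(his, rep(onsetTime, length(his)))
  nv <- nrow(mesh@vertices)
  vols <- tetVolumes(mesh@vertices, mesh@tets)
  if (any(abs(vols) < 1e-9)) stop("degenerate tetrahedra in mesh")
  Minv <- .tetTensorInv(fibers, config)

  nodeTimes <- solveNetwork(network, baseSrc)
  vertexTimes <- rep(Inf, nv)
  for (it in seq_len(config@maxCouplingIterations)) {
    act <- pmj[is.finite(nodeTimes[pmj])]
    if (!length(act)) break
    myoSrc <- sourceSet(network@pmjVertex[act],
                        nodeTimes[act] + config@delayPkToMyo)
    # warm start from the previous iterate: source times are non-increasing
    # across coupling sweeps, so the previous map is a valid upper bound
    init <- if (it > 1L) vertexTimes else numeric(0)
    newVertex <- .fim_solve(mesh@vertices, mesh@tets - 1L, Minv,
                            myoSrc$id - 1L, myoSrc$time,
                            config@solverTolerance, init)
    retro <- pmj[is.finite(newVertex[network@pmjVertex[pmj]])]
    netSrc <- rbind(baseSrc,
                    sourceSet(retro,
                              newVertex[network@pmjVertex[retro]] +
                                config@delayMyoToPk))
    newNode <- solveNetwork(network, netSrc)
    dv <- suppressWarnings(max(abs(newVertex - vertexTimes)[
      is.finite(newVertex) & is.finite(vertexTimes)], 0))
    dn <- suppressWarnings(max(abs(newNode - nodeTimes)[
      is.finite(newNode) & is.finite(nodeTimes)], 0))
    gained <- sum(is.finite(newVertex)) > sum(is.finite(vertexTimes)) ||
      sum(is.finite(newNode)) > sum(is.finite(nodeTimes))
    vertexTimes <- newVertex
    nodeTimes <- newNode
    if (!gained && max(dv, dn) < config@couplingTolerance) break
  }
  new("ActivationMap", vertexTimes = vertexTimes, nodeTimes = nodeTimes)
}
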