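#' @useDynLib PurkinjeFT, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# Region codes used on surface triangles
.REGION <- c(LV_ENDO = 1L, RV_ENDO = 2L, EPI = 3L, BASE = 4L,
             APM = 5L, PPM = 6L)
# Vertex labels on volume meshes
.VLABEL <- c(LV_WALL = 1L, RV_WALL = 2L, SEPTUM = 3L, APM = 4L, PPM = 5L)
# Purkinje node roles
.ROLES <- c("HIS_ORIGIN", "AV_NODE", "BUNDLE", "FASCICLE", "PMJ", "FT_NODE")

#' Labelled triangulated biventricular surface
#'
#' Vertices in mm, right-handed coordinates with the LV long axis along +z
#' and the apex at low z. Triangles carry an integer region label
#' (1 = LV endocardium, 2 = RV endocardium, 3 = epicardium, 4 = basal plane,
#' 5 = anterior papillary muscle, 6 = posterior papillary muscle). Named
#' landmark vertex indices identify the LV apex, mitral-valve centre,
#' His-bundle origin, AV node and RV apex.
#'
#' @slot vertices numeric n x 3 matrix of coordinates (mm).
#' @slot triangles integer m x 3 matrix of 1-based vertex indices.
#' @slot region integer vector, one region code per triangle.
#' @slot landmarks named integer vector of vertex indices.
#' @slot meta list of generator provenance (parametric coordinates, shape
#'   weights, scale) used by [tetrahedralize()] for structured wall meshing.
#' @export
setClass("VentricularSurface", representation(
  vertices = "matrix", triangles = "matrix", region = "integer",
  landmarks = "integer", meta = "list"))

setValidity("VentricularSurface", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must be m x 3")
  if (length(object@region) != nrow(object@triangles))
    msg <- c(msg, "one region label per triangle required")
  if (nrow(object@triangles) &&
      (max(object@triangles) > nrow(object@vertices) ||
       min(object@triangles) < 1L))
    msg <- c(msg, "triangle indices out of range")
  if (length(object@landmarks) &&
      (any(object@landmarks < 1L) ||
       any(object@landmarks > nrow(object@vertices))))
    msg <- c(msg, "landmark indices out of range")
  if (length(msg)) msg else TRUE
})

#' Statistical shape model of the biventricular anatomy
#'
#' Point-distribution model x = xbar + P' b: a mean shape of n 3-D landmarks
#' stored as a length-3n vector, t orthonormal deviation modes (rows of the
#' t x 3n mode matrix) and per-mode variances (eigenvalues, mm^2). The fixed
#' triangulation and region labels over the landmarks are kept in
#' \code{topology}.
#'
#' @slot meanShape numeric length-3n vector (mm), landmark-major (x,y,z).
#' @slot modes numeric t x 3n matrix with orthonormal rows.
#' @slot eigenvalues numeric, strictly positive, non-increasing.
#' @slot topology list with \code{triangles} and \code{region} as in
#'   \linkS4class{VentricularSurface}.
#' @slot landmarks named integer vector of landmark (vertex) indices.
#' @slot meta list: parametric node coordinates and the linear map from raw
#'   analytic deformation fields to the orthonormalized modes.
#' @export
setClass("ShapeModel", representation(
  meanShape = "numeric", modes = "matrix", eigenvalues = "numeric",
  topology = "list", landmarks = "integer", meta = "list"))

setValidity("ShapeModel", function(object) {
  msg <- character()
  if (length(object@meanShape) %% 3L != 0L)
    msg <- c(msg, "meanShape length must be a multiple of 3")
  if (ncol(object@modes) != length(object@meanShape))
    msg <- c(msg, "modes must be t x 3n")
  if (nrow(object@modes) != length(object@eigenvalues))
    msg <- c(msg, "one eigenvalue per mode required")
  if (any(object@eigenvalues <= 0))
    msg <- c(msg, "eigenvalues must be strictly positive")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' A shape drawn from a ShapeModel
#'
#' @slot weights numeric mode weights b (each within the model bounds).
#' @slot surface the reconstructed \linkS4class{VentricularSurface}.
#' @export
setClass("ShapeSample", representation(
  weights = "numeric", surface = "VentricularSurface"))

#' Papillary-muscle geometry parameters
#'
#' A papillary muscle is a cylinder (60% of its length L) capped by a
#' paraboloid z(r) = L - 4 * 0.4 * L * r^2 / d^2, attached to the LV
#' endocardium and tilted so that the azimuth between tip and attachment
#' about the LV axis equals \code{tipAngle} and the tip sits
#' \code{tipDistance} mm from the LV axis.
#'
#' @slot side "APM" or "PPM".
#' @slot length PM length L (mm), base to tip.
#' @slot diameter PM diameter d (mm).
#' @slot attachmentPoint numeric length-3, centre of the PM-LV junction (mm).
#' @slot attachmentTriangle integer surface triangle index (0 if unset).
#' @slot tipAngle degrees about the LV axis between attachment and tip.
#' @slot tipDistance tip distance from the LV axis (mm).
#' @slot paraboloidFraction fraction of L taken by the paraboloid cap (0.4).
#' @export
setClass("PMSpec", representation(
  side = "character", length = "numeric", diameter = "numeric",
  attachmentPoint = "numeric", attachmentTriangle = "integer",
  tipAngle = "numeric", tipDistance = "numeric",
  paraboloidFraction = "numeric"))

setValidity("PMSpec", function(object) {
  msg <- character()
  if (!object@side %in% c("APM", "PPM")) msg <- c(msg, "side must be APM|PPM")
  if (!(object@length > object@diameter && object@diameter > 0))
    msg <- c(msg, "need L > d > 0")
  if (object@tipAngle < 0 || object@tipAngle >= 90)
    msg <- c(msg, "tipAngle must be in [0, 90)")
  if (abs(object@paraboloidFraction - 0.4) > 1e-12)
    msg <- c(msg, "paraboloidFraction is fixed at 0.4")
  if (length(msg)) msg else TRUE
})

#' Labelled tetrahedral volume mesh of the myocardial wall
#'
#' @slot vertices numeric n x 3 (mm).
#' @slot tets integer m x 4, positively oriented.
#' @slot label integer per-vertex label (1 LV wall, 2 RV wall, 3 septum,
#'   4 APM, 5 PPM).
#' @slot e numeric per-vertex transmural coordinate in [0, 1]
#'   (0 endocardium, 1 epicardium).
#' @slot endo,epi logical per-vertex surface-correspondence flags.
#' @slot nodalVolume numeric lumped nodal volumes (mm^3).
#' @slot meta list (parametric provenance, PM tip vertex indices, landmark
#'   vertex indices, grid dimensions).
#' @export
setClass("VolumeMesh", representation(
  vertices = "matrix", tets = "matrix", label = "integer", e = "numeric",
  endo = "logical", epi = "logical", nodalVolume = "numeric", meta = "list"))

setValidity("VolumeMesh", function(object) {
  msg <- character()
  nv <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@tets) != 4L) msg <- c(msg, "tets must be m x 4")
  if (nrow(object@tets) && (min(object@tets) < 1L || max(object@tets) > nv))
    msg <- c(msg, "tet indices out of range")
  for (s in c("label", "e", "endo", "epi", "nodalVolume"))
    if (length(slot(object, s)) != nv)
      msg <- c(msg, paste0("slot '", s, "' must have one entry per vertex"))
  if (length(msg)) msg else TRUE
})

#' Myocardial fiber orientation field
#'
#' Per-vertex and per-tet unit fiber directions from the rule-based
#' Streeter model (helix angle linear in the transmural coordinate), with
#' papillary-muscle fibers aligned to the PM long axis.
#'
#' @slot vertexFibers numeric n x 3 unit vectors.
#' @slot tetFibers numeric m x 3 unit vectors (sign-aligned vertex average).
#' @slot e numeric per-vertex transmural coordinate.
#' @export
setClass("FiberField", representation(
  vertexFibers = "matrix", tetFibers = "matrix", e = "numeric"))

#' One-dimensional Purkinje conduction network
#'
#' A geometric graph: node coordinates (mm) constrained to the endocardial
#' or PM surface (false-tendon chords run free through the cavity), edges
#' with length, conduction velocity (mm/ms) and a blocked flag, per-node
#' roles, and for each PMJ the index of its nearest myocardial vertex.
#'
#' @slot nodes numeric k x 3 coordinates.
#' @slot edges data.frame with columns from, to, length, velocity, blocked.
#' @slot role character per-node role (HIS_ORIGIN, AV_NODE, BUNDLE,
#'   FASCICLE, PMJ, FT_NODE).
#' @slot pmjVertex integer per-node myocardial vertex index (NA unless PMJ
#'   or delta terminal).
#' @slot meta list: ordered left/right-bundle edge indices, per-branch
#'   generator statistics, false-tendon bookkeeping.
#' @export
setClass("PurkinjeNetwork", representation(
  nodes = "matrix", edges = "data.frame", role = "character",
  pmjVertex = "integer", meta = "list"))

setValidity("PurkinjeNetwork", function(object) {
  msg <- character()
  k <- nrow(object@nodes)
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be k x 3")
  if (length(object@role) != k) msg <- c(msg, "one role per node required")
  if (length(object@pmjVertex) != k) msg <- c(msg, "pmjVertex length mismatch")
  ed <- object@edges
  need <- c("from", "to", "length", "velocity", "blocked")
  if (!all(need %in% names(ed)))
    msg <- c(msg, "edges need columns from,to,length,velocity,blocked")
  else if (nrow(ed)) {
    if (min(ed$from, ed$to) < 1L || max(ed$from, ed$to) > k)
      msg <- c(msg, "edge endpoints out of range")
    len <- sqrt(rowSums((object@nodes[ed$from, , drop = FALSE] -
                         object@nodes[ed$to, , drop = FALSE])^2))
    if (any(abs(len - ed$length) > 1e-9))
      msg <- c(msg, "edge lengths must equal Euclidean node distances")
  }
  if (!all(object@role %in% .ROLES)) msg <- c(msg, "unknown node role")
  if (length(msg)) msg else TRUE
})

#' Conduction parameters for the coupled activation solve
#'
#' Defaults follow the standard fast/slow conduction setting: myocardial
#' velocities 0.8 mm/ms along and 0.3 mm/ms across the fiber, 3.5 mm/ms in
#' the Purkinje network and false tendon, and asymmetric Purkinje-muscle
#' junction delays of 6 ms (network to muscle) and 1 ms (muscle to network).
#'
#' @slot vLongitudinal,vTransversal,vPurkinje velocities (mm/ms).
#' @slot delayPkToMyo,delayMyoToPk PMJ delays (ms).
#' @slot couplingTolerance fixed-point stopping tolerance (ms).
#' @slot solverTolerance Eikonal iteration tolerance (ms).
#' @slot maxCouplingIterations integer cap on coupling sweeps.
#' @export
setClass("ConductionConfig", representation(
  vLongitudinal = "numeric", vTransversal = "numeric", vPurkinje = "numeric",
  delayPkToMyo = "numeric", delayMyoToPk = "numeric",
  couplingTolerance = "numeric", solverTolerance = "numeric",
  maxCouplingIterations = "integer"))

setValidity("ConductionConfig", function(object) {
  msg <- character()
  if (object@vLongitudinal <= 0 || object@vTransversal <= 0 ||
      object@vPurkinje <= 0)
    msg <- c(msg, "velocities must be positive")
  if (object@vLongitudinal < object@vTransversal)
    msg <- c(msg, "vLongitudinal must be >= vTransversal")
  if (length(msg)) msg else TRUE
})

#' Activation-time map
#'
#' @slot vertexTimes numeric per-myocardial-vertex activation time (ms;
#'   +Inf when unreached).
#' @slot nodeTimes numeric per-network-node activation time (ms).
#' @export
setClass("ActivationMap", representation(
  vertexTimes = "numeric", nodeTimes = "numeric"))

#' Per-simulation activation summary
#'
#' QRS duration (last minus first myocardial activation), first/last and
#' total activation times per ventricle (ms from His onset), and the
#' left-right dyssynchrony (absolute difference of the last activations).
#'
#' @slot qrsD,firstLV,firstRV,lastLV,lastRV,totalLV,totalRV,dyssynchrony
#'   numeric (ms).
#' @export
setClass("ActivationSummary", representation(
  qrsD = "numeric", firstLV = "numeric", firstRV = "numeric",
  lastLV = "numeric", lastRV = "numeric", totalLV = "numeric",
  totalRV = "numeric", dyssynchrony = "numeric"))

#' False-tendon configuration
#'
#' @slot endpoint "APM_TIP", "PPM_TIP" or "VFW".
#' @slot termination "DIRECT" or "DELTA".
#' @slot vfwPoint numeric length-3 free-wall endocardial point (mm); used
#'   when endpoint == "VFW".
#' @slot deltaSegmentLength,deltaSegmentSd,deltaBranchAngle,deltaAngleSd
#'   delta-termination growth parameters (mm, mm, deg, deg).
#' @slot deltaBranches integer number of delta branches (10).
#' @export
setClass("FTConfig", representation(
  endpoint = "character", termination = "character", vfwPoint = "numeric",
  deltaSegmentLength = "numeric", deltaSegmentSd = "numeric",
  deltaBranchAngle = "numeric", deltaAngleSd = "numeric",
  deltaBranches = "integer"))

setValidity("FTConfig", function(object) {
  msg <- character()
  if (!object@endpoint %in% c("APM_TIP", "PPM_TIP", "VFW"))
    msg <- c(msg, "endpoint must be APM_TIP|PPM_TIP|VFW")
  if (!object@termination %in% c("DIRECT", "DELTA"))
    msg <- c(msg, "termination must be DIRECT|DELTA")
  if (length(msg)) msg else TRUE
})

#' Assembled simulation-ready heart
#'
#' Convenience container binding the sampled surface, the labelled volume
#' mesh, the fiber field and the merged Purkinje network of one virtual
#' heart.
#'
#' @slot surface \linkS4class{VentricularSurface} (with PMs merged).
#' @slot mesh \linkS4class{VolumeMesh}.
#' @slot fibers \linkS4class{FiberField}.
#' @slot network \linkS4class{PurkinjeNetwork}.
#' @slot meta list (shape weights, PM specs, seeds).
#' @export
setClass("SimHeart", representation(
  surface = "VentricularSurface", mesh = "VolumeMesh",
  fibers = "FiberField", network = "PurkinjeNetwork", meta = "list"))
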