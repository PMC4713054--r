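#' @rdname VentricularSurface-class
#' @param object,x an object.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname VentricularSurface-class
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
#' @rdname VentricularSurface-class
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname VentricularSurface-class
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' LV length (apex to mitral-valve centre, mm)
#'
#' @param x a \linkS4class{VentricularSurface} or \linkS4class{ShapeSample}.
#' @return numeric scalar, mm.
#' @export
setGeneric("lvLength", function(x) standardGeneric("lvLength"))

#' @rdname VentricularSurface-class
#' @export
setMethod("vertices", "VentricularSurface", function(x) x@vertices)
#' @rdname VentricularSurface-class
#' @export
setMethod("triangles", "VentricularSurface", function(x) x@triangles)
#' @rdname VentricularSurface-class
#' @export
setMethod("regionLabels", "VentricularSurface", function(x) x@region)
#' @rdname VentricularSurface-class
#' @export
setMethod("landmarks", "VentricularSurface", function(x) x@landmarks)

#' @rdname lvLength
#' @export
setMethod("lvLength", "VentricularSurface", function(x) {
  lm <- x@landmarks
  apex <- x@vertices[lm[["lvApex"]], ]
  mc <- .mitralCentre(x)
  sqrt(sum((apex - mc)^2))
})

#' @rdname lvLength
#' @export
setMethod("lvLength", "ShapeSample", function(x) lvLength(x@surface))

# Mitral-valve centre: stored explicitly as a (possibly unreferenced)
# landmark vertex.
.mitralCentre <- function(surface) {
  surface@vertices[surface@landmarks[["mitralCentre"]], ]
}

#' @rdname VolumeMesh-class
#' @export
setMethod("vertices", "VolumeMesh", function(x) x@vertices)

#' Tetrahedra of a volume mesh
#' @param x a \linkS4class{VolumeMesh}.
#' @export
tetrahedra <- function(x) x@tets

#' Mode weights of a shape sample
#' @param x a \linkS4class{ShapeSample}.
#' @export
shapeWeights <- function(x) x@weights

#' Surface of a shape sample
#' @param x a \linkS4class{ShapeSample}.
#' @export
sampleSurface <- function(x) x@surface

#' Network edges / nodes / roles
#' @param x a \linkS4class{PurkinjeNetwork}.
#' @export
networkEdges <- function(x) x@edges
#' @rdname networkEdges
#' @export
networkNodes <- function(x) x@nodes
#' @rdname networkEdges
#' @export
nodeRoles <- function(x) x@role
#' @rdname networkEdges
#' @export
pmjVertices <- function(x) x@pmjVertex

setMethod("show", "VentricularSurface", function(object) {
  cat("VentricularSurface:", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles\n")
  tab <- table(factor(object@region, levels = .REGION,
                      labels = names(.REGION)))
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  LV length:", format(lvLength(object), digits = 4), "mm\n")
})

setMethod("show", "ShapeModel", function(object) {
  cat("ShapeModel:", length(object@meanShape) / 3L, "landmarks,",
      nrow(object@modes), "modes\n")
  cat("  sqrt(eigenvalues) [mm]:",
      paste(format(sqrt(object@eigenvalues), digits = 3), collapse = " "),
      "\n")
})

setMethod("show", "ShapeSample", function(object) {
  cat("ShapeSample: b =",
      paste(format(object@weights, digits = 3), collapse = " "), "\n")
  show(object@surface)
})

setMethod("show", "PMSpec", function(object) {
  cat(sprintf("PMSpec %s: L=%.1f mm d=%.1f mm tipAngle=%.1f deg tipDist=%.1f mm\n",
              object@side, object@length, object@diameter, object@tipAngle,
              object@tipDistance))
})

setMethod("show", "VolumeMesh", function(object) {
  cat("VolumeMesh:", nrow(object@vertices), "vertices,",
      nrow(object@tets), "tets, volume",
      format(sum(object@nodalVolume), digits = 5), "mm^3\n")
})

setMethod("show", "PurkinjeNetwork", function(object) {
  cat("PurkinjeNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges,",
      sum(object@role == "PMJ"), "PMJs,",
      sum(object@edges$blocked), "blocked edges\n")
})

setMethod("show", "ActivationMap", function(object) {
  ft <- object@vertexTimes[is.finite(object@vertexTimes)]
  cat("ActivationMap:", length(object@vertexTimes), "vertices (",
      length(ft), "finite ), range",
      paste(format(range(ft), digits = 4), collapse = " - "), "ms\n")
})

setMethod("show", "ActivationSummary", function(object) {
  cat(sprintf(paste0("ActivationSummary: QRSd=%.1f ms  firstLV=%.1f",
                     "  firstRV=%.1f  totalLV=%.1f  totalRV=%.1f",
                     "  dyssynchrony=%.1f\n"),
              object@qrsD, object@firstLV, object@firstRV, object@totalLV,
              object@totalRV, object@dyssynchrony))
})

setMethod("show", "ConductionConfig", function(object) {
  cat(sprintf(paste0("ConductionConfig: vL=%.2f vT=%.2f vPK=%.2f mm/ms, ",
                     "delays %.0f/%.0f ms\n"),
              object@vLongitudinal, object@vTransversal, object@vPurkinje,
              object@delayPkToMyo, object@delayMyoToPk))
})

setMethod("show", "FTConfig", function(object) {
  cat("FTConfig:", object@endpoint, "/", object@termination, "\n")
})

setMethod("show", "SimHeart", function(object) {
  cat("SimHeart\n  ")
  show(object@mesh)
  cat("  ")
  show(object@network)
})

#' Conduction configuration constructor
#'
#' @param vLongitudinal,vTransversal myocardial velocities along/across the
#'   fiber (mm/ms).
#' @param vPurkinje Purkinje and false-tendon velocity (mm/ms).
#' @param delayPkToMyo,delayMyoToPk PMJ transmission delays (ms).
#' @param couplingTolerance fixed-point tolerance (ms).
#' @param solverTolerance Eikonal tolerance (ms).
#' @param maxCouplingIterations cap on coupling sweeps.
#' @return a \linkS4class{ConductionConfig}.
#' @export
conductionConfig <- function(vLongitudinal = 0.8, vTransversal = 0.3,
                             vPurkinje = 3.5, delayPkToMyo = 6,
                             delayMyoToPk = 1, couplingTolerance = 0.01,
                             solverTolerance = 1e-6,
                             maxCouplingIterations = 20L) {
  new("ConductionConfig", vLongitudinal = vLongitudinal,
      vTransversal = vTransversal, vPurkinje = vPurkinje,
      delayPkToMyo = delayPkToMyo, delayMyoToPk = delayMyoToPk,
      couplingTolerance = couplingTolerance,
      solverTolerance = solverTolerance,
      maxCouplingIterations = as.integer(maxCouplingIterations))
}
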