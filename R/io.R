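#' @importFrom utils write.table
NULL

# Readers/writers for the standard interchange formats: legacy VTK
# PolyData and ASCII PLY/OFF for surfaces (with a JSON landmark sidecar),
# VTU (XML UnstructuredGrid, ASCII) for volume meshes and activation maps,
# JSON for Purkinje networks and PM specs. All coordinates in mm.

#' Write a ventricular surface
#'
#' Legacy ASCII VTK PolyData with an integer cell-data field
#' \code{region}, or ASCII PLY (positions + triangles only); landmark
#' indices go to a JSON sidecar (\code{<file>.landmarks.json}).
#'
#' @param surface a \linkS4class{VentricularSurface}.
#' @param file output path (.vtk or .ply decides the format).
#' @export
writeSurface <- function(surface, file) {
  v <- surface@vertices
  tr <- surface@triangles
  if (grepl("\\.ply$", file, ignore.case = TRUE)) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(tr)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    write.table(format(v, trim = TRUE), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    write.table(cbind(3L, tr - 1L), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c("# vtk DataFile Version 3.0", "ventricular surface",
                 "ASCII", "DATASET POLYDATA",
                 paste("POINTS", nrow(v), "float")), con)
    write.table(format(v, trim = TRUE), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    writeLines(paste("POLYGONS", nrow(tr), nrow(tr) * 4L), con)
    write.table(cbind(3L, tr - 1L), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    writeLines(c(paste("CELL_DATA", nrow(tr)),
                 "SCALARS region int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(surface@region), con)
  }
  if (length(surface@landmarks))
    jsonlite::write_json(as.list(surface@landmarks),
                         paste0(file, ".landmarks.json"), auto_unbox = TRUE)
  invisible(file)
}

#' Read a triangulated surface (ASCII PLY, OFF or legacy VTK PolyData)
#'
#' Landmarks are restored from the JSON sidecar when present; region
#' labels from VTK cell data (PLY/OFF surfaces get region 0).
#'
#' @param file input path.
#' @return a \linkS4class{VentricularSurface}.
#' @export
readSurface <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lower <- tolower(lines)
  if (length(lines) && grepl("^ply", lower[1])) {
    nv <- as.integer(sub(".*element vertex ", "",
                         lines[grep("element vertex", lower)[1]]))
    nf <- as.integer(sub(".*element face ", "",
                         lines[grep("element face", lower)[1]]))
    hEnd <- grep("end_header", lower)[1]
    v <- matrix(scan(text = lines[hEnd + seq_len(nv)], quiet = TRUE),
                nv, byrow = TRUE)[, 1:3, drop = FALSE]
    f <- matrix(scan(text = lines[hEnd + nv + seq_len(nf)], quiet = TRUE),
                nf, byrow = TRUE)
    tr <- f[, 2:4, drop = FALSE] + 1L
  } else if (length(lines) && grepl("^off", lower[1])) {
    hdr <- scan(text = lines[2], quiet = TRUE)
    nv <- hdr[1]
    nf <- hdr[2]
    v <- matrix(scan(text = lines[2 + seq_len(nv)], quiet = TRUE),
                nv, byrow = TRUE)[, 1:3, drop = FALSE]
    f <- matrix(scan(text = lines[2 + nv + seq_len(nf)], quiet = TRUE),
                nf, byrow = TRUE)
    tr <- f[, 2:4, drop = FALSE] + 1L
  } else if (any(grepl("DATASET POLYDATA", lines))) {
    ip <- grep("^POINTS", lines)[1]
    nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
    vals <- scan(text = lines[(ip + 1):length(lines)], n = 3 * nv,
                 quiet = TRUE)
    v <- matrix(vals, nv, 3, byrow = TRUE)
    it <- grep("^POLYGONS", lines)[1]
    nf <- as.integer(strsplit(lines[it], "\\s+")[[1]][2])
    fv <- scan(text = lines[(it + 1):length(lines)], n = 4 * nf,
               quiet = TRUE)
    f <- matrix(fv, nf, 4, byrow = TRUE)
    tr <- f[, 2:4, drop = FALSE] + 1L
    region <- rep(0L, nf)
    ic <- grep("^SCALARS region", lines)
    if (length(ic)) {
      region <- as.integer(scan(text = lines[(ic[1] + 2):length(lines)],
                                n = nf, quiet = TRUE))
    }
    lmk <- .readLandmarkSidecar(file, nv)
    return(new("VentricularSurface", vertices = v,
               triangles = matrix(as.integer(tr), ncol = 3),
               region = region, landmarks = lmk, meta = list()))
  } else {
    stop("unrecognized surface format: ", file)
  }
  lmk <- .readLandmarkSidecar(file, nrow(v))
  new("VentricularSurface", vertices = v,
      triangles = matrix(as.integer(tr), ncol = 3),
      region = rep(0L, nrow(tr)), landmarks = lmk, meta = list())
}

.readLandmarkSidecar <- function(file, nv) {
  side <- paste0(file, ".landmarks.json")
  if (file.exists(side)) {
    lst <- jsonlite::read_json(side, simplifyVector = TRUE)
    out <- vapply(lst, as.integer, integer(1))
    if (all(out >= 1 & out <= nv)) return(out)
  }
  stats::setNames(integer(0), character(0))
}

#' Write a volume mesh (and optional fields) as ASCII VTU
#'
#' XML UnstructuredGrid with point-data \code{label}, \code{e}, optional
#' \code{fiber} vectors and optional \code{activation_ms}.
#'
#' @param mesh a \linkS4class{VolumeMesh}.
#' @param file output path.
#' @param fibers optional \linkS4class{FiberField}.
#' @param map optional \linkS4class{ActivationMap}.
#' @export
writeVolumeMeshVTU <- function(mesh, file, fibers = NULL, map = NULL) {
  v <- mesh@vertices
  tt <- mesh@tets
  nv <- nrow(v)
  nt <- nrow(tt)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(format(x, trim = TRUE, digits = 9),
                           collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', nv,
    '" NumberOfCells="', nt, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(t(v)))
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  w(num(t(tt) - 1L))
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  w(num(seq_len(nt) * 4L))
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  w(num(rep(10L, nt)))
  w('</DataArray></Cells>')
  w('<PointData>')
  w('<DataArray type="Int32" Name="label" format="ascii">')
  w(num(mesh@label))
  w('</DataArray>')
  w('<DataArray type="Float64" Name="e" format="ascii">')
  w(num(mesh@e))
  w('</DataArray>')
  if (!is.null(fibers)) {
    w('<DataArray type="Float64" Name="fiber" NumberOfComponents="3" format="ascii">')
    w(num(t(fibers@vertexFibers)))
    w('</DataArray>')
  }
  if (!is.null(map)) {
    tms <- map@vertexTimes
    tms[!is.finite(tms)] <- -1
    w('<DataArray type="Float64" Name="activation_ms" format="ascii">')
    w(num(tms))
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}

#' Serialize a Purkinje network to JSON
#'
#' Nodes (id, xyz, role, PMJ vertex), edges (from, to, length, velocity,
#' blocked) and the left/right bundle tags.
#'
#' @param network a \linkS4class{PurkinjeNetwork}.
#' @param file output path.
#' @export
writeNetworkJSON <- function(network, file) {
  obj <- list(
    nodes = data.frame(id = seq_len(nrow(network@nodes)),
                       x = network@nodes[, 1], y = network@nodes[, 2],
                       z = network@nodes[, 3], role = network@role,
                       pmjVertex = network@pmjVertex),
    edges = network@edges,
    leftBundleEdges = network@meta$leftBundleEdges,
    rightBundleEdges = network@meta$rightBundleEdges)
  jsonlite::write_json(obj, file, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(file)
}

#' Read a Purkinje network from JSON
#'
#' @param file path written by [writeNetworkJSON()].
#' @return a \linkS4class{PurkinjeNetwork}.
#' @export
readNetworkJSON <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  nodes <- cbind(obj$nodes$x, obj$nodes$y, obj$nodes$z)
  ed <- as.data.frame(obj$edges)
  ed$blocked <- as.logical(ed$blocked)
  new("PurkinjeNetwork", nodes = nodes, edges = ed,
      role = as.character(obj$nodes$role),
      pmjVertex = as.integer(obj$nodes$pmjVertex),
      meta = list(leftBundleEdges = obj$leftBundleEdges,
                  rightBundleEdges = obj$rightBundleEdges))
}

#' Write a network as legacy VTK PolyData lines (for visualization)
#'
#' @param network a \linkS4class{PurkinjeNetwork}.
#' @param file output path.
#' @export
writeNetworkVTK <- function(network, file) {
  v <- network@nodes
  ed <- network@edges
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "purkinje network", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(v), "float")), con)
  write.table(format(v, trim = TRUE), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  writeLines(paste("LINES", nrow(ed), nrow(ed) * 3L), con)
  write.table(cbind(2L, ed$from - 1L, ed$to - 1L), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(c(paste("CELL_DATA", nrow(ed)),
               "SCALARS blocked int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(ed$blocked)), con)
  invisible(file)
}
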