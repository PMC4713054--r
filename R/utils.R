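# Internal geometry / RNG helpers.

# Evaluate expr with a local RNG stream; restores the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible child seed below 2^31.
childSeed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  x <- 0
  for (p in parts) x <- (x * 1000003 + (as.numeric(p) %% 2147483647)) %%
      2147483629
  as.integer(x %% 2147483647)
}

# Gaussian draw truncated symmetrically at +/- k sd (k shrunk to keep the
# support positive when required). Redraw-based, exact truncation.
rnormTrunc <- function(n, mean, sd, k = 3, positive = FALSE) {
  if (sd == 0) return(rep(mean, n))
  if (positive && mean - k * sd <= 0) k <- 0.95 * mean / sd
  lo <- mean - k * sd
  hi <- mean + k * sd
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    d <- stats::rnorm(length(need), mean, sd)
    ok <- d >= lo & d <= hi
    out[need[ok]] <- d[ok]
    need <- need[!ok]
  }
  out
}

# Variance of N(0, s^2) truncated at +/- k s.
truncNormVariance <- function(s2, k = 3) {
  z <- k
  frac <- 1 - 2 * z * stats::dnorm(z) / (2 * stats::pnorm(z) - 1)
  s2 * frac
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalize zero vector")
  v / n
}

rowNormalize <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n < 1e-300] <- 1
  m / n
}

crossProd3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of vector v about unit axis by angle (rad).
rotateAbout <- function(v, axis, angle) {
  axis <- normalize(axis)
  v * cos(angle) + crossProd3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

# Signed volume of tets (m x 4 indices into verts).
tetVolumes <- function(verts, tets) {
  a <- verts[tets[, 1], , drop = FALSE]
  b <- verts[tets[, 2], , drop = FALSE] - a
  c_ <- verts[tets[, 3], , drop = FALSE] - a
  d <- verts[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# Enclosed (signed) volume of a closed triangulated surface via the
# divergence theorem. Positive when triangles are oriented outward.
enclosedVolume <- function(verts, tris) {
  a <- verts[tris[, 1], , drop = FALSE]
  b <- verts[tris[, 2], , drop = FALSE]
  c_ <- verts[tris[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

triangleAreas <- function(verts, tris) {
  a <- verts[tris[, 1], , drop = FALSE]
  u <- verts[tris[, 2], , drop = FALSE] - a
  v <- verts[tris[, 3], , drop = FALSE] - a
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sqrt(nx^2 + ny^2 + nz^2) / 2
}

# Edge use counts of a triangulation; a closed 2-manifold uses every edge
# exactly twice.
edgeUseCounts <- function(tris) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

isClosedManifold <- function(tris) {
  all(edgeUseCounts(tris) == 2L)
}

# Area-weighted outward vertex normals of a triangulated surface.
vertexNormals <- function(verts, tris) {
  a <- verts[tris[, 1], , drop = FALSE]
  u <- verts[tris[, 2], , drop = FALSE] - a
  v <- verts[tris[, 3], , drop = FALSE] - a
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n <- matrix(0, nrow(verts), 3)
  for (k in 1:3) {
    idx <- tris[, k]
    n[, 1] <- n[, 1] + tapplyAdd(fn[, 1], idx, nrow(verts))
    n[, 2] <- n[, 2] + tapplyAdd(fn[, 2], idx, nrow(verts))
    n[, 3] <- n[, 3] + tapplyAdd(fn[, 3], idx, nrow(verts))
  }
  rowNormalize(n)
}

tapplyAdd <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Uniform-cell spatial index over a fixed bounding box (flat list of
# buckets, integer-indexed: no string hashing in the hot path).
flatGrid <- function(lo, hi, cell) {
  lo <- lo - 2 * cell
  hi <- hi + 2 * cell
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / cell)))
  env <- new.env(parent = emptyenv())
  env$lo <- lo
  env$cell <- cell
  env$dims <- dims
  env$buckets <- vector("list", prod(dims))
  env
}

.fgCellIdx <- function(g, p) {
  i <- pmin(pmax(floor((p - g$lo) / g$cell), 0), g$dims - 1L)
  1L + i[1] + g$dims[1] * (i[2] + g$dims[2] * i[3])
}

fgAdd <- function(g, p, id) {
  k <- .fgCellIdx(g, p)
  g$buckets[[k]] <- c(g$buckets[[k]], id)
  invisible(id)
}

# ids in the (2r+1)^3 block of cells around p (cube radius r cells)
.fgBlock <- function(g, p, r) {
  i <- pmin(pmax(floor((p - g$lo) / g$cell), 0), g$dims - 1L)
  x <- max(0, i[1] - r):min(g$dims[1] - 1L, i[1] + r)
  y <- max(0, i[2] - r):min(g$dims[2] - 1L, i[2] + r)
  z <- max(0, i[3] - r):min(g$dims[3] - 1L, i[3] + r)
  ks <- as.vector(outer(outer(1L + x, g$dims[1] * y, "+"),
                        g$dims[1] * g$dims[2] * z, "+"))
  unlist(g$buckets[ks], use.names = FALSE)
}

# Point index over a fixed point set, with nearest-neighbour queries.
makePointGrid <- function(points, cell = 3) {
  g <- flatGrid(apply(points, 2, min), apply(points, 2, max), cell)
  k <- vapply(seq_len(nrow(points)), function(r)
    .fgCellIdx(g, points[r, ]), numeric(1))
  sp <- split(seq_len(nrow(points)), k)
  for (nm in names(sp)) g$buckets[[as.integer(nm)]] <- sp[[nm]]
  g$points <- points
  g
}

gridNearest <- function(grid, p, maxRing = 6L) {
  for (ring in c(1L, 2L, maxRing)) {
    cand <- .fgBlock(grid, p, ring)
    if (length(cand)) {
      d2 <- (grid$points[cand, 1] - p[1])^2 +
        (grid$points[cand, 2] - p[2])^2 +
        (grid$points[cand, 3] - p[3])^2
      j <- which.min(d2)
      # accept if the nearest cannot be beaten by an unseen farther cell
      if (sqrt(d2[j]) <= (ring - 0) * grid$cell || ring == maxRing)
        return(list(index = cand[j], dist = sqrt(d2[j])))
    }
  }
  list(index = NA_integer_, dist = Inf)
}

# Vectorized hexahedron split (n x 8 index matrix: bottom ring columns
# 1-4, top ring 5-8, vertex 4+i above i). Fan of 6 tets around the main
# diagonal 1-7; face diagonals are consistent between neighbouring cells
# of a structured grid, so the decomposition is conformal.
hexGridToTets <- function(h) {
  rbind(cbind(h[, 1], h[, 2], h[, 3], h[, 7]),
        cbind(h[, 1], h[, 3], h[, 4], h[, 7]),
        cbind(h[, 1], h[, 4], h[, 8], h[, 7]),
        cbind(h[, 1], h[, 8], h[, 5], h[, 7]),
        cbind(h[, 1], h[, 5], h[, 6], h[, 7]),
        cbind(h[, 1], h[, 6], h[, 2], h[, 7]))
}

# Wedge/prism split (n x 6 index matrix: bottom triangle 1-3, top 4-6,
# vertex 3+i above i). Chosen so the quad-face diagonals match
# hexGridToTets across the cap/ring interface.
wedgeGridToTets <- function(w) {
  rbind(cbind(w[, 1], w[, 2], w[, 3], w[, 6]),
        cbind(w[, 1], w[, 2], w[, 6], w[, 5]),
        cbind(w[, 1], w[, 4], w[, 5], w[, 6]))
}

# Orient all tets to positive volume and drop (near-)degenerate ones.
cleanTets <- function(verts, tets, minVol = 1e-9) {
  dup <- (tets[, 1] == tets[, 2]) | (tets[, 1] == tets[, 3]) |
    (tets[, 1] == tets[, 4]) | (tets[, 2] == tets[, 3]) |
    (tets[, 2] == tets[, 4]) | (tets[, 3] == tets[, 4])
  tets <- tets[!dup, , drop = FALSE]
  vol <- tetVolumes(verts, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  keep <- abs(vol) > minVol
  tets[keep, , drop = FALSE]
}

# Lumped nodal volumes: each tet contributes a quarter of its volume to
# each of its vertices.
lumpNodalVolumes <- function(verts, tets) {
  vol <- abs(tetVolumes(verts, tets))
  nv <- nrow(verts)
  out <- numeric(nv)
  for (k in 1:4) out <- out + tapplyAdd(vol / 4, tets[, k], nv)
  out
}

# Quaternion-free rotation matrix about arbitrary unit axis.
rotationMatrix <- function(axis, angle) {
  axis <- normalize(axis)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# An orthonormal basis (u, v) of the plane orthogonal to unit n.
planeBasis <- function(n) {
  n <- normalize(n)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- normalize(crossProd3(n, ref))
  v <- crossProd3(n, u)
  list(u = u, v = v)
}
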