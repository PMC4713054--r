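# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

fixtureAtlas <- function() {
  if (is.null(.fx$atlas)) .fx$atlas <- buildSyntheticAtlas(seed = 1L)
  .fx$atlas
}

fixtureMeanSurface <- function() {
  if (is.null(.fx$meanSurf))
    .fx$meanSurf <- sampleShape(fixtureAtlas(),
                                rep(0, nrow(fixtureAtlas()@modes)))@surface
  .fx$meanSurf
}

# one mean-shape heart with fixed PMs, moderate mesh: reused across
# anatomy / purkinje / eikonal / metrics tests
fixtureHeart <- function() {
  if (is.null(.fx$heart))
    .fx$heart <- generateHeart(
      sampleShape(fixtureAtlas(), rep(0, nrow(fixtureAtlas()@modes))),
      seed = 7L, targetVertices = 15000L, pmFixed = TRUE)
  .fx$heart
}

# structured cube mesh (hex fan decomposition) as a VolumeMesh plus a
# constant fiber field along `fiber`
fixtureCubeMesh <- function(L = 40, n = 16, fiber = c(1, 0, 0)) {
  g <- expand.grid(x = 0:n, y = 0:n, z = 0:n)
  pos <- as.matrix(g) * (L / n)
  idx <- array(seq_len(nrow(g)), c(n + 1, n + 1, n + 1))
  hex <- NULL
  for (k in 1:n) {
    a <- idx[, , k]
    b <- idx[, , k + 1]
    h8 <- cbind(as.vector(a[-(n + 1), -(n + 1)]), as.vector(a[-1, -(n + 1)]),
                as.vector(a[-1, -1]), as.vector(a[-(n + 1), -1]),
                as.vector(b[-(n + 1), -(n + 1)]), as.vector(b[-1, -(n + 1)]),
                as.vector(b[-1, -1]), as.vector(b[-(n + 1), -1]))
    hex <- rbind(hex, h8)
  }
  tets <- PurkinjeFT:::hexGridToTets(hex)
  tets <- PurkinjeFT:::cleanTets(pos, tets, 1e-12)
  nv <- nrow(pos)
  mesh <- new("VolumeMesh", vertices = pos, tets = tets,
              label = rep(1L, nv), e = rep(0, nv),
              endo = rep(FALSE, nv), epi = rep(FALSE, nv),
              nodalVolume = PurkinjeFT:::lumpNodalVolumes(pos, tets),
              meta = list(parametric = FALSE))
  f <- matrix(fiber / sqrt(sum(fiber^2)), nv, 3, byrow = TRUE)
  tf <- matrix(fiber / sqrt(sum(fiber^2)), nrow(tets), 3, byrow = TRUE)
  fib <- new("FiberField", vertexFibers = f, tetFibers = tf, e = rep(0, nv))
  list(mesh = mesh, fibers = fib)
}

# closed unit cube surface
fixtureCubeSurface <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tris <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
                c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
                c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  new("VentricularSurface", vertices = v,
      triangles = matrix(as.integer(tris), ncol = 3),
      region = rep(4L, 12),
      landmarks = stats::setNames(integer(0), character(0)), meta = list())
}

# Bellman-Ford shortest-time oracle on an undirected weighted graph
bellmanFordOracle <- function(n, edges, weights, sources, sourceTimes) {
  dist <- rep(Inf, n)
  dist[sources] <- pmin(dist[sources], sourceTimes)
  for (iter in seq_len(n)) {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]; w <- weights[e]
      if (dist[a] + w < dist[b] - 1e-15) { dist[b] <- dist[a] + w; changed <- TRUE }
      if (dist[b] + w < dist[a] - 1e-15) { dist[a] <- dist[b] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  dist
}

# structured box mesh (hex fan decomposition) as a VolumeMesh with a
# constant fiber field
fixtureBoxMesh <- function(Ls, ns, fiber = c(1, 0, 0)) {
  g <- expand.grid(x = 0:ns[1], y = 0:ns[2], z = 0:ns[3])
  pos <- as.matrix(g) %*% diag(Ls / ns)
  idx <- array(seq_len(nrow(g)), ns + 1)
  hex <- NULL
  for (k in 1:ns[3]) {
    a <- idx[, , k]
    b <- idx[, , k + 1]
    h8 <- cbind(as.vector(a[-(ns[1] + 1), -(ns[2] + 1)]),
                as.vector(a[-1, -(ns[2] + 1)]),
                as.vector(a[-1, -1]), as.vector(a[-(ns[1] + 1), -1]),
                as.vector(b[-(ns[1] + 1), -(ns[2] + 1)]),
                as.vector(b[-1, -(ns[2] + 1)]),
                as.vector(b[-1, -1]), as.vector(b[-(ns[1] + 1), -1]))
    hex <- rbind(hex, h8)
  }
  tets <- PurkinjeFT:::cleanTets(pos, PurkinjeFT:::hexGridToTets(hex), 1e-12)
  nv <- nrow(pos)
  mesh <- new("VolumeMesh", vertices = pos, tets = tets,
              label = rep(1L, nv), e = rep(0, nv),
              endo = rep(FALSE, nv), epi = rep(FALSE, nv),
              nodalVolume = PurkinjeFT:::lumpNodalVolumes(pos, tets),
              meta = list(parametric = FALSE))
  f <- fiber / sqrt(sum(fiber^2))
  fib <- new("FiberField", vertexFibers = matrix(f, nv, 3, byrow = TRUE),
             tetFibers = matrix(f, nrow(tets), 3, byrow = TRUE),
             e = rep(0, nv))
  list(mesh = mesh, fibers = fib)
}

# anisotropic Dijkstra oracle on the structured box grid: edges along all
# primitive lattice offsets within Chebyshev radius `rad` (tet edges, the
# face/body diagonals and their higher-order refinements)
boxStencilOracle <- function(Ls, ns, vLong, vTrans, fiber = c(1, 0, 0),
                             rad = 3L) {
  g <- expand.grid(x = 0:ns[1], y = 0:ns[2], z = 0:ns[3])
  pos <- as.matrix(g) %*% diag(Ls / ns)
  idx <- array(seq_len(nrow(g)), ns + 1)
  offs <- as.matrix(expand.grid(dx = -rad:rad, dy = -rad:rad, dz = -rad:rad))
  keep <- rowSums(abs(offs)) > 0 &
    apply(offs, 1, function(o) {
      d <- abs(o)
      g2 <- Reduce(function(a, b) if (b == 0) a else if (a == 0) b else
        .gcd(a, b), d)
      g2 == 1
    })
  offs <- offs[keep, , drop = FALSE]
  ee <- NULL
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    xs <- max(1, 1 - o[1]):min(ns[1] + 1, ns[1] + 1 - o[1])
    ys <- max(1, 1 - o[2]):min(ns[2] + 1, ns[2] + 1 - o[2])
    zs <- max(1, 1 - o[3]):min(ns[3] + 1, ns[3] + 1 - o[3])
    a <- idx[xs, ys, zs]
    b <- idx[xs + o[1], ys + o[2], zs + o[3]]
    ee <- rbind(ee, cbind(as.vector(a), as.vector(b)))
  }
  ee <- unique(ee[ee[, 1] < ee[, 2], , drop = FALSE])
  f <- fiber / sqrt(sum(fiber^2))
  M <- diag(3) / vTrans^2 + (1 / vLong^2 - 1 / vTrans^2) * (f %o% f)
  dv <- pos[ee[, 2], ] - pos[ee[, 1], ]
  w <- sqrt(rowSums((dv %*% M) * dv))
  list(pos = pos, edges = ee, weights = w)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# acceptance-scale population shared by the acceptance test blocks
fixturePopulation <- function() {
  if (is.null(.fx$pop))
    .fx$pop <- runMainPopulation(nHearts = 10L, seed = 1L,
                                 targetVertices = 15000L)
  .fx$pop
}
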