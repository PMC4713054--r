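test_that("network shortest-time solve is exact", {
  # straight fiber, 35 mm at 3.5 mm/ms -> 10 ms at the far end
  k <- 11L
  nodes <- cbind(seq(0, 35, length.out = k), 0, 0)
  ed <- data.frame(from = 1:(k - 1), to = 2:k,
                   length = rep(3.5, k - 1), velocity = 3.5,
                   blocked = FALSE)
  net <- new("PurkinjeNetwork", nodes = nodes, edges = ed,
             role = c("HIS_ORIGIN", rep("FASCICLE", k - 2), "PMJ"),
             pmjVertex = rep(NA_integer_, k), meta = list())
  t <- solveNetwork(net, sourceSet(1L, 0))
  expect_equal(t[k], 10, tolerance = 1e-12)
  # blocking the only path makes everything downstream unreachable
  netB <- net
  netB@edges$blocked[5] <- TRUE
  tb <- solveNetwork(netB, sourceSet(1L, 0))
  expect_true(all(is.infinite(tb[6:k])))
  expect_true(all(is.finite(tb[1:5])))
  expect_error(solveNetwork(net, sourceSet(integer(0), numeric(0))))
})

test_that("network solve matches a Bellman-Ford oracle on random graphs", {
  set.seed(21)
  n <- 500L
  pos <- matrix(stats::runif(3 * n, 0, 50), n, 3)
  extra <- cbind(sample(n, 700, TRUE), sample(n, 700, TRUE))
  ring <- cbind(1:(n - 1), 2:n)
  ee <- rbind(ring, extra)
  ee <- ee[ee[, 1] != ee[, 2], ]
  len <- sqrt(rowSums((pos[ee[, 1], ] - pos[ee[, 2], ])^2))
  vel <- stats::runif(nrow(ee), 0.5, 4)
  ed <- data.frame(from = ee[, 1], to = ee[, 2], length = len,
                   velocity = vel, blocked = stats::runif(nrow(ee)) < 0.05)
  net <- new("PurkinjeNetwork", nodes = pos, edges = ed,
             role = rep("FASCICLE", n), pmjVertex = rep(NA_integer_, n),
             meta = list())
  src <- sourceSet(c(3L, 400L), c(0, 2.5))
  got <- solveNetwork(net, src)
  keep <- !ed$blocked
  want <- bellmanFordOracle(n, ee[keep, , drop = FALSE],
                            (len / vel)[keep], src$id, src$time)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("myocardial solver matches closed forms on cube and slab", {
  # isotropic medium, point source at a corner: distance / speed
  cm <- fixtureCubeMesh(L = 40, n = 16, fiber = c(1, 0, 0))
  cfg <- conductionConfig(vLongitudinal = 0.5, vTransversal = 0.5)
  d <- sqrt(rowSums(cm$mesh@vertices^2))
  ref <- d / 0.5
  # exact initialization in a small ball absorbs the point-source
  # singularity (standard factored-source practice)
  src <- which(d <= 7.5)
  phi <- solveMyocardium(cm$mesh, cm$fibers, sourceSet(src, ref[src]), cfg)
  rel <- abs(phi - ref) / pmax(ref, 1e-9)
  rel[src] <- 0
  expect_lt(max(rel), 0.03)
  # anisotropic slab, fibers +x, planar source at x = 0
  cfgA <- conductionConfig()
  srcP <- which(cm$mesh@vertices[, 1] == 0)
  phi2 <- solveMyocardium(cm$mesh, cm$fibers,
                          sourceSet(srcP, rep(0, length(srcP))), cfgA)
  v <- cm$mesh@vertices
  i1 <- which(v[, 1] == 10 & v[, 2] == 0 & v[, 3] == 0)
  expect_equal(phi2[i1], 10 / 0.8, tolerance = 0.03)
  phi3 <- solveMyocardium(cm$mesh, cm$fibers, sourceSet(1L, 0), cfgA)
  i2 <- which(v[, 1] == 0 & v[, 2] == 10 & v[, 3] == 0)
  expect_equal(phi3[i2], 10 / 0.3, tolerance = 0.03 * 10 / 0.3)
})

test_that("myocardial solver agrees with an anisotropic graph oracle", {
  # small mesh (< 2000 vertices): Dijkstra on the lattice edge+diagonal
  # graph with anisotropic edge weights; both routes share the exact
  # factored initialization around the point source, so the remaining
  # discrepancy is the metrication error of the two discretizations
  Ls <- c(30, 15, 7.5)
  ns <- c(16, 8, 4)
  bm <- fixtureBoxMesh(Ls, ns, fiber = c(1, 0, 0))
  expect_lte(nrow(bm$mesh@vertices), 2000L)
  M <- diag(c(1 / 0.8^2, 1 / 0.3^2, 1 / 0.3^2))
  tEx <- sqrt(rowSums((bm$mesh@vertices %*% M) * bm$mesh@vertices))
  src <- which(tEx <= 15) # exact times within a couple of stencil radii
  phi <- solveMyocardium(bm$mesh, bm$fibers, sourceSet(src, tEx[src]),
                         conductionConfig())
  ora <- boxStencilOracle(Ls, ns, 0.8, 0.3)
  oracle <- bellmanFordOracle(nrow(ora$pos), ora$edges, ora$weights,
                              src, tEx[src])
  sel <- setdiff(seq_along(oracle), src)
  expect_lt(max(abs(phi[sel] / oracle[sel] - 1)), 0.05)
})

test_that("grid refinement reduces the closed-form error monotonically", {
  errs <- vapply(c(6, 10, 16), function(n) {
    cm <- fixtureCubeMesh(L = 40, n = n, fiber = c(0, 0, 1))
    cfg <- conductionConfig(vLongitudinal = 0.6, vTransversal = 0.6)
    phi <- solveMyocardium(cm$mesh, cm$fibers, sourceSet(1L, 0), cfg)
    ref <- sqrt(rowSums(cm$mesh@vertices^2)) / 0.6
    max(abs(phi - ref))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("solutions are causal and homogeneous in velocity and scale", {
  cm <- fixtureCubeMesh(L = 20, n = 8, fiber = c(1, 1, 0))
  cfg <- conductionConfig()
  phi <- solveMyocardium(cm$mesh, cm$fibers, sourceSet(5L, 2), cfg)
  expect_true(all(phi >= 2 - 1e-12)) # never before the source time
  # velocities scaled by k divide conduction times by k exactly
  cfg2 <- conductionConfig(vLongitudinal = 1.6, vTransversal = 0.6)
  phi2 <- solveMyocardium(cm$mesh, cm$fibers, sourceSet(5L, 0), cfg2)
  phiH <- solveMyocardium(cm$mesh, cm$fibers, sourceSet(5L, 0),
                          conductionConfig(vLongitudinal = 0.8,
                                           vTransversal = 0.3))
  expect_equal(phi2, phiH / 2, tolerance = 1e-6)
  # geometric scaling by s multiplies times by s
  meshS <- cm$mesh
  meshS@vertices <- cm$mesh@vertices * 2
  phiS <- solveMyocardium(meshS, cm$fibers, sourceSet(5L, 0),
                          conductionConfig(vLongitudinal = 0.8,
                                           vTransversal = 0.3))
  expect_equal(phiS, phiH * 2, tolerance = 1e-6)
})

test_that("coupled solve obeys the delay contract and converges monotonely", {
  heart <- fixtureHeart()
  map <- coupledSolve(heart@mesh, heart@fibers, heart@network)
  pmj <- which(heart@network@role == "PMJ")
  # min myocardial time = min PMJ time + 6 ms exactly
  expect_equal(min(map@vertexTimes),
               min(map@nodeTimes[pmj]) + 6, tolerance = 1e-9)
  expect_true(all(is.finite(map@vertexTimes)))
  expect_true(all(map@vertexTimes >= 0))
  # a second solve with a tighter tolerance changes nothing material
  cfgT <- conductionConfig(couplingTolerance = 1e-4)
  map2 <- coupledSolve(heart@mesh, heart@fibers, heart@network, cfgT)
  expect_lt(max(abs(map2@vertexTimes - map@vertexTimes)), 0.05)
  # retrograde delay: under LBBB, every finite LV-side network node is no
  # earlier than its myocardial vertex + 1 ms would allow
  netB <- applyLbbb(heart@network)
  mapB <- coupledSolve(heart@mesh, heart@fibers, netB)
  nLv <- netB@meta$nLvNodes
  lvPmj <- pmj[pmj <= nLv]
  ok <- is.finite(mapB@nodeTimes[lvPmj])
  expect_true(any(ok)) # LV network is re-excited retrogradely
  expect_true(all(mapB@nodeTimes[lvPmj][ok] >=
                    min(mapB@vertexTimes) + 1 - 1e-9))
})
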