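test_that("papillary-muscle profile follows the cylinder+paraboloid rule", {
  L <- 33
  d <- 8.7
  expect_equal(pmParaboloidHeight(0, L, d), L)
  expect_equal(pmParaboloidHeight(d / 2, L, d), 0.6 * L)
  spec <- new("PMSpec", side = "APM", length = L, diameter = d,
              attachmentPoint = c(0, 0, 0), attachmentTriangle = 0L,
              tipAngle = 20, tipDistance = 24, paraboloidFraction = 0.4)
  pm <- buildPmSurface(spec)
  # total height base to tip
  expect_equal(diff(range(pm$vertices[, 3])), L, tolerance = 1e-9)
  # meshed volume (base capped) within 2% of the analytic value
  nO <- length(pm$baseRing)
  cap <- cbind(pm$baseRing[c(2:nO, 1)], pm$baseRing, nrow(pm$vertices) + 1)
  v2 <- rbind(pm$vertices, c(0, 0, 0))
  vol <- abs(PurkinjeFT:::enclosedVolume(v2, rbind(pm$triangles, cap)))
  expect_lt(abs(vol / pmAnalyticVolume(spec) - 1), 0.02)
  expect_error(buildPmSurface(new("PMSpec", side = "APM", length = 5,
                                  diameter = 4.9, attachmentPoint = c(0, 0, 0),
                                  attachmentTriangle = 0L, tipAngle = 10,
                                  tipDistance = 10,
                                  paraboloidFraction = 0.4)), NA)
})

test_that("PM statistics reproduce the printed normalized values", {
  set.seed(1)
  a <- samplePmSpec(98, "APM", fixed = TRUE)
  expect_equal(a@length, 33.6 / 100 * 98, tolerance = 1e-12)
  expect_equal(a@diameter, 8.9 / 100 * 98, tolerance = 1e-12)
  p <- samplePmSpec(98, "PPM", fixed = TRUE)
  expect_equal(p@diameter, 8.3 / 100 * 98, tolerance = 1e-12)
  expect_equal(p@length, 27.6 / 100 * 98, tolerance = 1e-12)
  # sample mean of the normalized APM length over many draws
  set.seed(2)
  lens <- vapply(seq_len(10000),
                 function(i) samplePmSpec(98, "APM")@length / 98 * 100,
                 numeric(1))
  expect_lt(abs(mean(lens) / 33.6 - 1), 0.02)
  expect_true(all(lens > 0))
  expect_error(samplePmSpec(-1, "APM"), "positive")
})

test_that("merging a PM keeps the surface watertight and removes the right volume", {
  surf <- fixtureMeanSurface()
  set.seed(3)
  specA <- samplePmSpec(98, "APM", fixed = TRUE)
  specP <- samplePmSpec(98, "PPM", fixed = TRUE)
  cv0 <- lvCavityVolume(surf)
  s1 <- attachPm(surf, specA)
  s2 <- attachPm(s1, specP)
  ec <- PurkinjeFT:::edgeUseCounts(s2@triangles)
  expect_true(all(ec %% 2 == 0)) # watertight
  drop <- cv0 - lvCavityVolume(s2)
  expected <- pmAnalyticVolume(specA) + pmAnalyticVolume(specP)
  expect_lt(abs(drop / expected - 1), 0.05)
  # tip azimuth offset about the LV axis matches the PMSpec value
  rec <- s2@meta$pmSpecs[[1]]
  axis <- PurkinjeFT:::.lvAxis(s2)
  a0 <- PurkinjeFT:::.axisCoords(rec$attachmentPoint, axis)
  at <- PurkinjeFT:::.axisCoords(rec$tip, axis)
  dAz <- abs(PurkinjeFT:::.wrapAngle(at[1, "az"] - a0[1, "az"])) * 180 / pi
  expect_lt(abs(dAz - specA@tipAngle), 1)
  # PM length preserved, tip distance honoured softly (within 10%)
  expect_equal(sqrt(sum((rec$tip - rec$attachmentPoint)^2)), specA@length,
               tolerance = 1e-9)
  expect_lt(abs(at[1, "r"] / specA@tipDistance - 1), 0.10)
  # a absurd spec is rejected as a placement error
  bad <- new("PMSpec", side = "APM", length = 60, diameter = 8,
             attachmentPoint = c(0, 0, 0), attachmentTriangle = 0L,
             tipAngle = 5, tipDistance = 80, paraboloidFraction = 0.4)
  expect_error(attachPm(surf, bad), "placement")
})

test_that("tetrahedralization conserves volume and hits the size target", {
  # generic star-shaped path: the unit cube is meshed exactly
  cube <- fixtureCubeSurface()
  cm <- tetrahedralize(cube, 500)
  expect_equal(sum(abs(PurkinjeFT:::tetVolumes(cm@vertices, cm@tets))), 1,
               tolerance = 1e-6)
  expect_true(all(PurkinjeFT:::tetVolumes(cm@vertices, cm@tets) > 0))
  # parametric path: wall volume within 1% of the surface-enclosed volume
  heart <- fixtureHeart()
  mesh <- heart@mesh
  expect_true(all(PurkinjeFT:::tetVolumes(mesh@vertices, mesh@tets) > 0))
  vS <- PurkinjeFT:::enclosedVolume(heart@surface@vertices,
                                    heart@surface@triangles)
  vT <- sum(abs(PurkinjeFT:::tetVolumes(mesh@vertices, mesh@tets)))
  expect_lt(abs(vT / vS - 1), 0.01)
  # every vertex labelled exactly once, flags consistent
  expect_true(all(mesh@label %in% 1:5))
  expect_identical(length(mesh@e), nrow(mesh@vertices))
  # default density target (~70000 within +/- 20%)
  m70 <- tetrahedralize(fixtureMeanSurface())
  expect_gte(nrow(m70@vertices), 56000L)
  expect_lte(nrow(m70@vertices), 84000L)
})

test_that("fiber field follows the linear Streeter rule", {
  heart <- fixtureHeart()
  mesh <- heart@mesh
  fib <- heart@fibers
  expect_lt(max(abs(sqrt(rowSums(fib@vertexFibers^2)) - 1)), 1e-9)
  # helix angle is linear in e: recompute the angle per LV vertex from the
  # local circumferential/longitudinal frame and regress on e
  d <- mesh@meta$dims
  lvIdx <- mesh@meta$lvIdx
  set.seed(4)
  ks <- sample(0:d$ne, 200, replace = TRUE)
  is <- sample(seq_len(d$nTheta), 200, replace = TRUE)
  js <- sample(2:(d$nPhi - 1), 200, replace = TRUE)
  ang <- numeric(200)
  ee <- numeric(200)
  ip1 <- c(2:d$nTheta, 1L)
  im1 <- c(d$nTheta, 1:(d$nTheta - 1L))
  for (r in 1:200) {
    v <- lvIdx[is[r], js[r], ks[r] + 1L]
    ec <- PurkinjeFT:::normalize(mesh@vertices[lvIdx[ip1[is[r]], js[r], ks[r] + 1L], ] -
                                 mesh@vertices[lvIdx[im1[is[r]], js[r], ks[r] + 1L], ])
    el <- PurkinjeFT:::normalize(mesh@vertices[lvIdx[is[r], js[r] + 1L, ks[r] + 1L], ] -
                                 mesh@vertices[lvIdx[is[r], js[r] - 1L, ks[r] + 1L], ])
    nrm <- PurkinjeFT:::normalize(PurkinjeFT:::crossProd3(ec, el))
    el2 <- PurkinjeFT:::crossProd3(nrm, ec)
    f <- fib@vertexFibers[v, ]
    ang[r] <- atan2(sum(f * el2), sum(f * ec)) * 180 / pi
    ee[r] <- mesh@e[v]
  }
  fit <- stats::lm(ang ~ ee)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999)
  expect_equal(unname(stats::coef(fit)), c(60, -120), tolerance = 0.02)
  # e = 0.5 -> exactly the mid helix angle through the linear rule
  expect_equal(stats::predict(fit, data.frame(ee = 0.5))[[1]],
               (60 - 60) / 2, tolerance = 1)
  # PM fibers along the PM axis
  for (pm in mesh@meta$pm) {
    dev <- fib@vertexFibers[pm$vertexIds, , drop = FALSE] -
      matrix(pm$axisDir, length(pm$vertexIds), 3, byrow = TRUE)
    expect_lt(max(abs(dev)), 1e-6)
  }
  # per-tet vectors are normalized sign-aligned means
  expect_lt(max(abs(sqrt(rowSums(fib@tetFibers^2)) - 1)), 1e-9)
})

test_that("fiber field is equivariant under rigid rotation", {
  heart <- fixtureHeart()
  mesh <- heart@mesh
  R <- PurkinjeFT:::rotationMatrix(c(1, 2, 3), 0.7)
  mesh2 <- mesh
  mesh2@vertices <- mesh@vertices %*% t(R)
  # a rigid rotation of the mesh rotates its geometric metadata too
  for (nm in names(mesh2@meta$pm))
    mesh2@meta$pm[[nm]]$axisDir <- as.numeric(R %*%
                                                mesh2@meta$pm[[nm]]$axisDir)
  fib <- heart@fibers
  fib2 <- assignFibers(mesh2)
  rotated <- fib@vertexFibers %*% t(R)
  angErr <- acos(pmin(1, abs(rowSums(rotated * fib2@vertexFibers))))
  expect_lt(max(angErr), 1e-6)
})
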