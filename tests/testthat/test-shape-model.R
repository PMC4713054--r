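test_that("synthetic atlas satisfies the shape-model invariants", {
  m <- fixtureAtlas()
  G <- m@modes %*% t(m@modes)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-9)
  expect_true(all(m@eigenvalues > 0))
  expect_false(is.unsorted(rev(m@eigenvalues)))
  expect_identical(nrow(m@modes), 10L)
  surf <- fixtureMeanSurface()
  expect_equal(lvLength(surf), 98.0, tolerance = 1 / 98)
  # closed (watertight) triangulation, 2-manifold within each region
  ec <- PurkinjeFT:::edgeUseCounts(surf@triangles)
  expect_true(all(ec %% 2 == 0))
  # LV endo, epicardium and basal caps are strict 2-manifolds; the RV
  # endocardium carries a short pinch seam where the free wall meets the
  # septal face (the wall thickness vanishes there by construction)
  for (r in c(1, 3, 4)) {
    sub <- surf@triangles[surf@region == r, , drop = FALSE]
    expect_lte(max(PurkinjeFT:::edgeUseCounts(sub)), 2L)
  }
  ecRV <- PurkinjeFT:::edgeUseCounts(
    surf@triangles[surf@region == 2, , drop = FALSE])
  expect_lte(max(ecRV), 4L)
  expect_lt(sum(ecRV > 2) / length(ecRV), 0.02)
  expect_gt(PurkinjeFT:::enclosedVolume(surf@vertices, surf@triangles), 0)
})

test_that("atlas construction is deterministic", {
  m1 <- buildSyntheticAtlas(seed = 3L)
  m2 <- buildSyntheticAtlas(seed = 3L)
  expect_identical(m1@meanShape, m2@meanShape)
  expect_identical(m1@modes, m2@modes)
  expect_error(buildSyntheticAtlas(config = list(wall = -1)),
               "positive")
})

test_that("shape sampling follows x = xbar + P'b with bound checking", {
  m <- fixtureAtlas()
  s0 <- sampleShape(m, rep(0, 10))
  expect_equal(as.numeric(t(s0@surface@vertices)), m@meanShape)
  # full-bound mode-1 sample: max per-vertex displacement equals
  # 3 sqrt(lambda_1) times the largest per-point mode norm (brute force)
  b <- rep(0, 10)
  b[1] <- 3 * sqrt(m@eigenvalues[1])
  s1 <- sampleShape(m, b)
  disp <- s1@surface@vertices - s0@surface@vertices
  n <- length(m@meanShape) / 3
  bruteMax <- 0
  for (i in seq_len(n)) { # independent per-vertex evaluation of the mode
    mi <- m@modes[1, (3 * i - 2):(3 * i)]
    bruteMax <- max(bruteMax, b[1] * sqrt(sum(mi^2)))
  }
  expect_equal(max(sqrt(rowSums(disp^2))), bruteMax, tolerance = 1e-9)
  # out-of-bounds weight
  b[1] <- 4 * sqrt(m@eigenvalues[1])
  expect_error(sampleShape(m, b), "bounds")
  # linearity of the reconstruction
  b1 <- seq(0.1, 1, length.out = 10) * sqrt(m@eigenvalues)
  b2 <- -rev(b1)
  d12 <- sampleShape(m, b1 + b2)@surface@vertices - s0@surface@vertices
  d1 <- sampleShape(m, b1)@surface@vertices - s0@surface@vertices
  d2 <- sampleShape(m, b2)@surface@vertices - s0@surface@vertices
  expect_lt(max(abs(d12 - (d1 + d2))), 1e-9)
})

test_that("random populations respect bounds and the sampling variance", {
  m <- fixtureAtlas()
  pop <- randomPopulation(m, 70, seed = 5L)
  expect_length(pop, 70L)
  bound <- 3 * sqrt(m@eigenvalues)
  for (s in pop) expect_true(all(abs(s@weights) <= bound + 1e-9))
  # reproducibility
  pop2 <- randomPopulation(m, 3, seed = 9L)
  pop3 <- randomPopulation(m, 3, seed = 9L)
  expect_identical(pop2[[2]]@weights, pop3[[2]]@weights)
  # Monte-Carlo variance against the closed-form truncated-normal variance
  big <- randomPopulation(m, 1000, seed = 12L)
  W <- do.call(rbind, lapply(big, shapeWeights))
  expected <- PurkinjeFT:::truncNormVariance(m@eigenvalues, k = 3)
  for (k in c(1, 4, 10)) {
    expect_lt(abs(stats::var(W[, k]) / expected[k] - 1), 0.15)
  }
  # population LV length is symmetric about the mean within sampling error
  lens <- vapply(big[1:300], lvLength, numeric(1))
  expect_lt(abs(mean(lens) - 98) / stats::sd(lens) * sqrt(300), 3.5)
})

test_that("degenerate variances collapse samples onto the mean shape", {
  m <- fixtureAtlas()
  m@eigenvalues <- rep(1e-12, 10)
  s <- randomPopulation(m, 1, seed = 2L)[[1]]
  expect_lt(max(abs(s@surface@vertices - fixtureMeanSurface()@vertices)),
            1e-4)
})

test_that("rescaling to a target LV length is an exact similarity", {
  surf <- fixtureMeanSurface()
  same <- scaleToLvLength(surf, lvLength(surf))
  expect_lt(max(abs(same@vertices - surf@vertices)), 1e-9)
  s80 <- scaleToLvLength(surf, 80)
  expect_equal(lvLength(s80), 80, tolerance = 1e-8)
  # all pairwise distances scale by 80/98
  idx <- seq(1, nrow(surf@vertices), length.out = 40)
  d0 <- stats::dist(surf@vertices[idx, ])
  d1 <- stats::dist(s80@vertices[idx, ])
  expect_equal(as.numeric(d1 / d0), rep(80 / lvLength(surf), length(d0)),
               tolerance = 1e-6)
  for (L in c(70, 90))
    expect_equal(lvLength(scaleToLvLength(surf, L)), L, tolerance = 1e-6)
  expect_error(scaleToLvLength(surf, -5), "positive")
})
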