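.mkMap <- function(vertexTimes, nodeTimes = numeric(0)) {
  new("ActivationMap", vertexTimes = vertexTimes, nodeTimes = nodeTimes)
}

test_that("QRS duration is last minus first myocardial activation", {
  expect_equal(qrsDuration(.mkMap(rep(42, 10))), 0)
  t <- stats::runif(50, 23, 120)
  t[c(3, 40)] <- c(23, 120)
  expect_equal(qrsDuration(.mkMap(t)), 97)
  expect_error(qrsDuration(.mkMap(c(1, 2, Inf))), "incomplete")
  # network times are ignored entirely
  m1 <- .mkMap(t, nodeTimes = stats::runif(5))
  m2 <- .mkMap(t, nodeTimes = stats::runif(5) + 500)
  expect_identical(qrsDuration(m1), qrsDuration(m2))
})

test_that("LV/RV split partitions the mesh through the mid-septal plane", {
  heart <- fixtureHeart()
  mesh <- heart@mesh
  sides <- splitLvRv(mesh)
  expect_identical(length(sides), nrow(mesh@vertices))
  expect_setequal(unique(sides), c("LV", "RV"))
  lmk <- mesh@meta$landmarks
  expect_identical(sides[lmk$lvApexVertex], "LV")
  expect_identical(sides[lmk$rvApexVertex], "RV")
  # PM vertices always belong to the LV
  expect_true(all(sides[mesh@label %in% c(4L, 5L)] == "LV"))
})

test_that("reflecting a symmetric mesh across the plane swaps the sides", {
  # idealized symmetric slab: septum at x in [-1, 1], walls on both sides
  set.seed(6)
  g <- as.matrix(expand.grid(x = seq(-5, 5, 1), y = seq(0, 4, 1),
                             z = seq(0, 4, 1)))
  n <- nrow(g)
  label <- ifelse(abs(g[, 1]) <= 1, 3L, ifelse(g[, 1] < 0, 1L, 2L))
  idx <- array(seq_len(n), c(11, 5, 5))
  hex <- NULL
  for (k in 1:4) for (j in 1:4) for (i in 1:10) {
    hex <- rbind(hex, c(idx[i, j, k], idx[i + 1, j, k], idx[i + 1, j + 1, k],
                        idx[i, j + 1, k], idx[i, j, k + 1], idx[i + 1, j, k + 1],
                        idx[i + 1, j + 1, k + 1], idx[i, j + 1, k + 1]))
  }
  tets <- PurkinjeFT:::cleanTets(g, PurkinjeFT:::hexGridToTets(hex), 1e-12)
  mesh <- new("VolumeMesh", vertices = g, tets = tets, label = label,
              e = rep(0.5, n), endo = rep(FALSE, n), epi = rep(FALSE, n),
              nodalVolume = rep(1, n), meta = list(parametric = FALSE))
  sides <- splitLvRv(mesh)
  meshR <- mesh
  meshR@vertices[, 1] <- -meshR@vertices[, 1]
  meshR@label <- ifelse(label == 1L, 2L, ifelse(label == 2L, 1L, 3L))
  sidesR <- splitLvRv(meshR)
  swap <- ifelse(sides == "LV", "RV", "LV")
  offPlane <- abs(g[, 1]) > 1e-9 # vertices on the plane itself may tie
  expect_identical(sidesR[offPlane], swap[offPlane])
})

test_that("synchrony metrics reduce to their defining arithmetic", {
  sides <- rep(c("LV", "RV"), each = 4)
  t <- c(23, 50, 80, 120, 26, 40, 60, 99)
  s <- synchronyMetrics(.mkMap(t), sides)
  expect_equal(s@firstLV, 23)
  expect_equal(s@firstRV, 26)
  expect_equal(s@totalLV, 97)
  expect_equal(s@totalRV, 73)
  expect_equal(s@qrsD, 120 - 23)
  expect_equal(s@dyssynchrony, 21)
  # symmetric map has zero dyssynchrony
  s2 <- synchronyMetrics(.mkMap(c(1, 5, 9, 1, 5, 9)),
                         rep(c("LV", "RV"), each = 3))
  expect_equal(s2@dyssynchrony, 0)
})

test_that("cumulative activation is a volume-weighted monotone CDF", {
  mesh <- new("VolumeMesh", vertices = matrix(0, 4, 3),
              tets = matrix(1:4, 1), label = rep(1L, 4), e = rep(0, 4),
              endo = rep(FALSE, 4), epi = rep(FALSE, 4),
              nodalVolume = rep(2, 4), meta = list())
  cst <- cumulativeActivation(.mkMap(rep(7, 4)), mesh)
  expect_equal(cst$percent[cst$time >= 7], 100)
  # uniform times on equal volumes: linear CDF within discretization
  n <- 101
  mesh2 <- new("VolumeMesh", vertices = matrix(0, n, 3),
               tets = matrix(1:4, 1), label = rep(1L, n), e = rep(0, n),
               endo = rep(FALSE, n), epi = rep(FALSE, n),
               nodalVolume = rep(1, n), meta = list())
  tu <- seq(0, 100, length.out = n)
  cu <- cumulativeActivation(.mkMap(tu), mesh2)
  expect_lt(max(abs(cu$percent - cu$time)), 1.5)
  expect_true(all(diff(cu$percent) >= 0))
  expect_equal(max(cu$percent), 100)
})

test_that("population statistics use a strict threshold and decade bins", {
  s <- populationStats(c(119, 121))
  expect_equal(s$pctAbove, 50)
  expect_equal(populationStats(rep(120, 8))$pctAbove, 0)
  h <- populationStats(c(5, 15, 15, 25))$decades
  expect_identical(as.integer(h), c(1L, 2L, 1L))
  expect_equal(sum(populationStats(stats::rnorm(70, 130, 10))$decades), 70)
})

test_that("two-sample KS matches a brute-force ECDF supremum", {
  eq <- ksTwoSample(1:50, 1:50)
  expect_equal(eq$D, 0)
  expect_equal(eq$p, 1)
  expect_equal(ksTwoSample(1:100, 101:200)$D, 1)
  a <- c(1, 2, 3)
  b <- c(1.5, 2.5, 3.5)
  got <- ksTwoSample(a, b)
  grid <- sort(c(a, b))
  brute <- max(vapply(grid, function(x)
    abs(mean(a <= x) - mean(b <= x)), numeric(1)))
  expect_equal(got$D, brute)
  expect_equal(got$D, 1 / 3)
})

test_that("IQR uses linear-interpolation quantiles", {
  expect_equal(iqrRange(1:5), 2)
  expect_equal(iqrRange(rep(3, 10)), 0)
  x <- stats::rexp(40)
  expect_equal(iqrRange(7 * x), 7 * iqrRange(x), tolerance = 1e-12)
})
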