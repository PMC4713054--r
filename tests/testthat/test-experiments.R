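test_that("per-heart configuration matrix has the designed shape", {
  pop <- runMainPopulation(nHearts = 1L, seed = 6L, targetVertices = 8000L)
  tab <- pop@table
  expect_identical(nrow(tab), 8L) # 1 heart x 8 configurations
  expect_setequal(tab$config,
                  c("Healthy", "LBBB", "APM-Direct", "APM-Delta",
                    "PPM-Direct", "PPM-Delta", "VFW-Direct", "VFW-Delta"))
  # QRS_Diff exists exactly on the six FT rows and references the matched
  # LBBB run of the same heart
  expect_identical(sum(!is.na(tab$qrsDiff)), 6L)
  ref <- tab$qrsD[tab$config == "LBBB"]
  for (cf in c("APM-Direct", "VFW-Delta")) {
    expect_equal(tab$qrsDiff[tab$config == cf],
                 ref - tab$qrsD[tab$config == cf])
  }
})

test_that("experiment drivers are deterministic for a fixed master seed", {
  p1 <- runMainPopulation(nHearts = 1L, seed = 17L, targetVertices = 8000L)
  p2 <- runMainPopulation(nHearts = 1L, seed = 17L, targetVertices = 8000L)
  expect_equal(p1@table$qrsD, p2@table$qrsD, tolerance = 1e-12)
  s1 <- runPkSensitivity(nNetworks = 2L, seed = 5L, targetVertices = 8000L)
  s2 <- runPkSensitivity(nNetworks = 2L, seed = 5L, targetVertices = 8000L)
  expect_identical(s1$table, s2$table)
  expect_identical(nrow(s1$table), 2L)
  expect_true(all(is.finite(s1$table$qrsD)))
})

test_that("size/shape/location sub-studies honour their design matrices", {
  res <- runP1P2P3(which = "P1", seed = 3L, nShapes = 1L,
                   sizes = c(80, 84), targetVertices = 8000L)
  tabP1 <- res$P1@table
  expect_identical(nrow(tabP1), 2L * 8L) # 1 shape x 2 sizes x 8 configs
  expect_setequal(round(unique(tabP1$lvLength)), c(80, 84))
  expect_identical(sum(!is.na(tabP1$qrsDiff)), 12L)

  res3 <- runP1P2P3(which = "P3", seed = 3L, nShapes = 1L,
                    nVfwPoints = 2L, fixedLength = 80,
                    targetVertices = 8000L)
  tabP3 <- res3$P3@table
  # healthy + LBBB + 2 locations x 2 terminations
  expect_identical(nrow(tabP3), 6L)
  expect_identical(sum(!is.na(tabP3$qrsDiff)), 4L)

  res2 <- runP1P2P3(which = "P2", seed = 3L, nHearts = 2L,
                    fixedLength = 80, targetVertices = 8000L)
  tabP2 <- res2$P2@table
  expect_identical(nrow(tabP2), 16L)
  expect_lt(max(abs(tabP2$lvLength - 80)), 1e-6)
})
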