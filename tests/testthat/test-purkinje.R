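test_that("degenerate growth yields exactly the stage-1 skeleton", {
  heart <- fixtureHeart()
  p <- growthParams("LV")
  p$stage2$maxBranches <- 0L
  p$stage3$maxBranches <- 0L
  lv <- growLvNetwork(heart@mesh, p, seed = 1L)
  # one trifurcation node: a single node of degree >= 3 on the fascicle
  # tree; three fascicles leave it
  deg <- tabulate(c(lv@edges$from, lv@edges$to), nbins = nrow(lv@nodes))
  branchNodes <- which(deg >= 3 & lv@role %in% c("BUNDLE", "FASCICLE"))
  expect_length(branchNodes, 1L)
  expect_identical(sum(deg == 1 & lv@role == "FASCICLE"), 3L)
  expect_identical(sum(lv@role == "PMJ"), 0L)

  pr <- growthParams("RV")
  pr$stage2$maxBranches <- 0L
  pr$stage3$maxBranches <- 0L
  rv <- growRvNetwork(heart@mesh, pr, seed = 1L)
  degR <- tabulate(c(rv@edges$from, rv@edges$to), nbins = nrow(rv@nodes))
  expect_identical(sum(degR == 1 & rv@role == "FASCICLE"), 2L)
})

test_that("branch draws reproduce the per-stage growth statistics", {
  heart <- fixtureHeart()
  lv2len <- lv2ang <- rv2len <- rv2ang <- lv3len <- numeric(0)
  for (s in 1:4) { # pool several networks for >= 1000 branches per stage
    lv <- growLvNetwork(heart@mesh, seed = 100L + s)
    rv <- growRvNetwork(heart@mesh, seed = 200L + s)
    lv2len <- c(lv2len, lv@meta$branchStats$stage2$len)
    lv2ang <- c(lv2ang, lv@meta$branchStats$stage2$ang)
    lv3len <- c(lv3len, lv@meta$branchStats$stage3$len)
    rv2len <- c(rv2len, rv@meta$branchStats$stage2$len)
    rv2ang <- c(rv2ang, rv@meta$branchStats$stage2$ang)
  }
  expect_gte(length(lv2len), 1000L)
  expect_gte(length(rv2len), 1000L)
  # LV second stage: 6 +/- 0.3 mm, 60 +/- 40 deg
  expect_gte(mean(lv2len), 5.9)
  expect_lte(mean(lv2len), 6.1)
  expect_lt(abs(stats::sd(lv2len) / 0.3 - 1), 0.05)
  expect_lt(abs(mean(lv2ang) / 60 - 1), 0.05)
  expect_lt(abs(stats::sd(lv2ang) / 40 - 1), 0.05)
  # RV second stage: 4 +/- 0.3 mm, 60 +/- 20 deg
  expect_lt(abs(mean(rv2len) / 4 - 1), 0.05)
  expect_gte(mean(rv2ang), 58)
  expect_lte(mean(rv2ang), 62)
  expect_lt(abs(stats::sd(rv2ang) / 20 - 1), 0.05)
  # LV third stage: 1 +/- 0.03 mm, at most 600 branches per network
  expect_lt(abs(mean(lv3len) / 1 - 1), 0.05)
  expect_lte(length(lv3len) / 4, 600)
})

test_that("full networks satisfy the structural invariants", {
  heart <- fixtureHeart()
  net <- heart@network
  mesh <- heart@mesh
  # determinism
  net2 <- growBiventricularNetwork(mesh, seed = heart@meta$seed)
  expect_identical(net@nodes, net2@nodes)
  expect_identical(net@edges, net2@edges)
  # edge lengths equal Euclidean node distances (validity already enforces
  # 1e-9; re-check directly)
  len <- sqrt(rowSums((net@nodes[net@edges$from, ] -
                       net@nodes[net@edges$to, ])^2))
  expect_lt(max(abs(len - net@edges$length)), 1e-9)
  # connected from the His origin
  g <- igraph::graph_from_edgelist(as.matrix(net@edges[, c("from", "to")]),
                                   directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(comp$no, 1)
  # every PMJ maps to a valid mesh vertex
  pmj <- which(net@role == "PMJ")
  expect_true(all(!is.na(net@pmjVertex[pmj])))
  expect_true(all(mesh@endo[net@pmjVertex[pmj]]))
  # PMJ budget: stage-2 + stage-3 terminals bounded by the branch budgets
  expect_lte(sum(net@role == "PMJ"),
             300 + 600 + 800 + 1000 + 5)
  # nodes lie on (or near) the endocardial/PM surface: within the surface
  # sampling distance of an endocardial vertex
  endoIds <- which(mesh@endo)
  grid <- PurkinjeFT:::makePointGrid(mesh@vertices[endoIds, ], cell = 5)
  notFT <- which(net@role != "FT_NODE")
  set.seed(8)
  sel <- sample(notFT, 400)
  dd <- vapply(sel, function(i)
    PurkinjeFT:::gridNearest(grid, net@nodes[i, ])$dist, numeric(1))
  h <- 2 * pi * 30 / mesh@meta$dims$nTheta # in-plane sampling distance
  expect_lt(max(dd), 1 + h)
  # stage-3 subgraph is acyclic; stage-2 subgraph may carry loops
  stage <- net@meta$stage
  e3 <- net@edges[stage[net@edges$from] == 3L | stage[net@edges$to] == 3L, ]
  g3 <- igraph::graph_from_edgelist(as.matrix(e3[, c("from", "to")]),
                                    directed = FALSE)
  expect_false(igraph::girth(g3)$girth > 0 &&
                 is.finite(igraph::girth(g3)$girth))
})

test_that("network merge keeps counts and bundle tags", {
  heart <- fixtureHeart()
  mesh <- heart@mesh
  lv <- growLvNetwork(mesh, seed = 31L)
  rv <- growRvNetwork(mesh, seed = 32L)
  net <- mergeNetworks(lv, rv)
  expect_identical(nrow(net@nodes), nrow(lv@nodes) + nrow(rv@nodes) - 1L)
  g <- igraph::graph_from_edgelist(as.matrix(net@edges[, c("from", "to")]),
                                   directed = FALSE)
  his <- which(net@role == "HIS_ORIGIN")
  expect_length(his, 1L)
  expect_equal(igraph::components(g)$no, 1)
  # left-bundle tag equals the LV stage-1 proximal path: graph traversal
  # oracle from His along BUNDLE nodes
  lbe <- net@meta$leftBundleEdges
  expect_true(all(net@role[net@edges$to[lbe]] == "BUNDLE"))
  bundleNodes <- unique(c(net@edges$from[lbe], net@edges$to[lbe]))
  reach <- igraph::subcomponent(
    igraph::subgraph_from_edges(g, lbe, delete.vertices = FALSE), his)
  expect_setequal(sort(as.integer(reach)), sort(bundleNodes))
})

test_that("complete LBBB blocks all antegrade LV conduction and is reversible", {
  heart <- fixtureHeart()
  net <- heart@network
  netB <- applyLbbb(net)
  expect_identical(sum(netB@edges$blocked), 1L)
  # reachability through the network alone (blocked edge removed)
  ed <- netB@edges[!netB@edges$blocked, ]
  g <- igraph::graph_from_edgelist(as.matrix(ed[, c("from", "to")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < nrow(netB@nodes))
    g <- igraph::add_vertices(g, nrow(netB@nodes) - igraph::vcount(g))
  his <- which(netB@role == "HIS_ORIGIN")
  reach <- as.integer(igraph::subcomponent(g, his))
  pmj <- which(netB@role == "PMJ")
  nLv <- netB@meta$nLvNodes
  lvPmj <- pmj[pmj <= nLv]
  rvPmj <- pmj[pmj > nLv]
  expect_identical(length(intersect(lvPmj, reach)), 0L)
  expect_gt(length(intersect(rvPmj, reach)), 0.9 * length(rvPmj))
  # removing the block restores reachability of all LV PMJs
  netC <- clearBlock(netB)
  g2 <- igraph::graph_from_edgelist(
    as.matrix(netC@edges[, c("from", "to")]), directed = FALSE)
  reach2 <- as.integer(igraph::subcomponent(g2, his))
  expect_true(all(lvPmj %in% reach2))
  expect_identical(netC@edges$blocked, rep(FALSE, nrow(netC@edges)))
})
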