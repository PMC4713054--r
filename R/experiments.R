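# Experiment drivers: single-heart assembly, the Purkinje-topology
# sensitivity study, the main virtual-population study (healthy / LBBB /
# six FT configurations per heart) and the size/shape/FT-location
# sub-populations.

#' Population result container
#'
#' @slot table data.frame, one row per heart x configuration.
#' @slot summary list of per-configuration summary statistics.
#' @slot meta list (seeds, scale, failures).
#' @export
setClass("PopulationResult", representation(
  table = "data.frame", summary = "list", meta = "list"))

setMethod("show", "PopulationResult", function(object) {
  cat("PopulationResult:", nrow(object@table), "simulation rows,",
      length(unique(object@table$heart)), "hearts\n")
  if (nrow(object@table)) {
    agg <- stats::aggregate(qrsD ~ config, object@table, function(x)
      sprintf("%.1f +/- %.1f", mean(x), stats::sd(x)))
    print(agg, row.names = FALSE)
  }
})

#' Assemble one simulation-ready heart
#'
#' Draws papillary-muscle parameters, merges the PMs into the sampled
#' surface, builds the labelled tetrahedral mesh and fiber field, and
#' grows the merged biventricular Purkinje network.
#'
#' @param sample a \linkS4class{ShapeSample} from [sampleShape()] or
#'   [randomPopulation()].
#' @param seed integer master seed for this heart (PM draws and network
#'   growth derive child seeds from it).
#' @param targetVertices tet-mesh size target.
#' @param scaleTo optional LV length (mm) to rescale to before meshing.
#' @param pmFixed if TRUE use population-mean PM parameters.
#' @return a \linkS4class{SimHeart}.
#' @export
generateHeart <- function(sample, seed = 1L, targetVertices = 70000L,
                          scaleTo = NULL, pmFixed = FALSE) {
  surf <- sample@surface
  if (!is.null(scaleTo)) surf <- scaleToLvLength(surf, scaleTo)
  lvLen <- lvLength(surf)
  surf <- withSeed(childSeed(seed, 11L), {
    s1 <- .attachPmRobust(surf, lvLen, "APM", pmFixed)
    .attachPmRobust(s1, lvLen, "PPM", pmFixed)
  })
  mesh <- tetrahedralize(surf, targetVertices)
  fibers <- assignFibers(mesh)
  network <- growBiventricularNetwork(mesh, seed = seed)
  new("SimHeart", surface = surf, mesh = mesh, fibers = fibers,
      network = network,
      meta = list(seed = seed, weights = sample@weights,
                  targetVertices = targetVertices, lvLength = lvLength(surf)))
}

# attach a PM, redrawing its parameters when a placement is geometrically
# infeasible on this shape (tip would cross the opposite wall)
.attachPmRobust <- function(surf, lvLen, side, pmFixed, maxTries = 25L) {
  for (k in seq_len(maxTries)) {
    spec <- samplePmSpec(lvLen, side, fixed = pmFixed && k == 1L)
    relax <- if (k <= 5L) 0.1 else 0.45 # pathological shapes: pull the
    out <- tryCatch(attachPm(surf, spec, # tip inward rather than fail
                             tipDistanceRelax = relax),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
  }
  stop("could not place ", side, " after ", maxTries, " redraws")
}

#' Grow and merge both ventricular networks
#'
#' @param mesh a parametric \linkS4class{VolumeMesh}.
#' @param seed master seed (LV and RV use derived child seeds).
#' @param lvParams,rvParams growth parameter overrides.
#' @return a merged \linkS4class{PurkinjeNetwork}.
#' @export
growBiventricularNetwork <- function(mesh, seed = 1L,
                                     lvParams = growthParams("LV"),
                                     rvParams = growthParams("RV")) {
  lv <- growLvNetwork(mesh, lvParams, seed = childSeed(seed, 21L))
  rv <- growRvNetwork(mesh, rvParams, seed = childSeed(seed, 22L))
  mergeNetworks(lv, rv)
}

#' Run one activation simulation on an assembled heart
#'
#' @param heart a \linkS4class{SimHeart}.
#' @param lbbb apply a complete left bundle branch block.
#' @param ft optional \linkS4class{FTConfig}; inserted before the block so
#'   the block lands immediately distal to the FT take-off.
#' @param config a \linkS4class{ConductionConfig}.
#' @param seed seed for the FT delta-tree growth.
#' @return list with the \linkS4class{ActivationMap}, the
#'   \linkS4class{ActivationSummary} and the network used.
#' @export
simulateActivation <- function(heart, lbbb = FALSE, ft = NULL,
                               config = conductionConfig(), seed = 1L) {
  net <- heart@network
  if (!is.null(ft))
    net <- addFalseTendon(net, heart@mesh, ft, seed = childSeed(seed, 41L))
  if (lbbb)
    net <- applyLbbb(net, ftOriginNode = if (!is.null(ft))
      net@meta$ft$originNode else NULL)
  map <- coupledSolve(heart@mesh, heart@fibers, net, config)
  sides <- splitLvRv(heart@mesh)
  list(map = map, summary = synchronyMetrics(map, sides), network = net)
}

#' Sensitivity of the QRS duration to the Purkinje topology
#'
#' One fixed geometry; independently seeded Purkinje networks (branch
#' lengths and angles vary through their Gaussian draws, all other growth
#' parameters fixed); healthy conduction, no FT.
#'
#' @param nNetworks number of network realizations (25 in the reference
#'   protocol).
#' @param seed master seed.
#' @param targetVertices mesh size.
#' @param config a \linkS4class{ConductionConfig}.
#' @param model optional prebuilt \linkS4class{ShapeModel}.
#' @return list with per-network QRS table and summary (mean, sd, min,
#'   max).
#' @export
runPkSensitivity <- function(nNetworks = 25L, seed = 1L,
                             targetVertices = 30000L,
                             config = conductionConfig(), model = NULL) {
  model <- model %||% buildSyntheticAtlas(seed = seed)
  sample <- sampleShape(model, rep(0, nrow(model@modes)))
  heart <- generateHeart(sample, seed = childSeed(seed, 1L),
                         targetVertices = targetVertices, pmFixed = TRUE)
  sides <- splitLvRv(heart@mesh)
  qrs <- numeric(nNetworks)
  for (k in seq_len(nNetworks)) {
    net <- growBiventricularNetwork(heart@mesh,
                                    seed = childSeed(seed, 100L + k))
    map <- coupledSolve(heart@mesh, heart@fibers, net, config)
    qrs[k] <- qrsDuration(map)
  }
  list(table = data.frame(network = seq_len(nNetworks), qrsD = qrs),
       summary = list(mean = mean(qrs), sd = stats::sd(qrs),
                      min = min(qrs), max = max(qrs)),
       heart = heart)
}

.ftLabel <- function(cfgFt) {
  paste0(sub("_TIP", "", cfgFt@endpoint), "-",
         ifelse(cfgFt@termination == "DIRECT", "Direct", "Delta"))
}

# run the eight per-heart configurations (healthy, LBBB, 6 x LBBB+FT)
.runHeartConfigs <- function(heart, config, seed,
                             ftConfigs = enumerateFtConfigs(heart@mesh)) {
  sides <- splitLvRv(heart@mesh)
  row <- function(label, sim, lbbb, ft) {
    s <- sim$summary
    data.frame(config = label, lbbb = lbbb, ft = ft, qrsD = s@qrsD,
               firstLV = s@firstLV, firstRV = s@firstRV,
               lastLV = s@lastLV, lastRV = s@lastRV,
               totalLV = s@totalLV, totalRV = s@totalRV,
               dyssynchrony = s@dyssynchrony)
  }
  out <- list()
  simH <- simulateActivation(heart, lbbb = FALSE, config = config,
                             seed = seed)
  out[[1]] <- row("Healthy", simH, FALSE, "none")
  simB <- simulateActivation(heart, lbbb = TRUE, config = config,
                             seed = seed)
  out[[2]] <- row("LBBB", simB, TRUE, "none")
  for (fc in ftConfigs) {
    simF <- suppressWarnings(
      simulateActivation(heart, lbbb = TRUE, ft = fc, config = config,
                         seed = seed))
    out[[length(out) + 1]] <- row(.ftLabel(fc), simF, TRUE, .ftLabel(fc))
  }
  do.call(rbind, out)
}

#' Main virtual-population study
#'
#' For every sampled heart: one healthy run, one run with a complete LBBB
#' and no FT, and six runs with a LBBB plus a false tendon (APM/PPM/VFW
#' endpoint, each with direct and delta termination) - eight
#' configurations per geometrical shape, all on the same mesh and base
#' network. Per-heart QRS_Diff is computed against the matched
#' LBBB-without-FT run.
#'
#' @param nHearts population size (70 in the reference protocol).
#' @param seed master seed.
#' @param targetVertices mesh size per heart.
#' @param config a \linkS4class{ConductionConfig}.
#' @param model optional prebuilt \linkS4class{ShapeModel}.
#' @return a \linkS4class{PopulationResult}; the table has one row per
#'   heart x configuration and carries \code{qrsDiff} on the FT rows.
#' @export
runMainPopulation <- function(nHearts = 70L, seed = 1L,
                              targetVertices = 30000L,
                              config = conductionConfig(), model = NULL) {
  model <- model %||% buildSyntheticAtlas(seed = seed)
  pop <- randomPopulation(model, nHearts, seed = childSeed(seed, 2L))
  rows <- list()
  failures <- character(0)
  for (h in seq_len(nHearts)) {
    res <- tryCatch({
      heart <- generateHeart(pop[[h]], seed = childSeed(seed, 300L + h),
                             targetVertices = targetVertices)
      tab <- .runHeartConfigs(heart, config, seed = childSeed(seed, h))
      tab$heart <- h
      tab
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("heart %d: %s", h,
                                      conditionMessage(res)))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  tab <- do.call(rbind, rows)
  tab <- .addQrsDiff(tab)
  new("PopulationResult", table = tab,
      summary = .populationSummary(tab),
      meta = list(seed = seed, nHearts = nHearts,
                  targetVertices = targetVertices, failures = failures))
}

.addQrsDiff <- function(tab) {
  tab$qrsDiff <- NA_real_
  for (h in unique(tab$heart)) {
    ref <- tab$qrsD[tab$heart == h & tab$config == "LBBB"]
    if (length(ref) == 1) {
      sel <- tab$heart == h & tab$lbbb & tab$ft != "none"
      tab$qrsDiff[sel] <- ref - tab$qrsD[sel]
    }
  }
  tab
}

.populationSummary <- function(tab, threshold = 120) {
  out <- list()
  for (cf in unique(tab$config)) {
    q <- tab$qrsD[tab$config == cf]
    out[[cf]] <- populationStats(q, threshold)
  }
  diffs <- tab$qrsDiff[!is.na(tab$qrsDiff)]
  if (length(diffs))
    out$qrsDiff <- list(mean = mean(diffs), sd = stats::sd(diffs),
                        n = length(diffs),
                        pctGe10 = 100 * mean(diffs >= 10),
                        iqr = iqrRange(diffs))
  out
}

#' Size, shape and FT-location sub-populations
#'
#' P1 (size): a few base shapes rescaled over a grid of LV lengths, fixed
#' FT attachment points. P2 (shape): the full population rescaled to one
#' LV length. P3 (FT location): base shapes at 80 mm with random VFW
#' attachment locations, direct and delta. Per-case QRS_Diff against the
#' matched LBBB run on the same heart.
#'
#' @param which subset of c("P1","P2","P3").
#' @param seed master seed.
#' @param nShapes number of base shapes for P1/P3 (4 in the reference
#'   protocol).
#' @param nHearts population size for P2 (70 in the reference protocol).
#' @param sizes LV-length grid for P1 (mm).
#' @param fixedLength LV length for P2/P3 (mm).
#' @param nVfwPoints random VFW locations per shape in P3 (50 in the
#'   reference protocol).
#' @param targetVertices mesh size.
#' @param config a \linkS4class{ConductionConfig}.
#' @param model optional prebuilt \linkS4class{ShapeModel}.
#' @return named list of \linkS4class{PopulationResult} objects.
#' @export
runP1P2P3 <- function(which = c("P1", "P2", "P3"), seed = 1L, nShapes = 4L,
                      nHearts = 70L, sizes = seq(70, 88, by = 2),
                      fixedLength = 80, nVfwPoints = 50L,
                      targetVertices = 30000L,
                      config = conductionConfig(), model = NULL) {
  which <- match.arg(which, several.ok = TRUE)
  model <- model %||% buildSyntheticAtlas(seed = seed)
  baseSamples <- randomPopulation(model, nShapes,
                                  seed = childSeed(seed, 51L))
  out <- list()

  runScaled <- function(sample, heartId, scaleTo, hseed,
                        ftConfigs = NULL) {
    heart <- generateHeart(sample, seed = hseed,
                           targetVertices = targetVertices,
                           scaleTo = scaleTo)
    tab <- .runHeartConfigs(heart, config, seed = hseed,
                            ftConfigs = ftConfigs %||%
                              enumerateFtConfigs(heart@mesh))
    tab$heart <- heartId
    tab$lvLength <- lvLength(heart@surface)
    tab
  }

  if ("P1" %in% which) {
    rows <- list()
    for (s in seq_len(nShapes)) for (L in sizes) {
      rows[[length(rows) + 1]] <- within(
        runScaled(baseSamples[[s]], paste0("shape", s, "_L", L), L,
                  childSeed(seed, 600L + 100L * s + L)),
        shape <- s)
    }
    tab <- .addQrsDiff(do.call(rbind, rows))
    out$P1 <- new("PopulationResult", table = tab,
                  summary = .populationSummary(tab),
                  meta = list(seed = seed, sizes = sizes))
  }
  if ("P2" %in% which) {
    pop <- randomPopulation(model, nHearts, seed = childSeed(seed, 2L))
    rows <- list()
    for (h in seq_len(nHearts)) {
      res <- tryCatch(
        runScaled(pop[[h]], h, fixedLength, childSeed(seed, 700L + h)),
        error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1]] <- res
    }
    tab <- .addQrsDiff(do.call(rbind, rows))
    out$P2 <- new("PopulationResult", table = tab,
                  summary = .populationSummary(tab),
                  meta = list(seed = seed, fixedLength = fixedLength))
  }
  if ("P3" %in% which) {
    rows <- list()
    for (s in seq_len(nShapes)) {
      hseed <- childSeed(seed, 800L + s)
      heart <- generateHeart(baseSamples[[s]], seed = hseed,
                             targetVertices = targetVertices,
                             scaleTo = fixedLength)
      vfwCfgs <- enumerateFtConfigs(heart@mesh, nVfwPoints = nVfwPoints,
                                    seed = hseed)
      vfwCfgs <- vfwCfgs[-seq_len(6L)] # only the random VFW configs
      tab <- .runHeartConfigs(heart, config, seed = hseed,
                              ftConfigs = vfwCfgs)
      tab$config <- make.unique(tab$config)
      tab$heart <- paste0("shape", s)
      tab$shape <- s
      rows[[length(rows) + 1]] <- tab
    }
    tab <- do.call(rbind, rows)
    # matched QRS_Diff against each shape's LBBB run
    tab$qrsDiff <- NA_real_
    for (h in unique(tab$heart)) {
      ref <- tab$qrsD[tab$heart == h & tab$config == "LBBB"]
      sel <- tab$heart == h & tab$lbbb & tab$ft != "none"
      tab$qrsDiff[sel] <- ref - tab$qrsD[sel]
    }
    out$P3 <- new("PopulationResult", table = tab,
                  summary = list(
                    byShapeTermination = if (nrow(tab)) stats::aggregate(
                      qrsDiff ~ heart + ft, tab[!is.na(tab$qrsDiff), ],
                      function(x) c(mean = mean(x), sd = stats::sd(x),
                                    iqr = iqrRange(x))) else NULL),
                  meta = list(seed = seed, nVfwPoints = nVfwPoints))
  }
  out
}
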