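# Activation metrics: QRS duration, LV/RV split and synchrony, cumulative
# activation curves, population summaries.

#' QRS duration of an activation map
#'
#' Last minus first myocardial activation (ms). Purkinje-network node
#' times are excluded: the charge carried by the network is negligible on
#' a surface ECG.
#'
#' @param map an \linkS4class{ActivationMap}.
#' @return QRS duration (ms).
#' @export
qrsDuration <- function(map) {
  t <- map@vertexTimes
  if (any(!is.finite(t)))
    stop("incomplete activation: unreached myocardial vertices")
  max(t) - min(t)
}

#' Split myocardial vertices into LV and RV sides
#'
#' A plane is fitted by least squares through the mid-septal vertices
#' (septum label, transmural coordinate near 0.5), oriented along the
#' LV-to-RV direction; every vertex is assigned to one side. PM vertices
#' are always LV.
#'
#' @param mesh a \linkS4class{VolumeMesh} with a labelled septum.
#' @return character vector ("LV"/"RV") per vertex.
#' @export
splitLvRv <- function(mesh) {
  sept <- which(mesh@label == .VLABEL[["SEPTUM"]] &
                  abs(mesh@e - 0.5) <= 0.25)
  if (!length(sept)) stop("no septal vertices to fit the dividing plane")
  pts <- mesh@vertices[sept, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  nrm <- sv$v[, 3]
  # orient the normal toward the RV
  rvC <- colMeans(mesh@vertices[mesh@label == .VLABEL[["RV_WALL"]], ,
                                drop = FALSE])
  if (sum((rvC - ctr) * nrm) < 0) nrm <- -nrm
  side <- ifelse(as.numeric(sweep(mesh@vertices, 2, ctr) %*% nrm) > 0,
                 "RV", "LV")
  side[mesh@label %in% c(.VLABEL[["APM"]], .VLABEL[["PPM"]])] <- "LV"
  side
}

#' Per-ventricle activation summary
#'
#' First and last activation per side (ms from His onset), total
#' activation per side, QRS duration and dyssynchrony (absolute difference
#' of the last LV and RV activations).
#'
#' @param map an \linkS4class{ActivationMap}.
#' @param sides per-vertex side labels from [splitLvRv()].
#' @return an \linkS4class{ActivationSummary}.
#' @export
synchronyMetrics <- function(map, sides) {
  t <- map@vertexTimes
  if (any(!is.finite(t)))
    stop("incomplete activation: unreached myocardial vertices")
  lv <- t[sides == "LV"]
  rv <- t[sides == "RV"]
  new("ActivationSummary",
      qrsD = max(t) - min(t),
      firstLV = min(lv), firstRV = min(rv),
      lastLV = max(lv), lastRV = max(rv),
      totalLV = max(lv) - min(lv), totalRV = max(rv) - min(rv),
      dyssynchrony = abs(max(rv) - max(lv)))
}

#' Cumulative activated-tissue curve
#'
#' Volume-weighted empirical CDF of myocardial activation times, sampled
#' on a 1 ms grid; monotone from 0 to 100 percent.
#'
#' @param map an \linkS4class{ActivationMap}.
#' @param mesh the matching \linkS4class{VolumeMesh} (lumped nodal
#'   volumes).
#' @param dt sampling interval (ms).
#' @return data.frame with columns \code{time} (ms) and \code{percent}.
#' @export
cumulativeActivation <- function(map, mesh, dt = 1) {
  t <- map@vertexTimes
  w <- mesh@nodalVolume
  ok <- is.finite(t)
  t <- t[ok]
  w <- w[ok]
  grid <- seq(floor(min(t)), ceiling(max(t)), by = dt)
  pct <- vapply(grid, function(g) sum(w[t <= g]), numeric(1)) / sum(w) * 100
  data.frame(time = grid, percent = pct)
}

#' Population summary of QRS durations
#'
#' @param qrsValues numeric vector (ms).
#' @param threshold decision threshold (ms); the proportion above uses a
#'   strict inequality.
#' @return list with mean, sd, count/percent above threshold and a 10 ms
#'   decade histogram (counts per [10k, 10(k+1)) bin).
#' @export
populationStats <- function(qrsValues, threshold = 120) {
  if (!length(qrsValues)) stop("empty value list")
  nAbove <- sum(qrsValues > threshold)
  lo <- floor(min(qrsValues, 0) / 10)
  hi <- ceiling(max(qrsValues) / 10)
  breaks <- seq(10 * lo, 10 * hi, by = 10)
  h <- table(cut(qrsValues, breaks, right = FALSE))
  list(mean = mean(qrsValues), sd = stats::sd(qrsValues),
       n = length(qrsValues), nAbove = nAbove,
       pctAbove = 100 * nAbove / length(qrsValues),
       decades = h)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Standard two-sample KS statistic with asymptotic p value.
#'
#' @param a,b numeric samples.
#' @return list with \code{D} and \code{p}.
#' @export
ksTwoSample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Interquartile range with linear-interpolation quantiles
#'
#' @param values numeric vector (ms).
#' @return Q3 - Q1 (type-7 quantiles).
#' @export
iqrRange <- function(values) {
  if (!length(values)) stop("empty value list")
  unname(diff(stats::quantile(values, c(0.25, 0.75), type = 7)))
}
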