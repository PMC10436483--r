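#' Simulate a uniform (complete spatial randomness) localization set
#'
#' @param n Number of localizations (>= 1).
#' @param bounds Bounding volume to fill (a [boundingBox()]).
#' @param seed Seed; the output is reproducible bit for bit.
#' @return A [LocalizationSet-class] with `bounds` as its bounding volume.
#' @export
#' @examples
#' locs <- simulateUniform(1000, boundingBox(c(0, 0, 0), rep(2000, 3)), 1)
#' nLocs(locs)
simulateUniform <- function(n, bounds, seed = 1L) {
  vcAssert(is.numeric(n) && length(n) == 1L && n >= 1L,
           "n must be a positive count", "input")
  d <- ncol(bounds)
  checkBox(bounds, d)
  vcAssert(boxMeasure(bounds) > 0, "bounds must have positive measure",
           "input")
  set.seed(seed)
  co <- vapply(seq_len(d), function(k)
    runif(n, bounds[1L, k], bounds[2L, k]), numeric(n))
  if (n == 1L) co <- matrix(co, nrow = 1L)
  LocalizationSet(co, bounds = bounds,
                  metadata = list(kind = "uniform", seed = seed))
}

#' Configuration for a clustered simulation
#'
#' Describes a synthetic SMLM dataset: isotropic clusters (Gaussian profile
#' with standard deviation `sigma`, or uniform spheres of radius `radius`)
#' planted at rejection-sampled centers with a minimum pairwise separation,
#' over a uniform background.  The defaults reproduce the reference
#' clustered condition used throughout the package: 20 Gaussian clusters of
#' 500 localizations each (sigma 50 nm) in a 2 x 2 x 2 um^3 volume with 10\%
#' of all localizations as uniform background.
#'
#' @param nClusters Number of clusters.
#' @param profile `"gaussian"` or `"uniform_sphere"`.
#' @param sigma Gaussian standard deviation (nm), isotropic.
#' @param radius Sphere radius (nm) for `"uniform_sphere"`.
#' @param locsPerCluster Localizations per cluster (scalar or per-cluster
#'   vector).
#' @param backgroundFraction Fraction of ALL localizations that are uniform
#'   background (ignored when `nBackground` is given).
#' @param nBackground Explicit background count.
#' @param bounds Bounding volume; default a 2000 nm cube (3D).
#' @param minSep Minimum pairwise center separation (nm).
#' @param margin Distance from `bounds` faces within which no center is
#'   placed; default `3 * sigma` or `1.1 * radius`.
#' @param seed Seed.
#' @param dim 2 or 3.
#' @param maxTries Rejection-sampling budget for center placement.
#' @return A list of class `"clusterSimConfig"`.
#' @export
clusterSimConfig <- function(nClusters = 20L,
                             profile = c("gaussian", "uniform_sphere"),
                             sigma = 50, radius = 100,
                             locsPerCluster = 500L,
                             backgroundFraction = 0.1, nBackground = NULL,
                             bounds = NULL, minSep = 500, margin = NULL,
                             seed = 1L, dim = 3L, maxTries = 100000L) {
  profile <- match.arg(profile)
  if (is.null(bounds))
    bounds <- boundingBox(rep(0, dim), rep(2000, dim))
  dim <- ncol(bounds)
  vcAssert(dim %in% 2:3, "dim must be 2 or 3", "config")
  vcAssert(nClusters >= 1L, "need at least one cluster", "config")
  lpc <- if (length(locsPerCluster) == 1L)
    rep(as.integer(locsPerCluster), nClusters) else as.integer(locsPerCluster)
  vcAssert(length(lpc) == nClusters && all(lpc >= 1L),
           "locsPerCluster must give a positive count per cluster", "config")
  if (is.null(nBackground)) {
    vcAssert(backgroundFraction >= 0 && backgroundFraction < 1,
             "backgroundFraction must be in [0, 1)", "config")
    nBackground <- round(backgroundFraction / (1 - backgroundFraction) *
                           sum(lpc))
  }
  if (is.null(margin))
    margin <- if (profile == "gaussian") 3 * sigma else 1.1 * radius
  structure(list(nClusters = as.integer(nClusters), profile = profile,
                 sigma = sigma, radius = radius, locsPerCluster = lpc,
                 nBackground = as.integer(nBackground), bounds = bounds,
                 minSep = minSep, margin = margin, seed = as.integer(seed),
                 dim = dim, maxTries = as.integer(maxTries)),
            class = "clusterSimConfig")
}

#' Simulate a clustered localization set with ground-truth labels
#'
#' Cluster centers are placed by rejection sampling honoring the minimum
#' pairwise separation and the face margin; member offsets follow the
#' configured profile and are resampled (not clipped) until they fall
#' inside the bounds, so no density spikes appear on the faces; background
#' localizations are uniform over the full bounds.  The per-localization
#' ground-truth label (cluster id, or 0 for background) is returned as the
#' `label` extras column, and the planted centers in the metadata.
#'
#' @param config A [clusterSimConfig()].
#' @return A [LocalizationSet-class]; `locExtras(x)$label` holds the
#'   ground truth and `x@metadata$centers` the planted centers.
#' @export
#' @examples
#' cfg <- clusterSimConfig(nClusters = 3, locsPerCluster = 50, seed = 2)
#' locs <- simulateClustered(cfg)
#' table(locExtras(locs)$label)
simulateClustered <- function(config) {
  stopifnot(inherits(config, "clusterSimConfig"))
  cfg <- config
  d <- cfg$dim
  lo <- cfg$bounds[1L, ]
  hi <- cfg$bounds[2L, ]
  vcAssert(all(hi - lo > 2 * cfg$margin),
           "margin leaves no room for cluster centers", "config")
  set.seed(cfg$seed)
  centers <- matrix(NA_real_, 0L, d)
  tries <- 0L
  while (nrow(centers) < cfg$nClusters) {
    tries <- tries + 1L
    if (tries > cfg$maxTries)
      vcStop(paste("could not place cluster centers with the requested",
                   "separation within the sampling budget"), "config")
    cand <- runif(d, lo + cfg$margin, hi - cfg$margin)
    if (nrow(centers) == 0L ||
        min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) >= cfg$minSep)
      centers <- rbind(centers, cand)
  }
  pts <- vector("list", cfg$nClusters)
  for (k in seq_len(cfg$nClusters)) {
    want <- cfg$locsPerCluster[k]
    got <- matrix(NA_real_, 0L, d)
    while (nrow(got) < want) {
      m <- want - nrow(got)
      off <- if (cfg$profile == "gaussian") {
        matrix(rnorm(d * m, 0, cfg$sigma), ncol = d)
      } else {
        # uniform in the d-ball: normalize gaussians, scale by U^(1/d)
        g <- matrix(rnorm(d * m), ncol = d)
        g <- g / sqrt(rowSums(g^2))
        g * cfg$radius * runif(m)^(1 / d)
      }
      cand <- off + matrix(centers[k, ], m, d, byrow = TRUE)
      ok <- rowSums(cand < matrix(lo, m, d, byrow = TRUE) |
                      cand > matrix(hi, m, d, byrow = TRUE)) == 0L
      got <- rbind(got, cand[ok, , drop = FALSE])
    }
    pts[[k]] <- got
  }
  lab <- rep.int(seq_len(cfg$nClusters), cfg$locsPerCluster)
  co <- do.call(rbind, pts)
  if (cfg$nBackground > 0L) {
    bg <- vapply(seq_len(d), function(k)
      runif(cfg$nBackground, lo[k], hi[k]), numeric(cfg$nBackground))
    if (cfg$nBackground == 1L) bg <- matrix(bg, nrow = 1L)
    co <- rbind(co, bg)
    lab <- c(lab, rep.int(0L, cfg$nBackground))
  }
  LocalizationSet(co, bounds = cfg$bounds,
                  extras = data.frame(label = lab),
                  metadata = list(kind = "clustered", centers = centers,
                                  config = unclass(cfg)))
}
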