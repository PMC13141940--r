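#' @include AllClasses.R structio.R
NULL

## electron counts per element, used as q-independent atomic form factors
## and as Rg weights
.ELECTRONS <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15, SE = 34)
## displaced-solvent electrons per heavy atom group (bulk water 0.334 e/A^3
## times an average atomic group volume); used by the excess-scattering mode
.DISPLACED <- c(H = 1.72, C = 5.49, N = 0.83, O = 3.05, S = 6.63,
                P = 6.63, SE = 6.63)

#' Construct a scattering profile
#'
#' @param q momentum transfer (inverse Angstrom), strictly increasing.
#' @param intensity intensities.
#' @param sigma optional uncertainties.
#' @return a [ScatteringProfile-class].
#' @export
ScatteringProfile <- function(q, intensity, sigma = numeric()) {
  new("ScatteringProfile", q = as.numeric(q), intensity = as.numeric(intensity),
      sigma = as.numeric(sigma))
}

#' Read a 1-D scattering profile from 3-column text
#'
#' Accepts the de facto SAXS `.dat` layout: whitespace- or comma-separated
#' columns Q, I and (optionally) sigma; comment/header lines (starting with
#' `#` or non-numeric) are skipped.  Rows with non-positive q are dropped.
#'
#' @param path file path.
#' @return a [ScatteringProfile-class].
#' @export
readProfile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  fields <- strsplit(gsub(",", " ", ln), "[[:space:]]+")
  num <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  ok <- vapply(num, function(v) length(v) >= 2 && !anyNA(v[1:2]), logical(1))
  num <- num[ok]
  if (!length(num)) stop("no numeric data rows in '", path, "'")
  q <- vapply(num, `[`, numeric(1), 1L)
  i <- vapply(num, `[`, numeric(1), 2L)
  s <- vapply(num, function(v) if (length(v) >= 3) v[3L] else NA_real_, numeric(1))
  keep <- q > 0
  q <- q[keep]; i <- i[keep]; s <- s[keep]
  ord <- order(q)
  sig <- if (all(is.finite(s)) && all(s[ord] > 0)) s[ord] else numeric()
  ScatteringProfile(q[ord], i[ord], sig)
}

#' Write a scattering profile as 3-column text
#'
#' @param profile a [ScatteringProfile-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeProfile <- function(profile, path) {
  s <- if (length(profile@sigma)) profile@sigma else rep(NA_real_, length(profile@q))
  utils::write.table(data.frame(q = profile@q, I = profile@intensity, sigma = s),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Reduce a SEC-SAXS frame series to a background-subtracted profile
#'
#' The background is the pointwise mean of the buffer frames (measured
#' before the sample fraction in a SEC-SAXS run); the result is the mean of
#' the sample frames minus the background.  Uncertainties are propagated in
#' quadrature through both averages and the subtraction.
#'
#' @param series a [FrameSeries-class].
#' @param bufferFrames,sampleFrames disjoint integer index sets into the
#'   frame columns.
#' @return a [ScatteringProfile-class].
#' @export
subtractBackground <- function(series, bufferFrames, sampleFrames) {
  bufferFrames <- as.integer(bufferFrames); sampleFrames <- as.integer(sampleFrames)
  nf <- ncol(series@intensities)
  if (!length(bufferFrames) || !length(sampleFrames))
    stop("invalid argument: buffer and sample frame sets must be non-empty")
  if (length(intersect(bufferFrames, sampleFrames)))
    stop("invalid argument: buffer and sample frame sets overlap")
  if (any(c(bufferFrames, sampleFrames) < 1L) ||
      any(c(bufferFrames, sampleFrames) > nf))
    stop("frame indices out of range 1..", nf)
  bg <- rowMeans(series@intensities[, bufferFrames, drop = FALSE])
  sm <- rowMeans(series@intensities[, sampleFrames, drop = FALSE])
  sig <- numeric()
  if (length(series@sigmas)) {
    vb <- rowSums(series@sigmas[, bufferFrames, drop = FALSE]^2) /
      length(bufferFrames)^2
    vs <- rowSums(series@sigmas[, sampleFrames, drop = FALSE]^2) /
      length(sampleFrames)^2
    sig <- sqrt(vb + vs)
  }
  ScatteringProfile(series@q, sm - bg, sig)
}

#' Radius of gyration from atomic coordinates
#'
#' Weighted root-mean-square distance from the weighted centroid, with
#' electron-count weights (default) or uniform weights.
#'
#' @param model a [StructureModel-class] with at least one atom.
#' @param weighting `"electron"` or `"uniform"`.
#' @return Rg in Angstrom.
#' @examples
#' two <- StructureModel(data.frame(chain = "A", resno = 1:2, resid = "GLY",
#'                                  elety = "CA", elesy = "C",
#'                                  x = c(0, 2), y = 0, z = 0))
#' rgFromCoords(two)  # 1
#' @export
rgFromCoords <- function(model, weighting = c("electron", "uniform")) {
  weighting <- match.arg(weighting)
  a <- atoms(model)
  if (!nrow(a)) stop("model must contain at least one atom")
  w <- if (weighting == "electron") .formWeights(a, "electron") else rep(1, nrow(a))
  xyz <- cbind(a$x, a$y, a$z)
  cen <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, cen)^2)) / sum(w))
}

.formWeights <- function(a, formFactor) {
  if (formFactor == "uniform") return(rep(1, nrow(a)))
  z <- .ELECTRONS[toupper(a$elesy)]
  if (any(is.na(z))) {
    bad <- unique(a$elesy[is.na(z)])
    stop("no electron count for element(s): ", paste(bad, collapse = ", "))
  }
  z <- unname(z)
  if (formFactor == "excess") {
    d <- .DISPLACED[toupper(a$elesy)]
    d[is.na(d)] <- 0
    z <- z - unname(d)
  }
  z
}

#' Theoretical scattering profile by the Debye formula
#'
#' Orientationally averaged intensity `I(q) = sum_ij f_i f_j sinc(q r_ij)`
#' with q-independent per-atom weights: electron counts (`"electron"`),
#' solvent-corrected excess electrons (`"excess"`), or unit weights
#' (`"uniform"`, for bead oracles).  `q = 0` is evaluated by the sinc limit,
#' so `I(0) = (sum f)^2` exactly.  For large structures the pair-distance
#' sum is histogram-binned (0.02 Angstrom bins), which is deterministic and
#' accurate to well below one percent over the small-angle range.
#'
#' @param model a non-empty [StructureModel-class].
#' @param q positive increasing grid (inverse Angstrom); 0 allowed.
#' @param formFactor `"electron"`, `"excess"` or `"uniform"`.
#' @param exactPairLimit use the exact pair list when the number of atom
#'   pairs is below this bound (default 2e5), else binning.
#' @return a [ScatteringProfile-class] (no sigma).
#' @export
debyeProfile <- function(model, q, formFactor = c("electron", "excess", "uniform"),
                         exactPairLimit = 2e5) {
  formFactor <- match.arg(formFactor)
  a <- atoms(model)
  if (!nrow(a)) stop("model must be non-empty")
  if (any(q < 0) || any(diff(q) <= 0)) stop("q grid must be non-negative increasing")
  f <- .formWeights(a, formFactor)
  xyz <- cbind(a$x, a$y, a$z)
  n <- nrow(xyz)
  sumF2 <- sum(f^2)
  npair <- n * (n - 1) / 2
  if (npair <= exactPairLimit) {
    d <- as.numeric(stats::dist(xyz))
    w <- 2 * .pairProducts(f)  # pair weights 2 f_i f_j in dist() ordering
    I <- vapply(q, function(qq) {
      if (qq == 0) return(sumF2 + sum(w))
      x <- qq * d
      sumF2 + sum(w * ifelse(x < 1e-8, 1, sin(x) / x))
    }, numeric(1))
  } else {
    ## histogram-binned pair distances with weighted counts
    bw <- 0.02
    res <- .binnedPairs(xyz, f, bw)
    I <- vapply(q, function(qq) {
      if (qq == 0) return(sumF2 + sum(res$w))
      x <- qq * res$r
      sumF2 + sum(res$w * ifelse(x < 1e-8, 1, sin(x) / x))
    }, numeric(1))
  }
  ScatteringProfile(q, I)
}

## products f_i * f_j for i < j in the same ordering as stats::dist
.pairProducts <- function(f) {
  n <- length(f)
  out <- numeric(n * (n - 1) / 2)
  k <- 1L
  for (i in seq_len(n - 1L)) {
    m <- n - i
    out[k:(k + m - 1L)] <- f[i] * f[(i + 1L):n]
    k <- k + m
  }
  out
}

## weighted pair-distance histogram (weight-averaged bin distance keeps the
## first distance moment exact within each bin)
.binnedPairs <- function(xyz, f, bw) {
  n <- nrow(xyz)
  maxd <- 0
  wsum <- dsum <- NULL
  nb <- NULL
  ## two passes in blocks to bound memory
  blocks <- split(seq_len(n), ceiling(seq_len(n) / 1000))
  ## first pass: max distance
  rng <- apply(xyz, 2, range)
  maxd <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  nb <- ceiling(maxd / bw) + 1L
  wsum <- numeric(nb); dsum <- numeric(nb)
  for (bi in seq_along(blocks)) {
    i <- blocks[[bi]]
    for (bj in bi:length(blocks)) {
      j <- blocks[[bj]]
      d2 <- outer(rowSums(xyz[i, , drop = FALSE]^2),
                  rowSums(xyz[j, , drop = FALSE]^2), "+") -
        2 * tcrossprod(xyz[i, , drop = FALSE], xyz[j, , drop = FALSE])
      d2[d2 < 0] <- 0
      d <- sqrt(d2)
      w <- tcrossprod(f[i], f[j])
      if (bi == bj) {
        keep <- upper.tri(d)
        d <- d[keep]; w <- w[keep]
      } else {
        d <- as.numeric(d); w <- as.numeric(w)
      }
      idx <- pmin(nb, floor(d / bw) + 1L)
      wsum <- wsum + unname(.rowsumVec(w, idx, nb))
      dsum <- dsum + unname(.rowsumVec(w * d, idx, nb))
    }
  }
  keep <- wsum > 0
  list(r = dsum[keep] / wsum[keep], w = 2 * wsum[keep])
}

.rowsumVec <- function(v, idx, nb) {
  out <- numeric(nb)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Guinier analysis of a scattering profile
#'
#' Weighted linear regression of `ln I` on `q^2` over the largest contiguous
#' low-q window satisfying `q_max * Rg <= qRgMax`, found by iterating the
#' window to self-consistency.  `Rg = sqrt(-3 * slope)`, `I(0) =
#' exp(intercept)`.
#'
#' @param profile a [ScatteringProfile-class] (positive intensities in the
#'   fitted range; uncertainties used as weights when present).
#' @param qRgMax dimensionless Guinier bound (default 1.3, the conventional
#'   validity limit for globular particles).
#' @param minPoints minimum number of points in the window (default 5).
#' @return a [GuinierResult-class].
#' @examples
#' q <- seq(0.005, 0.1, length.out = 60)
#' p <- ScatteringProfile(q, 7 * exp(-q^2 * 25^2 / 3))
#' radiusOfGyration(guinierFit(p))  # 25
#' @export
guinierFit <- function(profile, qRgMax = 1.3, minPoints = 5L) {
  q <- profile@q; I <- profile@intensity
  pos <- I > 0
  if (sum(pos) < minPoints)
    stop("fit error: fewer than ", minPoints, " positive intensities")
  ## contiguous positive run from the lowest q
  first <- which(pos)[1L]
  runEnd <- first
  while (runEnd < length(q) && pos[runEnd + 1L]) runEnd <- runEnd + 1L
  doFit <- function(idx) {
    x <- q[idx]^2; y <- log(I[idx])
    w <- if (length(profile@sigma)) (I[idx] / profile@sigma[idx])^2 else rep(1, length(idx))
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    slope <- fit$coefficients[2L]
    list(slope = slope, intercept = fit$coefficients[1L],
         r2 = 1 - sum(w * fit$residuals^2) /
           sum(w * (y - sum(w * y) / sum(w))^2))
  }
  idx <- first:runEnd
  rg <- NA_real_
  for (iter in 1:50) {
    f <- doFit(idx)
    if (f$slope >= 0)
      stop("non-Guinier error: non-negative slope of ln I vs q^2")
    rgNew <- sqrt(-3 * f$slope)
    hi <- max(which(q <= qRgMax / rgNew + 1e-12))
    hi <- min(hi, runEnd)
    newIdx <- first:max(hi, first + minPoints - 1L)
    if (length(newIdx) < minPoints)
      stop("fit error: fewer than ", minPoints, " points satisfy the Guinier bound")
    conv <- is.finite(rg) && abs(rgNew - rg) < 1e-6
    rg <- rgNew
    if (conv && identical(newIdx, idx)) break
    idx <- newIdx
  }
  f <- doFit(idx)
  rg <- sqrt(-3 * f$slope)
  new("GuinierResult", rg = unname(rg), i0 = unname(exp(f$intercept)),
      fitRange = as.integer(idx), qRgMax = qRgMax, rSquared = unname(f$r2))
}

#' Dimensionless (normalized) Kratky transform
#'
#' Returns the curve `(qRg, (qRg)^2 * I(q) / I(0))`.  Globular particles
#' peak near `qRg = sqrt(3)` at `3/e`; extended or flexible chains rise
#' monotonically with a plateau beyond `qRg ~ 4`.
#'
#' @param profile a [ScatteringProfile-class].
#' @param guinier a [GuinierResult-class] supplying Rg and I(0).
#' @return data.frame with columns `qRg` and `value` (same point count as
#'   the profile).
#' @export
normalizedKratky <- function(profile, guinier) {
  x <- profile@q * guinier@rg
  data.frame(qRg = x, value = x^2 * profile@intensity / guinier@i0)
}

#' Fit a theoretical profile to an experimental one
#'
#' Finds scale `c` and constant offset `b` minimizing
#' `sum(((I_exp - c I_th - b) / sigma)^2)`; reports the reduced chi-square
#' `chi^2 / (N - 2)`.  The theoretical curve is linearly interpolated onto
#' the experimental q grid (which must lie within the theoretical grid).
#'
#' @param theory,experiment [ScatteringProfile-class] objects; the
#'   experiment should carry uncertainties (a missing sigma triggers an
#'   unweighted fit with a warning).
#' @return list with `scale`, `offset`, `chiSquareReduced`, and `fitted`
#'   (the scaled theoretical [ScatteringProfile-class] on the experimental
#'   grid).
#' @export
fitTheoretical <- function(theory, experiment) {
  qe <- experiment@q
  if (min(qe) < min(theory@q) - 1e-12 || max(qe) > max(theory@q) + 1e-12)
    stop("experimental q grid extends beyond the theoretical grid")
  it <- stats::approx(theory@q, theory@intensity, xout = qe)$y
  ie <- experiment@intensity
  if (length(experiment@sigma)) {
    w <- 1 / experiment@sigma^2
  } else {
    warning("experiment has no uncertainties; performing an unweighted fit")
    w <- rep(1, length(qe))
  }
  X <- cbind(it, 1)
  fit <- stats::lm.wfit(X, ie, w)
  cb <- fit$coefficients
  chi2 <- sum(w * fit$residuals^2) / (length(qe) - 2)
  list(scale = unname(cb[1L]), offset = unname(cb[2L]),
       chiSquareReduced = chi2,
       fitted = ScatteringProfile(qe, as.numeric(X %*% cb)))
}
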