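# Ks distribution decomposition: kernel-density peak finding, EM fitting of
# normal mixtures (components = evolutionary events), multiplicative
# lineage-rate correction, and calibration-based dating.

#' Locate Ks density peaks by kernel smoothing
#'
#' Gaussian kernel density on a fixed 512-point grid; returns the mode
#' locations (local maxima), sorted ascending.
#'
#' @param ks numeric Ks sample (>= 30 values, all >= 0).
#' @param bandwidth numeric bandwidth or `"auto"` (Silverman's rule).
#' @param minHeight modes whose density is below this fraction of the
#'   highest mode are discarded as numerical wiggles (default 0.05).
#' @return numeric vector of peak locations.
#' @export
kdePeaks <- function(ks, bandwidth = "auto", minHeight = 0.05) {
  ks <- ks[is.finite(ks)]
  if (length(ks) < 30) stop("insufficient data: need >= 30 finite Ks values")
  if (any(ks < 0)) stop("Ks values must be >= 0")
  if (diff(range(ks)) == 0) stop("degenerate sample: all values identical")
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(ks) else bandwidth
  d <- stats::density(ks, bw = bw, n = 512)
  y <- d$y
  isMax <- c(FALSE, y[2:511] > y[1:510] & y[2:511] >= y[3:512], FALSE)
  isMax <- isMax & y >= minHeight * max(y)
  sort(d$x[isMax])
}

.dnormMix <- function(x, w, mu, sigma) {
  out <- 0
  for (k in seq_along(w)) out <- out + w[k] * stats::dnorm(x, mu[k], sigma[k])
  out
}

# one EM run for fixed k; deterministic given the initial means
.emFit <- function(x, mu0, tol = 1e-6, maxIter = 500) {
  k <- length(mu0)
  n <- length(x)
  w <- rep(1 / k, k)
  mu <- mu0
  sigma <- rep(max(stats::sd(x) / k, 1e-3), k)
  ll <- -Inf
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    newLL <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    sigma[sigma < 1e-3] <- 1e-3
    if (is.finite(ll) && abs(newLL - ll) < tol) { converged <- TRUE; ll <- newLL; break }
    ll <- newLL
  }
  if (!converged)
    stop("EM did not converge in ", maxIter, " iterations (k = ", k,
         ", n = ", n, ", last log-likelihood ", format(ll), ")")
  list(w = w, mu = mu, sigma = sigma, loglik = ll, iter = iter)
}

#' Fit a normal mixture to a Ks sample
#'
#' EM fit of a k-component normal mixture on the sample restricted to the
#' fit domain (default (0.02, 2\]: below, allelic noise; above, saturation).
#' Initial means come from [kdePeaks()] modes (topped up with quantiles when
#' fewer modes than components); `k = "auto"` selects k in 1..5 by BIC.
#' Component means are the event Ks peaks; component sd is the reported
#' "+/-" spread.
#'
#' @param ks numeric Ks sample (>= 50 values inside the domain).
#' @param k number of components, or `"auto"`.
#' @param seed integer; fixed for reproducibility of any RNG use downstream
#'   (the fit itself is deterministic given the data).
#' @param domain numeric(2) fit domain.
#' @param bandwidth passed to [kdePeaks()].
#' @return a [KsMixtureModel-class].
#' @export
fitKsMixture <- function(ks, k = "auto", seed = 1, domain = c(0.02, 2),
                         bandwidth = "auto") {
  x <- ks[is.finite(ks) & ks > domain[1] & ks <= domain[2]]
  if (length(x) < 50) stop("insufficient data: need >= 50 Ks values in domain")
  set.seed(seed)
  bw <- if (identical(bandwidth, "auto")) stats::bw.nrd0(x) else bandwidth
  modes <- tryCatch(kdePeaks(x, bandwidth = bw), error = function(e) stats::median(x))
  init <- function(kk) {
    mu <- modes[seq_len(min(kk, length(modes)))]
    if (length(mu) < kk)
      mu <- c(mu, stats::quantile(x, probs = seq(0.1, 0.9,
                                                 length.out = kk - length(mu)),
                                  names = FALSE))
    sort(mu)
  }
  fitOne <- function(kk) {
    f <- .emFit(x, init(kk))
    npar <- 3 * kk - 1
    f$bic <- -2 * f$loglik + npar * log(length(x))
    f$k <- kk
    f
  }
  if (identical(k, "auto")) {
    fits <- lapply(1:5, function(kk) tryCatch(fitOne(kk), error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("mixture fit failed for all k in 1..5")
    fit <- fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
  } else {
    stopifnot(k >= 1)
    fit <- fitOne(as.integer(k))
  }
  o <- order(fit$mu)
  cm <- data.frame(weight = fit$w[o], mean = fit$mu[o], sd = fit$sigma[o])
  # clamp means marginally outside the domain (can happen for tiny weights)
  cm$mean <- pmin(pmax(cm$mean, domain[1]), domain[2])
  new("KsMixtureModel", components = cm, domain = domain,
      n = length(x), bandwidth = bw, loglik = fit$loglik, bic = fit$bic)
}

#' Estimate multiplicative lineage rate-correction coefficients
#'
#' Anchored on one evolutionary event shared by all lineages: if lineage i
#' shows the shared event at Ks peak `mu_i`, its coefficient is
#' `lambda_i = mu_ref / mu_i` (so the reference lineage has lambda = 1 and
#' slower lineages get lambda > 1).
#'
#' @param peaks named numeric: per-lineage observed Ks peak of the shared
#'   benchmark event.
#' @param reference name of the reference lineage.
#' @param benchmark label of the benchmark event (bookkeeping).
#' @return a `RateCorrection` (list with `lambda`, `reference`,
#'   `benchmark`).
#' @export
estimateRateCorrection <- function(peaks, reference, benchmark = "shared") {
  if (!reference %in% names(peaks)) stop("reference lineage not among peaks")
  if (any(peaks <= 0)) stop("peaks must be positive")
  lambda <- peaks[[reference]] / peaks
  lambda[[reference]] <- 1
  structure(list(lambda = lambda, reference = reference,
                 benchmark = benchmark),
            class = "RateCorrection")
}

#' Apply a rate correction to a Ks value
#'
#' Within one genome the corrected value is `lambda_i * ks`; between two
#' genomes each lineage contributes half the path, so the correction is the
#' arithmetic mean of the two coefficients.
#'
#' @param ks observed Ks (peak) value.
#' @param lineages one or two lineage labels.
#' @param corr a `RateCorrection` from [estimateRateCorrection()].
#' @return corrected Ks.
#' @export
applyRateCorrection <- function(ks, lineages, corr) {
  stopifnot(inherits(corr, "RateCorrection"))
  if (!all(lineages %in% names(corr$lambda)))
    stop("unknown lineage(s): ",
         paste(setdiff(lineages, names(corr$lambda)), collapse = ", "))
  lam <- corr$lambda[lineages]
  if (length(lineages) == 1) unname(lam * ks)
  else if (length(lineages) == 2) unname(mean(lam) * ks)
  else stop("lineages must have length 1 or 2")
}

#' Date an event from its corrected Ks peak against a calibration
#'
#' Linear scaling against a calibrated event: `t = ks / peak * [tLo, tHi]`,
#' each bound rounded to the nearest integer Myr (printed ages are
#' integers).
#'
#' @param ks corrected Ks peak of the event to date (> 0).
#' @param calibration list with `peak` (corrected Ks of the calibrated
#'   event, > 0) and `interval` (numeric(2), Mya).
#' @return integer vector c(t_lo, t_hi) in Mya.
#' @export
dateEvent <- function(ks, calibration) {
  if (is.null(calibration$peak) || calibration$peak <= 0)
    stop("calibration peak must be positive")
  iv <- calibration$interval
  stopifnot(length(iv) == 2, iv[1] > 0, iv[1] <= iv[2])
  if (ks <= 0) stop("ks must be positive")
  as.integer(round(ks / calibration$peak * iv))
}
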