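# Asymptotic Kolmogorov survival function Q(lambda) = P(K > lambda).
kolmogorovQ <- function(lambda) {
  vapply(lambda, function(l) {
    if (!is.finite(l)) return(NA_real_)
    if (l <= 0) return(1)
    k <- seq_len(101)
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * l^2))))
  }, numeric(1))
}

#' Two-sample Kolmogorov test (direct implementation)
#'
#' `D` is the supremum distance between the two empirical CDFs, evaluated at
#' every pooled jump point (which handles ties exactly); the p-value comes
#' from the asymptotic Kolmogorov distribution at
#' \eqn{\lambda = \sqrt{n_e} D} with effective size
#' \eqn{n_e = |a||b| / (|a| + |b|)}.
#'
#' @param a,b numeric samples, each of size at least 2.
#' @return list with `D`, `p`, `nEff`.
#' @export
ksTwoSample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (anyNA(a) || anyNA(b)) stop("NA in samples")
  jumps <- sort(unique(c(a, b)))
  Fa <- findInterval(jumps, sort(a)) / length(a)
  Fb <- findInterval(jumps, sort(b)) / length(b)
  D <- max(abs(Fa - Fb))
  nEff <- length(a) * length(b) / (length(a) + length(b))
  list(D = D, p = kolmogorovQ(sqrt(nEff) * D), nEff = nEff)
}

# Fast D for equal-size tie-free subsamples drawn inside subsampledKS; falls
# back to the jump-point evaluation when ties are present.
fastD <- function(u, v) {
  m <- length(u); n <- length(v)
  w <- c(u, v)
  o <- order(w, method = "radix")
  steps <- ifelse(o <= m, 1 / m, -1 / n)
  z <- cumsum(steps)
  ws <- w[o]
  if (anyDuplicated(ws)) {
    last <- c(ws[-1] != ws[-length(ws)], TRUE)
    max(abs(z[last]))
  } else max(abs(z))
}

#' Repeated subsampled Kolmogorov comparison of used vs available
#'
#' With very large used/available samples any difference is "significant";
#' repeatedly testing small equal subsamples (m of each group) keeps the
#' test at a fixed, interpretable resolution. Each iteration draws `m`
#' values from each group -- without replacement by default (subsampling),
#' with replacement if `replace = TRUE` (bootstrap) -- and records the
#' Kolmogorov statistic and p-value; the summaries are their means and SDs
#' plus the rejection fraction at `alpha`.
#'
#' @param used,available numeric samples, each of size at least `m` (when
#'   subsampling without replacement).
#' @param nIter number of subsample iterations.
#' @param m per-group subsample size.
#' @param alpha rejection level for the reported rejection fraction.
#' @param seed RNG seed.
#' @param replace draw subsamples with replacement.
#' @return object of class `"ksResult"`: `DMean, DSd, pMean, pSd,
#'   rejectRate, nIter, m, alpha, seed` and the per-iteration vectors
#'   `D`, `p`.
#' @export
subsampledKS <- function(used, available, nIter = 10000, m = 100,
                         alpha = 0.05, seed = NULL, replace = FALSE) {
  used <- as.numeric(used); available <- as.numeric(available)
  if (!replace && (length(used) < m || length(available) < m))
    stop("m exceeds a group size")
  if (m < 2L) stop("m must be >= 2")
  withSeed(seed, {
    D <- numeric(nIter)
    for (i in seq_len(nIter)) {
      u <- sample(used, m, replace = replace)
      v <- sample(available, m, replace = replace)
      D[i] <- fastD(u, v)
    }
    p <- kolmogorovQ(sqrt(m / 2) * D)
    out <- list(DMean = mean(D), DSd = sd(D), pMean = mean(p), pSd = sd(p),
                rejectRate = mean(p < alpha), nIter = nIter, m = m,
                alpha = alpha, seed = seed, D = D, p = p)
    class(out) <- "ksResult"
    out
  })
}

#' @export
print.ksResult <- function(x, ...) {
  cat(sprintf(
    "subsampled Kolmogorov test: D = %.3f +/- %.3f, p = %.3g +/- %.3g\n",
    x$DMean, x$DSd, x$pMean, x$pSd))
  cat(sprintf("  %d iterations of %d vs %d; rejection at alpha=%g: %.1f%%\n",
              x$nIter, x$m, x$m, x$alpha, 100 * x$rejectRate))
  invisible(x)
}

#' Distribution-family choice for the revisitation rate
#'
#' Fits normal, log-normal, Weibull and gamma families by maximum likelihood
#' and ranks them by AIC (each family has two parameters, so AIC ties are
#' broken by log-likelihood). The positive-support families are skipped with
#' a warning when non-positive values are present.
#'
#' @param rates numeric sample (revisitation rates), length at least 10.
#' @return data frame ranked by AIC with columns `family, loglik, aic,
#'   par1, par2`; fitted objects in attribute `"fits"`.
#' @export
fitRateDistribution <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) < 10L) stop("need at least 10 values")
  families <- c("norm", "lnorm", "weibull", "gamma")
  allPos <- all(rates > 0)
  rows <- list(); fits <- list()
  for (fam in families) {
    if (fam != "norm" && !allPos) {
      warning("non-positive values: skipping ", fam)
      next
    }
    ft <- try(suppressWarnings(fitdistrplus::fitdist(rates, fam,
                                                     method = "mle")),
              silent = TRUE)
    if (inherits(ft, "try-error")) next
    ll <- as.numeric(logLik(ft))
    rows[[fam]] <- data.frame(family = fam, loglik = ll,
                              aic = 2 * length(ft$estimate) - 2 * ll,
                              par1 = ft$estimate[1], par2 = ft$estimate[2],
                              row.names = NULL)
    fits[[fam]] <- ft
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$aic, -out$loglik), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Kernel-density export for used/available overlays
#'
#' Gaussian kernel with Silverman's bandwidth on a shared grid -- a
#' reporting convenience for density-overlay figures, not part of any test.
#'
#' @param used,available numeric samples.
#' @param n grid size.
#' @return data frame `x, densityUsed, densityAvailable`.
#' @export
densityOverlay <- function(used, available, n = 512) {
  rng <- range(c(used, available))
  du <- stats::density(used, bw = "nrd0", from = rng[1], to = rng[2], n = n)
  da <- stats::density(available, bw = "nrd0", from = rng[1], to = rng[2],
                       n = n)
  data.frame(x = du$x, densityUsed = du$y, densityAvailable = da$y)
}
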