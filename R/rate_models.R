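#' Seasonal revisitation rate of one site
#'
#' Individuals tracked for different lengths of time accumulate different
#' visit counts, so counts are rescaled to visits per seasonal period: for a
#' season type the rate is the number of visits whose entry time falls in
#' intervals of that type, divided by the number of periods of that type the
#' individual's tracking span overlaps, fractional periods counted
#' fractionally. A site with no visit in a season type yields no record for
#' that type.
#'
#' @param visitEnters visit entry times of the site (`POSIXct`).
#' @param st a [SeasonTable-class].
#' @param span tracking span `c(first, last)` of the individual.
#' @return data frame `season, nVisits, nPeriods, rate` with one row per
#'   season type that has both overlap and visits.
#' @export
revisitationRate <- function(visitEnters, st, span) {
  ve <- as.numeric(asUTC(visitEnters))
  s0 <- as.numeric(span[1]); s1 <- as.numeric(span[2])
  rows <- list()
  for (season in c("wet", "dry")) {
    per <- seasonPeriods(st, season)
    a <- as.numeric(per$start); b <- as.numeric(per$end)
    frac <- pmax(0, pmin(s1, b) - pmax(s0, a)) / (b - a)
    nPeriods <- sum(frac)
    if (nPeriods <= 0) next
    inSeason <- vapply(ve, function(t) any(t >= a & t <= b), logical(1))
    nVisits <- sum(inSeason)
    if (nVisits == 0L) next
    rows[[season]] <- data.frame(season = season, nVisits = nVisits,
                                 nPeriods = nPeriods,
                                 rate = nVisits / nPeriods)
  }
  if (!length(rows))
    return(data.frame(season = character(0), nVisits = integer(0),
                      nPeriods = numeric(0), rate = numeric(0)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Equal-interval bin means of a response over a covariate
#'
#' The observed covariate range is split into `nBins` equal intervals
#' (final bin right-closed); the mean response per non-empty bin is
#' reported. Binning removes the dominance of heavily populated
#' intermediate covariate values in downstream regressions.
#'
#' @param x covariate values.
#' @param y response values (log revisitation rate).
#' @param nBins number of equal-width bins (default 1000).
#' @return object of class `"binnedTable"`: data frame `centre, meanY,
#'   count` (non-empty bins only) with the bin `edges` as an attribute.
#' @export
binMeans <- function(x, y, nBins = 1000) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) stop("no finite (x, y) pairs")
  if (max(x) <= min(x)) stop("constant covariate: no range to bin")
  edges <- seq(min(x), max(x), length.out = nBins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  agg <- aggregate(y, by = list(bin = bin), FUN = mean)
  cnt <- as.vector(table(bin)[as.character(agg$bin)])
  out <- data.frame(centre = (edges[agg$bin] + edges[agg$bin + 1]) / 2,
                    meanY = agg$x, count = cnt)
  attr(out, "edges") <- edges
  class(out) <- c("binnedTable", "data.frame")
  out
}

#' Quadratic regression on a binned table
#'
#' Ordinary least squares of the per-bin mean response on the bin centre and
#' its square; the curvature (the `x^2` coefficient) is the quantity of
#' interest for hump-shaped covariate responses.
#'
#' @param bt a `"binnedTable"` from [binMeans()] with at least 3 non-empty
#'   bins.
#' @return list with `coef` (named `x`, `x2`), `intercept`, `r2` and the
#'   `lm` fit.
#' @export
quadRegression <- function(bt) {
  if (nrow(bt) < 3L) stop("need at least 3 non-empty bins")
  fit <- lm(meanY ~ centre + I(centre^2), data = bt)
  list(coef = c(x = unname(coef(fit)[2]), x2 = unname(coef(fit)[3])),
       intercept = unname(coef(fit)[1]),
       r2 = summary(fit)$r.squared, fit = fit)
}

# ---- mixed-model machinery -------------------------------------------------

termVars <- function(term) {
  if (grepl(":", term, fixed = TRUE)) strsplit(term, ":", fixed = TRUE)[[1]]
  else if (grepl("^I\\(", term)) sub("^I\\((.*)\\^2\\)$", "\\1", term)
  else term
}

termKind <- function(term) {
  if (grepl(":", term, fixed = TRUE)) "interaction"
  else if (grepl("^I\\(", term)) "quadratic"
  else "linear"
}

# Marginality: a quadratic is removed before its linear term, an interaction
# before its main effects. A linear term is removable only when neither its
# quadratic nor any interaction involving it remains.
removableTerms <- function(terms) {
  kinds <- vapply(terms, termKind, character(1))
  rem <- terms[kinds != "linear"]
  for (v in terms[kinds == "linear"]) {
    blocked <- sprintf("I(%s^2)", v) %in% terms ||
      any(vapply(terms[kinds == "interaction"],
                 function(tm) v %in% termVars(tm), logical(1)))
    if (!blocked) rem <- c(rem, v)
  }
  sort(rem)
}

lmmFormula <- function(terms, response = "logRate", group = "individualId") {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  stats::as.formula(sprintf("%s ~ %s + (1 | %s)", response, rhs, group))
}

#' Fit a random-intercept linear mixed model
#'
#' Log revisitation rate on the given fixed-effect terms plus a random
#' intercept per individual. Fitted by maximum likelihood by default (not
#' REML) so AIC values are comparable across fixed-effect structures during
#' selection; the finally chosen model is conventionally refit with REML for
#' reported variance components.
#'
#' @param terms character vector of fixed-effect terms (e.g. `"phos"`,
#'   `"I(phos^2)"`, `"evi:slope"`); empty = intercept-only.
#' @param data data frame with `logRate`, `individualId` and the (scaled)
#'   covariates; at least 2 individuals and 10 rows.
#' @param reml use REML instead of ML.
#' @return object of class `"lmmFit"`: `terms`, `coef` (fixed effects),
#'   `sigmaAlpha2` (random-intercept variance), `sigmaEps2` (residual
#'   variance), `sigmaF2` (variance of the fixed-effect predictor over the
#'   data), `loglik`, `aic`, `n`, `converged`, and the underlying `model`.
#' @export
fitLmm <- function(terms, data, reml = FALSE) {
  if (length(unique(data$individualId)) < 2L)
    stop("need at least 2 individuals for a random intercept")
  if (nrow(data) < 10L) stop("need at least 10 rows")
  warned <- FALSE
  fit <- withCallingHandlers(
    lme4::lmer(lmmFormula(terms), data = data, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  vc <- lme4::VarCorr(fit)
  fixedPred <- predict(fit, re.form = NA)
  out <- list(terms = terms, coef = lme4::fixef(fit),
              sigmaAlpha2 = as.numeric(vc$individualId),
              sigmaEps2 = stats::sigma(fit)^2,
              sigmaF2 = var(fixedPred),
              loglik = as.numeric(logLik(fit)), aic = AIC(fit),
              n = nrow(data), converged = !warned, model = fit)
  class(out) <- "lmmFit"
  out
}

#' @export
print.lmmFit <- function(x, ...) {
  cat(sprintf("lmmFit: %d fixed term(s), AIC %.2f, n = %d%s\n",
              length(x$terms), x$aic, x$n,
              if (x$converged) "" else " (convergence flagged)"))
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = " + ")
      else "(intercept only)", "\n")
  cat(sprintf("  var: fixed %.3f, individual %.3f, residual %.3f\n",
              x$sigmaF2, x$sigmaAlpha2, x$sigmaEps2))
  invisible(x)
}

#' Marginal and conditional R-squared for mixed models
#'
#' Variance-component formulation: the marginal R2 is the fixed-effect
#' predictor variance over the total, the conditional R2 adds the
#' random-intercept variance to the numerator, so Rm2 <= Rc2 always.
#'
#' @param fit an `"lmmFit"`, or a numeric vector
#'   `c(sigmaF2, sigmaAlpha2, sigmaEps2)`.
#' @return named numeric `c(Rm2, Rc2)`.
#' @export
nakagawaR2 <- function(fit) {
  v <- if (inherits(fit, "lmmFit"))
    c(fit$sigmaF2, fit$sigmaAlpha2, fit$sigmaEps2)
  else as.numeric(fit)
  stopifnot(length(v) == 3L)
  tot <- sum(v)
  if (tot <= 0) stop("all variance components are zero: R2 undefined")
  c(Rm2 = v[1] / tot, Rc2 = (v[1] + v[2]) / tot)
}

#' Stratified resample over covariate gradients
#'
#' Each focal variable's observed range is cut into `nStrata` equal-width
#' strata; every non-empty stratum contributes `perStratum` rows (drawn
#' without replacement when the stratum is large enough, with replacement
#' otherwise). The union over focal variables is deduplicated. This flattens
#' the data density over the environmental gradients so model fits are not
#' dominated by the heavily populated intermediate values.
#'
#' @param data data frame.
#' @param focalVars column names to stratify over.
#' @param nStrata strata per variable.
#' @param perStratum rows drawn per non-empty stratum.
#' @param seed RNG seed.
#' @return row subset of `data`.
#' @export
stratifiedResample <- function(data, focalVars, nStrata = 10, perStratum = 50,
                               seed = NULL) {
  stopifnot(nrow(data) > 0, all(focalVars %in% names(data)))
  withSeed(seed, {
    take <- integer(0)
    for (v in focalVars) {
      x <- data[[v]]
      edges <- seq(min(x), max(x), length.out = nStrata + 1)
      s <- findInterval(x, edges, rightmost.closed = TRUE)
      for (k in unique(s)) {
        ix <- which(s == k)
        take <- c(take, if (length(ix) >= perStratum)
          sample(ix, perStratum) else sample(ix, perStratum, replace = TRUE))
      }
    }
    data[sort(unique(take)), , drop = FALSE]
  })
}

termSetKey <- function(terms) {
  if (!length(terms)) return("(intercept)")
  paste(sort(terms), collapse = " + ")
}

#' Backward AIC selection with the 2-delta-AIC parsimony rule
#'
#' Starting from the full fixed-effect structure, repeatedly removes the
#' single removable term whose removal lowers AIC the most (respecting
#' marginality: quadratics before their linear terms, interactions before
#' their main effects) until no removal lowers AIC. Among all models
#' visited on the path whose AIC is within 2 units of the best, the one
#' with the fewest fixed-effect terms is chosen (AIC/term-count ties break
#' deterministically by lexicographic term order). The chosen model is
#' refit by REML for reported variance components, and its marginal and
#' conditional R2 are averaged over `nRep` stratified resamples.
#'
#' @param fullTerms character vector of candidate fixed-effect terms.
#' @param data modelling data frame (see [fitLmm()]); when `resample` is
#'   given, selection runs on one stratified resample of it.
#' @param resample `NULL`, or a list with `focalVars`, `nStrata`,
#'   `perStratum` passed to [stratifiedResample()].
#' @param nRep number of stratified resamples for the R2 mean +/- SD
#'   (ignored when `resample` is `NULL`: R2 is then computed once on the
#'   selection data).
#' @param seed RNG seed (drives the resamples).
#' @return object of class `"selectionResult"`: `visited` (term set, number
#'   of terms, AIC, delta AIC per visited model), `chosenTerms`, `chosenFit`
#'   (REML), `Rm2Mean, Rm2Sd, Rc2Mean, Rc2Sd`, `nRep`.
#' @export
backwardAIC <- function(fullTerms, data, resample = NULL, nRep = 200,
                        seed = NULL) {
  selData <- if (is.null(resample)) data else
    stratifiedResample(data, resample$focalVars,
                       nStrata = resample$nStrata %||% 10,
                       perStratum = resample$perStratum %||% 50,
                       seed = deriveSeed(seed, 1L))
  cache <- new.env(parent = emptyenv())
  fitTerms <- function(terms) {
    key <- termSetKey(terms)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ft <- try(fitLmm(terms, selData), silent = TRUE)
    if (inherits(ft, "try-error")) ft <- NULL
    else if (!ft$converged) {
      warning("non-convergent fit excluded: ", key)
      ft <- NULL
    }
    cache[[key]] <- ft
    ft
  }
  visited <- list()
  note <- function(terms, ft) {
    visited[[termSetKey(terms)]] <<- list(terms = terms, aic = ft$aic)
  }
  current <- sort(fullTerms)
  curFit <- fitTerms(current)
  if (is.null(curFit)) stop("full model failed to fit")
  note(current, curFit)
  repeat {
    cand <- removableTerms(current)
    if (!length(cand)) break
    aics <- rep(NA_real_, length(cand))
    for (i in seq_along(cand)) {
      ft <- fitTerms(setdiff(current, cand[i]))
      if (!is.null(ft)) {
        aics[i] <- ft$aic
        note(setdiff(current, cand[i]), ft)
      }
    }
    if (all(is.na(aics))) break
    best <- which.min(aics) # first (lexicographically smallest) on ties
    if (aics[best] < curFit$aic) {
      current <- setdiff(current, cand[best])
      curFit <- fitTerms(current)
    } else break
  }
  vis <- data.frame(
    terms = vapply(visited, function(v) termSetKey(v$terms), character(1)),
    k = vapply(visited, function(v) length(v$terms), integer(1)),
    aic = vapply(visited, function(v) v$aic, numeric(1)),
    row.names = NULL)
  vis$dAIC <- vis$aic - min(vis$aic)
  vis <- vis[order(vis$aic, vis$k, vis$terms), , drop = FALSE]
  elig <- vis[vis$dAIC <= 2, , drop = FALSE]
  elig <- elig[order(elig$k, elig$aic, elig$terms), , drop = FALSE]
  chosenKey <- elig$terms[1]
  chosenTerms <- visited[[chosenKey]]$terms
  chosenAic <- visited[[chosenKey]]$aic # ML scale, comparable to `visited`
  chosenFit <- fitLmm(chosenTerms, selData, reml = TRUE)
  if (is.null(resample) || nRep < 2) {
    r2 <- nakagawaR2(chosenFit)
    r2m <- r2["Rm2"]; r2c <- r2["Rc2"]; r2mSd <- NA_real_; r2cSd <- NA_real_
    nRepUsed <- 1L
  } else {
    rm2 <- rc2 <- numeric(nRep)
    for (r in seq_len(nRep)) {
      ds <- stratifiedResample(data, resample$focalVars,
                               nStrata = resample$nStrata %||% 10,
                               perStratum = resample$perStratum %||% 50,
                               seed = deriveSeed(seed, 100L + r))
      ft <- try(fitLmm(chosenTerms, ds, reml = TRUE), silent = TRUE)
      if (inherits(ft, "try-error")) { rm2[r] <- NA; rc2[r] <- NA; next }
      r2 <- nakagawaR2(ft)
      rm2[r] <- r2["Rm2"]; rc2[r] <- r2["Rc2"]
    }
    r2m <- mean(rm2, na.rm = TRUE); r2mSd <- sd(rm2, na.rm = TRUE)
    r2c <- mean(rc2, na.rm = TRUE); r2cSd <- sd(rc2, na.rm = TRUE)
    nRepUsed <- nRep
  }
  out <- list(visited = vis, chosenTerms = chosenTerms, chosenAic = chosenAic,
              chosenFit = chosenFit,
              Rm2Mean = unname(r2m), Rm2Sd = unname(r2mSd),
              Rc2Mean = unname(r2c), Rc2Sd = unname(r2cSd),
              nRep = nRepUsed, seed = seed)
  class(out) <- "selectionResult"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.selectionResult <- function(x, ...) {
  cat(sprintf("selectionResult: %d model(s) visited, chosen (%d term(s)):\n",
              nrow(x$visited), length(x$chosenTerms)))
  cat("  ", if (length(x$chosenTerms))
    paste(x$chosenTerms, collapse = " + ") else "(intercept only)", "\n")
  cat(sprintf("  Rm2 = %.3f +/- %s, Rc2 = %.3f +/- %s (%d resample(s))\n",
              x$Rm2Mean, format(x$Rm2Sd, digits = 2), x$Rc2Mean,
              format(x$Rc2Sd, digits = 2), x$nRep))
  invisible(x)
}

#' Add allow-listed interactions to a selected model
#'
#' Augments the chosen base model with pairwise interactions from the
#' allow-list (interactions are considered only between variables whose
#' main effects survived base selection; others are skipped with a warning,
#' respecting marginality), then re-runs backward AIC selection on the
#' augmented term set. An empty allow-list returns the base selection
#' unchanged.
#'
#' @param base a `"selectionResult"` from [backwardAIC()].
#' @param allowList list of character pairs, e.g.
#'   `list(c("evi", "slope"), c("dw", "phos"))`. The default is the
#'   ecologically motivated set: EVI x slope, water x slope,
#'   EVI x phosphorus, water x phosphorus.
#' @param data,resample,nRep,seed as in [backwardAIC()].
#' @return a `"selectionResult"`.
#' @export
addInteractions <- function(base, data,
                            allowList = list(c("evi", "slope"),
                                             c("dw", "slope"),
                                             c("evi", "phos"),
                                             c("dw", "phos")),
                            resample = NULL, nRep = 200, seed = NULL) {
  stopifnot(inherits(base, "selectionResult"))
  if (!length(allowList)) return(base)
  ints <- character(0)
  for (pr in allowList) {
    pr <- sort(pr)
    if (!all(pr %in% base$chosenTerms)) {
      warning("skipping interaction ", paste(pr, collapse = ":"),
              ": main effect(s) not in the base model")
      next
    }
    ints <- c(ints, paste(pr, collapse = ":"))
  }
  if (!length(ints)) return(base)
  backwardAIC(c(base$chosenTerms, ints), data, resample = resample,
              nRep = nRep, seed = seed)
}
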