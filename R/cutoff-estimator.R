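# Positive draws from N(mean, sd): rejection-resample any non-positive
# values. With all default components P(X < 0) < 0.01, so the loop
# almost never runs more than once.
.rtruncpos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Crossing point of two weighted normal densities
#'
#' Solves `w1 * N(x; mu1, sd1) = w2 * N(x; mu2, sd2)` for the
#' classification boundary between the two components: the crossing at
#' which the weighted density advantage switches from the lower to the
#' upper component. For equal standard deviations the log-density
#' equality is linear in `x` with a single root; for unequal standard
#' deviations it is quadratic and the root where the lower component
#' dominates below and the upper dominates above is selected (for
#' ordinary adjacent-subpopulation geometry this root lies between the
#' two means). This is the theoretical boundary that the Monte Carlo
#' route [mcCutoffs()] estimates.
#'
#' @param w1,w2 positive component weights.
#' @param mu1,mu2 component means with `mu1 < mu2`.
#' @param sd1,sd2 positive component standard deviations.
#'
#' @return The crossing volume (um^3). If one weighted density
#'   dominates everywhere (extreme weight/variance imbalance) there is
#'   no boundary and an error of class `boutonsort_no_crossing` is
#'   raised, reporting any tangency root.
#' @examples
#' analyticCrossing(0.5, 0, 1, 0.5, 2, 1)       # 1 by symmetry
#' analyticCrossing(0.9, 0, 1, 0.1, 2, 1)       # 1 + log(9)/2
#' @export
analyticCrossing <- function(w1, mu1, sd1, w2, mu2, sd2) {
  stopifnot(w1 > 0, w2 > 0, sd1 > 0, sd2 > 0)
  if (!(mu1 < mu2)) stop("mu1 must be < mu2", call. = FALSE)
  # log w1 - log sd1 - (x-mu1)^2/(2 sd1^2) = log w2 - log sd2 - (x-mu2)^2/(2 sd2^2)
  # => (x-mu2)^2/sd2^2 - (x-mu1)^2/sd1^2 + C = 0 with
  C <- 2 * (log(w1) - log(sd1) - log(w2) + log(sd2))
  if (sd1 == sd2) {
    # linear: 2x(mu1 - mu2) + mu2^2 - mu1^2 + sd^2 * C = 0;
    # with equal sds the nearer component dominates each tail, so the
    # single root is always a valid boundary
    return((mu2^2 - mu1^2 + sd1^2 * C) / (2 * (mu2 - mu1)))
  }
  a <- 1 / sd2^2 - 1 / sd1^2
  b <- 2 * (mu1 / sd1^2 - mu2 / sd2^2)
  cc <- mu2^2 / sd2^2 - mu1^2 / sd1^2 + C
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) # one density dominates everywhere (or mere tangency)
    stop(.noCrossingError(if (disc == 0) -b / (2 * a) else numeric(0),
                          mu1, mu2))
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  # boundary root: lower component dominates just below it, upper just
  # above (the wider component dominates both tails, so exactly one of
  # the two roots qualifies)
  logdiff <- function(x)
    log(w1) - log(sd1) - (x - mu1)^2 / (2 * sd1^2) -
      (log(w2) - log(sd2) - (x - mu2)^2 / (2 * sd2^2))
  for (r in roots) {
    d <- 1e-7 * (abs(r) + 1)
    if (logdiff(r - d) > 0 && logdiff(r + d) < 0) return(r)
  }
  stop(.noCrossingError(roots, mu1, mu2))
}

.noCrossingError <- function(roots, mu1, mu2) {
  structure(
    class = c("boutonsort_no_crossing", "error", "condition"),
    list(message = sprintf(
      "no density crossing in (%g, %g); roots: %s", mu1, mu2,
      if (length(roots)) paste(signif(roots, 6), collapse = ", ")
      else "none (negative discriminant)"),
      call = NULL, roots = roots))
}

# Minimum-misclassification threshold between two samples known to come
# from the lower (x1) and upper (x2) component. Candidate thresholds are
# the midpoints of consecutive sorted pooled values, restricted to lie
# between the two sample means (a subpopulation boundary lives between
# the subpopulation centres); when several thresholds tie at the
# minimum, the midpoint of the tying plateau is returned.
.minMisclassCut <- function(x1, x2) {
  n1 <- length(x1)
  x <- c(x1, x2)
  low <- c(rep(TRUE, n1), rep(FALSE, length(x2)))
  o <- order(x)
  x <- x[o]
  low <- low[o]
  m <- length(x)
  cum1 <- cumsum(low)
  j <- seq_len(m - 1L)
  # below threshold -> lower class: errors = upper points below + lower above
  err <- (j - cum1[j]) + (n1 - cum1[j])
  mid <- (x[j] + x[j + 1L]) / 2
  inside <- mid > mean(x1) & mid < mean(x2)
  if (!any(inside)) return((mean(x1) + mean(x2)) / 2)
  err <- err[inside]
  mid <- mid[inside]
  best <- which(err == min(err))
  (mid[best[1L]] + mid[best[length(best)]]) / 2
}

# Per-iteration density-crossing estimate: weighted normal crossing from
# the simulated samples' empirical moments (relative sizes fixed by
# design). Falls back to the midpoint of the sample means when the
# moment densities do not cross, or cross outside the pooled sample
# range (rare, tiny samples).
.momentCrossingCut <- function(x1, x2, w1, w2) {
  m1 <- mean(x1); m2 <- mean(x2)
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  r <- tryCatch(analyticCrossing(w1, m1, s1, w2, m2, s2),
                boutonsort_no_crossing = function(e) NA_real_)
  if (is.na(r) || r < min(x1) || r > max(x2)) (m1 + m2) / 2 else r
}

#' Monte Carlo estimation of subpopulation volume cutoffs
#'
#' Implements the resampling estimate of the classification boundary
#' between each pair of adjacent mixture components. Per iteration,
#' component `i` is simulated with `multiplier * round(w_i * n)`
#' positive (zero-truncated) normal draws, keeping the relative
#' subpopulation sizes constant, and a cutoff between each pair of
#' adjacent components is computed from the two simulated samples. Two
#' per-iteration cutoff definitions are provided:
#' `"moment_crossing"` (default) takes the weighted-density crossing of
#' normals with the samples' empirical means and SDs; `"min_misclass"`
#' scans the midpoints of the sorted pooled sample for the threshold
#' minimising total misclassification, restricted to thresholds between
#' the two sample means, resolving ties at the plateau midpoint (an
#' unrestricted scan degenerates when adjacent subpopulation sizes are
#' very unequal - see the vignette). The reported boundary is the mean
#' over `R` iterations, with the across-iteration SD alongside.
#'
#' @param fit a [MixtureFit-class] (or [MixtureSpec-class], in which
#'   case `n` must be given) with at least two components.
#' @param R number of Monte Carlo iterations (default 10,000).
#' @param multiplier simulated-size multiplier (default 5).
#' @param seed integer seed.
#' @param n sample size used to derive cluster sizes; defaults to the
#'   fit's own `n`. Required when `fit` is a MixtureSpec.
#' @param family family label to record on the result; defaults to the
#'   spec's family, or `"DNM"` for a bare fit.
#' @param perIteration per-iteration cutoff definition,
#'   `"moment_crossing"` (default) or `"min_misclass"`.
#'
#' @return A [CutoffSet-class] with `k - 1` boundaries.
#' @seealso [analyticCrossing()] for the closed-form boundary the Monte
#'   Carlo mean converges to.
#' @export
mcCutoffs <- function(fit, R = 10000L, multiplier = 5L, seed = 1L,
                      n = NULL, family = NULL,
                      perIteration = c("moment_crossing",
                                       "min_misclass")) {
  perIteration <- match.arg(perIteration)
  if (is(fit, "MixtureSpec")) {
    if (is.null(n))
      stop("n is required when fit is a MixtureSpec", call. = FALSE)
    w <- fit@weight; mu <- fit@mean; sigma <- fit@sd
    if (is.null(family)) family <- fit@family
  } else if (is(fit, "MixtureFit")) {
    if (is.null(n)) n <- fit@n
    w <- fit@weight; mu <- fit@mean; sigma <- fit@sd
    if (is.null(family)) family <- "DNM"
  } else stop("fit must be a MixtureFit or MixtureSpec", call. = FALSE)
  k <- length(w)
  if (k < 2L) stop("at least two components required", call. = FALSE)
  R <- as.integer(R)
  multiplier <- as.integer(multiplier)
  if (R < 1L) stop("R must be >= 1", call. = FALSE)
  base <- round(w * n)
  if (any(base < 2))
    stop("component cluster size < 2 after rounding; increase n",
         call. = FALSE)
  sizes <- multiplier * base

  rng <- .seededRNG(seed)
  cuts <- matrix(NA_real_, R, k - 1L)
  rng$run({
    for (it in seq_len(R)) {
      draws <- lapply(seq_len(k), function(i)
        .rtruncpos(sizes[i], mu[i], sigma[i]))
      for (i in seq_len(k - 1L))
        cuts[it, i] <- if (perIteration == "min_misclass")
          .minMisclassCut(draws[[i]], draws[[i + 1L]])
        else
          .momentCrossingCut(draws[[i]], draws[[i + 1L]],
                             w[i], w[i + 1L])
    }
  })
  new("CutoffSet",
      family = family,
      boundaries = colMeans(cuts),
      method = "monte_carlo", iterations = R,
      multiplier = multiplier,
      boundarySD = apply(cuts, 2L, stats::sd))
}

#' Analytic cutoff set for a mixture
#'
#' Convenience wrapper computing the weighted-density crossing of every
#' adjacent component pair of a spec or fit.
#'
#' @param fit a [MixtureFit-class] or [MixtureSpec-class] with `k >= 2`.
#' @param family family label to record; defaults to the spec's family,
#'   or `"DNM"` for a bare fit.
#' @return A [CutoffSet-class] with `method = "analytic"`.
#' @export
analyticCutoffs <- function(fit, family = NULL) {
  w <- fit@weight; mu <- fit@mean; sigma <- fit@sd
  k <- length(w)
  if (k < 2L) stop("at least two components required", call. = FALSE)
  b <- vapply(seq_len(k - 1L), function(i)
    analyticCrossing(w[i], mu[i], sigma[i],
                     w[i + 1L], mu[i + 1L], sigma[i + 1L]), 0)
  if (is.null(family))
    family <- if (is(fit, "MixtureSpec")) fit@family else "DNM"
  new("CutoffSet",
      family = family,
      boundaries = b, method = "analytic", iterations = 1L,
      multiplier = 1L, boundarySD = rep(NA_real_, k - 1L))
}

#' Apply family cutoff sets to a bouton table
#'
#' Pipeline wiring: classifies each bouton into its family by
#' mitochondria class and into a volume-sorted subpopulation by the
#' family's cutoff set. Delegates to [assignFamily()],
#' [assignSubpopulation()] and [mapOrigin()].
#'
#' @param boutons data.frame with columns `volume` and `mito_class`.
#' @param cutoffsLM,cutoffsDNM [CutoffSet-class] objects for the two
#'   families.
#' @return `boutons` with `family`, `subpop` and `putative_origin`
#'   columns appended.
#' @export
applyCutoffs <- function(boutons, cutoffsLM, cutoffsDNM) {
  classifyBoutons(boutons, cutoffsLM, cutoffsDNM)
}
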