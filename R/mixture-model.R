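# Variance floor (um^6) guarding against singular components during EM.
.varianceFloor <- function() 1e-6

# Log-density matrix (n x k) of x under each weighted component,
# computed on the log scale for numerical stability.
.logDens <- function(x, w, mu, sigma) {
  k <- length(w)
  ld <- matrix(0, length(x), k)
  cst <- log(w) - log(sigma) - 0.5 * log(2 * pi)
  for (j in seq_len(k))
    ld[, j] <- cst[j] - 0.5 * ((x - mu[j]) / sigma[j])^2
  ld
}

# Row-wise log-sum-exp without apply(): column-looped pmax is much
# faster for the small k used here.
.logSumExpRows <- function(m) {
  mx <- m[, 1L]
  k <- ncol(m)
  if (k > 1L) for (j in 2:k) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

#' Fit a one-dimensional Gaussian mixture by expectation-maximisation
#'
#' Maximum-likelihood fit of a `k`-component univariate normal mixture
#' to bouton volumes. Either every component has its own variance
#' (`"free"`) or all components share one variance (`"equal"`). The fit
#' is the best of `restarts` seeded runs, each initialised by spreading
#' the component means over the sample quantiles with a small seeded
#' jitter. EM stops when the relative log-likelihood change falls below
#' `1e-8` or after 1,000 iterations. Components are returned sorted by
#' ascending mean, and the BIC is computed as `2 * loglik - p * log(n)`
#' (higher is better).
#'
#' @param volumes numeric vector of positive, finite volumes (um^3).
#' @param k number of components.
#' @param varianceModel `"free"` (default) or `"equal"`.
#' @param seed integer seed; all restart randomness derives from it.
#' @param restarts number of seeded restarts (default 10).
#' @param traceLik keep the per-iteration log-likelihood trace of the
#'   winning restart as attribute `"likTrace"` (default FALSE).
#'
#' @return A [MixtureFit-class] object.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(50, 1, 0.1), rnorm(50, 5, 0.4))
#' fitEM(x, k = 2, seed = 1)
#' @export
fitEM <- function(volumes, k, varianceModel = c("free", "equal"),
                  seed = 1L, restarts = 10L, traceLik = FALSE) {
  varianceModel <- match.arg(varianceModel)
  x <- as.numeric(volumes)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("volumes must be finite and strictly positive", call. = FALSE)
  n <- length(x)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (n < 2L * k)
    stop(sprintf("insufficient data: n = %d < 2k = %d", n, 2L * k),
         call. = FALSE)
  if (k > 1L && stats::var(x) == 0)
    stop("degenerate fit: all volumes identical with k > 1", call. = FALSE)

  if (k == 1L) {
    mu <- mean(x)
    v <- max(mean((x - mu)^2), .varianceFloor())
    ll <- sum(stats::dnorm(x, mu, sqrt(v), log = TRUE))
    return(.newFit(1L, 1, mu, sqrt(v), ll, varianceModel, n, TRUE))
  }

  floorV <- .varianceFloor()
  best <- NULL
  rng <- .seededRNG(seed)
  for (r in seq_len(restarts)) {
    # quantile-spread initialisation: the first restart spreads the
    # means over the full quantile range (so extreme minority clusters
    # get a starting mean), subsequent restarts use sorted random
    # quantiles
    probs <- if (r == 1L) seq(0, 1, length.out = k)
      else sort(rng$runif(k))
    mu <- as.numeric(stats::quantile(x, probs, names = FALSE))
    sigma <- rep(max(stats::sd(x) / k, sqrt(floorV)), k)
    w <- rep(1 / k, k)

    ll.old <- -Inf
    converged <- FALSE
    x2 <- x * x
    trace <- if (traceLik) numeric() else NULL
    for (it in seq_len(1000L)) {
      ld <- .logDens(x, w, mu, sigma)
      rowlse <- .logSumExpRows(ld)
      ll <- sum(rowlse)
      if (traceLik) trace <- c(trace, ll)
      resp <- exp(ld - rowlse)
      nk <- .colSums(resp, n, k)
      if (any(nk < 1e-12)) { # empty component; reseed its mean
        idx <- which(nk < 1e-12)
        mu[idx] <- rng$runif(length(idx), min(x), max(x))
        next
      }
      w <- nk / n
      sx <- .colSums(resp * x, n, k)
      sx2 <- .colSums(resp * x2, n, k)
      mu <- sx / nk
      # within-component second moments without outer(): E[x^2] - mu^2
      vk <- pmax(sx2 / nk - mu^2, 0)
      if (varianceModel == "free") {
        sigma <- sqrt(pmax(vk, floorV))
      } else {
        v <- sum(vk * nk) / n
        sigma <- rep(sqrt(max(v, floorV)), k)
      }
      if (is.finite(ll.old) &&
          abs(ll - ll.old) < 1e-8 * (abs(ll.old) + 1e-12)) {
        converged <- TRUE
        break
      }
      ll.old <- ll
    }
    ld <- .logDens(x, w, mu, sigma)
    ll <- sum(.logSumExpRows(ld))
    if (is.null(best) || ll > best$ll)
      best <- list(w = w, mu = mu, sigma = sigma, ll = ll,
                   converged = converged, trace = trace)
  }
  o <- order(best$mu)
  fit <- .newFit(k, best$w[o], best$mu[o], best$sigma[o], best$ll,
                 varianceModel, n, best$converged)
  if (traceLik) attr(fit, "likTrace") <- best$trace
  fit
}

.newFit <- function(k, w, mu, sigma, ll, varianceModel, n, converged,
                    bicTable = NULL) {
  p <- (k - 1L) + k + if (varianceModel == "free") k else 1L
  bic <- 2 * ll - p * log(n)
  if (is.null(bicTable))
    bicTable <- data.frame(k = integer(), variance_model = character(),
                           bic = numeric(), converged = logical())
  new("MixtureFit", k = as.integer(k), weight = as.numeric(w),
      mean = as.numeric(mu), sd = as.numeric(sigma), loglik = ll,
      bic = bic, varianceModel = varianceModel, n = as.integer(n),
      converged = converged, bicTable = bicTable)
}

#' Select the mixture component count by highest BIC
#'
#' Fits univariate normal mixtures with `k = 1..kMax` components under
#' both the equal-variance and free-variance models and returns the fit
#' with the highest BIC (`2 * loglik - p * log(n)`), together with the
#' full scan table for plotting. Values of `k` for which the sample is
#' too small (`n < 2k`) are skipped.
#'
#' @inheritParams fitEM
#' @param kMax largest component count to consider (default 9).
#'
#' @return A [MixtureFit-class]; `bicTable(fit)` holds the full
#'   `(k, variance model, BIC)` scan.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(120, 1, 0.1), rnorm(80, 4, 0.3))
#' fit <- selectByBIC(x, kMax = 4, seed = 1)
#' nComponents(fit)
#' @export
selectByBIC <- function(volumes, kMax = 9L, seed = 1L, restarts = 10L) {
  kMax <- as.integer(kMax)
  if (kMax < 1L) stop("kMax must be >= 1", call. = FALSE)
  n <- length(volumes)
  fits <- list()
  rows <- list()
  for (k in seq_len(kMax)) {
    if (n < 2L * k) next
    for (vm in c("equal", "free")) {
      fit <- tryCatch(
        fitEM(volumes, k, varianceModel = vm, seed = seed,
              restarts = restarts),
        error = function(e) NULL)
      if (is.null(fit)) next
      fits[[length(fits) + 1L]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, variance_model = vm, bic = fit@bic,
        converged = fit@converged, stringsAsFactors = FALSE)
    }
  }
  if (length(fits) == 0L)
    stop("modeling error: no mixture model could be fitted", call. = FALSE)
  tab <- do.call(rbind, rows)
  best <- fits[[which.max(tab$bic)]]
  best@bicTable <- tab
  best
}

# Small counter-based RNG wrapper: every draw stream derives from one
# explicit seed without touching the global .Random.seed.
.seededRNG <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  run <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) set.seed(as.integer(seed))
    else assign(".Random.seed", env$state, envir = globalenv())
    expr
  }
  list(
    runif = function(n, min = 0, max = 1) run(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(stats::rnorm(n, mean, sd)),
    rpois = function(n, lambda) run(stats::rpois(n, lambda)),
    sample = function(x, size, replace = FALSE, prob = NULL)
      run(sample(x, size, replace, prob)),
    run = run
  )
}
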