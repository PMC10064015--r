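#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared omnibus test combining the transformed sample skewness
#' (D'Agostino's Z of sqrt(b1)) and kurtosis (Anscombe-Glynn's Z of
#' b2); `K2 = Z1^2 + Z2^2` is compared against a chi-squared
#' distribution with 2 degrees of freedom. Requires at least 8
#' observations.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K2), `z_skew`, `z_kurt`, `p.value`.
#' @examples
#' dagostinoPearson(rnorm(100))$p.value
#' @export
dagostinoPearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L)
    stop("at least 8 observations required", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # Z for skewness (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # Z for kurtosis (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - Eb2) / sqrt(Vb2)
  sqrtB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtB1 * (2 / sqrtB1 + sqrt(1 + 4 / sqrtB1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xx * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Z1^2 + Z2^2
  list(statistic = K2, z_skew = Z1, z_kurt = Z2,
       p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Dunn's multiple-comparison test after Kruskal-Wallis
#'
#' Pairwise rank-sum z statistics with tie correction, with p-values
#' adjusted for multiple comparisons (Bonferroni by default, matching
#' the usual post-hoc convention).
#'
#' @param x numeric vector of observations.
#' @param g group labels (coerced to factor).
#' @param method p-adjustment method passed to [stats::p.adjust()].
#' @return data.frame with one row per group pair: `comparison`, `z`,
#'   `p.value`, `p.adjusted`.
#' @export
dunnTest <- function(x, g, method = "bonferroni") {
  g <- factor(g)
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  N <- length(x)
  if (nlevels(g) < 2L)
    stop("at least two groups required", call. = FALSE)
  r <- rank(x)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  meanR <- tapply(r, g, mean)
  nG <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) *
                 (1 / nG[[p[1]]] + 1 / nG[[p[2]]]))
    (meanR[[p[1]]] - meanR[[p[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             z = z, p.value = p,
             p.adjusted = stats::p.adjust(p, method = method),
             stringsAsFactors = FALSE)
}

#' Nonparametric comparison wrappers
#'
#' Thin convenience wrappers around the standard nonparametric tests
#' used throughout the analysis: two-sample Mann-Whitney U
#' ([stats::wilcox.test()]), Kruskal-Wallis ([stats::kruskal.test()])
#' followed by Dunn's multiple comparisons, and the D'Agostino-Pearson
#' omnibus normality test.
#'
#' @param samples named list of numeric vectors (one per group), or a
#'   single numeric vector for the normality test.
#' @param test one of `"mann_whitney"`, `"kruskal_wallis_dunn"`,
#'   `"dagostino_pearson"`.
#' @return data.frame of statistics and p-values; for
#'   `kruskal_wallis_dunn` the first row is the omnibus test and the
#'   remaining rows the Dunn pairwise comparisons (adjusted p in
#'   `p.value`).
#' @export
nonparametricTests <- function(samples,
                               test = c("mann_whitney",
                                        "kruskal_wallis_dunn",
                                        "dagostino_pearson")) {
  test <- match.arg(test)
  if (is.numeric(samples)) samples <- list(sample = samples)
  ns <- lengths(samples)
  switch(test,
    mann_whitney = {
      if (length(samples) != 2L)
        stop("mann_whitney needs exactly two samples", call. = FALSE)
      if (any(ns < 2L))
        stop("at least 2 observations per sample required",
             call. = FALSE)
      wt <- stats::wilcox.test(samples[[1]], samples[[2]], exact = FALSE)
      data.frame(test = "mann_whitney",
                 comparison = paste(names(samples), collapse = " vs "),
                 statistic = unname(wt$statistic),
                 p.value = wt$p.value, stringsAsFactors = FALSE)
    },
    kruskal_wallis_dunn = {
      if (length(samples) < 2L || any(ns < 2L))
        stop("at least two samples of >= 2 observations required",
             call. = FALSE)
      x <- unlist(samples, use.names = FALSE)
      g <- rep(names(samples), ns)
      kw <- stats::kruskal.test(x, factor(g))
      dn <- dunnTest(x, g)
      rbind(
        data.frame(test = "kruskal_wallis", comparison = "omnibus",
                   statistic = unname(kw$statistic),
                   p.value = kw$p.value, stringsAsFactors = FALSE),
        data.frame(test = "dunn", comparison = dn$comparison,
                   statistic = dn$z, p.value = dn$p.adjusted,
                   stringsAsFactors = FALSE))
    },
    dagostino_pearson = {
      if (any(ns < 8L))
        stop("at least 8 observations per sample required",
             call. = FALSE)
      do.call(rbind, lapply(names(samples), function(nm) {
        dp <- dagostinoPearson(samples[[nm]])
        data.frame(test = "dagostino_pearson", comparison = nm,
                   statistic = dp$statistic, p.value = dp$p.value,
                   stringsAsFactors = FALSE)
      }))
    })
}
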