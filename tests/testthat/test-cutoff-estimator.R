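test_that("analytic crossing solves symmetric and weighted equal-sd
           cases in closed form", {
  expect_equal(analyticCrossing(0.5, 0, 1, 0.5, 2, 1), 1.0)
  # log-density equality with equal sds: x = 1 + log(9)/2
  expect_equal(analyticCrossing(0.9, 0, 1, 0.1, 2, 1), 1 + log(9) / 2)
})

test_that("unequal-sd crossing agrees with a bisection oracle", {
  cases <- list(
    c(0.4, 1.0, 0.3, 0.6, 2.5, 0.7),
    c(0.7, 0.2, 0.05, 0.3, 0.5, 0.12),
    c(0.1, 3.0, 0.8, 0.9, 8.0, 1.5))
  for (p in cases) {
    f <- function(x)
      p[1] * dnorm(x, p[2], p[3]) - p[4] * dnorm(x, p[5], p[6])
    oracle <- uniroot(f, c(p[2], p[5]), tol = 1e-12)$root
    expect_equal(
      analyticCrossing(p[1], p[2], p[3], p[4], p[5], p[6]),
      oracle, tolerance = 1e-9)
  }
})

test_that("the weighted closed form handles imbalanced weights and
           absent crossings", {
  # single crossing beyond the upper mean under heavy weight imbalance
  expect_equal(analyticCrossing(0.9, 0, 1, 0.1, 2, 1), 1 + log(9) / 2)
  # extreme imbalance with a wider upper component: it dominates
  # everywhere, so no classification boundary exists
  err <- tryCatch(
    analyticCrossing(1e-9, 0, 0.5, 1 - 1e-9, 0.3, 1),
    boutonsort_no_crossing = function(e) e)
  expect_s3_class(err, "boutonsort_no_crossing")
  expect_match(conditionMessage(err), "no density crossing")
})

test_that("Monte Carlo boundaries match the analytic crossing for a
           symmetric two-component mixture", {
  spec <- MixtureSpec(label = c("a", "b"), weight = c(0.5, 0.5),
                      mean = c(1, 3), sd = c(0.3, 0.3), family = "LM")
  for (m in c("moment_crossing", "min_misclass")) {
    cs <- mcCutoffs(spec, R = 2000, multiplier = 5, seed = 1, n = 200,
                    perIteration = m)
    expect_equal(boundaries(cs), 2.0, tolerance = 0.02)
  }
})

test_that("Monte Carlo boundaries track the analytic crossing within
           2% for two-component fits", {
  spec <- MixtureSpec(label = c("a", "b"), weight = c(0.4, 0.6),
                      mean = c(1, 2.6), sd = c(0.35, 0.5),
                      family = "DNM")
  target <- boundaries(analyticCutoffs(spec))
  cs <- mcCutoffs(spec, R = 2000, multiplier = 5, seed = 2, n = 250)
  expect_equal(boundaries(cs), target, tolerance = 0.02)
})

test_that("a single iteration with a fixed seed is reproducible", {
  spec <- defaultMixtures()$DNM
  a <- mcCutoffs(spec, R = 1, seed = 9, n = 858)
  b <- mcCutoffs(spec, R = 1, seed = 9, n = 858)
  expect_identical(boundaries(a), boundaries(b))
  expect_equal(length(boundaries(a)), 4L)
})

test_that("boundaries scale with a uniform volume rescaling", {
  spec <- defaultMixtures()$LM
  c0 <- boundaries(mcCutoffs(spec, R = 50, seed = 5, n = 190))
  scaled <- MixtureSpec(label = spec@label, weight = spec@weight,
                        mean = 3 * spec@mean, sd = 3 * spec@sd,
                        family = "LM")
  c3 <- boundaries(mcCutoffs(scaled, R = 50, seed = 5, n = 190))
  expect_equal(c3, 3 * c0, tolerance = 1e-10)
  # analytic route scales exactly
  expect_equal(boundaries(analyticCutoffs(scaled)),
               3 * boundaries(analyticCutoffs(spec)))
})

test_that("Monte Carlo error shrinks as iterations grow", {
  spec <- MixtureSpec(label = c("a", "b"), weight = c(0.45, 0.55),
                      mean = c(1, 2.2), sd = c(0.3, 0.4),
                      family = "LM")
  target <- boundaries(analyticCutoffs(spec))
  errAt <- function(R) {
    mean(vapply(1:5, function(s)
      abs(boundaries(mcCutoffs(spec, R = R, seed = s, n = 300)) -
            target), 0))
  }
  expect_lt(errAt(800), errAt(25))
})

test_that("degenerate requests are rejected", {
  spec1 <- MixtureSpec(label = "a", weight = 1, mean = 1, sd = 0.1,
                       family = "LM")
  expect_error(mcCutoffs(spec1, n = 100), "two components")
  spec <- defaultMixtures()$DNM
  expect_error(mcCutoffs(spec, n = 20), "cluster size")
  expect_error(mcCutoffs(spec, R = 0, n = 858), "R must be")
})

test_that("applyCutoffs wires classification onto a bouton table", {
  pop <- rbind(
    generateBoutonPopulation(defaultMixtures()$LM, 200, seed = 1),
    generateBoutonPopulation(defaultMixtures()$DNM, 800, seed = 2))
  specs <- defaultMixtures()
  out <- applyCutoffs(pop, analyticCutoffs(specs$LM),
                      analyticCutoffs(specs$DNM))
  expect_true(all(c("family", "subpop", "putative_origin") %in%
                    names(out)))
  expect_equal(nrow(out), 1000L)
})
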