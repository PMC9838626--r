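test_that("hard memberships with one binary covariate reproduce the 2x2 odds ratio", {
  # cells (a, b; c, d) = counts of (phenotype 1|2) x (covariate 0|1)
  a <- 30; b <- 20; c <- 10; d <- 40
  ph <- rep(c(1, 2, 1, 2), times = c(a, b, c, d))
  x <- rep(c(0, 1), times = c(a + b, c + d))
  W <- cbind(ph == 1, ph == 2) + 0
  fit <- weightedMultinomial(W, data.frame(x = x), reference = 1)
  rrr <- fit@coefficients$rrr[fit@coefficients$term == "x"]
  expect_equal(rrr, (a * d) / (b * c), tolerance = 1e-6)
  expect_true(fit@converged)
  row <- fit@coefficients[fit@coefficients$term == "x", ]
  expect_true(row$ciLow < rrr && rrr < row$ciHigh)
})

test_that("hard memberships reduce exactly to unweighted multinomial regression", {
  skip_if_not_installed("nnet")
  set.seed(15)
  n <- 400
  x1 <- rnorm(n); x2 <- rbinom(n, 2, 0.3)  # additive genotype coding
  eta2 <- -0.4 + 0.8 * x1 + 0.5 * x2
  eta3 <- 0.2 - 0.6 * x1 + 0.3 * x2
  pr <- cbind(1, exp(eta2), exp(eta3)); pr <- pr / rowSums(pr)
  y <- apply(pr, 1, function(p) sample(3, 1, prob = p))
  W <- outer(y, 1:3, "==") + 0
  fit <- weightedMultinomial(W, data.frame(x1 = x1, x2 = x2), reference = 1)
  nn <- nnet::multinom(factor(y) ~ x1 + x2, trace = FALSE, reltol = 1e-12)
  expect_equal(unname(matrix(fit@coefficients$estimate, ncol = 2)),
               unname(t(coef(nn))), tolerance = 1e-4)
})

test_that("uninformative memberships give null covariate effects", {
  set.seed(16)
  W <- matrix(1 / 3, 90, 3)
  x <- rnorm(90)
  fit <- weightedMultinomial(W, data.frame(x = x), reference = 1)
  est <- fit@coefficients$estimate[fit@coefficients$term == "x"]
  expect_true(all(abs(est) < 1e-6))
})

test_that("the weighted log-likelihood never decreases across Newton steps", {
  set.seed(18)
  n <- 200
  W <- matrix(runif(n * 3), n, 3); W <- W / rowSums(W)
  x <- rnorm(n)
  fit <- weightedMultinomial(W, data.frame(x = x), reference = 2)
  expect_true(all(diff(fit@trace) >= -1e-9))
  expect_equal(fit@reference, 2L)
  # reference phenotype has no reported rows
  expect_false(2L %in% fit@coefficients$phenotype)
})

test_that("fractional membership weighting shrinks uncertain subjects' influence", {
  set.seed(20)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  ph <- 1 + rbinom(n, 1, plogis(-0.5 + 1.5 * x))
  hard <- outer(ph, 1:2, "==") + 0
  soft <- 0.5 + (hard - 0.5) * 0.2  # heavily flattened memberships
  bh <- weightedMultinomial(hard, data.frame(x = x))@coefficients
  bs <- weightedMultinomial(soft, data.frame(x = x))@coefficients
  eh <- bh$estimate[bh$term == "x"]; es <- bs$estimate[bs$term == "x"]
  expect_lt(abs(es), abs(eh))
  expect_gt(eh * es, 0)  # same direction
})

test_that("DerSimonian-Laird pooling matches hand-computed and single-study cases", {
  m1 <- dlMeta(0.7, 0.2)
  expect_equal(m1@pooled, 0.7)
  expect_equal(m1@tau2, 0)
  expect_equal(m1@ciLow, 0.7 - 1.96 * 0.2)
  expect_equal(m1@ciHigh, 0.7 + 1.96 * 0.2)

  mid <- dlMeta(rep(0.3, 4), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(mid@Q, 0)
  expect_equal(mid@tau2, 0)
  expect_equal(mid@pooled, 0.3)  # inverse-variance mean of equal effects

  m2 <- dlMeta(c(0, 1), c(0.5, 0.5))
  expect_equal(m2@Q, 2, tolerance = 1e-10)
  expect_equal(m2@tau2, 0.25, tolerance = 1e-10)
  expect_equal(m2@pooled, 0.5, tolerance = 1e-10)
  expect_error(dlMeta(c(0, 1), c(0.5, 0)), "positive")
})

test_that("DerSimonian-Laird pooling agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(22)
  for (r in 1:5) {
    y <- rnorm(6, 0.4, 0.3)
    se <- runif(6, 0.1, 0.5)
    mine <- dlMeta(y, se)
    ref <- metafor::rma(yi = y, sei = se, method = "DL")
    expect_equal(mine@pooled, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mine@tau2, ref$tau2, tolerance = 1e-8)
    expect_equal(mine@se, ref$se, tolerance = 1e-8)
    # pooled estimate lies within the range of the study effects
    expect_true(mine@pooled >= min(y) && mine@pooled <= max(y))
  }
})
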