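test_that("a one-class model reduces to independent Bernoulli fits", {
  set.seed(2)
  w <- matrix(rbinom(200 * 5, 1, 0.3), 200, 5)
  fit <- fitLCA(w, 1)
  ph <- colMeans(w)
  expect_equal(as.vector(fit@theta), pmin(pmax(ph, 1e-6), 1 - 1e-6),
               tolerance = 1e-12)
  ll <- sum(w %*% log(ph) + (1 - w) %*% log(1 - ph))
  expect_equal(fit@loglik, ll, tolerance = 1e-8)
  expect_equal(fit@nParams, 5L)
  expect_equal(fit@bic, -2 * ll + 5 * log(200), tolerance = 1e-8)
})

test_that("the EM log-likelihood is monotone on every tested input", {
  set.seed(6)
  for (r in 1:5) {
    w <- matrix(rbinom(300 * 5, 1, runif(1, 0.2, 0.8)), 300, 5)
    fit <- fitLCA(w, 3, nStarts = 3, seed = r)
    expect_true(all(diff(fit@trace) >= -1e-7 * abs(fit@trace[-1])))
  }
  co <- simulateCohort(2000, seed = 14)
  fit <- fitLCA(co, 5, nStarts = 5, seed = 14)
  expect_true(all(diff(fit@trace) >= -1e-7 * abs(fit@trace[-1])))
})

test_that("refits from different seeds agree on well-separated data", {
  # interior, well-identified three-class configuration
  theta <- rbind(c(.9, .9, .9, .1, .1), c(.1, .1, .9, .9, .9),
                 c(.2, .8, .2, .8, .2))
  set.seed(25)
  cls <- sample(3, 4000, TRUE, prob = c(.5, .3, .2))
  w <- matrix(as.integer(matrix(runif(2e4), 4000, 5) < theta[cls, ]), 4000, 5)
  f1 <- fitLCA(w, 3, nStarts = 10, seed = 1)
  f2 <- fitLCA(w, 3, nStarts = 10, seed = 2)
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-4)
  l1 <- lcaPosterior(f1, w)$labels
  l2 <- lcaPosterior(f2, w)$labels
  expect_equal(adjustedRand(l1, l2), 1)
})

test_that("posteriors are proper, sequence-pure and degenerate where expected", {
  co <- simulateCohort(500, seed = 33)
  fit <- fitLCA(co, 4, nStarts = 5, seed = 3)
  post <- lcaPosterior(fit, co)
  expect_true(all(abs(rowSums(post$posterior) - 1) < 1e-10))
  expect_true(all(post$posterior >= 0 & post$posterior <= 1))
  w <- wheezeMatrix(co)
  key <- apply(w, 1, paste, collapse = "")
  for (kk in unique(key)[1:5]) {
    rows <- post$posterior[key == kk, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
  # one-class posterior is trivially 1
  p1 <- lcaPosterior(fitLCA(w, 1), w)
  expect_true(all(p1$posterior == 1))
  expect_true(all(p1$labels == 1))

  # a subject matching a near-degenerate class profile is assigned with certainty
  params <- new("LCAFit", k = 2L, rho = c(0.5, 0.5),
                theta = rbind(rep(1e-6, 5), rep(1 - 1e-6, 5)),
                loglik = 0, bic = 0, nParams = 11L, converged = TRUE,
                trace = 0, nObs = 2L)
  p <- lcaPosterior(params, rbind(rep(0L, 5)))
  expect_gt(p$posterior[1, 1], 0.99)
})

test_that("BIC is minimised at the generating class count on separable data", {
  co <- simulateCohort(10000, seed = 41)
  bics <- sapply(3:7, function(k)
    fitLCA(co, k, nStarts = 10, seed = 41)@bic)
  expect_equal((3:7)[which.min(bics)], 5L)
})

test_that("EM recovers a well-identified three-class mixture", {
  theta <- rbind(c(.9, .9, .9, .1, .1), c(.1, .1, .9, .9, .9),
                 c(.2, .8, .2, .8, .2))
  rho <- c(0.5, 0.3, 0.2)
  set.seed(55)
  cls <- sample(3, 20000, TRUE, prob = rho)
  w <- matrix(as.integer(matrix(runif(1e5), 2e4, 5) < theta[cls, ]), 2e4, 5)
  fit <- fitLCA(w, 3, nStarts = 10, seed = 56)
  p <- match_classes(fit@theta, theta)
  expect_lt(max(abs(fit@theta[p, ] - theta)), 0.02)
  expect_lt(max(abs(fit@rho[p] - rho)), 0.02)
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(fitLCA(matrix(integer(0), 0, 5), 2), "empty")
  expect_error(fitLCA(rbind(c(1, NA, 0, 0, 1)), 2), "complete")
  w <- rbind(c(0L, 0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L, 1L))
  expect_warning(fitLCA(w, 3, nStarts = 2, seed = 1), "distinct sequences")
})
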