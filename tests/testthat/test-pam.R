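line_D <- function() as.matrix(dist(c(0, 1, 2, 10, 11, 12)))

test_that("two clusters on the line example recover the exhaustive optimum", {
  D <- line_D()
  fit <- pamFit(D, 2)
  expect_identical(fit@medoids, c(2L, 5L))  # values 1 and 11
  expect_equal(fit@totalCost, 4)
  expect_equal(fit@totalCost, oracle_pam_opt(D, 2))
  expect_identical(fit@assignment, c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("degenerate cluster counts behave per contract", {
  D <- line_D()
  expect_equal(pamFit(D, 6)@totalCost, 0)   # every point its own medoid
  expect_identical(pamFit(D, 6)@medoids, 1:6)
  f1 <- pamFit(D, 1)
  expect_equal(f1@totalCost, min(colSums(D)))
  expect_error(pamFit(D, 7), "between 1 and")
  expect_error(pamFit(matrix(c(0, 1, 2, 0), 2, 2), 1), "symmetric")
})

test_that("pamFit never beats the exhaustive optimum and is canonical", {
  skip_if_not_installed("cluster")
  set.seed(1)
  for (r in 1:25) {
    D <- as.matrix(dist(matrix(runif(20), 10, 2)))
    for (k in 2:3) {
      fit <- pamFit(D, k)
      opt <- oracle_pam_opt(D, k)
      expect_gte(fit@totalCost, opt - 1e-9)
      # same BUILD+SWAP family as cluster::pam; tie-resolution paths can
      # end in different local optima, so costs agree within a few percent
      cp <- cluster::pam(as.dist(D), k)
      expect_lte(fit@totalCost, cp$objective[["swap"]] * 10 * 1.05 + 1e-9)
    }
  }
})

test_that("total cost is non-increasing across SWAP iterations", {
  set.seed(13)
  for (r in 1:10) {
    D <- as.matrix(dist(matrix(runif(30), 15, 2)))
    tr <- pamFit(D, 3)@trace
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("the fit is invariant to subject permutation up to relabelling", {
  set.seed(17)
  co <- simulateCohort(150, seed = 17)
  D <- mixedDistance(spellFeatures(co))@D
  perm <- sample(nrow(D))
  f1 <- pamFit(D, 5)
  f2 <- pamFit(D[perm, perm], 5)
  expect_equal(adjustedRand(f1@assignment[perm], f2@assignment), 1)
})

test_that("silhouette widths match independent oracles", {
  skip_if_not_installed("cluster")
  D <- line_D()
  fit <- pamFit(D, 2)
  sw <- silhouetteWidth(D, fit@assignment)
  expect_equal(sw$widths, oracle_silhouette(D, fit@assignment),
               tolerance = 1e-12)
  cs <- cluster::silhouette(fit@assignment, dmatrix = D)
  expect_equal(sw$widths, unname(cs[, "sil_width"]), tolerance = 1e-12)
  expect_true(sw$average >= -1 && sw$average <= 1)

  # two tight, far-separated blobs
  x <- c(rnorm(10, 0, 0.01), rnorm(10, 100, 0.01))
  Db <- as.matrix(dist(x))
  expect_gt(silhouetteWidth(Db, rep(1:2, each = 10))$average, 0.9)

  # a point equidistant between its own and the other cluster
  De <- as.matrix(dist(c(0, 0, 2, 4, 4)))
  expect_equal(silhouetteWidth(De, c(1, 1, 1, 2, 2))$widths[3], 0)
  expect_error(silhouetteWidth(D, rep(1, 6)), "two clusters")
})

test_that("cluster-number selection works on the line example under both criteria", {
  D <- line_D()
  expect_equal(selectK(D, 2:4, criterion = "silhouette")$kStar, 2L)
  sel <- selectK(D, 2:4)
  expect_equal(sel$kStar, 2L)
  expect_identical(colnames(sel$diagnostics),
                   c("k", "totalCost", "avgSilhouette", "elbow"))
  expect_error(selectK(D, integer(0)), "empty")
  expect_error(selectK(D, 1:3), "2..n")
})

test_that("selection still returns an argmax on structureless data", {
  set.seed(23)
  D <- as.matrix(dist(matrix(runif(40), 20, 2)))
  sel <- selectK(D, 2:4, criterion = "silhouette")
  expect_true(sel$kStar %in% 2:4)
  expect_equal(sel$kStar,
               sel$diagnostics$k[which.max(sel$diagnostics$avgSilhouette)])
})

test_that("nearest-medoid assignment is consistent and breaks ties low", {
  co <- simulateCohort(200, seed = 19)
  metric <- mixedDistance(spellFeatures(co))
  fit <- pamFit(metric, 4)
  # training items reproduce the fit's own assignment
  cross <- metric@D[, fit@medoids, drop = FALSE]
  expect_identical(as.integer(assignNearestMedoid(cross)), fit@assignment)
  # a medoid lands in its own cluster
  expect_equal(assignNearestMedoid(cross[fit@medoids[2], , drop = FALSE]), 2L)
  # exact tie goes to the lowest medoid index
  expect_equal(assignNearestMedoid(matrix(c(0.5, 0.5, 0.9), 1)), 1L)
})
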