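test_that("complete data yields identical copies and hard consensus memberships", {
  co <- simulateCohort(300, seed = 51)
  ens <- imputeChained(co, M = 4, seed = 1)
  for (m in 1:4)
    expect_identical(wheezeMatrix(ens@tables[[m]]), wheezeMatrix(co))
  cons <- consensusCluster(co, M = 3, seed = 2, kRange = 3:6)
  expect_true(all(membership(cons) %in% c(0, 1)))
  expect_true(all(cons@certainty == 1))
  # and reduces exactly to a single pipeline run
  single <- selectK(mixedDistance(spellFeatures(co)), 3:6)
  expect_equal(cons@kStar, single$kStar)
  expect_equal(adjustedRand(clusterLabels(cons),
                            clusterLabels(single$fits[[paste0("k", single$kStar)]])), 1)
})

test_that("imputation is reproducible and never alters observed cells", {
  co <- simulateCohort(800, seed = 52, missingRate = 0.15)
  e1 <- imputeChained(co, M = 3, seed = 9, cycles = 3)
  e2 <- imputeChained(co, M = 3, seed = 9, cycles = 3)
  w <- wheezeMatrix(co)
  obs <- !is.na(w)
  for (m in 1:3) {
    wm <- wheezeMatrix(e1@tables[[m]])
    expect_false(anyNA(wm))
    expect_identical(wm[obs], w[obs])
    expect_identical(wm, wheezeMatrix(e2@tables[[m]]))
  }
})

test_that("MCAR imputation preserves per-epoch marginal frequencies", {
  co <- simulateCohort(10000, seed = 53, missingRate = 0.2,
                       maxMissingPerSubject = 3L)
  ens <- imputeChained(co, M = 2, seed = 10, cycles = 5)
  w <- wheezeMatrix(co)
  miss <- is.na(w)
  for (m in 1:2) {
    wm <- wheezeMatrix(ens@tables[[m]])
    for (j in 1:5) {
      if (sum(miss[, j]) < 200) next
      expect_lt(abs(mean(wm[miss[, j], j]) - mean(w[!miss[, j], j])), 0.03)
    }
  }
})

test_that("imputation rejects unidentifiable inputs", {
  w <- rbind(a = c(NA, NA, NA, NA, NA), b = c(0L, 1L, 0L, 0L, 1L))
  expect_error(imputeChained(make_cohort(w), M = 2, seed = 1),
               "no observed epoch")
  w2 <- rbind(a = c(NA, 1L, 0L, 0L, 1L), b = c(NA, 1L, 0L, 0L, 1L))
  expect_error(imputeChained(make_cohort(w2), M = 2, seed = 1),
               "no observed values")
})

test_that("label alignment recovers known permutations", {
  ref <- c(1L, 1L, 2L, 2L, 3L, 3L)
  renamed <- c(2L, 2L, 3L, 3L, 1L, 1L)  # cyclic rename of ref
  al <- alignLabels(list(renamed), ref)
  expect_identical(al$aligned[[1]], ref)
  expect_equal(sum(al$aligned[[1]] == ref), 6)
  # self-alignment is the identity permutation
  self <- alignLabels(list(ref), ref)
  expect_identical(self$permutations[[1]], 1:3)
  expect_error(alignLabels(list(ref[1:4]), ref), "same length")
})

test_that("alignment maximises agreement over all permutations of a known overlap", {
  # 3-cluster toy with a known optimal matching, verified by hand:
  # result label 1 mostly ref 2, label 2 mostly ref 3, label 3 mostly ref 1
  ref <- c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3)
  res <- c(3, 3, 3, 1, 1, 1, 1, 2, 2, 1)
  al <- alignLabels(list(res), ref)
  expect_identical(al$permutations[[1]], c(2L, 3L, 1L))
  expect_equal(sum(al$aligned[[1]] == ref), 8)
  # brute force over all 3! permutations agrees
  perms <- spellclust:::permutations_of(3)
  agree <- apply(perms, 1, function(p) sum(p[res] == ref))
  expect_equal(sum(al$aligned[[1]] == ref), max(agree))
})

test_that("consensus with M = 1 equals a single-imputation pipeline run", {
  co <- simulateCohort(400, seed = 54, missingRate = 0.1)
  cons <- consensusCluster(co, M = 1, seed = 7, kRange = 3:6)
  ens <- imputeChained(co, M = 1, seed = 7)
  single <- selectK(mixedDistance(spellFeatures(ens@tables[[1]])), 3:6)
  expect_equal(cons@kStar, single$kStar)
  expect_identical(clusterLabels(cons),
                   clusterLabels(single$fits[[paste0("k", single$kStar)]]))
  expect_true(all(membership(cons) %in% c(0, 1)))
})

test_that("membership rows sum to one and certainty is their maximum", {
  co <- simulateCohort(600, seed = 57, missingRate = 0.1)
  cons <- consensusCluster(co, M = 4, seed = 3, kRange = 4:6, cycles = 3)
  M <- membership(cons)
  expect_true(all(abs(rowSums(M) - 1) < 1e-10))
  expect_equal(cons@certainty, apply(M, 1, max))
  expect_identical(cons@consensus, as.integer(apply(M, 1, which.max)))
})
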