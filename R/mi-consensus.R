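# One chained-equations pass over the epochs: each epoch's missing cells are
# redrawn from a logistic regression on the other epochs, fitted to the
# subjects observed at that epoch, with an approximate posterior draw of the
# coefficients to propagate model uncertainty between imputations.
impute_cycle <- function(w, filled, miss) {
  T <- ncol(w)
  for (j in seq_len(T)) {
    mj <- miss[, j]
    if (!any(mj)) next
    df <- as.data.frame(filled)
    colnames(df) <- paste0("e", seq_len(T))
    form <- stats::as.formula(paste0("e", j, " ~ ",
             paste0("e", setdiff(seq_len(T), j), collapse = " + ")))
    obs <- !is.na(w[, j])
    fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                       data = df[obs, , drop = FALSE]))
    beta <- stats::coef(fit)
    V <- suppressWarnings(stats::vcov(fit))
    draw <- tryCatch({
      L <- chol(V)
      beta + drop(t(L) %*% stats::rnorm(length(beta)))
    }, error = function(e) beta)
    draw[!is.finite(draw)] <- 0
    Xd <- cbind(1, as.matrix(df[mj, setdiff(seq_len(T), j), drop = FALSE]))
    p <- stats::plogis(drop(Xd %*% draw))
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    filled[mj, j] <- as.integer(stats::runif(sum(mj)) < p)
  }
  filled
}

#' Multiple imputation of missing wheeze indicators by chained equations
#'
#' Produces M completed copies of a cohort. Missing cells are initialised by
#' random draws from the observed per-epoch margins and then updated over
#' \code{cycles} passes in which each epoch's missing values are drawn from
#' a logistic model on the other epochs (with posterior-draw coefficient
#' perturbation). Observed cells are never altered.
#'
#' @param table a \linkS4class{WheezeCohort}; every subject must have at
#'   least one observed epoch and every epoch at least one observed value.
#' @param M number of imputations.
#' @param seed integer seed; identical seeds give identical ensembles.
#' @param cycles chained-equation passes per imputation.
#' @return an \linkS4class{ImputationEnsemble}. A cohort with no missing
#'   cells yields M identical copies of the input.
#' @export
imputeChained <- function(table, M = 10L, seed = 1L, cycles = 10L) {
  w <- wheezeMatrix(table)
  if (nrow(w) && any(rowSums(!is.na(w)) == 0L))
    stop("some subjects have no observed epoch; filter them out first")
  if (nrow(w) && any(colSums(!is.na(w)) == 0L))
    stop("some epochs have no observed values; imputation model is undefined")
  grid <- epochGrid(table)
  miss <- is.na(w)
  set.seed(as.integer(seed))
  tables <- vector("list", M)
  margins <- colMeans(w, na.rm = TRUE)
  for (m in seq_len(M)) {
    filled <- w
    if (any(miss)) {
      for (j in seq_len(ncol(w))) {
        mj <- miss[, j]
        if (any(mj))
          filled[mj, j] <- as.integer(stats::runif(sum(mj)) < margins[j])
      }
      for (cyc in seq_len(cycles)) filled <- impute_cycle(w, filled, miss)
    }
    tables[[m]] <- WheezeCohort(filled, grid,
                                name = S4Vectors::metadata(table)$name,
                                truth = truthLabels(table))
  }
  new("ImputationEnsemble", tables = tables, M = as.integer(M),
      seed = as.integer(seed))
}

setMethod("show", "ImputationEnsemble", function(object) {
  cat(sprintf("ImputationEnsemble: M = %d completed cohorts, seed = %d\n",
              object@M, object@seed))
})

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    left <- if (pos > 1L) sub[, 1:(pos - 1L), drop = FALSE] else NULL
    right <- if (pos < k) sub[, pos:(k - 1L), drop = FALSE] else NULL
    cbind(left, matrix(k, nrow(sub), 1L), right)
  }))
}

best_permutation <- function(reference, result, k) {
  O <- table(factor(reference, levels = seq_len(k)),
             factor(result, levels = seq_len(k)))
  perms <- permutations_of(k)
  agree <- apply(perms, 1L, function(p) sum(O[cbind(p, seq_len(k))]))
  as.integer(perms[which.max(agree), ])
}

#' Align cluster labellings to a reference by optimal relabelling
#'
#' Cluster numbers are arbitrary across independent fits; this finds, for
#' each labelling, the permutation of its labels maximising agreement with
#' the reference (exact search over the k-by-k overlap table) and applies
#' it. All labellings must use the same k.
#'
#' @param results list of integer label vectors.
#' @param reference integer label vector of the same length.
#' @return list with \code{aligned} (relabelled vectors) and
#'   \code{permutations} (permutation applied to each, as a map from
#'   original label to aligned label).
#' @export
alignLabels <- function(results, reference) {
  ks <- vapply(results, function(r) max(r), 0)
  k <- max(c(ks, max(reference)))
  if (any(vapply(results, length, 0L) != length(reference)))
    stop("all labellings must have the same length")
  if (k > 9L) stop("label alignment supports at most 9 clusters")
  perms <- lapply(results, function(r) best_permutation(reference, r, k))
  aligned <- Map(function(r, p) p[r], results, perms)
  list(aligned = aligned, permutations = perms)
}

#' Consensus clustering across a multiple-imputation ensemble
#'
#' The missing-data arm of the spell-based pipeline. For each of M
#' completed datasets it derives spell features, fits the mixed-data
#' metric, selects the number of clusters by average silhouette and fits
#' PAM. The pooled cluster number k* is the modal selected k across
#' imputations (ties to the smallest); every imputation is then (re)fitted
#' at k*, labellings are aligned to the first imputation, and each
#' subject's membership probability in a phenotype is the fraction of
#' imputations assigning it there. With complete data all imputations are
#' identical and memberships are all 0 or 1.
#'
#' @param table a \linkS4class{WheezeCohort} (missingness allowed).
#' @param M number of imputations.
#' @param seed integer seed driving imputation.
#' @param kRange candidate cluster counts for [selectK()].
#' @param cycles chained-equation passes per imputation.
#' @param ... passed to [mixedDistance()].
#' @return a \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(table, M = 10L, seed = 1L, kRange = 2:8,
                             cycles = 10L, ...) {
  ens <- imputeChained(table, M = M, seed = seed, cycles = cycles)
  fits_at_k <- vector("list", M)
  sel_k <- integer(M)
  sel_sil <- numeric(M)
  sel_cost <- numeric(M)
  metrics <- vector("list", M)
  selections <- vector("list", M)
  for (m in seq_len(M)) {
    feats <- spellFeatures(ens@tables[[m]])
    metrics[[m]] <- mixedDistance(feats, ...)
    selections[[m]] <- selectK(metrics[[m]], kRange)
    sel_k[m] <- selections[[m]]$kStar
  }
  ktab <- table(sel_k)
  kStar <- as.integer(names(ktab)[ktab == max(ktab)][1L])
  labels <- vector("list", M)
  for (m in seq_len(M)) {
    f <- selections[[m]]$fits[[paste0("k", kStar)]]
    if (is.null(f)) f <- pamFit(metrics[[m]], kStar)
    labels[[m]] <- clusterLabels(f)
    sel_sil[m] <- f@avgSilhouette
    sel_cost[m] <- f@totalCost
  }
  al <- alignLabels(labels, labels[[1L]])
  n <- length(labels[[1L]])
  memb <- matrix(0, n, kStar)
  for (m in seq_len(M))
    memb <- memb + outer(al$aligned[[m]], seq_len(kStar), "==")
  memb <- memb / M
  rownames(memb) <- subjectIds(table)
  new("ConsensusResult", membership = memb,
      consensus = as.integer(apply(memb, 1L, which.max)),
      certainty = apply(memb, 1L, max), kStar = kStar,
      diagnostics = data.frame(imputation = seq_len(M), kSelected = sel_k,
                               avgSilhouette = sel_sil, totalCost = sel_cost),
      subjectIds = as.character(subjectIds(table)))
}

#' @rdname membership
setMethod("membership", "ConsensusResult", function(x) x@membership)

#' @rdname clusterLabels
setMethod("clusterLabels", "ConsensusResult", function(x) x@consensus)

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: n = %d, k* = %d, mean certainty = %.3f\n",
              nrow(object@membership), object@kStar, mean(object@certainty)))
  cat("  selected k per imputation:",
      paste(object@diagnostics$kSelected, collapse = " "), "\n")
})
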