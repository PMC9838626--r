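#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model:
#' 1 for partitions identical up to relabelling, about 0 for independent
#' random labellings; can be negative.
#'
#' @param a,b label vectors of equal length (n >= 2); any atomic type.
#' @return a single number <= 1.
#' @examples
#' adjustedRand(c(1, 2, 1, 2), c(1, 1, 2, 2))  # -0.5
#' @export
adjustedRand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least two subjects")
  O <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(O))
  sa <- sum(ch2(rowSums(O)))
  sb <- sum(ch2(colSums(O)))
  expected <- sa * sb / ch2(n)
  maxidx <- (sa + sb) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sij - expected) / (maxidx - expected)
}

#' Phenotype transition table between two models
#'
#' Cross-tabulates subjects by their cluster in each of two partitions —
#' the numeric backbone of an alluvial plot of phenotype membership flows.
#'
#' @param a,b label vectors of equal length.
#' @param namesA,namesB optional display names for the clusters of each
#'   partition (in sorted label order).
#' @return contingency matrix of counts; marginals equal cluster sizes.
#' @export
transitionTable <- function(a, b, namesA = NULL, namesB = NULL) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  O <- table(a, b)
  M <- matrix(as.numeric(O), nrow(O), ncol(O), dimnames = dimnames(O))
  if (!is.null(namesA)) rownames(M) <- namesA
  if (!is.null(namesB)) colnames(M) <- namesB
  M
}

#' Fraction of subjects changing phenotype between two models
#'
#' Aligns the second labelling to the first by optimal relabelling (cluster
#' numbers are arbitrary across independent fits) and returns the
#' proportion of subjects whose aligned label differs. Zero exactly when
#' the partitions are identical up to relabelling.
#'
#' @param a,b integer label vectors with the same number of clusters.
#' @return proportion in [0, 1].
#' @export
changedFraction <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  if (max(a) != max(b))
    stop("changedFraction requires the same number of clusters")
  al <- alignLabels(list(b), a)
  mean(al$aligned[[1L]] != a)
}

#' Within-cluster distribution profile of the spell variables
#'
#' Summarises, for every cluster and spell variable, the distribution of
#' values (category counts for the spell type, quantiles and histogram bins
#' for the quantitative variables), together with a scalar heterogeneity
#' score: for each variable the within-cluster variance normalised by the
#' overall variance (quantitative) or the probability that two random
#' members disagree (categorical), averaged over variables and
#' size-weighted over clusters. A cluster of identical vectors scores 0.
#'
#' @param features a \linkS4class{SpellFeatures} table.
#' @param assignment integer cluster labels aligned with its rows.
#' @param bins histogram bin count for quantitative variables.
#' @return list: \code{profile} (tidy data.frame cluster/variable/bin/count),
#'   \code{quantiles} (per cluster x variable), \code{score} (scalar) and
#'   \code{clusterScores}.
#' @export
homogeneityProfile <- function(features, assignment, bins = 10L) {
  X <- features@features
  if (nrow(X) != length(assignment))
    stop("assignment must align with the feature rows")
  cl <- sort(unique(assignment))
  rows <- list()
  qs <- list()
  cl_scores <- numeric(length(cl))
  overall_var <- vapply(X[spell_cols[1:5]], function(v)
    stats::var(v[!is.na(v)]), 0)
  for (ci in seq_along(cl)) {
    idx <- assignment == cl[ci]
    scores <- numeric(0)
    for (v in spell_cols) {
      x <- X[[v]][idx]
      if (v == "spell_type") {
        tab <- table(factor(x, levels = 0:2))
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl[ci], variable = v, bin = names(tab),
          count = as.numeric(tab))
        p <- as.numeric(tab) / max(sum(tab), 1)
        scores <- c(scores, 1 - sum(p^2))
      } else {
        obs <- x[!is.na(x)]
        if (length(obs)) {
          h <- graphics::hist(obs, breaks = bins, plot = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            cluster = cl[ci], variable = v,
            bin = sprintf("[%g,%g)", h$breaks[-length(h$breaks)],
                          h$breaks[-1L]),
            count = h$counts)
          qs[[length(qs) + 1L]] <- data.frame(
            cluster = cl[ci], variable = v,
            t(stats::quantile(obs, c(0, 0.25, 0.5, 0.75, 1))),
            check.names = FALSE)
        }
        ov <- overall_var[[v]]
        wv <- if (length(obs) > 1L) stats::var(obs) else 0
        scores <- c(scores, if (is.finite(ov) && ov > 0) wv / ov else 0)
      }
    }
    cl_scores[ci] <- mean(scores)
  }
  sizes <- as.numeric(table(factor(assignment, levels = cl)))
  list(profile = do.call(rbind, rows),
       quantiles = if (length(qs)) do.call(rbind, qs) else NULL,
       score = sum(cl_scores * sizes) / sum(sizes),
       clusterScores = stats::setNames(cl_scores, cl))
}
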