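feature_matrix <- function(features) {
  m <- as.matrix(features@features)
  storage.mode(m) <- "double"
  m
}

fit_scales <- function(X, kinds, scaleEstimator) {
  p <- ncol(X)
  s <- rep(1, p)
  for (k in seq_len(p)) {
    if (kinds[k] != 0L) next
    v <- X[, k][!is.na(X[, k])]
    s[k] <- if (scaleEstimator == "sd") stats::sd(v) else diff(range(v))
    if (!is.finite(s[k])) s[k] <- 0
  }
  s
}

#' Mixed-data dissimilarity between spell-feature vectors
#'
#' Gower-type dissimilarity combining variance-standardised squared
#' differences for the quantitative spell variables with simple mismatch for
#' the categorical spell type, under pairwise-deletion weighting of missing
#' values (the never-wheezers' undefined onset/offset ages):
#' \deqn{d_{ij}^2 = \frac{\sum_k \delta_{ijk} w_k g_k(i,j)}
#'                       {\sum_k \delta_{ijk} w_k}}
#' with \eqn{g_k = ((x_{ik}-x_{jk})/s_k)^2} for quantitative variables and a
#' 0/1 mismatch for categorical ones; \eqn{\delta_{ijk}} is 1 when variable k
#' is observed for both subjects. Scales \eqn{s_k} are fitted on the input
#' table. A variable that is constant across all subjects carries no
#' information and is excluded from both numerator and denominator (with a
#' warning for a zero-variance quantitative variable), so the matrix is
#' unchanged by dropping such a variable. The triangle inequality is not
#' guaranteed under pairwise deletion.
#'
#' @param features a \linkS4class{SpellFeatures} table.
#' @param weights nonnegative per-variable weights (at least one positive);
#'   default all 1.
#' @param scaleEstimator \code{"sd"} (sample SD, n-1 denominator) or
#'   \code{"range"}.
#' @param spellTypeAs treat spell type as \code{"categorical"} (mismatch) or
#'   \code{"quantitative"} (standardised difference).
#' @return a \linkS4class{MixedDistance}; a pair of subjects with no
#'   commonly observed variable of positive weight is an error naming the
#'   pair.
#' @seealso [pamFit()], [assignNearestMedoid()]
#' @export
mixedDistance <- function(features, weights = rep(1, 6),
                          scaleEstimator = c("sd", "range"),
                          spellTypeAs = c("categorical", "quantitative")) {
  scaleEstimator <- match.arg(scaleEstimator)
  spellTypeAs <- match.arg(spellTypeAs)
  stopifnot(length(weights) == 6L, all(weights >= 0), any(weights > 0))
  X <- feature_matrix(features)
  kinds <- c(0L, 0L, 0L, 0L, 0L,
             if (spellTypeAs == "categorical") 1L else 0L)
  s <- fit_scales(X, kinds, scaleEstimator)
  w <- weights
  for (k in seq_len(6L)) {
    if (w[k] <= 0) next
    if (kinds[k] == 0L && s[k] <= 0) {
      warning("quantitative variable \"", spell_cols[k],
              "\" has zero variance; it is ignored")
      w[k] <- 0
    } else if (kinds[k] == 1L) {
      v <- X[, k][!is.na(X[, k])]
      if (length(unique(v)) <= 1L) w[k] <- 0
    }
  }
  if (all(w <= 0)) stop("all variables are constant; no metric can be fitted")
  s[s <= 0] <- 1
  D <- cpp_mixed_distance(X, kinds, w, s)
  dimnames(D) <- list(features@subjectIds, features@subjectIds)
  new("MixedDistance", D = D, X = X, kinds = kinds, weights = w, scales = s)
}

#' @rdname MixedDistance-class
#' @param object a \linkS4class{MixedDistance}.
#' @export
setMethod("show", "MixedDistance", function(object) {
  cat(sprintf("MixedDistance: %d x %d, %d active variables\n",
              nrow(object@D), ncol(object@D), sum(object@weights > 0)))
})

as_dist_matrix <- function(D) {
  if (is(D, "MixedDistance")) return(D@D)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(D < 0) || any(!is.finite(D))) stop("distances must be finite and nonnegative")
  D
}

#' Dissimilarities from new items to the fitted table
#'
#' Places new feature vectors relative to the subjects a
#' \linkS4class{MixedDistance} was fitted on, reusing the fitted scales and
#' active weights (no refitting), as needed to assign enumerated sequences
#' or held-out subjects to existing medoids.
#'
#' @param newFeatures a \linkS4class{SpellFeatures} table for the new items.
#' @param metric the fitted \linkS4class{MixedDistance}.
#' @param columns optional column indices of the fitted table to compare
#'   against (default: all).
#' @return matrix of dissimilarities, new items in rows.
#' @export
crossDistance <- function(newFeatures, metric, columns = NULL) {
  stopifnot(is(metric, "MixedDistance"))
  Y <- metric@X
  if (!is.null(columns)) Y <- Y[columns, , drop = FALSE]
  cpp_cross_distance(feature_matrix(newFeatures), Y, metric@kinds,
                     metric@weights, metric@scales)
}
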