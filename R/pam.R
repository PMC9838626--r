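#' Partition around medoids over a precomputed dissimilarity
#'
#' Deterministic PAM: greedy BUILD initialisation (first medoid minimises
#' total dissimilarity) followed by steepest-descent SWAP, stopping when no
#' single medoid/non-medoid exchange lowers the total cost. All ties break
#' to the lowest index, so the fit is a pure function of the matrix. Cluster
#' labels are numbered 1..k in ascending medoid-index order and each subject
#' is assigned to its nearest medoid.
#'
#' @param D a \linkS4class{MixedDistance} or symmetric nonnegative matrix.
#' @param k number of clusters, 1 <= k <= n.
#' @return a \linkS4class{PAMResult}; \code{trace} holds the total cost
#'   after BUILD and each accepted swap (non-increasing).
#' @examples
#' x <- c(0, 1, 2, 10, 11, 12)
#' fit <- pamFit(as.matrix(dist(x)), 2)
#' fit@medoids  # 2 and 5
#' @export
pamFit <- function(D, k) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie between 1 and n = ", n)
  res <- cpp_pam(D, k)
  sil <- if (k >= 2L && k < n) silhouetteWidth(D, res$assignment)
         else list(widths = rep(NA_real_, n), average = NA_real_)
  if (k == n) sil <- list(widths = rep(0, n), average = 0)
  new("PAMResult", k = k, medoids = as.integer(res$medoids),
      assignment = as.integer(res$assignment),
      totalCost = as.numeric(res$cost),
      silWidths = sil$widths, avgSilhouette = sil$average,
      trace = as.numeric(res$trace))
}

#' @rdname clusterLabels
setMethod("clusterLabels", "PAMResult", function(x) x@assignment)

setMethod("show", "PAMResult", function(object) {
  cat(sprintf("PAMResult: k = %d, n = %d, total cost = %.4f, avg silhouette = %s\n",
              object@k, length(object@assignment), object@totalCost,
              ifelse(is.na(object@avgSilhouette), "NA",
                     sprintf("%.3f", object@avgSilhouette))))
  cat("  cluster sizes:", paste(tabulate(object@assignment, object@k),
                                collapse = " "), "\n")
})

#' Silhouette widths of a partition
#'
#' Standard silhouette: \eqn{s(i) = (b_i - a_i)/\max(a_i, b_i)} where
#' \eqn{a_i} is the mean dissimilarity to the other members of i's cluster
#' and \eqn{b_i} the smallest mean dissimilarity to another cluster.
#' Members of singleton clusters get \eqn{s(i) = 0}.
#'
#' @param D dissimilarity matrix or \linkS4class{MixedDistance}.
#' @param assignment integer cluster labels; at least two nonempty clusters.
#' @return list with per-point \code{widths} and their \code{average}.
#' @export
silhouetteWidth <- function(D, assignment) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  stopifnot(length(assignment) == n)
  cl <- sort(unique(assignment))
  if (length(cl) < 2L) stop("silhouette needs at least two clusters")
  sizes <- as.numeric(table(factor(assignment, levels = cl)))
  Z <- outer(assignment, cl, "==") + 0
  S <- D %*% Z                              # n x k sums of dissimilarities
  own <- match(assignment, cl)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    if (sizes[own[i]] == 1) { widths[i] <- 0; next }
    a <- S[i, own[i]] / (sizes[own[i]] - 1)
    b <- min(S[i, -own[i]] / sizes[-own[i]])
    m <- max(a, b)
    widths[i] <- if (m > 0) (b - a) / m else 0
  }
  list(widths = widths, average = mean(widths))
}

#' Choose the number of clusters
#'
#' Fits PAM at every candidate k and selects k* by one of two fit
#' statistics, returning a per-k diagnostics table so other criteria can be
#' applied by the caller.
#'
#' \code{"elbow"} (default) takes the knee of the total-cost curve on the
#' log scale: the k maximising the curvature
#' \eqn{\log W(k-1) - 2 \log W(k) + \log W(k+1)} of the PAM objective
#' (zero for a geometric cost decay, large where the proportional gain of
#' one more medoid collapses), fitting the two flanking k values as
#' needed. Once every well-populated pattern
#' of longitudinal wheeze has a medoid, the marginal gain of another medoid
#' collapses, so the knee sits at the number of latent phenotypes. This is
#' the default because binary wheeze sequences make spell-feature space
#' heavily duplicated: a cluster holding a single pattern has zero
#' within-cluster dissimilarity and silhouette width exactly 1 however
#' close its neighbours are, so the average silhouette keeps increasing as
#' extra medoids peel off rare patterns and cannot locate the phenotype
#' number. \code{"silhouette"} (the classical PAM companion, largest
#' average silhouette width) remains available and is reported in the
#' diagnostics for every k. Ties go to the smallest k under both criteria.
#'
#' @param D dissimilarity matrix or \linkS4class{MixedDistance}.
#' @param kRange candidate cluster counts (each >= 2).
#' @param criterion \code{"elbow"} or \code{"silhouette"}.
#' @return list: \code{kStar}, \code{diagnostics} (k, totalCost,
#'   avgSilhouette, and the elbow second difference where defined) and
#'   \code{fits} (the \linkS4class{PAMResult} per candidate k).
#' @export
selectK <- function(D, kRange = 2:8, criterion = c("elbow", "silhouette")) {
  criterion <- match.arg(criterion)
  D <- as_dist_matrix(D)
  kRange <- sort(unique(as.integer(kRange)))
  if (!length(kRange)) stop("kRange must not be empty")
  if (any(kRange < 2L) || any(kRange > nrow(D)))
    stop("every candidate k must lie in 2..n")
  fits <- lapply(kRange, function(k) pamFit(D, k))
  cost <- vapply(fits, function(f) f@totalCost, 0)
  sil <- vapply(fits, function(f) f@avgSilhouette, 0)
  diag <- data.frame(k = kRange, totalCost = cost, avgSilhouette = sil)
  # cost at the flanking ks so every candidate has a second difference
  extra <- setdiff(c(min(kRange) - 1L, max(kRange) + 1L), kRange)
  extra <- extra[extra >= 1L & extra <= nrow(D)]
  allk <- c(kRange, extra)
  allc <- c(cost, vapply(extra, function(k) pamFit(D, k)@totalCost, 0))
  allc <- allc[order(allk)]; allk <- sort(allk)
  lc <- log(pmax(allc, 1e-12))
  d2 <- vapply(kRange, function(k) {
    im <- match(k - 1L, allk); i <- match(k, allk); ip <- match(k + 1L, allk)
    if (is.na(im) || is.na(ip)) return(-Inf)
    lc[im] - 2 * lc[i] + lc[ip]
  }, 0)
  diag$elbow <- ifelse(is.finite(d2), d2, NA_real_)
  kStar <- if (criterion == "silhouette") kRange[which.max(sil)]
           else kRange[which.max(d2)]
  list(kStar = kStar, diagnostics = diag,
       fits = stats::setNames(fits, paste0("k", kRange)))
}

#' Assign items to their nearest medoid
#'
#' @param D matrix of dissimilarities from items (rows) to the k medoids
#'   (columns), e.g. from [crossDistance()] with \code{columns = fit@medoids}.
#' @return integer labels in 1..k; ties go to the lowest medoid index.
#' @export
assignNearestMedoid <- function(D) {
  D <- as.matrix(D)
  as.vector(apply(D, 1L, which.min))  # which.min takes the first (lowest) on ties
}

#' Build a deterministic sequence-to-cluster assigner from a fitted pipeline
#'
#' Composes spell-feature derivation, the fitted mixed-data metric and
#' nearest-medoid assignment into a single function mapping any complete
#' binary sequence to a cluster of the fit, for use with [sequenceAudit()].
#'
#' @param fit a \linkS4class{PAMResult}.
#' @param metric the \linkS4class{MixedDistance} the fit was computed on.
#' @param grid the \linkS4class{EpochGrid} of the training cohort.
#' @return function: 0/1 vector of length T -> cluster label in 1..k.
#' @export
medoidAssigner <- function(fit, metric, grid) {
  force(fit); force(metric); force(grid)
  function(seq) {
    f <- spellFeatures(matrix(seq, nrow = 1L), grid)
    assignNearestMedoid(crossDistance(f, metric, columns = fit@medoids))
  }
}
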