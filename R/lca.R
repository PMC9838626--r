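theta_clip <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)

# Collapse complete binary rows to unique patterns with counts; EM weighted
# by pattern counts is exact and fast (<= 2^T patterns).
pattern_table <- function(w) {
  key <- apply(w, 1L, paste, collapse = "")
  tab <- table(key)
  pat <- do.call(rbind, lapply(strsplit(names(tab), ""), as.integer))
  list(patterns = pat, counts = as.numeric(tab), key = key)
}

# log P(pattern | class) for all patterns x classes
pattern_loglik <- function(pat, theta) {
  lt <- log(theta); l1 <- log1p(-theta)
  pat %*% t(lt) + (1 - pat) %*% t(l1)
}

em_once <- function(pat, cnt, k, rho, theta, tol, maxIter) {
  n <- sum(cnt)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    lp <- sweep(pattern_loglik(pat, theta), 2L, log(rho), "+")
    mx <- apply(lp, 1L, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(cnt * lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lp - lse)                      # patterns x k
    wresp <- resp * cnt
    nk <- pmax(colSums(wresp), 1e-12)
    rho <- nk / n
    theta <- theta_clip(t(wresp) %*% pat / nk)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(rho = rho, theta = theta, loglik = ll_trace[length(ll_trace)],
       trace = ll_trace, converged = converged)
}

#' Fit a Bernoulli-mixture latent class model by EM
#'
#' The comparison arm for the spell-based clustering: k latent classes,
#' within each of which the T epoch indicators are independent Bernoulli
#' draws with class-specific probabilities. Fitted by EM from
#' \code{nStarts} random initialisations, keeping the best log-likelihood.
#' Internally the data are collapsed to unique response patterns, so the
#' fit scales with 2^T rather than n. Item probabilities are clipped to
#' [1e-6, 1 - 1e-6].
#'
#' @param x a complete \linkS4class{WheezeCohort} or 0/1 matrix
#'   (subjects by epochs).
#' @param k number of classes (>= 1).
#' @param nStarts random restarts; @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter EM iteration cap per start (non-convergence is flagged).
#' @return an \linkS4class{LCAFit}; \code{bic = -2 loglik + p log(n)} with
#'   \code{p = (k - 1) + k T}.
#' @seealso [lcaPosterior()]
#' @export
fitLCA <- function(x, k, nStarts = 20L, seed = 1L, tol = 1e-8,
                   maxIter = 1000L) {
  w <- if (is(x, "WheezeCohort")) wheezeMatrix(x) else as.matrix(x)
  if (nrow(w) == 0L) stop("cannot fit a latent class model to an empty table")
  if (anyNA(w)) stop("latent class fitting requires complete data")
  if (k < 1L) stop("k must be at least 1")
  tt <- pattern_table(w)
  if (k > nrow(tt$patterns))
    warning("k exceeds the number of distinct sequences (", nrow(tt$patterns),
            "); the fit proceeds but classes will be redundant")
  n <- nrow(w); T <- ncol(w)
  if (k == 1L) {
    theta <- theta_clip(matrix(colMeans(w), 1L, T))
    ll <- sum(tt$counts * pattern_loglik(tt$patterns, theta))
    best <- list(rho = 1, theta = theta, loglik = ll, trace = ll,
                 converged = TRUE)
  } else {
    set.seed(as.integer(seed))
    best <- NULL
    for (s in seq_len(nStarts)) {
      rho0 <- stats::runif(k, 0.25, 1); rho0 <- rho0 / sum(rho0)
      theta0 <- matrix(stats::runif(k * T, 0.1, 0.9), k, T)
      fit <- em_once(tt$patterns, tt$counts, k, rho0, theta0, tol, maxIter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  }
  p <- as.integer((k - 1L) + k * T)
  new("LCAFit", k = as.integer(k), rho = as.numeric(best$rho),
      theta = best$theta, loglik = best$loglik,
      bic = -2 * best$loglik + p * log(n), nParams = p,
      converged = best$converged, trace = best$trace, nObs = as.integer(n))
}

setMethod("show", "LCAFit", function(object) {
  cat(sprintf("LCAFit: k = %d classes, n = %d, loglik = %.2f, BIC = %.2f%s\n",
              object@k, object@nObs, object@loglik, object@bic,
              if (object@converged) "" else " (not converged)"))
  cat("  class weights:", paste(sprintf("%.3f", object@rho), collapse = " "),
      "\n")
})

#' Posterior class probabilities and maximum-posterior labels
#'
#' Responsibilities are proportional to
#' \eqn{\rho_c \prod_t \theta_{ct}^{x_t} (1-\theta_{ct})^{1-x_t}},
#' normalised per subject; hard labels take the maximum posterior with ties
#' to the lowest class index. Identical sequences always receive identical
#' posterior rows.
#'
#' @param params an \linkS4class{LCAFit}.
#' @param x a complete \linkS4class{WheezeCohort} or 0/1 matrix with the
#'   same number of epochs the model was fitted on.
#' @return list with \code{posterior} (n x k, rows sum to 1) and
#'   \code{labels} (integer).
#' @export
lcaPosterior <- function(params, x) {
  w <- if (is(x, "WheezeCohort")) wheezeMatrix(x) else as.matrix(x)
  if (anyNA(w)) stop("posterior computation requires complete data")
  if (ncol(w) != ncol(params@theta))
    stop("epoch count of the data does not match the fitted model")
  lp <- sweep(pattern_loglik(w, params@theta), 2L, log(params@rho), "+")
  mx <- apply(lp, 1L, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  dimnames(post) <- list(rownames(w), NULL)
  list(posterior = post, labels = apply(post, 1L, which.max))
}
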