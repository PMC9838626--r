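multinom_ll <- function(B, X, W) {
  eta <- cbind(0, X %*% B)          # reference class first column
  mx <- apply(eta, 1L, max)
  lse <- mx + log(rowSums(exp(eta - mx)))
  sum(W * (eta - lse))
}

multinom_probs <- function(B, X) {
  eta <- cbind(0, X %*% B)
  mx <- apply(eta, 1L, max)
  e <- exp(eta - mx)
  e / rowSums(e)
}

#' Membership-weighted multinomial logistic regression
#'
#' Association stage consuming the phenotype membership probabilities of
#' the multiple-imputation consensus: each subject contributes one
#' fractional observation per phenotype, weighted by its membership
#' probability, to a multinomial logit against a reference phenotype
#' (algebraically identical to expanding subjects into weighted rows).
#' Fitted by Newton iterations with step-halving, so the weighted
#' log-likelihood never decreases. With hard 0/1 memberships the fit is
#' exactly an unweighted multinomial regression. Effects are reported as
#' relative risk ratios (exponentiated coefficients) with Wald 95\%
#' confidence intervals. Genotypes enter like any numeric covariate
#' (additively coded 0/1/2).
#'
#' @param memberships a \linkS4class{ConsensusResult} or an n-by-k matrix
#'   with rows summing to 1.
#' @param covariates data.frame or matrix of numeric covariates (categorical
#'   covariates pre-expanded to indicators); an intercept is added.
#' @param reference index of the reference phenotype (no rows reported).
#' @param maxIter Newton iteration cap.
#' @return an \linkS4class{AssociationResult}; non-convergence and apparent
#'   complete separation (|log RRR| > 15) are flagged.
#' @export
weightedMultinomial <- function(memberships, covariates, reference = 1L,
                                maxIter = 100L) {
  W <- if (is(memberships, "ConsensusResult")) membership(memberships)
       else as.matrix(memberships)
  if (max(abs(rowSums(W) - 1)) > 1e-8)
    stop("membership rows must sum to 1")
  k <- ncol(W)
  reference <- as.integer(reference)
  if (reference < 1L || reference > k) stop("invalid reference phenotype")
  cov_m <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(cov_m)) stop("covariates must be numeric (pre-expanded)")
  if (nrow(cov_m) != nrow(W)) stop("covariates must align with memberships")
  X <- cbind("(Intercept)" = 1, cov_m)
  p <- ncol(X)
  W <- W[, c(reference, setdiff(seq_len(k), reference)), drop = FALSE]
  pheno_ids <- setdiff(seq_len(k), reference)

  B <- matrix(0, p, k - 1L)
  ll <- multinom_ll(B, X, W)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    P <- multinom_probs(B, X)
    G <- crossprod(X, W[, -1L, drop = FALSE] - P[, -1L, drop = FALSE])
    H <- matrix(0, p * (k - 1L), p * (k - 1L))
    for (c1 in seq_len(k - 1L)) for (c2 in seq_len(k - 1L)) {
      wts <- P[, c1 + 1L] * ((c1 == c2) - P[, c2 + 1L])
      blk <- crossprod(X, X * wts)
      H[((c1 - 1L) * p + 1L):(c1 * p), ((c2 - 1L) * p + 1L):(c2 * p)] <- -blk
    }
    step <- tryCatch(solve(H, -as.vector(G)), error = function(e) NULL)
    if (is.null(step)) break
    ok <- FALSE
    for (half in 0:20) {
      Bnew <- B + matrix(step / 2^half, p, k - 1L)
      llnew <- multinom_ll(Bnew, X, W)
      if (is.finite(llnew) && llnew >= ll - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    B <- Bnew
    trace <- c(trace, llnew)
    if (abs(llnew - ll) < 1e-10 * (abs(ll) + 1)) { converged <- TRUE; ll <- llnew; break }
    ll <- llnew
  }

  P <- multinom_probs(B, X)
  H <- matrix(0, p * (k - 1L), p * (k - 1L))
  for (c1 in seq_len(k - 1L)) for (c2 in seq_len(k - 1L)) {
    wts <- P[, c1 + 1L] * ((c1 == c2) - P[, c2 + 1L])
    H[((c1 - 1L) * p + 1L):(c1 * p), ((c2 - 1L) * p + 1L):(c2 * p)] <-
      -crossprod(X, X * wts)
  }
  V <- tryCatch(solve(-H), error = function(e)
    matrix(NA_real_, p * (k - 1L), p * (k - 1L)))
  se <- matrix(sqrt(pmax(diag(V), 0)), p, k - 1L)
  separation <- any(abs(B) > 15)

  est <- as.vector(B)
  ses <- as.vector(se)
  coefs <- data.frame(
    phenotype = rep(pheno_ids, each = p),
    term = rep(colnames(X), k - 1L),
    estimate = est, rrr = exp(est), se = ses,
    ciLow = exp(est - 1.96 * ses), ciHigh = exp(est + 1.96 * ses),
    p = 2 * stats::pnorm(-abs(est / ses)),
    stringsAsFactors = FALSE)
  new("AssociationResult", coefficients = coefs,
      reference = reference, loglik = ll,
      converged = converged, separation = separation, trace = trace)
}

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult: reference phenotype %d, loglik = %.3f%s%s\n",
              object@reference, object@loglik,
              if (object@converged) "" else " (not converged)",
              if (object@separation) " (possible separation)" else ""))
  print(object@coefficients, digits = 4)
})

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment-based random-effects pooling of per-cohort log effects (log odds
#' or risk ratios): with fixed-effect weights \eqn{w_i = 1/se_i^2} and
#' heterogeneity \eqn{Q = \sum w_i (y_i - \hat y_{FE})^2},
#' \deqn{\tau^2 = \max\left(0, \frac{Q - (m-1)}
#'       {\sum w_i - \sum w_i^2 / \sum w_i}\right)}
#' and the pooled effect is the inverse-variance mean with weights
#' \eqn{1/(se_i^2 + \tau^2)}. A single study is returned unchanged with
#' \eqn{\tau^2 = 0}.
#'
#' @param effects per-cohort effects on the log scale.
#' @param ses their standard errors (all > 0).
#' @return a \linkS4class{MetaResult} with pooled effect, SE, Wald 95\% CI
#'   (symmetric on the log scale), tau2, Q and the study count.
#' @examples
#' m <- dlMeta(c(0, 1), c(0.5, 0.5))
#' c(m@Q, m@tau2, m@pooled)  # 2, 0.25, 0.5
#' @export
dlMeta <- function(effects, ses) {
  if (length(effects) != length(ses)) stop("effects and ses must align")
  m <- length(effects)
  if (m < 1L) stop("at least one study is required")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  yfe <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - yfe)^2)
  tau2 <- if (m == 1L) 0 else max(0, (Q - (m - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  pooled <- sum(wr * effects) / sum(wr)
  se <- sqrt(1 / sum(wr))
  new("MetaResult", pooled = pooled, se = se,
      ciLow = pooled - 1.96 * se, ciHigh = pooled + 1.96 * se,
      tau2 = tau2, Q = Q, m = as.integer(m))
}

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult: %d studies, pooled = %.4f [%.4f, %.4f], tau^2 = %.4f, Q = %.4f\n",
              object@m, object@pooled, object@ciLow, object@ciHigh,
              object@tau2, object@Q))
})
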