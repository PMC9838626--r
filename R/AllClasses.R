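#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @useDynLib spellclust, .registration = TRUE
NULL

#' Epoch grid for a harmonised longitudinal wheeze study
#'
#' Describes the ordered follow-up windows ("epochs") at which current wheeze
#' is recorded, each covering an age range in years, together with the rule
#' used to encode epochs as numeric ages for the age-valued spell variables.
#' Two encodings are supported: \code{"ordinal"} (epoch indices 1..T, equal
#' spacing) and \code{"midpoint"} (the midpoint of each age range in years).
#'
#' @slot labels character vector of epoch names.
#' @slot ageLow,ageHigh numeric vectors of age-range bounds in years.
#' @slot encoding \code{"ordinal"} or \code{"midpoint"}.
#'
#' @seealso [defaultEpochGrid()], [encodedAges()]
#' @export
setClass("EpochGrid",
  representation(labels = "character", ageLow = "numeric",
                 ageHigh = "numeric", encoding = "character"),
  validity = function(object) {
    msg <- NULL
    t <- length(object@labels)
    if (t < 2L) msg <- c(msg, "an epoch grid needs at least 2 epochs")
    if (length(object@ageLow) != t || length(object@ageHigh) != t)
      msg <- c(msg, "age bounds must match the number of epochs")
    else {
      if (any(object@ageHigh <= object@ageLow))
        msg <- c(msg, "each age range must have high > low")
      if (t > 1L && any(object@ageLow[-1L] < object@ageHigh[-t]))
        msg <- c(msg, "age ranges must be strictly increasing and non-overlapping")
    }
    if (length(object@encoding) != 1L ||
        !object@encoding %in% c("ordinal", "midpoint"))
      msg <- c(msg, "encoding must be \"ordinal\" or \"midpoint\"")
    if (is.null(msg)) TRUE else msg
  })

#' Cohort of binary longitudinal wheeze records
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"wheeze"}
#' holding the epochs-by-subjects matrix of 0/1/NA wheeze indicators.
#' Epoch metadata (labels, age ranges) live in \code{rowData}; per-subject
#' annotation such as simulation truth labels lives in \code{colData}.
#'
#' @seealso [WheezeCohort()], [wheezeMatrix()], [readCohortCSV()]
#' @export
setClass("WheezeCohort", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"wheeze" %in% SummarizedExperiment::assayNames(object))
      return("assay \"wheeze\" is required")
    w <- SummarizedExperiment::assay(object, "wheeze")
    if (!all(w %in% c(0L, 1L, NA)))
      msg <- c(msg, "wheeze values must be 0, 1 or NA")
    ids <- colnames(object)
    if (ncol(object) > 0L && (is.null(ids) || anyDuplicated(ids)))
      msg <- c(msg, "subject ids (colnames) must be present and unique")
    if (!all(c("label", "age_low", "age_high") %in%
             colnames(SummarizedExperiment::rowData(object))))
      msg <- c(msg, "rowData must carry label, age_low, age_high")
    if (is.null(msg)) TRUE else msg
  })

#' Spell-variable table derived from complete wheeze sequences
#'
#' Six variables per subject: encoded age of the first and last wheezy epoch
#' (\code{first_age}, \code{last_age}; NA for never-wheezers), total number of
#' wheezy epochs (\code{n_records}), duration of the longest spell
#' (\code{longest_spell}), number of separate spells (\code{n_spells}), and
#' the categorical \code{spell_type} (0 = no wheeze, 1 = single spell,
#' 2 = intermittent, i.e. at least two non-consecutive spells).
#'
#' @slot features data.frame with the six columns above.
#' @slot subjectIds character vector aligned with rows of \code{features}.
#' @slot grid the \linkS4class{EpochGrid} the sequences were observed on.
#' @export
setClass("SpellFeatures",
  representation(features = "data.frame", subjectIds = "character",
                 grid = "EpochGrid"),
  validity = function(object) {
    need <- c("first_age", "last_age", "n_records", "longest_spell",
              "n_spells", "spell_type")
    if (!identical(colnames(object@features), need))
      return("features must have exactly the six spell-variable columns")
    if (nrow(object@features) != length(object@subjectIds))
      return("subjectIds must align with feature rows")
    TRUE
  })

#' Mixed-data dissimilarity over spell variables
#'
#' Symmetric pairwise dissimilarity matrix plus the fitted per-variable
#' scales and weights, so that new items (e.g. enumerated sequences) can be
#' placed relative to fitted medoids with the same metric.
#'
#' @slot D symmetric dissimilarity matrix, zero diagonal.
#' @slot X the encoded numeric feature matrix the metric was fitted on.
#' @slot kinds integer per variable: 0 quantitative, 1 categorical.
#' @slot weights,scales per-variable weights and fitted scales.
#' @export
setClass("MixedDistance",
  representation(D = "matrix", X = "matrix", kinds = "integer",
                 weights = "numeric", scales = "numeric"),
  validity = function(object) {
    D <- object@D
    if (nrow(D) != ncol(D)) return("D must be square")
    if (any(!is.finite(D)) || any(D < 0)) return("D must be finite and nonnegative")
    if (max(abs(D - t(D))) > 1e-12) return("D must be symmetric within 1e-12")
    if (any(diag(D) != 0)) return("D must have an exactly zero diagonal")
    TRUE
  })

#' Partition-around-medoids fit
#'
#' @slot k number of clusters.
#' @slot medoids indices of the k medoid subjects (ascending).
#' @slot assignment integer cluster labels in 1..k (clusters numbered in
#'   medoid-index order).
#' @slot totalCost sum of dissimilarities of subjects to their medoid.
#' @slot silWidths per-subject silhouette widths (NA when k = 1).
#' @slot avgSilhouette average silhouette width.
#' @slot trace total cost after BUILD and after each accepted swap.
#' @export
setClass("PAMResult",
  representation(k = "integer", medoids = "integer", assignment = "integer",
                 totalCost = "numeric", silWidths = "numeric",
                 avgSilhouette = "numeric", trace = "numeric"))

#' Bernoulli-mixture latent class fit
#'
#' @slot k number of classes.
#' @slot rho class weights (sum to 1).
#' @slot theta k-by-T matrix of class-conditional wheeze probabilities.
#' @slot loglik maximised log-likelihood; @slot bic Bayesian information
#'   criterion; @slot nParams (k - 1) + k*T free parameters.
#' @slot converged logical; @slot trace log-likelihood per EM iteration of
#'   the best start; @slot nObs number of subjects fitted.
#' @export
setClass("LCAFit",
  representation(k = "integer", rho = "numeric", theta = "matrix",
                 loglik = "numeric", bic = "numeric", nParams = "integer",
                 converged = "logical", trace = "numeric", nObs = "integer"))

#' Multiply-imputed completions of a cohort
#'
#' @slot tables list of M complete \linkS4class{WheezeCohort} objects sharing
#'   subjects and all observed cells with the input.
#' @slot M number of imputations; @slot seed the seed used.
#' @export
setClass("ImputationEnsemble",
  representation(tables = "list", M = "integer", seed = "integer"))

#' Consensus clustering over a multiple-imputation ensemble
#'
#' @slot membership n-by-k matrix; entry (i, c) is the fraction of
#'   imputations assigning subject i to phenotype c after label alignment.
#' @slot consensus hard labels (argmax, ties to the lowest cluster index).
#' @slot certainty per-subject maximum membership probability.
#' @slot kStar pooled cluster number (modal selected k across imputations).
#' @slot diagnostics per-imputation selected k, silhouette and cost.
#' @slot subjectIds subject identifiers aligned with rows.
#' @export
setClass("ConsensusResult",
  representation(membership = "matrix", consensus = "integer",
                 certainty = "numeric", kStar = "integer",
                 diagnostics = "data.frame", subjectIds = "character"),
  validity = function(object) {
    rs <- rowSums(object@membership)
    if (length(rs) && max(abs(rs - 1)) > 1e-10)
      return("membership rows must sum to 1")
    TRUE
  })

#' Membership-weighted multinomial regression result
#'
#' @slot coefficients data.frame with one row per non-reference phenotype and
#'   term: log-scale estimate, RRR, SE, Wald 95% CI, p-value.
#' @slot reference index of the reference phenotype.
#' @slot loglik maximised weighted log-likelihood.
#' @slot converged,separation fit diagnostics.
#' @slot trace log-likelihood per Newton iteration.
#' @export
setClass("AssociationResult",
  representation(coefficients = "data.frame", reference = "integer",
                 loglik = "numeric", converged = "logical",
                 separation = "logical", trace = "numeric"))

#' DerSimonian-Laird random-effects pooling result
#'
#' @slot pooled pooled log-scale effect; @slot se its standard error.
#' @slot ciLow,ciHigh Wald 95% confidence bounds; @slot tau2 between-study
#'   variance; @slot Q Cochran heterogeneity statistic; @slot m study count.
#' @export
setClass("MetaResult",
  representation(pooled = "numeric", se = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", tau2 = "numeric", Q = "numeric",
                 m = "integer"))

#' Latent phenotype archetypes for the synthetic cohort generator
#'
#' @slot labels phenotype names.
#' @slot prevalence mixing proportions (sum to 1 within 1e-12).
#' @slot wheezeProbs k-by-T matrix of per-epoch wheeze probabilities.
#' @export
setClass("PhenotypeArchetypes",
  representation(labels = "character", prevalence = "numeric",
                 wheezeProbs = "matrix"),
  validity = function(object) {
    k <- length(object@labels)
    if (length(object@prevalence) != k || nrow(object@wheezeProbs) != k)
      return("labels, prevalence and wheezeProbs must align")
    if (abs(sum(object@prevalence) - 1) > 1e-12)
      return("prevalences must sum to 1 within 1e-12")
    if (any(object@wheezeProbs < 0 | object@wheezeProbs > 1))
      return("wheeze probabilities must lie in [0, 1]")
    TRUE
  })
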