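#' @rdname EpochGrid-class
#' @param x an object carrying an epoch grid.
#' @export
setGeneric("epochGrid", function(x) standardGeneric("epochGrid"))

#' Numeric encoding of the epochs of a grid
#'
#' Ordinal encoding returns indices 1..T; midpoint encoding returns the
#' midpoints of the age ranges in years. Both are strictly increasing.
#'
#' @param x an \linkS4class{EpochGrid} or an object carrying one.
#' @return numeric vector of length T.
#' @export
setGeneric("encodedAges", function(x) standardGeneric("encodedAges"))

#' Subjects-by-epochs wheeze matrix of a cohort
#'
#' @param x a \linkS4class{WheezeCohort}.
#' @return integer matrix (subjects in rows, epochs in columns, NA = missing)
#'   with subject ids as rownames.
#' @export
setGeneric("wheezeMatrix", function(x) standardGeneric("wheezeMatrix"))

#' @rdname WheezeCohort-class
#' @param x a \linkS4class{WheezeCohort}.
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' Ground-truth phenotype labels of a simulated cohort
#'
#' @param x a \linkS4class{WheezeCohort} produced by [simulateCohort()].
#' @return factor of archetype labels, or NULL when the cohort carries none.
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' Derive the six spell variables
#'
#' @param x a complete binary sequence, a subjects-by-epochs 0/1 matrix, or a
#'   complete \linkS4class{WheezeCohort}.
#' @param grid the \linkS4class{EpochGrid} (taken from the cohort when
#'   \code{x} is one).
#' @return a \linkS4class{SpellFeatures} table.
#' @export
setGeneric("spellFeatures", function(x, grid, ...) standardGeneric("spellFeatures"))

#' Cluster assignment of a fit
#'
#' @param x a fitted clustering object.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Per-subject phenotype membership probabilities
#'
#' @param x a \linkS4class{ConsensusResult}.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
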