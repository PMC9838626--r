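#' Construct an epoch grid
#'
#' @param labels epoch names, one per follow-up window.
#' @param ageLow,ageHigh age-range bounds in years; ranges must be strictly
#'   increasing and non-overlapping.
#' @param encoding how epochs are encoded as numeric ages for the age-valued
#'   spell variables: \code{"ordinal"} (indices 1..T) or \code{"midpoint"}
#'   (range midpoints in years).
#' @return an \linkS4class{EpochGrid}.
#' @examples
#' defaultEpochGrid()
#' @export
EpochGrid <- function(labels, ageLow, ageHigh, encoding = "ordinal") {
  new("EpochGrid", labels = as.character(labels), ageLow = as.numeric(ageLow),
      ageHigh = as.numeric(ageHigh), encoding = match.arg(encoding,
      c("ordinal", "midpoint")))
}

#' Default five-epoch grid from infancy to adolescence
#'
#' Infancy (0.5-1 yr), early childhood (2-3 yr), preschool to early school
#' (4-5 yr), middle childhood (8-10 yr) and adolescence (14-18 yr).
#'
#' @inheritParams EpochGrid
#' @export
defaultEpochGrid <- function(encoding = "ordinal") {
  EpochGrid(labels = c("infancy", "early_childhood", "preschool_early_school",
                       "middle_childhood", "adolescence"),
            ageLow = c(0.5, 2, 4, 8, 14), ageHigh = c(1, 3, 5, 10, 18),
            encoding = encoding)
}

#' @rdname encodedAges
setMethod("encodedAges", "EpochGrid", function(x) {
  if (x@encoding == "ordinal") seq_along(x@labels)
  else (x@ageLow + x@ageHigh) / 2
})

#' @rdname encodedAges
setMethod("encodedAges", "WheezeCohort", function(x) encodedAges(epochGrid(x)))

setMethod("show", "EpochGrid", function(object) {
  cat(sprintf("EpochGrid: %d epochs (%s encoding)\n", length(object@labels),
              object@encoding))
  cat(sprintf("  %s [%g-%g yr] -> %g\n", object@labels, object@ageLow,
              object@ageHigh, encodedAges(object)), sep = "")
})

nEpochs <- function(grid) length(grid@labels)

#' Construct a wheeze cohort
#'
#' @param wheeze subjects-by-epochs matrix over \{0, 1, NA\}; rownames are
#'   used as subject ids (generated as s1..sn when absent).
#' @param grid an \linkS4class{EpochGrid}; its length must match the number
#'   of epoch columns.
#' @param name optional cohort name, stored in the metadata.
#' @param truth optional per-subject phenotype labels (simulation truth).
#' @return a \linkS4class{WheezeCohort}.
#' @examples
#' w <- rbind(a = c(0, 1, 1, 0, 0), b = c(0, 0, 0, 0, 0))
#' WheezeCohort(w, defaultEpochGrid())
#' @export
WheezeCohort <- function(wheeze, grid = defaultEpochGrid(), name = "cohort",
                         truth = NULL) {
  wheeze <- as.matrix(wheeze)
  if (ncol(wheeze) != nEpochs(grid))
    stop("wheeze matrix has ", ncol(wheeze), " epochs but the grid has ",
         nEpochs(grid))
  storage.mode(wheeze) <- "integer"
  if (is.null(rownames(wheeze)))
    rownames(wheeze) <- if (nrow(wheeze)) paste0("s", seq_len(nrow(wheeze)))
                        else character(0)
  assay <- t(wheeze)
  rownames(assay) <- grid@labels
  rd <- S4Vectors::DataFrame(label = grid@labels, age_low = grid@ageLow,
                             age_high = grid@ageHigh)
  cd <- S4Vectors::DataFrame(row.names = colnames(assay))
  if (!is.null(truth)) {
    stopifnot(length(truth) == ncol(assay))
    cd$truth <- factor(truth)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(wheeze = assay), rowData = rd, colData = cd,
    metadata = list(name = name, encoding = grid@encoding))
  new("WheezeCohort", se)
}

#' @rdname epochGrid
setMethod("epochGrid", "WheezeCohort", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  EpochGrid(rd$label, rd$age_low, rd$age_high,
            encoding = S4Vectors::metadata(x)$encoding)
})

#' @rdname wheezeMatrix
setMethod("wheezeMatrix", "WheezeCohort", function(x)
  t(SummarizedExperiment::assay(x, "wheeze")))

#' @rdname WheezeCohort-class
setMethod("subjectIds", "WheezeCohort", function(x) colnames(x))

#' @rdname truthLabels
setMethod("truthLabels", "WheezeCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("truth" %in% colnames(cd)) cd$truth else NULL
})

setMethod("show", "WheezeCohort", function(object) {
  w <- SummarizedExperiment::assay(object, "wheeze")
  cat(sprintf("WheezeCohort \"%s\": %d subjects x %d epochs, %d missing cells (%.1f%%)\n",
              S4Vectors::metadata(object)$name, ncol(w), nrow(w),
              sum(is.na(w)), if (length(w)) 100 * mean(is.na(w)) else 0))
  if (!is.null(truthLabels(object)))
    cat("  carries simulation truth labels\n")
})

#' Read a wide-format cohort CSV
#'
#' Expects a header row \code{subject_id, w1..wT}. Cells must be 0, 1 or a
#' missing token (\code{"NA"} or the empty string by default). Any other
#' value raises a format error naming the offending row and column;
#' duplicated subject ids raise a validation error.
#'
#' @param path CSV file path.
#' @param grid the \linkS4class{EpochGrid} the columns are harmonised to.
#' @param missingTokens cell values parsed as missing.
#' @param name cohort name stored in the result.
#' @return a \linkS4class{WheezeCohort}.
#' @seealso [writeCohortCSV()]
#' @export
readCohortCSV <- function(path, grid = defaultEpochGrid(),
                          missingTokens = c("NA", ""), name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (ncol(raw) != nEpochs(grid) + 1L)
    stop("expected ", nEpochs(grid) + 1L, " columns (subject_id + ",
         nEpochs(grid), " epochs), found ", ncol(raw))
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- matrix(NA_integer_, nrow = nrow(raw), ncol = nEpochs(grid),
              dimnames = list(ids, NULL))
  for (j in seq_len(nEpochs(grid))) {
    cell <- raw[[j + 1L]]
    miss <- cell %in% missingTokens
    ok <- miss | cell %in% c("0", "1")
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop(sprintf("unparseable value \"%s\" at row %d, column %s",
                   cell[bad], bad, colnames(raw)[j + 1L]))
    }
    w[!miss, j] <- as.integer(cell[!miss])
  }
  WheezeCohort(w, grid, name = name)
}

#' Write a cohort to wide-format CSV
#'
#' Emits \code{subject_id, w1..wT} with missing cells written as \code{"NA"};
#' the output round-trips through [readCohortCSV()].
#'
#' @param table a \linkS4class{WheezeCohort}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCohortCSV <- function(table, path) {
  w <- wheezeMatrix(table)
  ids <- rownames(w)
  if (is.null(ids)) ids <- character(0)
  df <- data.frame(subject_id = ids, w,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("subject_id", paste0("w", seq_len(ncol(w))))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Filter subjects by number of observed epochs
#'
#' Reproduces the two analysis populations used throughout: the
#' complete-case set (\code{requireComplete = TRUE}) and the
#' at-least-m-observations set for the multiple-imputation arm.
#'
#' @param table a \linkS4class{WheezeCohort}.
#' @param minObserved minimum number of non-missing epochs to keep a subject.
#' @param requireComplete keep only subjects with no missing epoch.
#' @return the filtered \linkS4class{WheezeCohort}; subject order preserved.
#' @export
filterByObserved <- function(table, minObserved = 0L, requireComplete = FALSE) {
  w <- wheezeMatrix(table)
  if (minObserved < 0L || minObserved > ncol(w))
    stop("minObserved must be between 0 and the number of epochs")
  nobs <- rowSums(!is.na(w))
  keep <- if (requireComplete) nobs == ncol(w) else nobs >= minObserved
  table[, keep]
}
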