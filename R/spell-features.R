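spell_cols <- c("first_age", "last_age", "n_records", "longest_spell",
                "n_spells", "spell_type")

derive_one <- function(seq, ages) {
  if (anyNA(seq))
    stop("sequence contains missing entries; impute before deriving spell variables")
  ones <- which(seq == 1L)
  if (!length(ones))
    return(c(first_age = NA_real_, last_age = NA_real_, n_records = 0,
             longest_spell = 0, n_spells = 0, spell_type = 0))
  runs <- rle(as.integer(seq))
  spells <- runs$lengths[runs$values == 1L]
  c(first_age = ages[ones[1L]], last_age = ages[ones[length(ones)]],
    n_records = length(ones), longest_spell = max(spells),
    n_spells = length(spells),
    spell_type = if (length(spells) >= 2L) 2 else 1)
}

#' @describeIn spellFeatures a single complete 0/1 sequence; returns a named
#'   numeric vector of the six spell variables.
#' @export
setMethod("spellFeatures", "numeric", function(x, grid, ...) {
  if (length(x) != nEpochs(grid)) stop("sequence length must equal T")
  if (!all(x %in% c(0, 1, NA))) stop("sequence values must be 0 or 1")
  derive_one(as.integer(x), encodedAges(grid))
})

#' @describeIn spellFeatures a subjects-by-epochs 0/1 matrix.
#' @export
setMethod("spellFeatures", "matrix", function(x, grid, ...) {
  ages <- encodedAges(grid)
  if (ncol(x) != nEpochs(grid)) stop("matrix epochs must match the grid")
  feats <- t(apply(x, 1L, derive_one, ages = ages))
  if (nrow(x) == 0L) feats <- matrix(numeric(0), 0L, 6L)
  feats <- as.data.frame(feats)
  colnames(feats) <- spell_cols
  ids <- rownames(x)
  if (is.null(ids)) ids <- if (nrow(x)) paste0("s", seq_len(nrow(x)))
                           else character(0)
  new("SpellFeatures", features = feats, subjectIds = as.character(ids),
      grid = grid)
})

#' @describeIn spellFeatures a complete \linkS4class{WheezeCohort}; the grid
#'   is taken from the cohort.
#' @export
setMethod("spellFeatures", "WheezeCohort", function(x, grid, ...) {
  spellFeatures(wheezeMatrix(x), epochGrid(x))
})

#' @rdname SpellFeatures-class
#' @param object,x a \linkS4class{SpellFeatures} table.
#' @export
setMethod("show", "SpellFeatures", function(object) {
  cat(sprintf("SpellFeatures: %d subjects, %s encoding\n",
              nrow(object@features), object@grid@encoding))
  print(utils::head(object@features, 5L))
})

#' Feature table as a data.frame
#'
#' @param x a \linkS4class{SpellFeatures} object.
#' @param ... unused.
#' @return data.frame with subject_id plus the six spell variables.
#' @export
setMethod("as.data.frame", "SpellFeatures",
  function(x, row.names = NULL, optional = FALSE, ...) {
    cbind(data.frame(subject_id = x@subjectIds, stringsAsFactors = FALSE),
          x@features)
  })

#' Enumerate all complete binary wheeze sequences
#'
#' @param T number of epochs (>= 1).
#' @return a 2^T-by-T 0/1 matrix in lexicographic row order, with rownames
#'   like \code{"01010"}.
#' @examples
#' nrow(enumerateSequences(5))  # 32
#' @export
enumerateSequences <- function(T) {
  if (T < 1L) stop("T must be at least 1")
  g <- rev(expand.grid(rev(replicate(T, 0:1, simplify = FALSE))))
  m <- as.matrix(g)
  dimnames(m) <- list(apply(m, 1L, paste, collapse = ""), NULL)
  storage.mode(m) <- "integer"
  m
}

#' Audit sequence-to-cluster assignment consistency
#'
#' Applies an assigner to every complete binary sequence of length T,
#' several times per sequence, and checks that each sequence always lands
#' in the same cluster. A deterministic assigner (e.g. spell features plus
#' nearest fitted medoid) always passes; an assigner with subject-level
#' randomness (e.g. drawing from posterior class probabilities) can fail.
#'
#' @param assigner function taking a 0/1 vector of length T and returning a
#'   single cluster label.
#' @param T number of epochs.
#' @param replicates calls per sequence used to probe consistency.
#' @return list with \code{table} (data.frame: sequence, cluster) and
#'   \code{consistent} (logical flag).
#' @export
sequenceAudit <- function(assigner, T, replicates = 3L) {
  seqs <- enumerateSequences(T)
  labs <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    calls <- lapply(seq_len(replicates), function(r) assigner(seqs[i, ]))
    if (any(vapply(calls, function(x) length(x) != 1L || is.na(x), TRUE)))
      stop("assigner failed to label sequence ", rownames(seqs)[i])
    labs[[i]] <- calls
  }
  consistent <- all(vapply(labs, function(cl)
    length(unique(vapply(cl, as.character, ""))) == 1L, TRUE))
  list(table = data.frame(sequence = rownames(seqs),
                          cluster = vapply(labs, function(cl)
                            as.character(cl[[1L]]), ""),
                          stringsAsFactors = FALSE),
       consistent = consistent)
}
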