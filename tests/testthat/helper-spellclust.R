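# Shared fixtures and independent oracles, built in code at test time.

tiny_grid <- function(encoding = "ordinal") defaultEpochGrid(encoding)

make_cohort <- function(w, ...) {
  WheezeCohort(w, tiny_grid(), ...)
}

# Feature table with arbitrary values (unit tests of the metric)
make_features <- function(df, ids = paste0("s", seq_len(nrow(df)))) {
  colnames(df) <- c("first_age", "last_age", "n_records", "longest_spell",
                    "n_spells", "spell_type")
  new("SpellFeatures", features = as.data.frame(df), subjectIds = ids,
      grid = tiny_grid())
}

# Direct-formula mixed-distance oracle (double loop, no shared code path)
oracle_mixed_distance <- function(X, kinds, w = rep(1, ncol(X)),
                                  scale = "sd") {
  p <- ncol(X); n <- nrow(X)
  s <- rep(1, p)
  for (k in seq_len(p)) {
    if (kinds[k] != 0) next
    v <- X[, k][!is.na(X[, k])]
    s[k] <- if (scale == "sd") sd(v) else diff(range(v))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(p)) {
      if (w[k] <= 0 || is.na(X[i, k]) || is.na(X[j, k])) next
      g <- if (kinds[k] == 0) ((X[i, k] - X[j, k]) / s[k])^2
           else as.numeric(X[i, k] != X[j, k])
      num <- num + w[k] * g; den <- den + w[k]
    }
    D[i, j] <- sqrt(num / den)
  }
  D
}

# Exhaustive k-medoids optimum (brute force over all medoid subsets)
oracle_pam_opt <- function(D, k) {
  combs <- utils::combn(nrow(D), k)
  min(apply(combs, 2, function(m)
    sum(apply(D[, m, drop = FALSE], 1, min))))
}

# Hand-coded silhouette oracle (per-point loops, no matrix algebra)
oracle_silhouette <- function(D, cl) {
  n <- nrow(D)
  sapply(seq_len(n), function(i) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(sapply(setdiff(unique(cl), cl[i]), function(c2)
      mean(D[i, cl == c2])))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  })
}

# Matches fitted LCA classes to generator classes by theta rows
match_classes <- function(theta_hat, theta_true) {
  k <- nrow(theta_true)
  perms <- spellclust:::permutations_of(k)
  d <- apply(perms, 1, function(p) sum((theta_hat[p, ] - theta_true)^2))
  perms[which.min(d), ]
}
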