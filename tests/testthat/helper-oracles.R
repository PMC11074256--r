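# Independent oracles used to cross-check the implementation, written as
# plain direct summations / exhaustive enumerations so they share no code
# with the vectorized paths they verify.

# Direct-summation entropy in bits.
oracle_entropy <- function(counts) {
  n <- sum(counts)
  h <- 0
  for (c in counts) if (c > 0) h <- h - (c / n) * log2(c / n)
  h
}

oracle_info_gain <- function(parent, children) {
  n <- sum(parent)
  h <- oracle_entropy(parent)
  for (ch in children) h <- h - sum(ch) / n * oracle_entropy(ch)
  h
}

oracle_split_info <- function(sizes) {
  n <- sum(sizes)
  s <- 0
  for (sz in sizes) s <- s - (sz / n) * log2(sz / n)
  s
}

# Exhaustive best-split enumeration: every feature, every midpoint threshold,
# mean-gain guard over positive-gain candidates, maximize gain ratio; ties by
# lower feature index then lower threshold. Returns NULL or
# list(feature, threshold).
oracle_best_split <- function(x, y, min_gain = 1e-6) {
  classes <- sort(unique(y))
  cnt <- function(rows) vapply(classes, function(cl) sum(y[rows] == cl),
                               numeric(1))
  n <- nrow(x)
  parent <- cnt(seq_len(n))
  cand <- list()
  for (fi in seq_len(ncol(x))) {
    v <- sort(unique(x[, fi]))
    if (length(v) < 2) next
    for (t in (v[-1] + v[-length(v)]) / 2) {
      left <- which(x[, fi] <= t)
      right <- which(x[, fi] > t)
      g <- oracle_info_gain(parent, list(cnt(left), cnt(right)))
      si <- oracle_split_info(c(length(left), length(right)))
      cand[[length(cand) + 1]] <- list(fidx = fi, threshold = t,
                                       gain = g, si = si)
    }
  }
  if (!length(cand)) return(NULL)
  gains <- vapply(cand, `[[`, numeric(1), "gain")
  if (max(gains) < min_gain) return(NULL)
  pos <- gains >= min_gain
  mg <- mean(gains[pos])
  adm <- which(gains >= mg - 1e-12 & gains >= min_gain)
  ratios <- vapply(adm, function(i) cand[[i]]$gain / cand[[i]]$si, numeric(1))
  fidx <- vapply(adm, function(i) cand[[i]]$fidx, numeric(1))
  thr <- vapply(adm, function(i) cand[[i]]$threshold, numeric(1))
  # near-ties on the ratio (1e-9 relative) break by feature index then
  # threshold; candidates are already enumerated in (fidx, thr) order
  rmax <- max(ratios)
  b <- adm[which(ratios >= rmax - 1e-9 * max(1, rmax))[1]]
  list(feature = colnames(x)[cand[[b]]$fidx], threshold = cand[[b]]$threshold)
}

# Direct-counting accuracy oracles on a predicted x true count matrix.
oracle_overall_accuracy <- function(m) {
  correct <- 0
  for (i in seq_len(nrow(m))) correct <- correct + m[i, i]
  correct / sum(m)
}

oracle_producer <- function(m, r) {
  tot <- sum(m[, r])
  if (tot == 0) return(NA_real_)
  m[r, r] / tot
}

oracle_user <- function(m, r) {
  tot <- sum(m[r, ])
  if (tot == 0) return(NA_real_)
  m[r, r] / tot
}

oracle_kappa <- function(m) {
  T <- sum(m)
  diag_sum <- 0
  chance <- 0
  for (g in seq_len(nrow(m))) {
    diag_sum <- diag_sum + m[g, g]
    chance <- chance + sum(m[g, ]) * sum(m[, g])
  }
  if (T^2 - chance == 0) return(NA_real_)
  (T * diag_sum - chance) / (T^2 - chance)
}

# Small random labelled table for tree/forest checks.
random_table <- function(n_rows, n_feat, n_classes, seed,
                         integer_features = TRUE) {
  set.seed(seed)
  x <- if (integer_features)
    matrix(sample(0:9, n_rows * n_feat, replace = TRUE), n_rows)
  else matrix(rnorm(n_rows * n_feat), n_rows)
  colnames(x) <- sprintf("f%02d", seq_len(n_feat))
  feature_table(x, label = sample(letters[seq_len(n_classes)], n_rows,
                                  replace = TRUE))
}

# Majority-vote training error of a labelled table.
majority_error <- function(labels) 1 - max(table(labels)) / length(labels)

# Training error of a tree on its own table.
tree_train_error <- function(tree, table) {
  mean(predict_tree(tree, table)$label != table$label)
}

# Tiny two-class table, perfectly separable by a threshold on "sig".
separable_table <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  x <- cbind(sig = c(runif(n_per_class, 0, 1), runif(n_per_class, 2, 3)),
             noise = rnorm(2 * n_per_class))
  feature_table(x, label = rep(c("a", "b"), each = n_per_class))
}
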