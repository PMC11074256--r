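# Random forest of gain-ratio trees with bagging and positive-class-aware
# weighted feature subsampling. The per-feature sampling weights mix a
# uniform floor with each feature's one-vs-rest gain-ratio score for the
# positive (minority) class: the score term raises the chance of drawing
# features that help classify positive objects, while the uniform floor keeps
# every feature — including those useful only for the negative class — in
# play.

#' Forest configuration
#'
#' @param n_trees number of trees (default 100).
#' @param m_features features sampled per tree; default `ceiling(sqrt(F))`
#'   at training time when `NULL` (10 for the 85-feature manifest).
#' @param positive_class label of the positive (minority) class whose
#'   separability drives the feature weights; default: the rarest class.
#' @param lambda_weight mixing fraction in `[0, 1]` between the uniform floor
#'   (`1 - lambda`) and the normalized gain-ratio scores (`lambda`);
#'   `0` reduces to a classical uniform-feature random forest (default 0.5).
#' @param bootstrap draw a with-replacement bootstrap per tree (default TRUE).
#' @param prune prune each tree pessimistically (default TRUE).
#' @param per_tree_weights recompute feature weights on each bootstrap
#'   sample instead of once on the full table (default FALSE).
#' @param tree_config a [tree_config()].
#' @param seed integer seed; each tree uses the named substream
#'   `"tree_<i>"` so trees are independent and order-insensitive.
#' @return a `forest_config` list.
#' @export
forest_config <- function(n_trees = 100, m_features = NULL,
                          positive_class = NULL, lambda_weight = 0.5,
                          bootstrap = TRUE, prune = TRUE,
                          per_tree_weights = FALSE,
                          tree_config = vegrf::tree_config(), seed = 1L) {
  stopifnot(is_count(n_trees), n_trees >= 1,
            lambda_weight >= 0, lambda_weight <= 1)
  if (!is.null(m_features)) stopifnot(is_count(m_features), m_features >= 1)
  structure(list(n_trees = as.integer(n_trees), m_features = m_features,
                 positive_class = positive_class,
                 lambda_weight = lambda_weight,
                 bootstrap = isTRUE(bootstrap), prune = isTRUE(prune),
                 per_tree_weights = isTRUE(per_tree_weights),
                 tree_config = tree_config, seed = as.integer(seed)),
            class = "forest_config")
}

#' Positive-class-aware feature sampling weights
#'
#' Scores each feature by its best single-split gain ratio on the one-vs-rest
#' problem (positive class vs all others), under the same mean-gain guard as
#' [best_split()], pooled across all features' candidates; features with no
#' admissible split score 0. The sampling weights are the mixture
#' `(1 - lambda) / F + lambda * score / sum(score)` (uniform when all scores
#' are 0), so they sum to 1 and every feature keeps a weight of at least
#' `(1 - lambda) / F` (floored at a strictly positive minimum so no feature
#' is ever unselectable).
#'
#' @param table a labelled [feature_table()] containing `positive_class`.
#' @param positive_class the positive class label.
#' @param lambda_weight mixing fraction in `[0, 1]`.
#' @param tree_config a [tree_config()] (supplies `min_gain`).
#' @return named numeric vector of per-feature probabilities summing to 1.
#' @export
compute_feature_weights <- function(table, positive_class,
                                    lambda_weight = 0.5,
                                    tree_config = vegrf::tree_config()) {
  if (is.null(table$label)) stop("table must be labelled")
  if (!positive_class %in% table$label)
    stop("positive_class '", positive_class, "' absent from table")
  x <- feature_matrix(table)
  f <- ncol(x)
  yi <- ifelse(table$label == positive_class, 1L, 2L)
  scans <- lapply(seq_len(f), function(j)
    split_scan(x[, j], yi, 2L, tree_config$min_leaf))
  pos_gains <- unlist(lapply(scans, function(s)
    if (is.null(s)) numeric(0) else s$gain[s$gain >= tree_config$min_gain]))
  scores <- if (!length(pos_gains)) numeric(f) else {
    mg <- mean(pos_gains)
    vapply(scans, function(s) {
      if (is.null(s)) return(0)
      adm <- s$gain >= tree_config$min_gain & s$gain >= mg - 1e-12
      if (!any(adm)) return(0)
      max(s$gain[adm] / s$split_info[adm])
    }, numeric(1))
  }
  w <- if (sum(scores) > 0)
    (1 - lambda_weight) / f + lambda_weight * scores / sum(scores)
  else rep(1 / f, f)
  names(w) <- colnames(x)
  w <- pmax(w, 1e-12)
  w / sum(w)
}

#' Weighted feature subsampling without replacement
#'
#' Sequential draw with renormalization (the behaviour of [sample()] with a
#' `prob` argument and `replace = FALSE`).
#'
#' @param weights named per-feature probabilities.
#' @param m subset size, `m <= length(weights)`.
#' @return character vector of `m` distinct feature names.
#' @export
sample_features <- function(weights, m) {
  f <- length(weights)
  if (m > f) stop("m exceeds the number of features")
  if (m == f) return(names(weights))
  names(weights)[sample.int(f, m, replace = FALSE, prob = weights)]
}

#' Bootstrap sample of row indices
#'
#' `n` draws with replacement; the out-of-bag set is the complement, with
#' expected OOB fraction `(1 - 1/n)^n` (about `exp(-1)` for large `n`).
#'
#' @param n number of rows (>= 1).
#' @return list with integer vectors `in_bag` (length `n`) and `oob`.
#' @export
bootstrap_sample <- function(n) {
  stopifnot(is_count(n), n >= 1)
  in_bag <- sample.int(n, n, replace = TRUE)
  list(in_bag = in_bag, oob = setdiff(seq_len(n), in_bag))
}

#' Train the weighted-feature random forest
#'
#' Grows (and by default prunes) `n_trees` gain-ratio trees, each on its own
#' bootstrap sample restricted to `m_features` features drawn without
#' replacement under the positive-class-aware weights. The model records the
#' per-tree feature subsets and out-of-bag row sets, so [oob_score()] and
#' [feature_importance()] need no retraining. Fully determined by
#' `(seed, config, table)`.
#'
#' @param table a labelled [feature_table()] with at least two classes.
#' @param config a [forest_config()].
#' @return an object of class `veg_forest`.
#' @export
train_forest <- function(table, config = forest_config()) {
  if (is.null(table$label)) stop("table must be labelled")
  classes <- sort(unique(table$label))
  if (length(classes) < 2) stop("single-class table: need >= 2 classes")
  fnames <- feature_names(table)
  f <- length(fnames)
  m <- config$m_features %||% ceiling(sqrt(f))
  if (m > f) stop("m_features exceeds the number of features")
  positive <- config$positive_class %||%
    names(which.min(table(table$label)))
  weights <- compute_feature_weights(table, positive, config$lambda_weight,
                                     config$tree_config)
  n <- nrow(table)
  trees <- vector("list", config$n_trees)
  subsets <- vector("list", config$n_trees)
  oob_sets <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    with_seed(substream_seed(config$seed, paste0("tree_", i)), {
      if (config$bootstrap) {
        bs <- bootstrap_sample(n)
        rows <- bs$in_bag
        oob_sets[[i]] <- bs$oob
      } else {
        rows <- seq_len(n)
        oob_sets[[i]] <- integer(0)
      }
      w_i <- if (config$per_tree_weights)
        compute_feature_weights(table[rows, , drop = FALSE], positive,
                                config$lambda_weight, config$tree_config)
      else weights
      feats <- sort(sample_features(w_i, m))
      tr <- grow_tree(table[rows, , drop = FALSE], feats,
                      config$tree_config, classes = classes)
      if (config$prune) tr <- prune_tree(tr)
      trees[[i]] <- tr
      subsets[[i]] <- feats
    })
  }
  structure(list(trees = trees, feature_subsets = subsets,
                 oob_sets = oob_sets, feature_weights = weights,
                 classes = classes, positive_class = positive,
                 feature_names = fnames, n_train = n, config = config),
            class = "veg_forest")
}

# Tie-break helper: majority vote, ties by higher summed leaf probability,
# then lexicographic (classes are kept sorted).
vote_labels <- function(votes, probsum, classes) {
  n <- nrow(votes)
  vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1) {
      p <- probsum[i, top]
      top <- top[p == max(p)]
    }
    classes[top[1]]
  }, character(1))
}

#' Predict with a trained forest
#'
#' Per-row majority vote over the trees; ties are broken by the higher summed
#' leaf probability, then by lexicographic class label.
#'
#' @param model a [train_forest()] result.
#' @param newdata a [feature_table()] or data frame with every feature any
#'   tree uses.
#' @return list with `label` (character), `votes` (rows x classes vote
#'   fractions, rows summing to 1) and `prob` (mean leaf probabilities).
#' @export
predict_forest <- function(model, newdata) {
  nt <- length(model$trees)
  classes <- model$classes
  x <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, setdiff(colnames(newdata), c("object_id", "label")),
                      drop = FALSE])
  need <- unique(unlist(lapply(model$trees, tree_features_used)))
  missing <- setdiff(need, colnames(x))
  if (length(missing)) stop("missing feature(s): ",
                            paste(missing, collapse = ", "))
  n <- nrow(x)
  votes <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  probsum <- votes
  for (tr in model$trees) {
    p <- predict_tree(tr, x)
    votes[cbind(seq_len(n), match(p$label, classes))] <-
      votes[cbind(seq_len(n), match(p$label, classes))] + 1
    probsum <- probsum + p$prob[, classes, drop = FALSE]
  }
  list(label = vote_labels(votes, probsum, classes),
       votes = votes / nt, prob = probsum / nt)
}

#' Out-of-bag accuracy of a bagged forest
#'
#' Each training row is predicted only by the trees whose bootstrap sample
#' did not contain it. Rows that are in-bag for every tree are excluded from
#' the accuracy and reported in `n_excluded`.
#'
#' @param model a [train_forest()] result trained with `bootstrap = TRUE`.
#' @param table the training [feature_table()] (same row order).
#' @return list with `overall` accuracy, `per_class` recall (named by true
#'   class; `NA` for classes never scored), `n_excluded`, and the OOB
#'   `predictions` (`NA` for excluded rows).
#' @export
oob_score <- function(model, table) {
  if (!model$config$bootstrap) stop("oob_score requires bootstrap = TRUE")
  if (is.null(table$label)) stop("table must be labelled")
  n <- nrow(table)
  if (n != model$n_train) stop("table does not match the training table size")
  classes <- model$classes
  x <- feature_matrix(table)
  votes <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  probsum <- votes
  covered <- rep(FALSE, n)
  for (i in seq_along(model$trees)) {
    oob <- model$oob_sets[[i]]
    if (!length(oob)) next
    covered[oob] <- TRUE
    p <- predict_tree(model$trees[[i]], x[oob, , drop = FALSE])
    ij <- cbind(oob, match(p$label, classes))
    votes[ij] <- votes[ij] + 1
    probsum[oob, ] <- probsum[oob, ] + p$prob[, classes, drop = FALSE]
  }
  pred <- rep(NA_character_, n)
  if (any(covered))
    pred[covered] <- vote_labels(votes[covered, , drop = FALSE],
                                 probsum[covered, , drop = FALSE], classes)
  truth <- table$label
  per_class <- vapply(classes, function(cl) {
    sel <- covered & truth == cl
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] == cl)
  }, numeric(1))
  list(overall = mean(pred[covered] == truth[covered]),
       per_class = per_class, n_excluded = sum(!covered),
       predictions = pred)
}

#' Gain-weighted feature importance
#'
#' For every internal node, the node's information gain times the fraction of
#' training rows reaching it is credited to the split feature; credits are
#' summed over all trees and normalized to sum 1. Features never used score 0.
#'
#' @param model a [train_forest()] result.
#' @return named numeric vector over all features, summing to 1 when any
#'   split exists (all zero otherwise).
#' @export
feature_importance <- function(model) {
  imp <- stats::setNames(numeric(length(model$feature_names)),
                         model$feature_names)
  for (tr in model$trees) {
    root_n <- tr$root$n
    walk <- function(node) {
      if (node$leaf) return(invisible())
      imp[node$split$feature] <<- imp[node$split$feature] +
        node$split$info_gain * node$n / root_n
      walk(node$left)
      walk(node$right)
    }
    walk(tr$root)
  }
  s <- sum(imp)
  if (s > 0) imp / s else imp
}

#' Serialize a forest model to a JSON bundle
#'
#' The bundle holds the config, feature weights, class labels, per-tree
#' feature subsets and trees; round-trips losslessly through
#' [forest_from_json()] (out-of-bag row sets included so OOB scoring
#' survives the round trip).
#'
#' @param model a `veg_forest`.
#' @param path optional file path.
#' @return the JSON string (invisibly when written to a file).
#' @export
forest_to_json <- function(model, path = NULL) {
  cfg <- unclass(model$config)
  cfg$tree_config <- unclass(cfg$tree_config)
  obj <- list(
    format = "vegrf_forest", version = "1",
    config = cfg, classes = model$classes,
    positive_class = model$positive_class,
    feature_names = model$feature_names,
    feature_weights = as.list(model$feature_weights),
    n_train = model$n_train,
    feature_subsets = model$feature_subsets,
    oob_sets = model$oob_sets,
    trees = lapply(model$trees, function(tr)
      list(classes = tr$classes, features = tr$features,
           root = node_to_list(tr$root)))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a forest model from a JSON bundle
#' @param json JSON string or file path from [forest_to_json()].
#' @return a `veg_forest`.
#' @export
forest_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(obj$format, "vegrf_forest")) stop("not a vegrf forest bundle")
  cfg <- obj$config
  tc <- cfg$tree_config
  tc$max_depth <- if (is.character(tc$max_depth %||% Inf)) Inf else
    tc$max_depth %||% Inf
  cfg$tree_config <- do.call(tree_config, tc)
  cfg$m_features <- cfg$m_features %||% NULL
  cfg$positive_class <- cfg$positive_class %||% NULL
  config <- do.call(forest_config, cfg)
  classes <- unlist(obj$classes)
  trees <- lapply(obj$trees, function(t)
    structure(list(root = node_from_list(t$root, unlist(t$classes)),
                   classes = unlist(t$classes),
                   features = unlist(t$features),
                   config = config$tree_config),
              class = "c50_tree"))
  structure(list(trees = trees,
                 feature_subsets = lapply(obj$feature_subsets, unlist),
                 oob_sets = lapply(obj$oob_sets, function(v)
                   as.integer(unlist(v) %||% integer(0))),
                 feature_weights = unlist(obj$feature_weights),
                 classes = classes,
                 positive_class = obj$positive_class,
                 feature_names = unlist(obj$feature_names),
                 n_train = obj$n_train, config = config),
            class = "veg_forest")
}

#' @export
print.veg_forest <- function(x, ...) {
  cat(sprintf(
    "veg_forest: %d trees, %d features (m = %d per tree), classes: %s\n",
    length(x$trees), length(x$feature_names),
    length(x$feature_subsets[[1]]), paste(x$classes, collapse = ", ")))
  invisible(x)
}
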