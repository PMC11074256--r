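# From-scratch C5.0-style decision-tree induction: entropy, information gain,
# gain ratio, binary numeric splits with the C4.5 mean-gain guard, recursive
# partitioning, and bottom-up pessimistic pruning.

#' Tree induction configuration
#'
#' @param min_split smallest node size that may be split (default 2).
#' @param min_leaf smallest allowed child size (default 2, the classic
#'   C4.5/C5.0 "minimum cases" setting; singleton leaves make spurious trees
#'   immune to leaf-summed pessimistic pruning).
#' @param min_gain smallest admissible information gain in bits; absorbs
#'   floating-point noise (default 1e-6).
#' @param max_depth maximum tree depth, `Inf` for unlimited.
#' @param prune_confidence confidence level of the pessimistic-pruning upper
#'   binomial bound, in `(0, 0.5]` (default 0.25, the classic C4.5 value).
#' @return a `tree_config` list.
#' @export
tree_config <- function(min_split = 2, min_leaf = 2, min_gain = 1e-6,
                        max_depth = Inf, prune_confidence = 0.25) {
  stopifnot(min_leaf >= 1, min_split >= 2, min_gain >= 0,
            max_depth >= 1, prune_confidence > 0, prune_confidence <= 0.5)
  structure(list(min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf),
                 min_gain = min_gain, max_depth = max_depth,
                 prune_confidence = prune_confidence),
            class = "tree_config")
}

#' Shannon entropy of class counts, in bits
#'
#' `-sum(p log2 p)` over classes with positive count.
#'
#' @param class_counts non-negative integer vector, not all zero.
#' @return entropy in bits.
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0)) stop("class counts must be >= 0")
  n <- sum(class_counts)
  if (n == 0) stop("class counts must not all be zero")
  plogp2(class_counts / n)
}

#' Information gain of a partition, in bits
#'
#' `entropy(parent) - sum (n_child / n) entropy(child)`; always >= 0.
#'
#' @param parent_counts class counts at the parent node.
#' @param children_counts list of class-count vectors, one per child; they
#'   must sum (classwise) to `parent_counts`.
#' @return information gain in bits.
#' @export
info_gain <- function(parent_counts, children_counts) {
  tot <- Reduce(`+`, children_counts)
  if (!isTRUE(all.equal(unname(tot), unname(parent_counts))))
    stop("children counts must sum to parent counts")
  n <- sum(parent_counts)
  wh <- sum(vapply(children_counts,
                   function(ch) sum(ch) / n * entropy(ch), numeric(1)))
  max(0, entropy(parent_counts) - wh)
}

#' Split information of a partition, in bits
#'
#' Entropy of the partition's size distribution: `-sum (n_i/n) log2 (n_i/n)`.
#'
#' @param children_sizes positive child sizes, at least two children.
#' @return split information in bits.
#' @export
split_info <- function(children_sizes) {
  if (length(children_sizes) < 2) stop("need at least two children")
  if (any(children_sizes <= 0)) stop("children sizes must be positive")
  plogp2(children_sizes / sum(children_sizes))
}

# Row-wise entropy (bits) of a count matrix.
row_entropy <- function(M) {
  n <- rowSums(M)
  p <- M / ifelse(n > 0, n, 1)
  t1 <- ifelse(p > 0, p * log2(p), 0)
  -rowSums(t1)
}

# All candidate binary splits of one numeric feature: thresholds are
# midpoints between consecutive distinct sorted values. Returns a list of
# vectors (threshold, gain, split_info, n_left) or NULL if the feature is
# constant. y must be an integer class code in 1..k.
split_scan <- function(x, y, k, min_leaf = 1L) {
  n <- length(x)
  ord <- order(x, method = "radix")
  xs <- x[ord]
  ys <- y[ord]
  cut_idx <- which(diff(xs) > 0)
  if (min_leaf > 1)
    cut_idx <- cut_idx[cut_idx >= min_leaf & (n - cut_idx) >= min_leaf]
  if (!length(cut_idx)) return(NULL)
  cum <- vapply(seq_len(k), function(cl) cumsum(ys == cl),
                numeric(n))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  left <- cum[cut_idx, , drop = FALSE]
  total <- cum[n, ]
  right <- sweep(-left, 2, total, `+`)
  nl <- cut_idx
  nr <- n - nl
  h_parent <- entropy(total)
  gain <- h_parent - (nl * row_entropy(left) + nr * row_entropy(right)) / n
  pl <- nl / n
  si <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
  list(threshold = (xs[cut_idx] + xs[cut_idx + 1]) / 2,
       gain = pmax(0, gain), split_info = si, n_left = nl)
}

#' Best binary split under the gain-ratio criterion
#'
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' values of each feature. Following the C4.5 guard against the gain-ratio
#' bias toward near-trivial splits, only candidates whose information gain is
#' at least the mean gain of all positive-gain candidates (gain at or above
#' `min_gain`, which absorbs floating-point noise) compete, and among
#' them the one maximizing gain ratio wins. Ties are broken by lower feature
#' position in `features`, then lower threshold. Returns `NULL` when no
#' candidate reaches `min_gain`.
#'
#' @param x numeric feature matrix (rows = objects).
#' @param y factor or character class labels, one per row.
#' @param features feature names (columns of `x`) to consider, in manifest
#'   order.
#' @param config a [tree_config()].
#' @return a list `(feature, threshold, info_gain, split_info, gain_ratio)`
#'   of class `split_candidate`, or `NULL`.
#' @export
best_split <- function(x, y, features = colnames(x), config = tree_config()) {
  if (!length(features)) stop("empty feature set")
  y <- factor(y)
  sp <- best_split_core(x[, features, drop = FALSE], as.integer(y),
                        nlevels(y), config)
  if (is.null(sp)) return(NULL)
  structure(list(feature = features[sp$fidx], threshold = sp$threshold,
                 info_gain = sp$gain, split_info = sp$split_info,
                 gain_ratio = sp$gain / sp$split_info),
            class = "split_candidate")
}

# Hot path shared by best_split and grow_tree: x already restricted to the
# candidate features (columns in manifest order), y as integer codes 1..k.
best_split_core <- function(x, yi, k, config) {
  nf <- ncol(x)
  scans <- vector("list", nf)
  gain_sum <- 0
  gain_n <- 0L
  gain_max <- 0
  for (fi in seq_len(nf)) {
    s <- split_scan(x[, fi], yi, k, config$min_leaf)
    scans[fi] <- list(s)
    if (is.null(s)) next
    pos <- s$gain >= config$min_gain
    gain_sum <- gain_sum + sum(s$gain[pos])
    gain_n <- gain_n + sum(pos)
    gain_max <- max(gain_max, s$gain[pos], 0)
  }
  if (gain_n == 0L || gain_max < config$min_gain) return(NULL)
  mean_gain <- gain_sum / gain_n
  # gain-ratio ties (within a 1e-9 relative tolerance, robust to float-path
  # noise between mathematically identical partitions) break to the lower
  # feature index, then the lower threshold
  cands <- vector("list", nf)
  for (fi in seq_len(nf)) {
    s <- scans[[fi]]
    if (is.null(s)) next
    adm <- which(s$gain >= mean_gain - 1e-12 & s$gain >= config$min_gain)
    if (!length(adm)) next
    ratio <- s$gain[adm] / s$split_info[adm]
    rmax <- max(ratio)
    o <- adm[which(ratio >= rmax - 1e-9 * max(1, rmax))[1]] # lowest threshold
    cands[[fi]] <- list(fidx = fi, threshold = s$threshold[o],
                        gain = s$gain[o], split_info = s$split_info[o],
                        ratio = s$gain[o] / s$split_info[o])
  }
  cands <- cands[!vapply(cands, is.null, logical(1))]
  if (!length(cands)) return(NULL)
  ratios <- vapply(cands, `[[`, numeric(1), "ratio")
  rmax <- max(ratios)
  cands[[which(ratios >= rmax - 1e-9 * max(1, rmax))[1]]] # lowest fidx
}

node_counts <- function(yi, k, classes) {
  cnt <- tabulate(yi, nbins = k)
  names(cnt) <- classes
  cnt
}

#' Grow a gain-ratio decision tree
#'
#' Recursive binary partitioning on numeric features using [best_split()];
#' recursion stops at node purity, `min_split`, `max_depth`, or when no
#' admissible split remains. Leaves store per-class training counts.
#'
#' @param table a labelled [feature_table()].
#' @param features feature names to consider (default: all).
#' @param config a [tree_config()].
#' @param classes full class-label set; defaults to the labels present.
#'   Supplying it lets a tree trained on a subsample (which may miss a rare
#'   class) keep the full class dimension in its leaf counts.
#' @return an object of class `c50_tree`.
#' @export
grow_tree <- function(table, features = feature_names(table),
                      config = tree_config(), classes = NULL) {
  if (is.null(table$label)) stop("grow_tree requires a labelled table")
  if (is.null(classes)) classes <- sort(unique(table$label))
  if (!all(table$label %in% classes)) stop("labels outside the class set")
  y <- factor(table$label, levels = classes)
  yi <- as.integer(y)
  k <- length(classes)
  x <- as.matrix(table[, features, drop = FALSE]) # only candidate features
  build <- function(rows, depth) {
    cnt <- node_counts(yi[rows], k, classes)
    pure <- sum(cnt > 0) <= 1
    if (pure || length(rows) < config$min_split || depth >= config$max_depth)
      return(list(leaf = TRUE, counts = cnt, n = length(rows), depth = depth))
    sp <- best_split_core(x[rows, , drop = FALSE], yi[rows], k, config)
    if (is.null(sp))
      return(list(leaf = TRUE, counts = cnt, n = length(rows), depth = depth))
    split <- structure(list(feature = features[sp$fidx],
                            threshold = sp$threshold,
                            info_gain = sp$gain, split_info = sp$split_info,
                            gain_ratio = sp$ratio),
                       class = "split_candidate")
    go_left <- x[rows, sp$fidx] <= sp$threshold
    list(leaf = FALSE, counts = cnt, n = length(rows), depth = depth,
         split = split,
         left = build(rows[go_left], depth + 1),
         right = build(rows[!go_left], depth + 1))
  }
  structure(list(root = build(seq_len(nrow(x)), 0L), classes = classes,
                 features = features, config = config),
            class = "c50_tree")
}

# Upper confidence bound on the binomial error rate at confidence cf
# (Clopper-Pearson upper limit); e errors in n trials.
pessimistic_error_rate <- function(e, n, cf) {
  if (n == 0) return(0)
  if (e >= n) return(1)
  stats::qbeta(1 - cf, e + 1, n - e)
}

# Pessimistic error count of a node treated as a leaf.
leaf_pessimistic <- function(counts, cf) {
  n <- sum(counts)
  e <- n - max(counts)
  n * pessimistic_error_rate(e, n, cf)
}

subtree_pessimistic <- function(node, cf) {
  if (node$leaf) return(leaf_pessimistic(node$counts, cf))
  subtree_pessimistic(node$left, cf) + subtree_pessimistic(node$right, cf)
}

#' Pessimistic (C4.5-style) bottom-up pruning
#'
#' A subtree is replaced by a leaf when the leaf's pessimistic training
#' error — `n` times the upper binomial confidence bound at
#' `prune_confidence` on the node's training errors — does not exceed the sum
#' of its leaves' pessimistic errors. Node count never increases, and the
#' tree's total pessimistic error bound never increases.
#'
#' @param tree a [grow_tree()] result.
#' @param config a [tree_config()] (supplies `prune_confidence`).
#' @return the pruned `c50_tree`.
#' @export
prune_tree <- function(tree, config = tree$config) {
  cf <- config$prune_confidence
  prune <- function(node) {
    if (node$leaf) return(node)
    node$left <- prune(node$left)
    node$right <- prune(node$right)
    as_leaf <- leaf_pessimistic(node$counts, cf)
    keep <- subtree_pessimistic(node$left, cf) +
      subtree_pessimistic(node$right, cf)
    if (as_leaf <= keep)
      return(list(leaf = TRUE, counts = node$counts, n = node$n,
                  depth = node$depth))
    node
  }
  tree$root <- prune(tree$root)
  tree
}

#' Number of nodes in a tree
#' @param tree a `c50_tree`.
#' @return integer node count (leaves + internal nodes).
#' @export
tree_size <- function(tree) {
  count <- function(node)
    if (node$leaf) 1L else 1L + count(node$left) + count(node$right)
  count(tree$root)
}

#' Total pessimistic training-error bound of a tree
#' @param tree a `c50_tree`.
#' @param config a [tree_config()] (supplies `prune_confidence`).
#' @return the summed pessimistic error over the tree's leaves.
#' @export
tree_pessimistic_error <- function(tree, config = tree$config) {
  subtree_pessimistic(tree$root, config$prune_confidence)
}

route_rows <- function(node, x, rows, assign_leaf) {
  if (!length(rows)) return(invisible())
  if (node$leaf) {
    assign_leaf(rows, node)
    return(invisible())
  }
  go_left <- x[rows, node$split$feature] <= node$split$threshold
  route_rows(node$left, x, rows[go_left], assign_leaf)
  route_rows(node$right, x, rows[!go_left], assign_leaf)
}

#' Predict with a decision tree
#'
#' Routes each row by the stored thresholds; the label is the argmax of the
#' reached leaf's class counts (ties broken by class order) and the
#' probabilities are the normalized leaf counts.
#'
#' @param tree a `c50_tree`.
#' @param newdata a [feature_table()], data frame or numeric matrix carrying
#'   every feature the tree uses.
#' @return list with `label` (character vector) and `prob` (rows x classes
#'   matrix, rows summing to 1).
#' @export
predict_tree <- function(tree, newdata) {
  x <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, setdiff(colnames(newdata), c("object_id", "label")),
                      drop = FALSE])
  used <- tree_features_used(tree)
  missing <- setdiff(used, colnames(x))
  if (length(missing)) stop("missing feature(s): ",
                            paste(missing, collapse = ", "))
  n <- nrow(x)
  prob <- matrix(0, n, length(tree$classes),
                 dimnames = list(NULL, tree$classes))
  route_rows(tree$root, x, seq_len(n), function(rows, node) {
    p <- node$counts / sum(node$counts)
    prob[rows, ] <<- matrix(p, length(rows), length(p), byrow = TRUE)
  })
  lab <- tree$classes[max.col(prob, ties.method = "first")]
  list(label = lab, prob = prob)
}

#' Features actually used by a tree's splits
#' @param tree a `c50_tree`.
#' @return character vector of feature names (possibly empty).
#' @export
tree_features_used <- function(tree) {
  walk <- function(node) {
    if (node$leaf) return(character(0))
    c(node$split$feature, walk(node$left), walk(node$right))
  }
  unique(walk(tree$root))
}

node_to_list <- function(node) {
  if (node$leaf)
    return(list(leaf = TRUE, class_counts = as.list(node$counts),
                n = node$n, depth = node$depth))
  list(leaf = FALSE, feature_name = node$split$feature,
       threshold = node$split$threshold,
       info_gain = node$split$info_gain,
       split_info = node$split$split_info,
       class_counts = as.list(node$counts), n = node$n, depth = node$depth,
       left = node_to_list(node$left), right = node_to_list(node$right))
}

node_from_list <- function(l, classes) {
  cnt <- unlist(l$class_counts)[classes]
  if (isTRUE(l$leaf))
    return(list(leaf = TRUE, counts = cnt, n = l$n, depth = l$depth))
  list(leaf = FALSE, counts = cnt, n = l$n, depth = l$depth,
       split = structure(list(feature = l$feature_name,
                              threshold = l$threshold,
                              info_gain = l$info_gain,
                              split_info = l$split_info,
                              gain_ratio = l$info_gain / l$split_info),
                         class = "split_candidate"),
       left = node_from_list(l$left, classes),
       right = node_from_list(l$right, classes))
}

#' Serialize a tree to JSON
#' @param tree a `c50_tree`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(classes = tree$classes, features = tree$features,
              config = unclass(tree$config), root = node_to_list(tree$root))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a tree from JSON
#' @param json a JSON string or file path produced by [tree_to_json()].
#' @return a `c50_tree`.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  cfg <- obj$config
  cfg$max_depth <- cfg$max_depth %||% Inf
  if (is.character(cfg$max_depth)) cfg$max_depth <- Inf
  structure(list(root = node_from_list(obj$root, unlist(obj$classes)),
                 classes = unlist(obj$classes),
                 features = unlist(obj$features),
                 config = do.call(tree_config, cfg)),
            class = "c50_tree")
}

#' @export
print.c50_tree <- function(x, ...) {
  cat(sprintf("c50_tree: %d nodes, classes: %s\n", tree_size(x),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}
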