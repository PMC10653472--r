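#' Forest growth parameters
#'
#' @param n_trees number of trees.
#' @param mtry candidate features per split; default `ceiling(sqrt(p))`,
#'   resolved at fit time.
#' @param min_node minimal node size (nodes smaller than `2 * min_node`
#'   become leaves); default 1 grows trees to purity, the classification
#'   default.
#' @param max_depth optional depth cap (`NULL` = unlimited).
#' @param bootstrap grow each tree on an in-tree bootstrap (default); turn
#'   off only for deterministic single-tree fixtures.
#' @param seed integer seed.
#' @return an object of class `mirf_forest_params`.
#' @export
forest_params <- function(n_trees = 500, mtry = NULL, min_node = 1,
                          max_depth = NULL, bootstrap = TRUE, seed = 1) {
  if (n_trees < 1) stop_config("n_trees", "must be >= 1")
  if (min_node < 1) stop_config("min_node", "must be >= 1")
  structure(
    list(n_trees = as.integer(n_trees), mtry = mtry,
         min_node = as.integer(min_node), max_depth = max_depth,
         bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
    class = "mirf_forest_params"
  )
}

#' Parameters for generalized Random Intersection Trees
#'
#' Defaults follow the reference RIT implementation: 500 intersection
#' trees of depth 5 with binary branching, reporting sets of order >= 2.
#'
#' @param n_rit_trees number of intersection trees.
#' @param depth tree depth `D`; every surviving leaf set is the
#'   intersection of `depth + 1` sampled itemsets along its branch.
#' @param n_child branching factor.
#' @param min_order smallest reported interaction order.
#' @return an object of class `mirf_rit_params`.
#' @export
rit_params <- function(n_rit_trees = 500, depth = 5, n_child = 2,
                       min_order = 2) {
  vals <- c(n_rit_trees = n_rit_trees, depth = depth, n_child = n_child,
            min_order = min_order)
  if (any(vals < 1)) stop_config(names(vals)[which(vals < 1)[1]], "must be >= 1")
  structure(as.list(lapply(vals, as.integer)), class = "mirf_rit_params")
}

check_xy <- function(X, y) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) {
    stop("y must contain both classes", call. = FALSE)
  }
  list(X = X, y = y)
}

#' Fit a feature-weighted random forest
#'
#' Classification forest of axis-aligned trees grown on in-tree bootstrap
#' samples. At every split, `mtry` distinct candidate features are drawn
#' without replacement with probability proportional to `feature_weights`;
#' the winning split maximizes the count-weighted Gini decrease
#' `n * G(parent) - n_L * G(left) - n_R * G(right)`. Importances are the
#' per-tree sums of these decreases averaged over trees ("mean decrease in
#' Gini impurity" on the count-weighted scale).
#'
#' @param X samples x features numeric matrix.
#' @param y binary 0/1 labels (or a two-level factor).
#' @param feature_weights nonnegative sampling weights, one per feature;
#'   `NULL` for uniform. Features with zero weight are never candidates and
#'   thus have importance exactly zero.
#' @param params a [forest_params()] object.
#' @return an object of class `mirf_forest` with elements `trees`,
#'   `importances` (named), `feature_weights`, `params`, `feature_names`.
#' @export
fit_weighted_forest <- function(X, y, feature_weights = NULL,
                                params = forest_params()) {
  xy <- check_xy(X, y)
  X <- xy$X; y <- xy$y
  p <- ncol(X)
  w <- feature_weights %||% rep(1, p)
  if (length(w) != p) stop("feature_weights length must equal ncol(X)",
                           call. = FALSE)
  if (any(w < 0) || all(w == 0)) {
    stop("feature_weights must be nonnegative with at least one positive",
         call. = FALSE)
  }
  w <- w / sum(w)
  mtry <- params$mtry %||% ceiling(sqrt(p))
  mtry <- max(1L, min(as.integer(mtry), p))
  max_depth <- if (is.null(params$max_depth)) -1L else
    as.integer(params$max_depth)
  fit <- cpp_grow_forest(X, y, w, params$n_trees, mtry, params$min_node,
                         max_depth, params$bootstrap %||% TRUE, params$seed)
  feature_names <- colnames(X) %||% paste0("V", seq_len(p))
  imp <- as.numeric(fit$importances)
  names(imp) <- feature_names
  structure(
    list(trees = fit$trees, importances = imp, feature_weights = w,
         params = params, mtry = mtry, feature_names = feature_names),
    class = "mirf_forest"
  )
}

#' @export
print.mirf_forest <- function(x, ...) {
  cat(sprintf("weighted random forest: %d trees, %d features, mtry = %d\n",
              length(x$trees), length(x$importances), x$mtry))
  invisible(x)
}

#' Predict class-1 probabilities
#'
#' Mean over trees of the leaf class-1 fraction.
#'
#' @param object a `mirf_forest`.
#' @param newdata samples x features matrix with the training feature order.
#' @param ... unused.
#' @return numeric vector of class-1 probabilities.
#' @export
predict.mirf_forest <- function(object, newdata, ...) {
  as.numeric(cpp_predict_forest(object$trees, as.matrix(newdata)))
}

#' Mean decrease in Gini impurity
#'
#' Count-weighted importances: for feature `j`,
#' `(1 / n_trees) * sum over trees and nodes splitting on j` of the
#' count-weighted Gini decrease. The count weighting keeps values on the
#' scale where the retention threshold `gini_min = 1` is meaningful; note
#' this scale grows with the training-set size.
#'
#' @param forest a `mirf_forest`.
#' @return named numeric vector of importances (all `>= 0`).
#' @export
gini_importance <- function(forest) {
  stopifnot(inherits(forest, "mirf_forest"))
  forest$importances
}

#' Iteratively reweighted random forest
#'
#' Iteration 1 uses uniform feature weights; iteration `k > 1` samples
#' split candidates proportionally to the previous iteration's Gini
#' importances, floored at `1e-6` of the maximum so that no feature is
#' permanently excluded by one unlucky forest. Returns the iteration-`K`
#' forest.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param K number of iterations (`K = 1` is a plain random forest).
#' @param params a [forest_params()]; iteration `k` uses the substream seed
#'   `derive_seed(params$seed, k)`.
#' @return list with `forest` (the final `mirf_forest`), `weights` (the
#'   weights used to grow it) and `weight_history` (K x p matrix).
#' @export
iterate_reweighted_forest <- function(X, y, K = 5, params = forest_params()) {
  stopifnot(K >= 1)
  p <- ncol(X)
  w <- rep(1 / p, p)
  history <- matrix(NA_real_, nrow = K, ncol = p,
                    dimnames = list(NULL, colnames(X)))
  forest <- NULL
  for (k in seq_len(K)) {
    history[k, ] <- w
    pk <- params
    pk$seed <- derive_seed(params$seed, k)
    forest <- fit_weighted_forest(X, y, w, pk)
    imp <- forest$importances
    if (k < K) {
      if (all(imp == 0)) {
        warning("all importances zero; falling back to uniform weights")
        w <- rep(1 / p, p)
      } else {
        w <- pmax(imp, 1e-6 * max(imp))
        w <- w / sum(w)
      }
    }
  }
  list(forest = forest, weights = forest$feature_weights,
       weight_history = history)
}

#' Extract signed root-to-leaf itemsets
#'
#' For every leaf holding at least one class-1 training sample, emits the
#' set of `(feature, sign)` pairs along its root-to-leaf path (sign `-`
#' for the `<=` branch, `+` for the `>` branch), weighted by the leaf's
#' class-1 count. When a path splits twice on one feature with opposite
#' directions, the deepest split's sign is kept (the binding constraint in
#' the leaf's region).
#'
#' Items are encoded as signed integers `+-(feature index)`.
#'
#' @param forest a `mirf_forest`.
#' @return list with `items` (list of signed integer vectors) and
#'   `weights` (integer leaf class-1 counts).
#' @export
extract_signed_itemsets <- function(forest) {
  stopifnot(inherits(forest, "mirf_forest"))
  out <- cpp_extract_itemsets(forest$trees)
  list(items = out$items, weights = as.integer(out$weights))
}

#' Generalized Random Intersection Trees
#'
#' Builds `n_rit_trees` intersection trees: the root is an itemset sampled
#' with probability proportional to its weight; each node at depth `< D`
#' has `n_child` children, each the intersection of the parent set with a
#' freshly sampled itemset. Leaf sets of size `>= min_order` are returned,
#' deduplicated. Sets frequent among class-1 decision paths survive the
#' repeated intersections; rare sets are destroyed.
#'
#' @param itemsets list with `items` and `weights` as produced by
#'   [extract_signed_itemsets()], or a plain list of signed integer vectors
#'   (unit weights).
#' @param params a [rit_params()].
#' @param seed integer seed.
#' @return list of signed integer vectors (sorted, unique).
#' @export
run_rit <- function(itemsets, params = rit_params(), seed = 1) {
  if (is.list(itemsets) && !is.null(itemsets$items)) {
    items <- itemsets$items
    weights <- as.numeric(itemsets$weights)
  } else {
    items <- itemsets
    weights <- rep(1, length(itemsets))
  }
  if (length(items) == 0) stop("no itemsets to intersect", call. = FALSE)
  stopifnot(all(weights >= 1))
  cpp_rit(items, weights, params$n_rit_trees, params$depth, params$n_child,
          params$min_order, as.integer(seed))
}

#' Bagged stability scores for interactions
#'
#' Outer-layer bootstrap: for `b = 1..B`, resample the training samples
#' with replacement, refit the final weighted forest (using the supplied
#' iteration-K feature weights), extract class-1 itemsets and run RIT.
#' The stability of an interaction is the fraction of the `B` replicates
#' recovering it.
#'
#' @param X samples x features training matrix.
#' @param y binary labels.
#' @param feature_weights weights of the final reweighted-forest iteration.
#' @param B number of bootstrap replicates.
#' @param forest_params a [forest_params()].
#' @param rit_params a [rit_params()].
#' @param seed integer master seed; replicate `b` uses
#'   `derive_seed(seed, b)`.
#' @return data frame with columns `key` (canonical signed interaction,
#'   e.g. `"+G0001,-P0003"`), `order`, and `stability` in `[0, 1]`,
#'   sorted by decreasing stability.
#' @export
bagged_stability <- function(X, y, feature_weights = NULL, B = 50,
                             forest_params = mirf::forest_params(),
                             rit_params = mirf::rit_params(), seed = 1) {
  stopifnot(B >= 1)
  X <- as.matrix(X)
  n <- nrow(X)
  feature_names <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    sub_seed <- derive_seed(seed, b)
    set.seed(sub_seed)
    idx <- NULL
    for (attempt in 1:10) {
      cand <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[cand])) == 2) { idx <- cand; break }
    }
    if (is.null(idx)) next # degenerate bootstrap; skip replicate
    fp <- forest_params
    fp$seed <- derive_seed(seed, b, 1)
    forest <- fit_weighted_forest(X[idx, , drop = FALSE], y[idx],
                                  feature_weights, fp)
    its <- extract_signed_itemsets(forest)
    if (length(its$items) == 0) next
    sets <- run_rit(its, rit_params, seed = derive_seed(seed, b, 2))
    keys <- unique(vapply(sets, signed_key, character(1),
                          feature_names = feature_names))
    for (k in keys) {
      counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0) {
    return(data.frame(key = character(0), order = integer(0),
                      stability = numeric(0), stringsAsFactors = FALSE))
  }
  stab <- vapply(keys, function(k) counts[[k]] / B, numeric(1))
  ord <- vapply(keys, function(k) nrow(parse_signed_key(k)), integer(1))
  out <- data.frame(key = keys, order = ord, stability = as.numeric(stab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$stability, out$key), , drop = FALSE]
}

#' Serialize a forest to a JSON tree schema
#'
#' Nodes are stored as parallel arrays (`feature` as 1-based column index
#' or null for leaves, `threshold`, `left`, `right`, `n`, `n1`,
#' `decrease`). Useful for fixture tests and model exchange.
#'
#' @param forest a `mirf_forest`.
#' @param path output file; when `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
forest_to_json <- function(forest, path = NULL) {
  stopifnot(inherits(forest, "mirf_forest"))
  obj <- list(
    feature_names = forest$feature_names,
    mtry = forest$mtry,
    importances = as.numeric(forest$importances),
    trees = lapply(forest$trees, function(tr) lapply(tr, as.vector))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Load a forest from the JSON tree schema
#'
#' @param path file path or JSON string produced by [forest_to_json()].
#' @return a `mirf_forest` (prediction-capable; growth parameters absent).
#' @export
forest_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  trees <- lapply(obj$trees, function(tr) {
    list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         n = as.integer(tr$n), n1 = as.integer(tr$n1),
         decrease = as.numeric(tr$decrease))
  })
  imp <- as.numeric(obj$importances)
  names(imp) <- obj$feature_names
  structure(
    list(trees = trees, importances = imp, feature_weights = NULL,
         params = NULL, mtry = obj$mtry, feature_names = obj$feature_names),
    class = "mirf_forest"
  )
}
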