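#' Pipeline configuration
#'
#' Bundles the three bootstrap-layer sizes and the selection thresholds.
#' Defaults mirror the published tuning: `K = 5` reweighting iterations,
#' `B = 50` stability bootstraps, `R = 100` outer replicates, an 80/20
#' train/test split, feature retention at mean Gini decrease `>= 1`
#' (count-weighted scale, inclusive) persisting in `>= 50%` of replicates
#' (inclusive), and interaction retention at mean stability `> 0.5`
#' (strict).
#'
#' @param K reweighting iterations.
#' @param B stability bootstraps per replicate.
#' @param R outer bootstrap replicates.
#' @param train_fraction training share of each replicate's bootstrap
#'   sample (stratified by class).
#' @param gini_min importance retention threshold (inclusive).
#' @param persistence_min replicate-fraction retention threshold (inclusive).
#' @param stability_min interaction stability threshold (strict `>`).
#' @param forest a [forest_params()].
#' @param rit a [rit_params()].
#' @param seed master seed; every (design, replicate, bootstrap) stage uses
#'   an independent derived substream.
#' @return an object of class `mirf_config`.
#' @export
mirf_config <- function(K = 5, B = 50, R = 100, train_fraction = 0.8,
                        gini_min = 1, persistence_min = 0.5,
                        stability_min = 0.5, forest = forest_params(),
                        rit = rit_params(), seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_config("train_fraction", "must lie in (0, 1)")
  }
  if (K < 1 || B < 1 || R < 1) stop_config("K/B/R", "must be >= 1")
  if (persistence_min < 0 || persistence_min > 1) {
    stop_config("persistence_min", "must lie in [0, 1]")
  }
  if (stability_min < 0 || stability_min > 1) {
    stop_config("stability_min", "must lie in [0, 1]")
  }
  structure(
    list(K = as.integer(K), B = as.integer(B), R = as.integer(R),
         train_fraction = train_fraction, gini_min = gini_min,
         persistence_min = persistence_min, stability_min = stability_min,
         forest = forest, rit = rit, seed = as.integer(seed)),
    class = "mirf_config"
  )
}

stratified_split <- function(y, train_fraction, seed) {
  set.seed(seed)
  for (attempt in 1:10) {
    train <- logical(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_train <- max(1L, round(train_fraction * length(idx)))
      n_train <- min(n_train, length(idx) - 1L)
      if (n_train < 1) next
      train[sample(idx, n_train)] <- TRUE
    }
    if (length(unique(y[train])) == 2 && length(unique(y[!train])) == 2) {
      return(train)
    }
  }
  stop("could not produce a stratified split with both classes on each side",
       call. = FALSE)
}

#' Area under the precision-recall step curve
#'
#' Area of the step function through the (recall, precision) points
#' obtained at every distinct score threshold, scanned from the highest
#' score down: `sum over thresholds of (R_i - R_{i-1}) * P_i`.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary 0/1 labels.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  # keep only the last index of each tied-score block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  npos <- sum(l)
  recall <- tp / npos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form with ties averaged: the probability that a random
#' positive outscores a random negative, counting ties as one half.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Replicate summary: mean, t-based 95% CI, p-value against a baseline
#'
#' One-sample two-sided t-test of the replicate values against the given
#' baseline (0.5 for AUROC; the class-1 prevalence for AUPR). A constant
#' vector yields a width-zero CI and `NA` p-value.
#'
#' @param values numeric vector of per-replicate metrics (length >= 2).
#' @param baseline null value to test against.
#' @param conf confidence level.
#' @return list with `mean`, `ci` (length 2), `p`, `n`.
#' @export
replicate_ci <- function(values, baseline = 0.5, conf = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 replicate values", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    return(list(mean = m, ci = c(m, m), p = NA_real_, n = n))
  }
  se <- s / sqrt(n)
  tcrit <- qt(1 - (1 - conf) / 2, df = n - 1)
  p <- 2 * pt(-abs((m - baseline) / se), df = n - 1)
  list(mean = m, ci = c(m - tcrit * se, m + tcrit * se), p = p, n = n)
}

#' Run one outer bootstrap replicate
#'
#' Bootstrap the full dataset, split the bootstrap sample into stratified
#' train/test parts, run the K-iteration reweighted forest on the training
#' part, score the held-out part (test AUPR), and compute bagged stability
#' scores (B inner bootstraps) on the training part with the final
#' iteration's feature weights.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param config a [mirf_config()].
#' @param replicate_seed seed for this replicate's substreams.
#' @return list with `importances`, `interactions` (data frame `key`,
#'   `order`, `stability`), `test_aupr`, `train_aupr`, `test_auroc`,
#'   `prevalence`, `n_train`, `n_test`.
#' @export
run_replicate <- function(X, y, config = mirf_config(), replicate_seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  n <- nrow(X)
  set.seed(derive_seed(replicate_seed, 1))
  boot <- NULL
  for (attempt in 1:10) {
    cand <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[cand])) == 2) { boot <- cand; break }
  }
  if (is.null(boot)) stop("bootstrap sample lost a class", call. = FALSE)
  Xb <- X[boot, , drop = FALSE]
  yb <- y[boot]
  # split by original sample identity so that bootstrap copies of one
  # sample never straddle the train/test boundary (no leakage)
  uniq <- sort(unique(boot))
  utrain <- stratified_split(y[uniq], config$train_fraction,
                             derive_seed(replicate_seed, 2))
  train <- boot %in% uniq[utrain]
  if (length(unique(yb[train])) < 2 || length(unique(yb[!train])) < 2) {
    train <- stratified_split(yb, config$train_fraction,
                              derive_seed(replicate_seed, 2)) # fallback
  }
  fp <- config$forest
  fp$seed <- derive_seed(replicate_seed, 3)
  fit <- iterate_reweighted_forest(Xb[train, , drop = FALSE], yb[train],
                                   K = config$K, params = fp)
  prob_test <- predict(fit$forest, Xb[!train, , drop = FALSE])
  prob_train <- predict(fit$forest, Xb[train, , drop = FALSE])
  inter <- bagged_stability(Xb[train, , drop = FALSE], yb[train],
                            feature_weights = fit$weights, B = config$B,
                            forest_params = fp, rit_params = config$rit,
                            seed = derive_seed(replicate_seed, 4))
  list(
    importances = fit$forest$importances,
    interactions = inter,
    test_aupr = aupr(prob_test, yb[!train]),
    train_aupr = aupr(prob_train, yb[train]),
    test_auroc = auroc(prob_test, yb[!train]),
    prevalence = mean(yb[!train]),
    n_train = sum(train),
    n_test = sum(!train)
  )
}

#' Persistence-based feature selection
#'
#' A feature qualifies in a replicate when its importance is at least
#' `gini_min` (inclusive); it is retained when the qualifying fraction is
#' at least `persistence_min` (inclusive).
#'
#' @param replicates list of [run_replicate()] results (each with an
#'   `importances` vector).
#' @param gini_min importance threshold.
#' @param persistence_min replicate-fraction threshold.
#' @return data frame `feature`, `frequency`, `mean_importance`, sorted by
#'   decreasing frequency then importance; only retained features.
#' @export
select_persistent_features <- function(replicates, gini_min = 1,
                                       persistence_min = 0.5) {
  stopifnot(length(replicates) >= 1)
  imp <- do.call(rbind, lapply(replicates, `[[`, "importances"))
  qualify <- imp >= gini_min
  freq <- colMeans(qualify)
  keep <- freq >= persistence_min
  out <- data.frame(
    feature = colnames(imp)[keep],
    frequency = freq[keep],
    mean_importance = colMeans(imp)[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$frequency, -out$mean_importance), , drop = FALSE]
}

#' Aggregate interactions over replicates
#'
#' Per interaction, stability is averaged over all replicates (a replicate
#' that did not recover the interaction contributes zero). An interaction
#' is selected when the mean stability strictly exceeds `stability_min`
#' and every member feature is in `active_features`.
#'
#' @param replicates list of [run_replicate()] results.
#' @param active_features character vector of active (persistent) features.
#' @param stability_min strict stability threshold.
#' @return data frame `key`, `order`, `mean_stability`, `all_active`,
#'   `selected`, sorted by decreasing mean stability.
#' @export
aggregate_interactions <- function(replicates, active_features,
                                   stability_min = 0.5) {
  R <- length(replicates)
  acc <- new.env(parent = emptyenv())
  for (rep_res in replicates) {
    tab <- rep_res$interactions
    for (i in seq_len(nrow(tab))) {
      k <- tab$key[i]
      acc[[k]] <- (acc[[k]] %||% 0) + tab$stability[i]
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) {
    return(data.frame(key = character(0), order = integer(0),
                      mean_stability = numeric(0), all_active = logical(0),
                      selected = logical(0), stringsAsFactors = FALSE))
  }
  mean_stab <- vapply(keys, function(k) acc[[k]] / R, numeric(1))
  members <- lapply(keys, function(k) parse_signed_key(k)$feature)
  all_active <- vapply(members, function(m) all(m %in% active_features),
                       logical(1))
  out <- data.frame(
    key = keys, order = vapply(members, length, integer(1)),
    mean_stability = as.numeric(mean_stab), all_active = all_active,
    selected = mean_stab > stability_min & all_active,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$mean_stability, out$key), , drop = FALSE]
}

strip_view_prefix <- function(x) sub("^[^:]*:", "", x)

#' Run the full multiview pipeline
#'
#' Executes `R` outer bootstrap replicates for each requested design (gene
#' view, protein view, and their feature-wise integration) on the chosen
#' binary task, then aggregates persistent features, interactions, metric
#' summaries and the cross-design consensus (features retained both by a
#' single view and by the integrated design).
#'
#' The task labels come from [binarize_outcomes()] applied to the cohort's
#' clinical table (`task = "os"`: long = 1 vs short = 0; `task = "kps"`:
#' high = 1 vs low = 0); alternatively, explicit binary `labels` (one per
#' cohort sample, NA = excluded) override the clinical thresholds, which is
#' how simulated planted outcomes are analyzed.
#'
#' @param cohort a `mirf_cohort` (or any list with `gene_matrix`,
#'   `protein_matrix`, `clinical`).
#' @param task `"os"` or `"kps"`.
#' @param config a [mirf_config()].
#' @param designs subset of `c("gene", "protein", "integrated")`.
#' @param labels optional explicit 0/1/NA labels overriding the task.
#' @return an object of class `mirf_result`: per-design list with
#'   `replicates`, `features`, `interactions`, `metrics`, plus `consensus`
#'   and the configuration echo.
#' @export
run_mirf <- function(cohort, task = c("os", "kps"), config = mirf_config(),
                     designs = c("gene", "protein", "integrated"),
                     labels = NULL) {
  task <- match.arg(task)
  designs <- match.arg(designs, several.ok = TRUE)
  if (is.null(labels)) {
    bins <- binarize_outcomes(cohort$clinical)
    labels <- if (task == "os") {
      ifelse(bins$os_class == "long", 1L,
             ifelse(bins$os_class == "short", 0L, NA_integer_))
    } else {
      ifelse(bins$kps_class == "high", 1L,
             ifelse(bins$kps_class == "low", 0L, NA_integer_))
    }
  }
  labels <- as.integer(labels)
  keep <- !is.na(labels)
  if (sum(keep) < 10) stop("too few labeled samples", call. = FALSE)
  y <- labels[keep]
  views <- list(gene = cohort$gene_matrix[, keep, drop = FALSE],
                protein = cohort$protein_matrix[, keep, drop = FALSE])
  mats <- list(
    gene = t(views$gene),
    protein = t(views$protein),
    integrated = t(integrate_views(views))
  )
  result <- list(task = task, config = config, designs = list())
  for (d in designs) {
    X <- mats[[d]]
    reps <- vector("list", config$R)
    for (r in seq_len(config$R)) {
      reps[[r]] <- run_replicate(X, y, config,
                                 replicate_seed = derive_seed(
                                   config$seed, match(d, names(mats)), r))
    }
    features <- select_persistent_features(reps, config$gini_min,
                                           config$persistence_min)
    interactions <- aggregate_interactions(reps, features$feature,
                                           config$stability_min)
    safe_ci <- function(values, baseline) {
      values <- values[is.finite(values)]
      if (length(values) >= 2) return(replicate_ci(values, baseline))
      v <- if (length(values)) values else NA_real_
      list(mean = v, ci = c(v, v), p = NA_real_, n = length(values))
    }
    aupr_s <- safe_ci(vapply(reps, `[[`, numeric(1), "test_aupr"),
                      baseline = mean(vapply(reps, `[[`, numeric(1),
                                             "prevalence")))
    # per-replicate interaction AUROC: stability vs all-members-active
    int_auroc <- vapply(reps, function(rr) {
      tab <- rr$interactions
      if (nrow(tab) == 0) return(NA_real_)
      pos <- vapply(tab$key, function(k) {
        all(parse_signed_key(k)$feature %in% features$feature)
      }, logical(1))
      if (length(unique(pos)) < 2) return(NA_real_)
      auroc(tab$stability, as.integer(pos))
    }, numeric(1))
    auroc_s <- safe_ci(int_auroc, baseline = 0.5)
    result$designs[[d]] <- list(
      replicates = reps, features = features, interactions = interactions,
      metrics = list(test_aupr = aupr_s, interaction_auroc = auroc_s)
    )
  }
  if ("integrated" %in% designs) {
    integ <- strip_view_prefix(result$designs$integrated$features$feature)
    cons <- list()
    for (d in intersect(c("gene", "protein"), designs)) {
      cons[[d]] <- intersect(result$designs[[d]]$features$feature, integ)
    }
    result$consensus <- cons
  }
  class(result) <- "mirf_result"
  result
}

#' @export
print.mirf_result <- function(x, ...) {
  cat(sprintf("multiview iRF result (task: %s; K=%d, B=%d, R=%d)\n",
              x$task, x$config$K, x$config$B, x$config$R))
  for (d in names(x$designs)) {
    des <- x$designs[[d]]
    cat(sprintf(
      "  %-10s %d persistent feature(s), %d selected interaction(s), mean test AUPR %.3f\n",
      d, nrow(des$features), sum(des$interactions$selected),
      des$metrics$test_aupr$mean))
  }
  if (!is.null(x$consensus)) {
    for (d in names(x$consensus)) {
      if (length(x$consensus[[d]])) {
        cat(sprintf("  consensus (%s & integrated): %s\n", d,
                    paste(x$consensus[[d]], collapse = ", ")))
      }
    }
  }
  invisible(x)
}
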