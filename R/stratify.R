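#' Per-sample signature score
#'
#' Unweighted mean of z-scored expression over the signature features.
#' Duplicated signature entries are collapsed with a warning; features
#' absent from the matrix are reported and skipped (mirroring how a
#' signature gene missing from an external cohort is handled).
#'
#' @param matrix features x samples z-scored expression.
#' @param signature_features character vector of feature names.
#' @return named numeric vector of per-sample scores.
#' @export
signature_score <- function(matrix, signature_features) {
  if (anyDuplicated(signature_features)) {
    warning("duplicated signature features collapsed")
    signature_features <- unique(signature_features)
  }
  present <- signature_features %in% rownames(matrix)
  if (!any(present)) {
    stop("no signature feature present in the matrix", call. = FALSE)
  }
  if (any(!present)) {
    warning(sprintf("skipping %d signature feature(s) absent from matrix: %s",
                    sum(!present),
                    paste(signature_features[!present], collapse = ", ")))
  }
  sub <- matrix[signature_features[present], , drop = FALSE]
  colMeans(sub)
}

#' Expression-mean stratification cutoffs
#'
#' Cutoffs are the long-survivor and short-survivor group means of the
#' signature score; the groups are compared by a two-sided unpaired Welch
#' t-test with Bonferroni correction over `n_tests` signatures.
#'
#' @param scores per-sample signature scores.
#' @param os_class per-sample class: `"long"`, `"short"` (anything else is
#'   ignored).
#' @param n_tests number of signatures tested (Bonferroni multiplier).
#' @return an object of class `mirf_cutoffs`: list with `long_mean`,
#'   `short_mean`, `p_raw`, `p_adj` (capped at 1), `orientation`
#'   (sign of short minus long mean).
#' @export
derive_cutoffs <- function(scores, os_class, n_tests = 1) {
  long <- scores[os_class == "long"]
  short <- scores[os_class == "short"]
  if (length(long) < 2 || length(short) < 2) {
    stop("each survival class needs at least 2 samples", call. = FALSE)
  }
  p_raw <- if (sd(long) == 0 && sd(short) == 0) {
    if (mean(long) == mean(short)) 1 else 0
  } else {
    t.test(long, short)$p.value
  }
  structure(
    list(long_mean = mean(long), short_mean = mean(short), p_raw = p_raw,
         p_adj = min(1, p_raw * n_tests),
         orientation = sign(mean(short) - mean(long)),
         n_long = length(long), n_short = length(short)),
    class = "mirf_cutoffs"
  )
}

#' Assign samples to survival zones
#'
#' With the long-survivor mean below the short-survivor mean
#' (`rule = "beyond-mean"`), a sample is in the long zone when its score is
#' at or below the long mean, in the short zone when at or above the short
#' mean, and unassigned in between; orientation is mirrored when the long
#' mean is the larger. The alternative `rule = "midpoint"` splits at the
#' midpoint of the two means and assigns every sample.
#'
#' @param scores per-sample signature scores.
#' @param cutoffs a [derive_cutoffs()] object (or list with `long_mean`,
#'   `short_mean`).
#' @param rule `"beyond-mean"` (default) or `"midpoint"`.
#' @return an object of class `mirf_zones`: list with `zone` (factor
#'   `long`/`short`/`unassigned`), `fraction_long`, `fraction_short`,
#'   `fraction_assigned`.
#' @export
assign_zones <- function(scores, cutoffs, rule = c("beyond-mean", "midpoint")) {
  rule <- match.arg(rule)
  lo <- cutoffs$long_mean
  sh <- cutoffs$short_mean
  if (!is.finite(lo) || !is.finite(sh)) stop("cutoffs must be finite",
                                             call. = FALSE)
  if (lo == sh) stop("equal cutoffs give no zone separation", call. = FALSE)
  flip <- lo > sh # mirrored orientation
  if (rule == "beyond-mean") {
    zone <- if (!flip) {
      ifelse(scores <= lo, "long", ifelse(scores >= sh, "short", "unassigned"))
    } else {
      ifelse(scores >= lo, "long", ifelse(scores <= sh, "short", "unassigned"))
    }
  } else {
    mid <- (lo + sh) / 2
    zone <- if (!flip) {
      ifelse(scores <= mid, "long", "short")
    } else {
      ifelse(scores >= mid, "long", "short")
    }
  }
  zone <- factor(zone, levels = c("long", "short", "unassigned"))
  tab <- table(zone) / length(zone)
  structure(
    list(zone = zone,
         fraction_long = as.numeric(tab["long"]),
         fraction_short = as.numeric(tab["short"]),
         fraction_assigned = as.numeric(tab["long"] + tab["short"]),
         rule = rule),
    class = "mirf_zones"
  )
}

#' PCA embedding with explained-variance ratios
#'
#' Centered singular-value decomposition over samples; deterministic up to
#' component sign.
#'
#' @param matrix features x samples matrix.
#' @param n_components number of components to return.
#' @return list with `components` (samples x n_components scores),
#'   `explained_variance_ratio`, `sdev` (all components).
#' @export
pca_embed <- function(matrix, n_components = 2) {
  X <- t(matrix)
  max_comp <- min(nrow(X) - 1, ncol(X))
  if (n_components > max_comp) {
    warning(sprintf("rank supports only %d component(s)", max_comp))
    n_components <- max_comp
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  list(components = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance_ratio = ratio[seq_len(n_components)],
       sdev = pc$sdev)
}

#' Two-dimensional t-SNE embedding
#'
#' Exact (non-tree) t-distributed stochastic neighbor embedding: Gaussian
#' input affinities calibrated per point to the target perplexity by
#' bisection, Student-t output kernel, gradient descent with momentum and
#' early exaggeration. Suitable for the cohort sizes used here (hundreds
#' of samples). The default perplexity is `floor(sqrt(n))`; the perplexity
#' must be below `(n - 1) / 3`.
#'
#' @param matrix features x samples matrix.
#' @param perplexity target perplexity (default `floor(sqrt(n))`).
#' @param seed seed for the random initialization.
#' @param max_iter gradient-descent iterations (default 1000).
#' @return samples x 2 coordinate matrix.
#' @export
tsne_embed <- function(matrix, perplexity = NULL, seed = 1, max_iter = 1000) {
  X <- t(matrix)
  n <- nrow(X)
  perplexity <- perplexity %||% max(2, floor(sqrt(n)))
  if (perplexity >= (n - 1) / 3) {
    stop(sprintf("perplexity must be < (n - 1) / 3 = %.1f (got %s)",
                 (n - 1) / 3, format(perplexity)), call. = FALSE)
  }
  D2 <- as.matrix(dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:60) { # bisection on precision
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { hi <- beta; beta <- (lo + hi) / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - target) < 1e-7) break
      if (H > target) lo <- beta else hi <- beta
      beta <- if (is.finite(hi) && hi < 1e19) (lo + hi) / 2 else beta * 2
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(derive_seed(seed, 42))
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  gain <- matrix(1, n, 2)
  update <- matrix(0, n, 2)
  eta <- 200
  for (iter in seq_len(max_iter)) {
    exag <- if (iter <= 100) 12 else 1
    momentum <- if (iter <= 250) 0.5 else 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, 1e-12)
    L <- (exag * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) %*% Y - L %*% Y)
    gain <- ifelse(sign(grad) != sign(update), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    update <- momentum * update - eta * gain * grad
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}
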