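#' Screening configuration
#'
#' Thresholds for the cleaning and differential-expression screen.
#' `lfc_threshold` is an absolute difference of class means: inputs are
#' already log-scale, z-standardized expression, where a difference of
#' means is the standard reading of a log fold change.
#'
#' @param fdr_threshold Benjamini-Hochberg FDR cutoff (selection uses `<`).
#' @param lfc_threshold absolute effect-size cutoff (selection uses `>`).
#' @param missing_threshold features with missing fraction `>=` this are
#'   dropped (inclusive boundary).
#' @param impute_k neighbor count for feature-wise KNN imputation.
#' @return an object of class `mirf_screen_config`.
#' @export
screen_config <- function(fdr_threshold = 0.05, lfc_threshold = 0.5,
                          missing_threshold = 0.8, impute_k = 10) {
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop_config("fdr_threshold", "must lie in (0, 1)")
  }
  if (missing_threshold <= 0 || missing_threshold > 1) {
    stop_config("missing_threshold", "must lie in (0, 1]")
  }
  if (lfc_threshold < 0) stop_config("lfc_threshold", "must be >= 0")
  if (impute_k < 1) stop_config("impute_k", "must be >= 1")
  structure(
    list(fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold,
         missing_threshold = missing_threshold, impute_k = as.integer(impute_k)),
    class = "mirf_screen_config"
  )
}

#' Read a Firehose-style expression matrix
#'
#' First column holds the feature symbol; remaining columns are samples;
#' `NA` marks missing entries.
#'
#' @param path TSV file path.
#' @return numeric matrix, features x samples.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  mat
}

#' Read a cBioPortal-style clinical table
#'
#' Expects columns `SAMPLE_ID`, `OS_MONTHS`, `OS_STATUS`
#' (`LIVING`/`DECEASED`) and `KPS`.
#'
#' @param path TSV file path.
#' @return data frame with `sample_id`, `os_months`, `os_event`, `kps`.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("SAMPLE_ID", "OS_MONTHS", "OS_STATUS", "KPS")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("clinical table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  data.frame(
    sample_id = df$SAMPLE_ID,
    os_months = as.numeric(df$OS_MONTHS),
    os_event = as.integer(df$OS_STATUS == "DECEASED"),
    kps = as.integer(df$KPS),
    stringsAsFactors = FALSE
  )
}

#' Drop features with excessive missingness
#'
#' Features whose missing fraction is at least `missing_threshold` are
#' removed (the boundary is inclusive: a feature exactly at the threshold
#' is dropped).
#'
#' @param matrix features x samples matrix with `NA` for missing.
#' @param missing_threshold inclusive missing-fraction cutoff.
#' @return list with `matrix` (filtered) and `removed` (character names).
#' @export
drop_high_missing <- function(matrix, missing_threshold = 0.8) {
  stopifnot(nrow(matrix) >= 1)
  frac <- rowMeans(is.na(matrix))
  drop <- frac >= missing_threshold
  if (all(drop)) {
    stop("all features exceed the missingness threshold; lower the threshold",
         call. = FALSE)
  }
  list(matrix = matrix[!drop, , drop = FALSE],
       removed = rownames(matrix)[drop])
}

#' Feature-wise K-nearest-mean imputation
#'
#' Each missing entry is replaced by the mean over the `impute_k` nearest
#' features (Euclidean distance computed on mutually observed samples,
#' normalized per pair) among those observed at that sample. Features with
#' no usable neighbor fall back to the feature's own observed mean.
#' Observed entries are never altered.
#'
#' @param matrix features x samples matrix with `NA` for missing.
#' @param impute_k neighbor count.
#' @return complete matrix.
#' @export
knn_impute <- function(matrix, impute_k = 10) {
  miss <- is.na(matrix)
  if (!any(miss)) return(matrix)
  if (any(rowSums(!miss) == 0)) {
    stop("feature with zero observed values; drop it before imputing",
         call. = FALSE)
  }
  p <- nrow(matrix)
  need <- which(rowSums(miss) > 0)
  out <- matrix
  for (i in need) {
    d <- rep(Inf, p)
    xi <- matrix[i, ]
    for (j in seq_len(p)) {
      if (j == i) next
      shared <- !miss[i, ] & !miss[j, ]
      if (!any(shared)) next
      d[j] <- sqrt(mean((xi[shared] - matrix[j, shared])^2))
    }
    ord <- order(d)
    for (s in which(miss[i, ])) {
      usable <- ord[is.finite(d[ord]) & !miss[ord, s]]
      if (length(usable) == 0) {
        out[i, s] <- mean(xi, na.rm = TRUE)
      } else {
        nb <- usable[seq_len(min(impute_k, length(usable)))]
        out[i, s] <- mean(matrix[nb, s])
      }
    }
  }
  out
}

#' Z-score standardize features
#'
#' Each feature is centered and scaled to unit population standard
#' deviation (divisor `n`). Constant features become all zeros with a
#' warning.
#'
#' @param matrix complete features x samples matrix.
#' @return standardized matrix.
#' @export
zscore_standardize <- function(matrix) {
  if (any(is.na(matrix))) stop("matrix must be complete", call. = FALSE)
  n <- ncol(matrix)
  mu <- rowMeans(matrix)
  centered <- matrix - mu
  sdev <- sqrt(rowMeans(centered^2))
  const <- sdev == 0
  if (any(const)) {
    warning(sprintf("%d constant feature(s) mapped to zeros", sum(const)))
    sdev[const] <- 1
  }
  out <- centered / sdev
  out[const, ] <- 0
  out
}

#' Binarize overall survival and KPS
#'
#' Overall survival: short if `os_months <= 6`, long if `os_months >= 24`,
#' otherwise excluded from the survival task. KPS: high if `>= 80`, low if
#' `<= 60`, the intermediate value 70 excluded.
#'
#' @param clinical data frame with `os_months` and `kps`.
#' @return list with character vectors `os_class`
#'   (`"short"`/`"long"`/`"excluded"`) and `kps_class`
#'   (`"low"`/`"high"`/`"excluded"`), both named by `sample_id` when present.
#' @export
binarize_outcomes <- function(clinical) {
  if (any(clinical$os_months < 0, na.rm = TRUE)) {
    stop("negative os_months", call. = FALSE)
  }
  os <- ifelse(clinical$os_months <= 6, "short",
               ifelse(clinical$os_months >= 24, "long", "excluded"))
  kps <- ifelse(clinical$kps >= 80, "high",
                ifelse(clinical$kps <= 60, "low", "excluded"))
  if (!is.null(clinical$sample_id)) {
    names(os) <- names(kps) <- clinical$sample_id
  }
  if (all(os == "excluded")) {
    stop("no samples fall in the short/long survival classes", call. = FALSE)
  }
  list(os_class = os, kps_class = kps)
}

trigamma_inverse <- function(x) {
  # Newton iteration on trigamma(y) = x (monotone decreasing)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Differential-expression screen with moderated t-statistics
#'
#' Two-group comparison with empirical-Bayes variance moderation: the
#' posterior variance is `(d0 * s0^2 + d * s^2) / (d0 + d)` where the prior
#' degrees of freedom `d0` and prior variance `s0^2` are fitted by moments
#' on the log sample variances, as in the standard moderated-t approach.
#' P-values use `d + d0` degrees of freedom and are Benjamini-Hochberg
#' adjusted. A feature is selected when `fdr < fdr_threshold` and
#' `|effect| > lfc_threshold`, where effect is the difference of class
#' means (second class minus first).
#'
#' @param matrix features x samples matrix (complete).
#' @param labels two-level factor (or coercible) over samples; excluded
#'   samples should be removed beforehand.
#' @param config a [screen_config()].
#' @param method `"moderated"` (default) or `"welch"` for a plain Welch t.
#' @return list with `table` (feature, effect, t, df, p, fdr) and
#'   `selected` (character vector of feature names).
#' @export
deg_screen <- function(matrix, labels, config = screen_config(),
                       method = c("moderated", "welch")) {
  method <- match.arg(method)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have two levels", call. = FALSE)
  i1 <- labels == levels(labels)[1]
  i2 <- labels == levels(labels)[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("each class needs at least 2 samples",
                             call. = FALSE)
  m1 <- rowMeans(matrix[, i1, drop = FALSE])
  m2 <- rowMeans(matrix[, i2, drop = FALSE])
  v1 <- apply(matrix[, i1, drop = FALSE], 1, var)
  v2 <- apply(matrix[, i2, drop = FALSE], 1, var)
  effect <- m2 - m1

  if (method == "welch") {
    se <- sqrt(v1 / n1 + v2 / n2)
    tt <- effect / se
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    pos <- s2 > 0
    e <- log(s2[pos])
    ve <- var(e)
    excess <- ve - trigamma(d / 2)
    if (is.na(excess) || excess <= 0) {
      d0 <- Inf
      s02 <- exp(mean(e) - digamma(d / 2) + log(d / 2))
    } else {
      d0 <- 2 * trigamma_inverse(excess)
      s02 <- exp(mean(e) - (digamma(d / 2) - log(d / 2)) +
                   (digamma(d0 / 2) - log(d0 / 2)))
    }
    s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
      (d0 * s02 + d * s2) / (d0 + d)
    }
    se <- sqrt(s2_post * (1 / n1 + 1 / n2))
    tt <- effect / se
    df <- rep(min(d + d0, 1e6), length(tt))
  }
  p <- 2 * pt(-abs(tt), df)
  fdr <- p.adjust(p, method = "BH")
  tab <- data.frame(
    feature = rownames(matrix), effect = effect, t = tt, df = df, p = p,
    fdr = fdr, stringsAsFactors = FALSE, row.names = NULL
  )
  sel <- tab$feature[tab$fdr < config$fdr_threshold &
                       abs(tab$effect) > config$lfc_threshold]
  list(table = tab, selected = sel)
}

#' Concatenate views into one matrix with view-tagged feature names
#'
#' @param views named list of features x samples matrices sharing sample
#'   order.
#' @return single matrix whose row names are `view:feature`.
#' @export
integrate_views <- function(views) {
  stopifnot(length(views) >= 1, !is.null(names(views)))
  ref <- colnames(views[[1]])
  for (v in views) {
    if (!identical(colnames(v), ref)) {
      stop("views must share identical sample order", call. = FALSE)
    }
  }
  out <- do.call(rbind, views)
  rownames(out) <- unlist(lapply(names(views), function(nm) {
    paste0(nm, ":", rownames(views[[nm]]))
  }))
  out
}

#' Split an integrated matrix back into views by name prefix
#'
#' @param matrix output of [integrate_views()].
#' @return named list of matrices with original feature names.
#' @export
split_views <- function(matrix) {
  prefix <- sub(":.*$", "", rownames(matrix))
  lapply(split(seq_len(nrow(matrix)), prefix), function(idx) {
    m <- matrix[idx, , drop = FALSE]
    rownames(m) <- sub("^[^:]*:", "", rownames(m))
    m
  })
}
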