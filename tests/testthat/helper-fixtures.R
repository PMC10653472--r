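# Shared fixture builders. Everything is generated in code; no stored data.

# small two-class expression fixture: features x samples with `shift` added
# to the first `n_signal` features in class 2
make_two_class_matrix <- function(p = 20, n1 = 15, n2 = 15, n_signal = 0,
                                  shift = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(p * (n1 + n2)), nrow = p,
              dimnames = list(sprintf("F%03d", seq_len(p)),
                              sprintf("S%03d", seq_len(n1 + n2))))
  if (n_signal > 0) {
    m[seq_len(n_signal), (n1 + 1):(n1 + n2)] <-
      m[seq_len(n_signal), (n1 + 1):(n1 + n2)] + shift
  }
  list(matrix = m, labels = rep(c("a", "b"), c(n1, n2)))
}

# separable toy classification data (samples x features)
make_separable_xy <- function(n = 50, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.integer(X[, 1] > 0)
  list(X = X, y = y)
}

# AND-interaction classification data for forest/RIT tests
make_interaction_xy <- function(n = 200, p = 20, p_signal = 0.9,
                                p_noise = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  pr <- ifelse(X[, 1] > 0 & X[, 2] > 0, p_signal, p_noise)
  y <- as.integer(runif(n) < pr)
  list(X = X, y = y)
}

# proportional-hazards survival data with a single unit-effect covariate
make_ph_data <- function(n = 500, beta = 1, censor_rate = 0, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  vals <- matrix(x, nrow = 1, dimnames = list("x", NULL))
  s <- simulate_survival(vals, beta, weibull_shape = 1.2, weibull_scale = 12,
                         censor_rate = censor_rate, seed = seed + 1)
  list(x = x, time = s$os_months, event = s$os_event)
}

# brute-force AUPR via explicit threshold enumeration (independent oracle)
oracle_aupr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    precision <- tp / (tp + fp)
    recall <- tp / npos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# brute-force AUROC by pair counting (independent oracle)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(pos) * length(neg))
}

# weighted prevalence of every signed subset of every itemset (oracle for RIT)
oracle_prevalence <- function(items, weights) {
  keys <- new.env(parent = emptyenv())
  all_subsets <- function(v) {
    if (length(v) > 12) stop("oracle limited to small itemsets")
    unlist(lapply(seq_len(2^length(v) - 1), function(mask) {
      paste(sort(v[bitwAnd(mask, 2^(seq_along(v) - 1)) > 0]), collapse = ",")
    }))
  }
  total <- sum(weights)
  for (i in seq_along(items)) {
    for (k in all_subsets(items[[i]])) {
      keys[[k]] <- (keys[[k]] %||% 0) + weights[i]
    }
  }
  ks <- ls(keys)
  data.frame(
    key = ks,
    prevalence = vapply(ks, function(k) keys[[k]] / total, numeric(1)),
    size = lengths(strsplit(ks, ",")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
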