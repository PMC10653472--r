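#' Derive a reproducible substream seed
#'
#' Mixes a master seed with one or more integer stream labels through a
#' Fowler/Noll/Vo-style multiplicative hash so that independent pipeline
#' stages (design, replicate, bootstrap) get decorrelated but reproducible
#' seeds. The result is always in `[1, 2^31 - 2]`, safe for R's 32-bit
#' integer seeds and for the C++ Mersenne Twister.
#'
#' @param master master seed (single integer).
#' @param ... integer stream labels identifying the substream.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, ...) {
  labels <- c(master, unlist(list(...)))
  stopifnot(all(is.finite(labels)))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 2166136261 %% m
  for (k in as.numeric(labels)) {
    h <- (h * 16777619 + (k %% m) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# canonical text key for a signed itemset given as +-(index) over `names`
signed_key <- function(items, feature_names) {
  stopifnot(all(abs(items) >= 1), all(abs(items) <= length(feature_names)))
  nm <- feature_names[abs(items)]
  sg <- ifelse(items > 0, "+", "-")
  paste(sort(paste0(sg, nm)), collapse = ",")
}

# split a canonical key back into feature names and signs
parse_signed_key <- function(key) {
  parts <- strsplit(key, ",", fixed = TRUE)[[1]]
  data.frame(
    feature = substring(parts, 2),
    sign = ifelse(substring(parts, 1, 1) == "+", 1L, -1L),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}
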