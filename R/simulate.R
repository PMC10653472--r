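#' Simulation configuration for a synthetic two-omics cohort
#'
#' Describes a "stated world" for the generator: two z-scored expression
#' views (gene microarray-like and protein RPPA-like) over a shared sample
#' set, a small planted set of signal features acting marginally and through
#' a low-order Boolean interaction on a binary outcome, Weibull
#' proportional-hazards survival whose log-hazard is linear in the planted
#' features, an ordinal Karnofsky-performance-like score coupled to the
#' survival score, and missing-completely-at-random entries.
#'
#' The Boolean rule is a disjunction of conjunctions over planted-feature
#' labels: `rule = list(c("g1", "p1"), "g2")` reads
#' `(g1 > 0 AND p1 > 0) OR (g2 > 0)`. A literal prefixed with `-` is
#' activated when the feature is `<= 0`.
#'
#' Defaults plant two gene features and one protein feature, the protein
#' being a correlated noisy copy (`rho`) of the first gene so that the
#' planted pair spans the two views, emulating cross-view consensus
#' signatures. The default rule `g1 > 0 AND (p1 > 0 OR g2 > 0)` makes all
#' three planted features marginally informative while concentrating the
#' class-1 decision paths on the cross-view conjunction `(g1, p1)`, the
#' planted interaction pair.
#'
#' @param n_samples number of samples.
#' @param p_gene,p_protein feature counts per view.
#' @param planted data frame with columns `view` ("gene"/"protein"),
#'   `index` (row within the view), `label` (name usable in `rule`),
#'   and optional `copy_of` (label of a planted gene that a planted protein
#'   copies with correlation `rho`; `NA` for independent features).
#' @param rule Boolean outcome rule (see Details); `list()` is always-false.
#' @param p_signal,p_noise probability of outcome 1 when the rule is
#'   true/false; must satisfy `p_signal > p_noise` unless equal (null world).
#' @param beta log-hazard coefficient per planted feature (recycled).
#' @param weibull_shape,weibull_scale baseline Weibull survival parameters;
#'   scale is in months.
#' @param censor_rate expected censored fraction in `[0, 1)`.
#' @param missing_rate MCAR missingness rate in `[0, 1)` applied to both views.
#' @param rho correlation of planted protein copies with their source gene.
#' @param kps_coupling coupling in `[0, 1]` between the (negated) survival
#'   linear predictor and the latent score mapped to KPS {40, 60, 80, 100}.
#' @param seed integer seed.
#' @return an object of class `mirf_sim_config`.
#' @export
simulation_config <- function(n_samples = 400,
                              p_gene = 150,
                              p_protein = 150,
                              planted = NULL,
                              rule = NULL,
                              p_signal = 0.9,
                              p_noise = 0.1,
                              beta = 0.4,
                              weibull_shape = 1.2,
                              weibull_scale = 12,
                              censor_rate = 0.2,
                              missing_rate = 0,
                              rho = 0.6,
                              kps_coupling = 0.6,
                              seed = 1) {
  if (is.null(planted)) {
    planted <- data.frame(
      view = c("gene", "gene", "protein"),
      index = c(1L, 2L, 1L),
      label = c("g1", "g2", "p1"),
      copy_of = c(NA, NA, "g1"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(planted$copy_of)) planted$copy_of <- NA_character_
  if (is.null(rule)) rule <- list(c("g1", "p1"), c("g1", "g2"))

  if (n_samples < 2) stop_config("n_samples", "need at least 2 samples")
  if (p_gene < 1 || p_protein < 1) {
    stop_config("p_gene/p_protein", "each view needs at least one feature")
  }
  if (!all(planted$view %in% c("gene", "protein"))) {
    stop_config("planted", "view must be 'gene' or 'protein'")
  }
  bounds <- ifelse(planted$view == "gene", p_gene, p_protein)
  if (any(planted$index < 1 | planted$index > bounds)) {
    stop_config("planted", "planted index outside view bounds")
  }
  if (anyDuplicated(planted$label)) {
    stop_config("planted", "labels must be unique")
  }
  if (!(p_signal >= p_noise)) {
    stop_config("p_signal", "must satisfy p_signal >= p_noise")
  }
  if (any(c(p_signal, p_noise) < 0 | c(p_signal, p_noise) > 1)) {
    stop_config("p_signal/p_noise", "must lie in [0, 1]")
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop_config("censor_rate", "must lie in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_config("missing_rate", "must lie in [0, 1)")
  }
  if (weibull_shape <= 0 || weibull_scale <= 0) {
    stop_config("weibull_shape/weibull_scale", "must be positive")
  }
  if (abs(rho) > 1) stop_config("rho", "must lie in [-1, 1]")
  lits <- sub("^-", "", unlist(rule))
  if (length(lits) && !all(lits %in% planted$label)) {
    stop_config("rule", paste(
      "rule references unknown feature(s):",
      paste(setdiff(lits, planted$label), collapse = ", ")
    ))
  }
  beta <- rep_len(beta, nrow(planted))
  if (any(!is.finite(beta))) stop_config("beta", "must be finite")

  structure(
    list(
      n_samples = as.integer(n_samples), p_gene = as.integer(p_gene),
      p_protein = as.integer(p_protein), planted = planted, rule = rule,
      p_signal = p_signal, p_noise = p_noise, beta = beta,
      weibull_shape = weibull_shape, weibull_scale = weibull_scale,
      censor_rate = censor_rate, missing_rate = missing_rate, rho = rho,
      kps_coupling = kps_coupling, seed = as.integer(seed)
    ),
    class = "mirf_sim_config"
  )
}

eval_rule <- function(values, rule) {
  n <- ncol(values)
  if (length(rule) == 0) return(rep(FALSE, n))
  out <- rep(FALSE, n)
  for (clause in rule) {
    if (length(clause) == 0) stop("empty clause in rule", call. = FALSE)
    hit <- rep(TRUE, n)
    for (lit in clause) {
      neg <- startsWith(lit, "-")
      feat <- sub("^-", "", lit)
      if (!feat %in% rownames(values)) {
        stop(sprintf("rule references unknown feature '%s'", feat),
             call. = FALSE)
      }
      hit <- hit & if (neg) values[feat, ] <= 0 else values[feat, ] > 0
    }
    out <- out | hit
  }
  out
}

#' Binary outcome from a Boolean rule over planted features
#'
#' Evaluates an AND/OR rule over thresholded (at zero) planted-feature
#' values and draws the label 1 with probability `p_signal` where the rule
#' holds and `p_noise` elsewhere.
#'
#' @param values planted-feature submatrix, features x samples, with row
#'   names matching the rule's literals.
#' @param rule list of character clauses (OR of ANDs); see
#'   [simulation_config()].
#' @param p_signal,p_noise outcome probabilities when the rule is true/false.
#' @param seed integer seed.
#' @return integer vector of 0/1 labels, one per sample.
#' @export
boolean_outcome <- function(values, rule, p_signal, p_noise, seed = 1) {
  values <- as.matrix(values)
  active <- eval_rule(values, rule)
  set.seed(seed)
  pr <- ifelse(active, p_signal, p_noise)
  as.integer(runif(length(pr)) < pr)
}

#' Weibull proportional-hazards survival times with random censoring
#'
#' Event times follow a Weibull baseline with hazard multiplied by
#' `exp(values' beta)`. Censoring times are exponential with rate calibrated
#' (on the drawn event times) so that the expected censored fraction matches
#' `censor_rate`; censoring is independent of the event process.
#'
#' @param values planted-feature submatrix, features x samples.
#' @param beta log-hazard coefficients, one per feature row.
#' @param weibull_shape,weibull_scale baseline Weibull parameters
#'   (scale in months).
#' @param censor_rate expected censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return list with `os_months` (observed time) and `os_event`
#'   (1 = death observed, 0 = censored).
#' @export
simulate_survival <- function(values, beta, weibull_shape, weibull_scale,
                              censor_rate = 0, seed = 1) {
  values <- as.matrix(values)
  beta <- rep_len(beta, nrow(values))
  if (any(!is.finite(beta))) stop("beta must be finite", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  }
  n <- ncol(values)
  lp <- as.numeric(crossprod(values, beta))
  set.seed(seed)
  u <- runif(n)
  times <- weibull_scale * (-log(u) * exp(-lp))^(1 / weibull_shape)
  event <- rep(1L, n)
  if (censor_rate > 0) {
    # exponential rate theta with mean(1 - exp(-theta * T)) = censor_rate
    f <- function(theta) mean(1 - exp(-theta * times)) - censor_rate
    theta <- uniroot(f, c(1e-10, 1e6), tol = 1e-10)$root
    cens <- rexp(n, rate = theta)
    event <- as.integer(times <= cens)
    times <- pmin(times, cens)
  }
  list(os_months = times, os_event = event)
}

#' Inject missing-completely-at-random entries
#'
#' @param matrix numeric matrix.
#' @param missing_rate probability in `[0, 1)` that an entry is set to `NA`.
#' @param seed integer seed.
#' @return the matrix with entries removed; observed entries are unchanged.
#' @export
inject_missing <- function(matrix, missing_rate, seed = 1) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (missing_rate == 0) return(matrix)
  set.seed(seed)
  mask <- runif(length(matrix)) < missing_rate
  matrix[mask] <- NA
  matrix
}

#' Simulate a multiview cohort with planted signal
#'
#' Draws both views as standard-normal z-scores. Planted protein features
#' with a `copy_of` source are correlated (`rho`) noisy copies of the named
#' planted gene. The binary outcome follows the configured Boolean rule via
#' [boolean_outcome()]; survival months follow [simulate_survival()] with
#' log-hazard linear in the planted features; KPS is a thresholded latent
#' score positively coupled (`kps_coupling`) to longer survival; finally
#' MCAR missingness is injected in both views.
#'
#' @param config a [simulation_config()] object.
#' @return an object of class `mirf_cohort`: list with `sample_ids`,
#'   `gene_matrix`, `protein_matrix` (features x samples), `clinical`
#'   (data frame: `sample_id`, `os_months`, `os_event`, `kps`) and `truth`
#'   (planted table, rule, beta, binary `outcome`, rule indicator).
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "mirf_sim_config"))
  n <- config$n_samples
  set.seed(derive_seed(config$seed, 101))
  gene <- matrix(rnorm(config$p_gene * n), nrow = config$p_gene,
                 dimnames = list(sprintf("G%04d", seq_len(config$p_gene)),
                                 sprintf("S%04d", seq_len(n))))
  protein <- matrix(rnorm(config$p_protein * n), nrow = config$p_protein,
                    dimnames = list(sprintf("P%04d", seq_len(config$p_protein)),
                                    sprintf("S%04d", seq_len(n))))
  pl <- config$planted
  # correlated cross-view copies
  for (i in seq_len(nrow(pl))) {
    src <- pl$copy_of[i]
    if (!is.na(src) && config$rho != 0) {
      j <- match(src, pl$label)
      if (is.na(j) || pl$view[j] != "gene" || pl$view[i] != "protein") {
        stop_config("planted", "copy_of must name a planted gene label")
      }
      g <- gene[pl$index[j], ]
      protein[pl$index[i], ] <- config$rho * g +
        sqrt(1 - config$rho^2) * protein[pl$index[i], ]
    }
  }
  planted_values <- matrix(0, nrow = nrow(pl), ncol = n,
                           dimnames = list(pl$label, colnames(gene)))
  for (i in seq_len(nrow(pl))) {
    planted_values[i, ] <- if (pl$view[i] == "gene") {
      gene[pl$index[i], ]
    } else {
      protein[pl$index[i], ]
    }
  }
  outcome <- boolean_outcome(planted_values, config$rule, config$p_signal,
                             config$p_noise, seed = derive_seed(config$seed, 102))
  surv <- simulate_survival(planted_values, config$beta, config$weibull_shape,
                            config$weibull_scale, config$censor_rate,
                            seed = derive_seed(config$seed, 103))
  # KPS: latent score positively associated with longer survival
  set.seed(derive_seed(config$seed, 104))
  lp <- as.numeric(crossprod(planted_values, config$beta))
  lps <- if (sd(lp) > 0) (lp - mean(lp)) / sd(lp) else lp
  kps_score <- -config$kps_coupling * lps +
    sqrt(max(0, 1 - config$kps_coupling^2)) * rnorm(n)
  kps <- c(40L, 60L, 80L, 100L)[findInterval(kps_score, c(-1, 0, 1)) + 1L]

  gene <- inject_missing(gene, config$missing_rate,
                         seed = derive_seed(config$seed, 105))
  protein <- inject_missing(protein, config$missing_rate,
                            seed = derive_seed(config$seed, 106))

  clinical <- data.frame(
    sample_id = colnames(gene),
    os_months = surv$os_months,
    os_event = surv$os_event,
    kps = kps,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      sample_ids = colnames(gene),
      gene_matrix = gene,
      protein_matrix = protein,
      clinical = clinical,
      truth = list(
        planted = pl,
        planted_names = ifelse(pl$view == "gene",
                               rownames(gene)[pl$index],
                               rownames(protein)[pl$index]),
        rule = config$rule,
        beta = config$beta,
        outcome = outcome,
        rule_active = eval_rule(planted_values, config$rule)
      ),
      config = config
    ),
    class = "mirf_cohort"
  )
}

#' @export
print.mirf_cohort <- function(x, ...) {
  cat(sprintf(
    "multiview cohort: %d samples, %d gene + %d protein features\n",
    length(x$sample_ids), nrow(x$gene_matrix), nrow(x$protein_matrix)
  ))
  cat(sprintf("planted features: %s\n",
              paste(x$truth$planted_names, collapse = ", ")))
  invisible(x)
}

#' Write a cohort to Firehose/cBioPortal-style TSV files
#'
#' Each view is written tab-separated with the feature symbol in the first
#' column and one column per sample; missing entries are serialized as `NA`.
#' The clinical table has columns `SAMPLE_ID`, `OS_MONTHS`, `OS_STATUS`
#' (`LIVING`/`DECEASED`) and `KPS`.
#'
#' @param cohort a `mirf_cohort`.
#' @param directory output directory (created if absent).
#' @return named character vector of file paths (`gene`, `protein`,
#'   `clinical`).
#' @export
write_cohort_files <- function(cohort, directory) {
  stopifnot(inherits(cohort, "mirf_cohort"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", directory),
                  call. = FALSE)
  }
  write_view <- function(mat, path) {
    df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  }
  paths <- c(
    gene = file.path(directory, "gene_expression.tsv"),
    protein = file.path(directory, "protein_expression.tsv"),
    clinical = file.path(directory, "clinical.tsv")
  )
  write_view(cohort$gene_matrix, paths[["gene"]])
  write_view(cohort$protein_matrix, paths[["protein"]])
  clin <- data.frame(
    SAMPLE_ID = cohort$clinical$sample_id,
    OS_MONTHS = cohort$clinical$os_months,
    OS_STATUS = ifelse(cohort$clinical$os_event == 1, "DECEASED", "LIVING"),
    KPS = cohort$clinical$kps,
    stringsAsFactors = FALSE
  )
  write.table(clin, paths[["clinical"]], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  paths
}
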