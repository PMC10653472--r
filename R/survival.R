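#' Kaplan-Meier product-limit estimator
#'
#' @param time observed times (> 0), months.
#' @param event 1 = event (death), 0 = censored.
#' @return an object of class `mirf_km`: data frame with `time` (distinct
#'   event times, ascending), `n_risk`, `n_event`, `survival`; `S(0) = 1`
#'   implicitly.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  event <- as.integer(event)
  stopifnot(all(event %in% c(0L, 1L)))
  ev_times <- sort(unique(time[event == 1]))
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
               survival = surv),
    class = c("mirf_km", "data.frame")
  )
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time, the observed minus
#' expected events in group 1 under the hypergeometric null;
#' `statistic = U^2 / V` referred to a chi-squared distribution with one
#' degree of freedom.
#'
#' @param time observed times.
#' @param event 1 = event, 0 = censored.
#' @param group two-level grouping (factor or coercible).
#' @return list with `statistic`, `p`, `significant` (`p < 0.05`),
#'   `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("need exactly two groups", call. = FALSE)
  if (any(table(group) == 0)) stop("each group must be nonempty",
                                   call. = FALSE)
  event <- as.integer(event)
  g1 <- group == levels(group)[1]
  ev_times <- sort(unique(time[event == 1]))
  U <- 0; V <- 0; e1 <- 0
  o1 <- sum(event[g1])
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    exp1 <- d * n1 / n
    U <- U + (d1 - exp1)
    e1 <- e1 + exp1
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  stat <- if (V > 0) U^2 / V else 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p = p, significant = p < 0.05,
       observed = c(o1, sum(event) - o1),
       expected = c(e1, sum(event) - e1))
}

#' Dichotomize expression at its mean
#'
#' High = value strictly above the mean; values at or below the mean go to
#' low (fixed convention).
#'
#' @param expr numeric vector (nonconstant).
#' @return factor with levels `low`, `high`.
#' @export
dichotomize_by_mean <- function(expr) {
  if (sd(expr) == 0) stop("constant feature cannot be dichotomized",
                          call. = FALSE)
  factor(ifelse(expr > mean(expr), "high", "low"), levels = c("low", "high"))
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs whose predicted risk ordering matches the
#' observed survival ordering. A pair is usable when the earlier observed
#' time is an event; risk ties count one half. Higher risk should go with
#' shorter survival.
#'
#' @param risk_scores predicted risk (higher = worse prognosis).
#' @param time observed times.
#' @param event 1 = event, 0 = censored.
#' @return C in `[0, 1]`.
#' @export
concordance_index <- function(risk_scores, time, event) {
  n <- length(time)
  event <- as.integer(event)
  conc <- 0; usable <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      a <- if (time[i] < time[j]) i else j # earlier
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next # censored before the later time: unusable
      usable <- usable + 1
      if (risk_scores[a] > risk_scores[b]) {
        conc <- conc + 1
      } else if (risk_scores[a] == risk_scores[b]) {
        conc <- conc + 0.5
      }
    }
  }
  if (usable == 0) stop("no comparable pairs", call. = FALSE)
  conc / usable
}

#' Unpenalized Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow tie handling (Efron
#' available); per-feature hazard ratios with 95% Wald intervals and
#' p-values, model concordance and the likelihood-ratio test p-value.
#'
#' @param time observed times.
#' @param event 1 = event, 0 = censored.
#' @param covariates samples x features matrix or data frame.
#' @param features optional subset of column names to use.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return an object of class `mirf_cox`: list with `table` (feature,
#'   beta, HR, CI bounds, p), `concordance`, `lr_p`, `loglik`, `aic` and
#'   the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(time, event, covariates, features = NULL,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (!is.null(features)) {
    missing_f <- setdiff(features, names(covariates))
    if (length(missing_f)) {
      stop(sprintf("unknown feature(s): %s",
                   paste(missing_f, collapse = ", ")), call. = FALSE)
    }
    covariates <- covariates[, features, drop = FALSE]
  }
  if (ncol(covariates) == 0) stop("no covariates", call. = FALSE)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  qrX <- qr(as.matrix(covariates))
  if (qrX$rank < ncol(covariates)) {
    stop("rank-deficient (collinear) covariate matrix", call. = FALSE)
  }
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = ties)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    stop("Cox fit did not converge", call. = FALSE)
  }
  beta <- coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 20)) {
    grad <- tryCatch(
      sqrt(sum(colSums(as.matrix(stats::residuals(fit, type = "score")))^2)),
      error = function(e) NA_real_)
    stop(sprintf(
      "separation suspected (|beta| up to %.1f, score-gradient norm %.2e)",
      max(abs(beta)), grad), call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  z <- beta / se
  sm <- summary(fit)
  tab <- data.frame(
    feature = names(beta),
    beta = as.numeric(beta),
    HR = exp(as.numeric(beta)),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    p = 2 * pnorm(-abs(z)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  structure(
    list(table = tab,
         concordance = as.numeric(sm$concordance["C"]),
         lr_statistic = lr,
         lr_p = pchisq(lr, df = length(beta), lower.tail = FALSE),
         loglik = fit$loglik[2],
         aic = -2 * fit$loglik[2] + 2 * length(beta),
         fit = fit),
    class = "mirf_cox"
  )
}

#' Elastic-net Cox regression with concordance-selected penalty
#'
#' Fits the penalized Cox partial likelihood with penalty
#' `lambda * (alpha * |beta|_1 + (1 - alpha) / 2 * |beta|_2^2)` over a
#' log-spaced lambda path starting at the all-zero solution, then selects
#' lambda by event-stratified k-fold cross-validation maximizing the
#' held-out Harrell C-index. Features with nonzero coefficients at the
#' chosen lambda are flagged important.
#'
#' @param time observed times.
#' @param event 1 = event, 0 = censored.
#' @param covariates samples x features matrix.
#' @param alpha elastic-net mixing in `[0, 1]` (1 = lasso); default 0.5.
#' @param n_lambda path length.
#' @param n_folds cross-validation folds (event-stratified).
#' @param seed fold-assignment seed.
#' @return an object of class `mirf_coxnet`: list with `lambda` (path),
#'   `cv_c` (mean CV concordance per lambda), `lambda_opt`, `beta`
#'   (at `lambda_opt`), `nonzero` (feature names), `alpha`, `cindex_opt`,
#'   and the `glmnet` path fit.
#' @export
fit_coxnet <- function(time, event, covariates, alpha = 0.5, n_lambda = 50,
                       n_folds = 10, seed = 1) {
  X <- as.matrix(covariates)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  y <- survival::Surv(time, event)
  path <- glmnet::glmnet(X, y, family = "cox", alpha = alpha,
                         nlambda = n_lambda)
  lambda <- path$lambda
  set.seed(seed)
  folds <- integer(length(time))
  for (e in unique(event)) { # event-stratified folds
    idx <- which(event == e)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  cv_c <- matrix(NA_real_, nrow = n_folds, ncol = length(lambda))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (sum(event[tr]) < 2 || sum(!tr) < 3 || sum(event[!tr]) < 1) next
    fit_f <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "cox",
                            alpha = alpha, lambda = lambda)
    lp <- predict(fit_f, newx = X[!tr, , drop = FALSE], type = "link")
    for (l in seq_len(ncol(lp))) {
      cv_c[f, l] <- tryCatch(
        concordance_index(lp[, l], time[!tr], event[!tr]),
        error = function(e) NA_real_
      )
    }
  }
  mean_c <- colMeans(cv_c, na.rm = TRUE)
  mean_c[is.nan(mean_c)] <- NA_real_
  opt <- which.max(mean_c)
  beta <- as.numeric(coef(path, s = lambda[opt]))
  names(beta) <- colnames(X)
  structure(
    list(lambda = lambda, cv_c = mean_c, lambda_opt = lambda[opt],
         beta = beta, nonzero = names(beta)[beta != 0], alpha = alpha,
         cindex_opt = mean_c[opt], path = path),
    class = "mirf_coxnet"
  )
}

#' Backward stepwise Cox selection
#'
#' Starting from the full multivariate model, repeatedly removes the
#' feature whose removal most improves the criterion (AIC by default)
#' until no removal improves it. Removing the last feature is considered
#' against the null (intercept-free) Cox model.
#'
#' @param time observed times.
#' @param event 1 = event, 0 = censored.
#' @param covariates samples x features matrix or data frame.
#' @param features starting feature set (default: all columns).
#' @param criterion `"AIC"` (the only built-in).
#' @return list with `retained` (character vector, possibly empty) and
#'   `trace` (data frame of steps: dropped feature and criterion value).
#' @export
backward_stepwise <- function(time, event, covariates, features = NULL,
                              criterion = "AIC") {
  stopifnot(criterion == "AIC")
  covariates <- as.data.frame(covariates)
  current <- features %||% names(covariates)
  null_fit <- survival::coxph(survival::Surv(time, event) ~ 1)
  null_aic <- -2 * null_fit$loglik[1]
  model_aic <- function(feats) {
    if (length(feats) == 0) return(null_aic)
    cox_fit(time, event, covariates, features = feats)$aic
  }
  cur_aic <- model_aic(current)
  trace <- data.frame(dropped = NA_character_, aic = cur_aic,
                      stringsAsFactors = FALSE)
  repeat {
    if (length(current) == 0) break
    cand_aic <- vapply(current, function(f) {
      tryCatch(model_aic(setdiff(current, f)), error = function(e) Inf)
    }, numeric(1))
    best <- which.min(cand_aic)
    if (cand_aic[best] < cur_aic) {
      dropped <- current[best]
      current <- setdiff(current, dropped)
      cur_aic <- cand_aic[best]
      trace <- rbind(trace, data.frame(dropped = dropped, aic = cur_aic,
                                       stringsAsFactors = FALSE))
    } else {
      break
    }
  }
  list(retained = current, trace = trace)
}
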