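test_that("config validation names the offending field", {
  expect_error(simulation_config(n_samples = 1), "n_samples")
  expect_error(simulation_config(censor_rate = 1), "censor_rate")
  expect_error(simulation_config(missing_rate = 1.2), "missing_rate")
  expect_error(simulation_config(p_signal = 0.1, p_noise = 0.5), "p_signal")
  expect_error(
    simulation_config(planted = data.frame(view = "gene", index = 999,
                                           label = "g1"),
                      rule = list("g1")),
    "bounds"
  )
  expect_error(simulation_config(rule = list("nosuch")), "unknown")
})

test_that("simulation is deterministic and carries its truth block", {
  cfg <- simulation_config(n_samples = 60, p_gene = 20, p_protein = 15,
                           seed = 7)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  expect_identical(a$gene_matrix, b$gene_matrix)
  expect_identical(a$protein_matrix, b$protein_matrix)
  expect_identical(a$clinical, b$clinical)
  expect_identical(dim(a$gene_matrix), c(20L, 60L))
  expect_false(anyDuplicated(rownames(a$gene_matrix)) > 0)
  expect_true(all(a$clinical$os_months >= 0))
  expect_true(all(a$clinical$kps %in% c(40L, 60L, 80L, 100L)))
  expect_setequal(a$truth$planted_names, c("G0001", "G0002", "P0001"))
})

test_that("no-signal configuration yields null feature-label association", {
  cfg <- simulation_config(n_samples = 1000, p_gene = 30, p_protein = 30,
                           p_signal = 0.5, p_noise = 0.5, seed = 3)
  co <- simulate_multiomics(cfg)
  y <- co$truth$outcome
  r <- apply(rbind(co$gene_matrix, co$protein_matrix), 1,
             function(x) cor(x, y))
  expect_lt(max(abs(r)), 0.1)
  # chi-square screen with Bonferroni control finds nothing at alpha 0.01
  p <- apply(rbind(co$gene_matrix, co$protein_matrix) > 0, 1, function(x) {
    suppressWarnings(stats::chisq.test(table(x, y))$p.value)
  })
  expect_gt(min(p * length(p)), 0.01)
})

test_that("outcome prevalence matches the rule's closed-form probability", {
  # independent planted features, rule (g1>0 & g2>0) | (p1>0):
  # P(rule) = 1 - (1 - 1/4) * 1/2 = 0.625
  planted <- data.frame(view = c("gene", "gene", "protein"),
                        index = c(1L, 2L, 1L),
                        label = c("g1", "g2", "p1"),
                        copy_of = NA_character_)
  cfg <- simulation_config(n_samples = 500, p_gene = 50, p_protein = 50,
                           planted = planted,
                           rule = list(c("g1", "g2"), "p1"),
                           p_signal = 0.9, p_noise = 0.1, seed = 1)
  co <- simulate_multiomics(cfg)
  expected <- 0.1 + 0.8 * 0.625
  expect_lt(abs(mean(co$truth$outcome) - expected), 0.05)
})

test_that("boolean_outcome follows the rule exactly at extreme probabilities", {
  set.seed(9)
  vals <- matrix(rnorm(3 * 200), nrow = 3,
                 dimnames = list(c("g1", "g2", "p1"), NULL))
  lab <- boolean_outcome(vals, list("g1"), p_signal = 1, p_noise = 0, seed = 2)
  expect_identical(lab, as.integer(vals["g1", ] > 0))
  # empty rule: always false, labels ~ Bernoulli(p_noise)
  lab0 <- boolean_outcome(vals, list(), p_signal = 1, p_noise = 0.2, seed = 2)
  expect_lt(abs(mean(lab0) - 0.2), 0.1)
  expect_error(boolean_outcome(vals, list("zz"), 0.9, 0.1), "unknown")
})

test_that("AND-of-two rule hits its closed-form class balance", {
  set.seed(4)
  vals <- matrix(rnorm(2 * 2000), nrow = 2, dimnames = list(c("a", "b"), NULL))
  lab <- boolean_outcome(vals, list(c("a", "b")), 0.9, 0.1, seed = 5)
  expect_lt(abs(mean(lab) - (0.1 + 0.8 * 0.25)), 0.03)
})

test_that("null survival model matches its Weibull baseline", {
  vals <- matrix(rnorm(2000), nrow = 1, dimnames = list("x", NULL))
  s <- simulate_survival(vals, beta = 0, weibull_shape = 1.3,
                         weibull_scale = 10, censor_rate = 0, seed = 6)
  ks <- suppressWarnings(
    ks.test(s$os_months, stats::pweibull, shape = 1.3, scale = 10))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(s$os_event == 1L))
})

test_that("Cox refit recovers the generating hazard coefficient", {
  d <- make_ph_data(n = 1000, beta = 1, censor_rate = 0, seed = 2)
  fit <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x)
  expect_lt(abs(unname(coef(fit)) - 1), 0.15)
})

test_that("censoring calibration lands near the requested rate", {
  vals <- matrix(rnorm(2000), nrow = 1, dimnames = list("x", NULL))
  s <- simulate_survival(vals, beta = 0.5, weibull_shape = 1.2,
                         weibull_scale = 12, censor_rate = 0.3, seed = 8)
  frac <- mean(s$os_event == 0)
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.35)
  expect_error(simulate_survival(vals, beta = NaN, 1, 1), "finite")
})

test_that("survival generator respects proportional hazards", {
  d <- make_ph_data(n = 500, beta = 1, censor_rate = 0.2, seed = 11)
  g <- factor(ifelse(d$x > median(d$x), "high", "low"))
  lr <- logrank_test(d$time, d$event, g)
  expect_lt(lr$p, 0.01)
})

test_that("MCAR injection has binomial missing counts and a stable mask", {
  m <- matrix(rnorm(100 * 100), 100)
  expect_identical(inject_missing(m, 0), m)
  m1 <- inject_missing(m, 0.1, seed = 3)
  bounds <- stats::qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(sum(is.na(m1)), bounds[1])
  expect_lte(sum(is.na(m1)), bounds[2])
  expect_identical(which(is.na(inject_missing(m, 0.1, seed = 3))),
                   which(is.na(m1)))
  expect_identical(m1[!is.na(m1)], m[!is.na(m1)]) # observed untouched
  expect_error(inject_missing(m, 1), "missing_rate")
})

test_that("cohort files round-trip losslessly, including missing entries", {
  cfg <- simulation_config(n_samples = 12, p_gene = 6, p_protein = 4,
                           missing_rate = 0.15, seed = 5)
  co <- simulate_multiomics(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort_files(co, dir)
  g <- read_expression_matrix(paths[["gene"]])
  p <- read_expression_matrix(paths[["protein"]])
  expect_equal(g, co$gene_matrix, tolerance = 1e-12)
  expect_equal(p, co$protein_matrix, tolerance = 1e-12)
  expect_identical(is.na(g), is.na(co$gene_matrix))
  clin <- read_clinical(paths[["clinical"]])
  expect_equal(clin$os_months, co$clinical$os_months, tolerance = 1e-12)
  expect_identical(clin$os_event, co$clinical$os_event)
  expect_identical(clin$kps, co$clinical$kps)
})

test_that("clinical file has one header plus one line per sample", {
  cfg <- simulation_config(n_samples = 3, p_gene = 2, p_protein = 2, seed = 1)
  co <- simulate_multiomics(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort_files(co, dir)
  expect_length(readLines(paths[["clinical"]]), 4L)
})

test_that("KPS is positively coupled to survival", {
  cfg <- simulation_config(n_samples = 800, beta = 0.8, censor_rate = 0,
                           seed = 13)
  co <- simulate_multiomics(cfg)
  expect_gt(cor(co$clinical$kps, co$clinical$os_months,
                method = "spearman"), 0.1)
})
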