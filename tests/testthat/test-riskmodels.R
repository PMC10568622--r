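# lightweight covariate simulator for the regression checks (independent of
# the cohort generator): medication counts from a truncated normal, outcome
# from the logistic model
sim_cov <- function(n, beta = 0.087, b0 = -3.72, seed = 1) {
  set.seed(seed)
  plo <- pnorm(5, 18.26, 6.42)
  phi <- pnorm(40, 18.26, 6.42)
  m <- round(qnorm(runif(n, plo, phi), 18.26, 6.42))
  tibble::tibble(n_medications = m,
                 ade_occurred = rbinom(n, 1, plogis(b0 + beta * m)))
}

test_that("IRLS logistic fit matches glm coefficients to 1e-6", {
  cov <- sim_cov(400, seed = 7)
  fit <- fit_logistic(cov, covariates = "n_medications")
  ref <- glm(ade_occurred ~ n_medications, family = binomial(), data = cov)
  expect_true(fit$converged)
  expect_equal(fit$coefficients$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_equal(fit$coefficients$odds_ratio, exp(fit$coefficients$beta))
  expect_true(all(fit$coefficients$ci_low < fit$coefficients$odds_ratio &
                    fit$coefficients$odds_ratio < fit$coefficients$ci_high))
})

test_that("separation is flagged rather than silently reported", {
  cov <- tibble::tibble(ade_occurred = rep(c(0L, 1L), each = 20))
  cov$perfect <- cov$ade_occurred
  fit <- fit_logistic(cov, covariates = "perfect")
  expect_false(fit$converged)
  expect_true(fit$separation)
})

test_that("too few events is an explicit error", {
  cov <- tibble::tibble(ade_occurred = c(rep(0L, 50), rep(1L, 5)),
                        n_medications = rnorm(55, 18, 6))
  expect_error(fit_logistic(cov, covariates = "n_medications"),
               "fewer than 10 events")
})

test_that("coefficient recovery improves with sample size", {
  est <- vapply(c(500, 2000, 8000), function(n) {
    b <- vapply(1:10, function(s) {
      fit <- fit_logistic(sim_cov(n, seed = 100 + s),
                          covariates = "n_medications")
      fit$coefficients$beta[2]
    }, numeric(1))
    mean(b)
  }, numeric(1))
  # analytic Wald SE shrinks ~ 1/sqrt(n); the mean of 10 fits should sit
  # within 3 of those SEs of the truth at every n
  se <- c(0.024, 0.012, 0.006) / sqrt(10)
  expect_true(all(abs(est - 0.087) < 3 * se))
})

test_that("group comparisons: identical groups give p = 1", {
  base <- tibble::tibble(
    age = rep(70:79, 2), length_of_stay = rep(5:14, 2),
    n_diagnoses = rep(3:12, 2), n_medications = rep(11:20, 2),
    antibacterial_hours = rep(seq(0, 90, 10), 2),
    sex = rep(c("male", "female"), 10),
    antibacterial_use = rep(c(0L, 1L), 10))
  cov <- dplyr::bind_rows(base, base)
  cov$ade_occurred <- rep(c(0L, 1L), each = nrow(base))
  res <- compare_groups(cov)
  expect_true(all(res$p_value > 0.999))
})

test_that("group comparisons are invariant to row order and group relabeling", {
  g <- generate_cohort(synth_config(n_admissions = 150, seed = 51),
                       verify = FALSE)
  ades <- causality_filter(read_adjudications(g$adjudications, g$cohort))
  cov <- assemble_covariates(g$cohort, ades)
  res1 <- compare_groups(cov)
  set.seed(1)
  res2 <- compare_groups(cov[sample(nrow(cov)), ])
  expect_equal(res1$p_value, res2$p_value)
  flipped <- cov
  flipped$ade_occurred <- 1L - flipped$ade_occurred
  res3 <- compare_groups(flipped)
  expect_equal(res1$p_value, res3$p_value)
})

test_that("a planted medication-count shift is detected at n = 480", {
  # +3 medications in the ADE group (d ~ 0.47 with groups of 51 and 429)
  # gives rank-sum power near 0.7 at alpha = 0.01; the observed detection
  # rate over 200 replicates must sit in that band, and detection at the
  # 5% level must be clearly more frequent still
  p_values <- vapply(1:200, function(s) {
    set.seed(s)
    n1 <- 51; n0 <- 429
    cov <- tibble::tibble(
      ade_occurred = rep(c(1L, 0L), c(n1, n0)),
      n_medications = round(c(rnorm(n1, 21.26, 6.42), rnorm(n0, 18.26, 6.42))))
    res <- compare_groups(cov, continuous = "n_medications",
                          categorical = character())
    res$p_value
  }, numeric(1))
  expect_gte(mean(p_values < 0.01), 0.55)
  expect_lte(mean(p_values < 0.01), 0.90)
  expect_gte(mean(p_values < 0.05), 0.80)
})

test_that("antibacterial-use contingency pattern is non-significant", {
  # 2x2 table: rows antibacterial yes/no, columns ADE yes/no
  cov <- tibble::tibble(
    antibacterial_use = rep(c(1L, 1L, 0L, 0L), c(17, 131, 29, 298)),
    ade_occurred = rep(c(1L, 0L, 1L, 0L), c(17, 131, 29, 298)))
  res <- compare_groups(cov, continuous = character(),
                        categorical = "antibacterial_use")
  expect_gt(res$p_value, 0.05)
})

test_that("covariate assembly is complete-case and counts orders", {
  g <- generate_cohort(synth_config(n_admissions = 60, seed = 61),
                       verify = FALSE)
  ades <- causality_filter(read_adjudications(g$adjudications, g$cohort))
  cov <- assemble_covariates(g$cohort, ades)
  expect_equal(nrow(cov), 60)
  expect_false(anyNA(cov))
  expect_equal(cov$n_medications,
               as.integer(table(factor(g$cohort$medications$admission_id,
                                       cov$admission_id))))
  expect_setequal(cov$admission_id[cov$ade_occurred == 1],
                  unique(ades$admission_id))
})
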