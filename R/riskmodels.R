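# riskmodels module: group comparisons (rank-sum / chi-square) and the
# binary logistic regression of ADE risk factors. The logistic fit is an
# iteratively reweighted least-squares maximum-likelihood implementation
# with Wald inference, written against the module contract (tolerance 1e-8
# on the log-likelihood change, at most 50 iterations, separation flagged).

#' Assemble the risk-factor covariate rows
#'
#' One row per admission: ADE outcome, length of stay, number of diagnoses,
#' number of medications administered, antibacterial use and its total
#' duration in hours, age and sex. Complete-case: rows with missing values
#' are dropped.
#'
#' @param cohort a `gtt_cohort`.
#' @param ades ADE tibble after [causality_filter()].
#' @return tibble of covariate rows.
#' @export
assemble_covariates <- function(cohort, ades) {
  a <- cohort$admissions
  m <- cohort$medications
  n_med <- table(factor(m$admission_id, a$admission_id))
  anti <- m[m$drug_class == "antibacterial", , drop = FALSE]
  anti_hours <- tapply(
    ifelse(is.na(anti$stop_ts), 24, hours_between(anti$stop_ts, anti$start_ts)),
    factor(anti$admission_id, a$admission_id), sum)
  anti_hours[is.na(anti_hours)] <- 0
  out <- tibble(
    admission_id = a$admission_id,
    ade_occurred = as.integer(a$admission_id %in% ades$admission_id),
    length_of_stay = a$length_of_stay,
    n_diagnoses = a$n_diagnoses,
    n_medications = as.integer(n_med),
    antibacterial_use = as.integer(anti_hours > 0),
    antibacterial_hours = as.numeric(anti_hours),
    age = a$age,
    sex = a$sex)
  out[complete.cases(out), ]
}

#' Compare ADE and no-ADE groups
#'
#' Continuous covariates are compared with the two-sample rank-sum
#' (Wilcoxon) test, categorical covariates with the chi-square test
#' (without Yates continuity correction by default).
#'
#' @param cov covariate rows from [assemble_covariates()].
#' @param continuous names of continuous covariates.
#' @param categorical names of categorical covariates.
#' @param yates apply the continuity correction in 2x2 chi-square tests
#'   (default `FALSE`).
#' @return tibble `variable`, `test`, `statistic`, `p_value`.
#' @export
compare_groups <- function(cov,
                           continuous = c("age", "length_of_stay",
                                          "n_diagnoses", "n_medications",
                                          "antibacterial_hours"),
                           categorical = c("sex", "antibacterial_use"),
                           yates = FALSE) {
  g <- cov$ade_occurred
  if (length(unique(g)) < 2) {
    abort("both outcome groups must be non-empty")
  }
  rows <- list()
  for (v in continuous) {
    wt <- suppressWarnings(
      wilcox.test(cov[[v]][g == 1], cov[[v]][g == 0], exact = FALSE))
    rows[[v]] <- tibble(variable = v, test = "rank_sum",
                        statistic = unname(wt$statistic),
                        p_value = wt$p.value)
  }
  for (v in categorical) {
    tab <- table(cov[[v]], g)
    ct <- suppressWarnings(chisq.test(tab, correct = yates))
    rows[[v]] <- tibble(variable = v, test = "chi_square",
                        statistic = unname(ct$statistic),
                        p_value = ct$p.value)
  }
  bind_rows(rows)
}

#' Binary logistic regression of ADE occurrence
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares. Convergence is declared when the log-likelihood changes by less
#' than `tol` (default 1e-8) between iterations, with at most `max_iter`
#' (default 50) iterations. Standard errors are Wald (inverse observed
#' information); 95% confidence intervals are exp(beta +/- 1.96 SE).
#' Quasi-separation is flagged, not silently reported.
#'
#' @param cov covariate rows from [assemble_covariates()].
#' @param covariates model terms (default mirrors the risk-factor model:
#'   length of stay, diagnoses, medications, antibacterial use and its
#'   duration).
#' @param outcome outcome column (0/1; default `ade_occurred`).
#' @param tol,max_iter convergence controls.
#' @return a `gtt_logit` list: `coefficients` tibble (`term`, `beta`, `se`,
#'   `odds_ratio`, `p_value`, `ci_low`, `ci_high`), `converged`,
#'   `separation`, `iterations`, `loglik`, `n`, `n_events`.
#' @export
fit_logistic <- function(cov,
                         covariates = c("length_of_stay", "n_diagnoses",
                                        "n_medications", "antibacterial_use",
                                        "antibacterial_hours"),
                         outcome = "ade_occurred",
                         tol = 1e-8, max_iter = 50L) {
  y <- cov[[outcome]]
  stopifnot(all(y %in% c(0, 1)))
  if (sum(y) < 10) abort("fewer than 10 events; logistic fit not attempted")
  X <- cbind(`(Intercept)` = 1,
             as.matrix(cov[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  if (qr(X)$rank < ncol(X)) abort("design matrix is rank deficient")

  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- drop(solve(XtW %*% X, XtW %*% z))
    ll <- sum(y * log(pmax(plogis(drop(X %*% beta)), 1e-300)) +
                (1 - y) * log(pmax(1 - plogis(drop(X %*% beta)), 1e-300)))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  # quasi-separation: fitted probabilities saturate and coefficients drift;
  # the ML estimate does not exist, so the fit is not 'converged'
  separation <- max(abs(beta)) > 15 || all(abs(y - mu) < 1e-4)
  if (separation) converged <- FALSE
  info <- t(X * pmax(mu * (1 - mu), 1e-10)) %*% X
  se <- sqrt(diag(solve(info)))
  zval <- beta / se
  coefs <- tibble(term = colnames(X), beta = unname(beta), se = unname(se),
                  odds_ratio = exp(unname(beta)),
                  p_value = unname(2 * pnorm(-abs(zval))),
                  ci_low = exp(unname(beta - 1.96 * se)),
                  ci_high = exp(unname(beta + 1.96 * se)))
  structure(list(coefficients = coefs, converged = converged,
                 separation = separation, iterations = iter,
                 loglik = sum(y * log(pmax(mu, 1e-300)) +
                                (1 - y) * log(pmax(1 - mu, 1e-300))),
                 n = nrow(X), n_events = sum(y)),
            class = "gtt_logit")
}

#' @export
print.gtt_logit <- function(x, ...) {
  cat(sprintf("Logistic regression: %d observations, %d events, %s in %d iteration(s)\n",
              x$n, x$n_events,
              if (x$converged) "converged" else
                if (x$separation) "NOT converged (separation suspected)" else
                  "NOT converged",
              x$iterations))
  print(x$coefficients)
  invisible(x)
}
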