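test_that("identical seeds give byte-identical cohorts", {
  a <- generate_cohort(synth_config(n_admissions = 80, seed = 17),
                       verify = FALSE)
  b <- generate_cohort(synth_config(n_admissions = 80, seed = 17),
                       verify = FALSE)
  for (nm in c("admissions", "medications", "labs", "events", "context")) {
    expect_identical(a$cohort[[nm]], b$cohort[[nm]], info = nm)
  }
  expect_identical(a$adjudications, b$adjudications)
  expect_identical(a$ground_truth$plants, b$ground_truth$plants)
  da <- withr::local_tempdir(); db <- withr::local_tempdir()
  write_cohort(a$cohort, da); write_cohort(b$cohort, db)
  for (f in list.files(da)) {
    expect_identical(readLines(file.path(da, f)), readLines(file.path(db, f)),
                     info = f)
  }
  c2 <- generate_cohort(synth_config(n_admissions = 80, seed = 18),
                        verify = FALSE)
  expect_false(identical(a$cohort$labs, c2$cohort$labs))
})

test_that("generated cohorts are schema-valid and eligibility-clean", {
  g <- generate_cohort(synth_config(n_admissions = 120, seed = 23),
                       verify = FALSE)
  expect_equal(nrow(cohort_rejects(g$cohort)), 0)
  kept <- apply_eligibility(g$cohort)
  expect_equal(nrow(kept$admissions), 120)
  expect_true(all(g$cohort$admissions$age >= 65))
  expect_true(all(g$cohort$admissions$length_of_stay >= 2))
})

test_that("planted conditions pass the generation-time engine self-check", {
  expect_no_error(g <- generate_cohort(synth_config(n_admissions = 60,
                                                    seed = 29), verify = TRUE))
  expect_gt(nrow(g$ground_truth$plants), 0)
})

test_that("engine recall on noise-free plants is 100% with no false hits", {
  g <- generate_cohort(synth_config(n_admissions = 160, seed = 37),
                       verify = FALSE)
  hits <- evaluate_cohort(g$cohort)
  want <- paste(g$ground_truth$plants$admission_id,
                g$ground_truth$plants$trigger_id)
  got <- paste(hits$admission_id, hits$trigger_id)
  expect_setequal(got, want)
})

test_that("noise plants appear in the ground truth and add about f x n hits", {
  f <- 0.1
  g <- generate_cohort(synth_config(n_admissions = 480, seed = 43,
                                    noise_rate = f), verify = FALSE)
  hits <- evaluate_cohort(g$cohort)
  plants <- g$ground_truth$plants
  # all hits are still accounted for by the (noise-inclusive) plant list
  expect_setequal(paste(hits$admission_id, hits$trigger_id),
                  paste(plants$admission_id, plants$trigger_id))
  n_noise <- sum(plants$is_noise)
  # binomial 3-SE band around f x n, allowing for collisions with real plants
  expect_lt(abs(n_noise - f * 480), 3 * sqrt(480 * f * (1 - f)) + 12)
})

test_that("ADE patient fraction stays in the 3-SE band around the target", {
  for (seed in c(3, 19)) {
    g <- generate_cohort(synth_config(seed = seed), verify = FALSE)
    frac <- length(unique(g$ground_truth$ades$admission_id)) / 480
    expect_gte(frac, 0.08)
    expect_lte(frac, 0.14)
  }
})

test_that("marginals are calibrated across 50 seeds", {
  n <- 480
  stats <- vapply(1:50, function(s) {
    g <- generate_cohort(synth_config(seed = 1000 + s), verify = FALSE)
    a <- g$cohort$admissions
    n_med <- table(factor(g$cohort$medications$admission_id, a$admission_id))
    c(age = mean(a$age), los = mean(a$length_of_stay),
      med = mean(n_med), dx = mean(a$n_diagnoses),
      female = mean(a$sex == "female"),
      age_sd = sd(a$age), los_sd = sd(a$length_of_stay))
  }, numeric(7))
  targets <- c(age = 72.61, los = 8.95, med = 18.26, dx = 5.38,
               female = 0.4562)
  sds <- c(age = 5.94, los = 4.57, med = 6.42, dx = 2.80,
           female = sqrt(0.4562 * 0.5438))
  for (nm in names(targets)) {
    per_seed_ok <- abs(stats[nm, ] - targets[[nm]]) <
      3 * sds[[nm]] / sqrt(n) + 0.06  # 0.06 absorbs integer rounding
    expect_gte(sum(per_seed_ok), 47)
    pooled <- mean(stats[nm, ])
    expect_lt(abs(pooled - targets[[nm]]),
              4 * sds[[nm]] / sqrt(50 * n) + 0.06)
  }
  # dispersion of the two headline marginals also tracks the targets
  expect_lt(abs(mean(stats["age_sd", ]) - 5.94), 0.4)
  expect_lt(abs(mean(stats["los_sd", ]) - 4.57), 0.4)
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(plant_rates = c(L1 = 1.5)), "infeasible")
  expect_error(synth_config(p_female = -0.1), "infeasible")
  expect_error(synth_config(noise_rate = 2), "infeasible")
  expect_error(synth_config(n_admissions = 0), "n_admissions")
  expect_error(synth_config(plant_rates = c(BOGUS = 0.5)), "trigger id")
})

test_that("a targeted plant realizes its trigger on every admission", {
  # hypotension: systolic below 90 with an antihypertensive active
  cfg <- synth_config(n_admissions = 10, seed = 53,
                      plant_rates = c(L16 = 1), ade_prevalence = 0.01,
                      extra_candidate_rate = 0)
  g <- generate_cohort(cfg, verify = FALSE)
  hits <- evaluate_cohort(g$cohort)
  expect_true(all(g$cohort$admissions$admission_id %in%
                    hits$admission_id[hits$trigger_id == "L16"]))
  sb <- g$cohort$labs[g$cohort$labs$analyte == "systolic_bp", ]
  expect_true(any(sb$value < 90))
})

test_that("study-counts fixture is internally consistent", {
  fx <- study_counts_fixture()
  expect_equal(nrow(fx$trigger_counts), 36)
  expect_equal(sum(fx$trigger_counts$positives), 281L)
  expect_equal(sum(fx$trigger_counts$detections), 67L)
  expect_equal(sum(fx$onset_counts$n), fx$n_ades)
  expect_equal(sum(fx$severity_counts$n), fx$n_ades)
  expect_equal(sum(fx$multiplicity_counts$n_patients), fx$n_patients_with_ade)
  expect_equal(sum(fx$multiplicity_counts$n_patients *
                     fx$multiplicity_counts$n_ades_per_patient), fx$n_ades)
  expect_equal(fx$patient_days, fx$n_admissions * fx$mean_los_days)
  expect_true(all(fx$trigger_counts$detections <= fx$trigger_counts$positives))
})
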