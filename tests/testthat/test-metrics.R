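test_that("PPV table handles never-fired triggers and reports a weighted overall", {
  counts <- tibble::tibble(trigger_id = c("L1", "T1", "C1"),
                           positives = c(10L, 0L, 40L),
                           detections = c(5L, 0L, 4L))
  ppv <- ppv_table(counts)
  expect_equal(ppv$ppv_percent[ppv$trigger_id == "L1"], 50)
  expect_true(is.na(ppv$ppv_percent[ppv$trigger_id == "T1"]))
  expect_equal(overall_ppv(ppv), 100 * 9 / 50)
  # overall lies between the extremes of the fired triggers (weighted mean)
  fired <- ppv$ppv_percent[!is.na(ppv$ppv_percent) & ppv$trigger_id != "Total"]
  expect_gte(overall_ppv(ppv), min(fired))
  expect_lte(overall_ppv(ppv), max(fired))
  expect_error(ppv_table(tibble::tibble(trigger_id = "X", positives = 1L,
                                        detections = 2L)), "exceed")
})

test_that("rate panel computes the three surveillance rates", {
  p <- rate_panel(1, 1, 1, 10)
  expect_equal(p$incidence_percent, 100)
  expect_equal(p$ades_per_100_admissions, 100)
  expect_equal(p$ades_per_1000_patient_days, 100)  # 1000 x 1/10
  z <- rate_panel(100, 0, 0, 900)
  expect_equal(z$incidence_percent, 0)
  expect_equal(z$ades_per_1000_patient_days, 0)
  expect_error(rate_panel(0, 0, 0, 1), "positive number of admissions")
  # scale equivariance: duplicating every admission and ADE changes nothing
  a <- rate_panel(480, 51, 56, 4296)
  b <- rate_panel(960, 102, 112, 8592)
  expect_equal(a$incidence_percent, b$incidence_percent)
  expect_equal(a$ades_per_100_admissions, b$ades_per_100_admissions)
  expect_equal(a$ades_per_1000_patient_days, b$ades_per_1000_patient_days)
})

test_that("monthly series degenerates to the rate panel and conserves patient-days", {
  g <- generate_cohort(synth_config(n_admissions = 150, seed = 31),
                       verify = FALSE)
  ades <- causality_filter(read_adjudications(g$adjudications, g$cohort))
  panel <- rate_panel_from_data(g$cohort, ades)
  series <- monthly_rate_series(g$cohort, ades)
  expect_equal(sum(series$patient_days), panel$patient_days)
  expect_equal(sum(series$n_ades), panel$n_ades)
  expect_equal(sum(series$n_admissions), panel$n_admissions)

  # single-month cohort: series of length 1 equal to the panel
  one <- g$cohort
  keep <- format(one$admissions$admit_ts, "%m") == "03"
  ids <- one$admissions$admission_id[keep]
  for (nm in names(one)) one[[nm]] <- one[[nm]][one[[nm]]$admission_id %in% ids, ]
  ades1 <- ades[ades$admission_id %in% ids, ]
  s1 <- monthly_rate_series(one, ades1)
  p1 <- rate_panel_from_data(one, ades1)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$ades_per_100_admissions, p1$ades_per_100_admissions)
  expect_equal(s1$ades_per_1000_patient_days, p1$ades_per_1000_patient_days)

  # an empty month inside the span is NA, not zero
  two <- g$cohort
  keep2 <- format(two$admissions$admit_ts, "%m") %in% c("01", "03")
  ids2 <- two$admissions$admission_id[keep2]
  for (nm in names(two)) two[[nm]] <- two[[nm]][two[[nm]]$admission_id %in% ids2, ]
  s2 <- monthly_rate_series(two, ades[ades$admission_id %in% ids2, ])
  feb <- s2[s2$month == "2021-02", ]
  expect_equal(feb$n_admissions, 0)
  expect_true(is.na(feb$ades_per_100_admissions))
})

test_that("distribution tables sum to their totals with percentages near 100", {
  g <- generate_cohort(synth_config(n_admissions = 200, seed = 41),
                       verify = FALSE)
  ades <- causality_filter(read_adjudications(g$adjudications, g$cohort))
  tabs <- distribution_tables(ades)
  expect_equal(sum(tabs$onset$n), nrow(ades))
  expect_equal(sum(tabs$severity$n), nrow(ades))
  expect_gte(sum(tabs$organ$n), nrow(ades))  # multi-system ADEs add entries
  for (nm in c("onset", "organ", "severity", "multiplicity")) {
    expect_equal(sum(tabs[[nm]]$percent), 100, tolerance = 1e-9, info = nm)
  }
  expect_equal(sum(tabs$multiplicity$n_patients *
                     tabs$multiplicity$n_ades_per_patient), nrow(ades))
  # degenerate case: a single ADE
  one <- ades[1, ]
  t1 <- distribution_tables(one)
  expect_equal(sum(t1$onset$n), 1)
  expect_equal(max(t1$severity$percent), 100)
})

test_that("sample-size formula rounds to nearest and guards its domain", {
  # 1.96^2 x 0.5 x 0.5 / 0.05^2 = 384.16 -> 384
  expect_equal(sample_size(P = 0.5, Z = 1.96, delta = 0.05), 384L)
  expect_equal(sample_size(P = 0.2, Z = 1.96, delta = 0.02),
               as.integer(floor(1.96^2 * 0.2 * 0.8 / 4e-4 + 0.5)))
  expect_error(sample_size(P = 0, delta = 0.03), "between 0 and 1")
  expect_error(sample_size(P = 1.2, delta = 0.03), "between 0 and 1")
  expect_error(sample_size(P = 0.1, delta = 1e-9), "delta")
})

test_that("rendering rounds half-to-even at two decimals", {
  expect_equal(render_round(23.8434), 23.84)
  expect_equal(render_round(11.66667), 11.67)
  expect_equal(render_round(10.625), 10.62)
})
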