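test_that("ratio metrics divide, zero denominators go missing, negatives error", {
  expect_equal(ratio_metric(4, 2), 2)
  expect_equal(ratio_metric(0, 5), 0)
  expect_warning(r <- ratio_metric(3, 0), "zero denominator")
  expect_true(is.na(r))
  expect_error(ratio_metric(-1, 2), "negative")
  expect_error(ratio_metric(1, -2), "negative")
  # vectorized with NA pass-through
  expect_warning(v <- ratio_metric(c(4, NA, 3), c(2, 1, 0)))
  expect_equal(v, c(2, NA, NA))
})

test_that("median dichotomization sends ties to low", {
  expect_equal(unname(dichotomize_by_median(c(1, 2, 3, 4))$labels),
               c("low", "low", "high", "high"))
  # odd n: the median element itself is low
  expect_equal(unname(dichotomize_by_median(c(1, 2, 3))$labels),
               c("low", "low", "high"))
  # degenerate: all equal -> all low with a warning
  expect_warning(d <- dichotomize_by_median(c(5, 5, 5, 5)), "identical")
  expect_equal(unname(d$labels), rep("low", 4))
  # missing values stay missing and are excluded from the median
  d2 <- dichotomize_by_median(c(1, NA, 3, 4))
  expect_true(is.na(d2$labels[2]))
  expect_equal(d2$rule$median, 3)
})

test_that("dichotomization partition: |low| >= |high| and they cover all non-missing", {
  set.seed(12)
  for (i in 1:25) {
    v <- sample(0:5, sample(2:30, 1), replace = TRUE)
    lab <- suppressWarnings(dichotomize_by_median(v))$labels
    expect_equal(sum(lab == "low") + sum(lab == "high"), length(v))
    expect_gte(sum(lab == "low"), sum(lab == "high"))
    med <- median(v)
    expect_true(all(v[lab == "high"] > med))
    expect_true(all(v[lab == "low"] <= med))
  }
})

test_that("Immunoscore equals the indicator sum over all 16 combinations", {
  combos <- expand.grid(b1 = 0:1, b2 = 0:1, b3 = 0:1, b4 = 0:1)
  # bit = 1 -> value 10 (above the pooled median 5.5), bit = 0 -> value 1
  dens <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:16),
    cd3_tumor = ifelse(combos$b1 == 1, 10, 1),
    cd3_stroma = ifelse(combos$b2 == 1, 10, 1),
    cd8_tumor = ifelse(combos$b3 == 1, 10, 1),
    cd8_stroma = ifelse(combos$b4 == 1, 10, 1)
  )
  sc <- compute_immunoscore(dens)
  expect_equal(sc$score, rowSums(combos))
  expect_equal(sc$cd3_tumor_high, combos$b1)
  expect_equal(sc$cd8_stroma_high, combos$b4)
  expect_equal(sc$class, dplyr::case_when(
    sc$score == 0 ~ "I0", sc$score == 4 ~ "I4", TRUE ~ "IntI"
  ))
  # a patient missing one metric gets a missing class, flagged not dropped
  dens$cd8_tumor[3] <- NA
  sc2 <- compute_immunoscore(dens)
  expect_true(is.na(sc2$class[3]))
  expect_equal(nrow(sc2), 16)
})

test_that("concordance groups combine CD3/CD68 labels", {
  expect_equal(concordance_group("high", "high"), "concordant")
  expect_equal(concordance_group("low", "low"), "concordant")
  expect_equal(concordance_group("high", "low"), "discordant")
  expect_equal(concordance_group("low", "high"), "discordant")
  expect_true(is.na(concordance_group("high", NA)))
  expect_error(concordance_group("hi", "low"), "labels")
})

test_that("RECIST disease-control classification", {
  r <- classify_response(c("CR", "PR", "SD", "PD"))
  expect_equal(r$dcr_group, c("CD", "CD", "CD", "PD"))
  expect_error(classify_response("XX"), "unknown RECIST")
  # idempotent on the resulting partition: every patient is CD or PD
  set.seed(2)
  rec <- sample(c("CR", "PR", "SD", "PD"), 50, replace = TRUE)
  g <- classify_response(rec)$dcr_group
  expect_true(all(g %in% c("CD", "PD")))
  expect_equal(sum(g == "CD") + sum(g == "PD"), 50)
  expect_equal(classify_response(rec)$dcr_group, g)
})
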