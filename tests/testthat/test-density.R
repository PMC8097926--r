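labelled_field <- function(n_a_tumor, n_a_stroma, n_b = 0, n_ab = 0,
                           areas = c(tumor = 0.5, stroma = 0.5)) {
  labels <- c(rep(list("A"), n_a_tumor + n_a_stroma),
              rep(list("B"), n_b), rep(list(c("A", "B")), n_ab))
  comp <- c(rep("tumor", n_a_tumor), rep("stroma", n_a_stroma),
            rep("stroma", n_b + n_ab))
  n <- length(labels)
  toy_field(x = seq_len(n), y = rep(1, n), labels = labels,
            compartment = comp, areas = areas)
}

test_that("compartment density divides counts by the compartment area", {
  f <- labelled_field(50, 10)
  s <- toy_sample(list(f))
  expect_equal(compartment_density(s, "A", "tumor")$value, 100) # 50 / 0.5
  expect_equal(compartment_density(s, "A", "stroma")$value, 20)
  # total-area metric: pooled counts over pooled area, not a mean of densities
  expect_equal(compartment_density(s, "A", "total")$value, 60)
})

test_that("patient density is the unweighted mean over fields", {
  f1 <- labelled_field(50, 0)                                  # 100 /mm^2
  f2 <- labelled_field(100, 0)                                 # 200 /mm^2
  s <- toy_sample(list(f1, f2))
  r <- compartment_density(s, "A", "tumor")
  expect_equal(r$value, 150)
  expect_equal(r$n_fields_used, 2)
})

test_that("fields with zero compartment area are excluded, never zeroed", {
  f1 <- labelled_field(50, 0)
  f0 <- labelled_field(0, 8, areas = c(tumor = 0, stroma = 0.5))
  s <- toy_sample(list(f1, f0))
  r <- compartment_density(s, "A", "tumor")
  expect_equal(r$value, 100)
  expect_equal(r$n_fields_excluded, 1)
  # all fields excluded: missing value, flagged
  s0 <- toy_sample(list(f0))
  r0 <- compartment_density(s0, "A", "tumor")
  expect_true(is.na(r0$value))
  expect_equal(r0$n_fields_used, 0)
  # but the same field is perfectly valid for a stromal metric
  expect_equal(compartment_density(s0, "A", "stroma")$value, 16)
})

test_that("percentages divide child by parent counts per field", {
  # 5 of 20 A cells also carry B -> 25 % B among A
  f <- toy_field(1:20, rep(1, 20),
                 c(rep(list(c("A", "B")), 5), rep(list("A"), 15)))
  s <- toy_sample(list(f))
  expect_equal(phenotype_percentage(s, "B", "A", "stroma")$value, 25)
  # zero children among parents is a valid 0 %
  f0 <- toy_field(1:20, rep(1, 20), rep(list("A"), 20))
  expect_equal(phenotype_percentage(toy_sample(list(f0)), "B", "A",
                                    "stroma")$value, 0)
  # field means: 25 % and 75 % average to 50 %
  f75 <- toy_field(1:20, rep(1, 20),
                   c(rep(list(c("A", "B")), 15), rep(list("A"), 5)))
  expect_equal(phenotype_percentage(toy_sample(list(f, f75)), "B", "A",
                                    "stroma")$value, 50)
  # fields with no parent cells are excluded
  fb <- toy_field(1:4, rep(1, 4), rep(list("B"), 4))
  r <- phenotype_percentage(toy_sample(list(f, fb)), "B", "A", "stroma")
  expect_equal(r$value, 25)
  expect_equal(r$n_fields_excluded, 1)
})

test_that("a phenotype is 100 % of itself wherever defined", {
  f <- random_field(120, seed = 5)
  s <- toy_sample(list(f))
  for (ph in c("A", "B")) {
    for (comp in c("tumor", "stroma", "total")) {
      v <- phenotype_percentage(s, ph, ph, comp)$value
      if (!is.na(v)) expect_equal(v, 100)
    }
  }
})

test_that("patient aggregation reports mean, used and excluded counts", {
  expect_equal(patient_aggregate(c(1, 2, 3)),
               list(mean = 2, n_used = 3L, n_excluded = 0L))
  expect_equal(patient_aggregate(numeric(0)),
               list(mean = NA_real_, n_used = 0L, n_excluded = 0L))
  expect_equal(patient_aggregate(c(10, NA, 30)),
               list(mean = 20, n_used = 2L, n_excluded = 1L))
})
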