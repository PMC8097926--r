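test_that("nearest-neighbor distance matches hand geometry", {
  # 3-4-5 triangle
  f <- toy_field(c(0, 3), c(0, 4), list("A", "B"))
  expect_equal(nearest_neighbor_mean_distance(f, "A", "B"), 5)

  # two references, two targets: distances 1.0 and 5.0, mean 3.0
  f2 <- toy_field(c(0, 10, 0, 14), c(0, 0, 1, 3),
                  list("A", "A", "B", "B"))
  expect_equal(nearest_neighbor_mean_distance(f2, "A", "B"), 3)
})

test_that("a cell is never its own nearest neighbor", {
  solo <- toy_field(5, 5, list("A"))
  expect_true(is.na(nearest_neighbor_mean_distance(solo, "A", "A")))

  trio <- toy_field(c(0, 1, 3), c(0, 0, 0), list("A", "A", "A"))
  # nearest other-cell distances: 1, 1, 2
  expect_equal(nearest_neighbor_mean_distance(trio, "A", "A"), 4 / 3)
})

test_that("fraction-within-radius counts the boundary as within", {
  f <- toy_field(c(0, 0), c(0, 25), list("A", "B"))
  expect_equal(fraction_within_radius(f, "A", "B", 25), 100)
  expect_equal(fraction_within_radius(f, "A", "B", 24.999), 0)
})

test_that("fraction-within-radius fractions and empty-target cases", {
  f <- toy_field(c(0, 50, 100, 0), c(0, 0, 0, 10),
                 list("A", "A", "A", "B"))
  expect_equal(fraction_within_radius(f, "A", "B", 20), 100 / 3)
  # no target cells at all: a valid 0%, not an exclusion
  expect_equal(fraction_within_radius(f, "A", "C", 20), 0)
  # no reference cells: excluded
  expect_true(is.na(fraction_within_radius(f, "C", "A", 20)))
})

test_that("spatial metrics agree exactly with the brute-force oracle", {
  set.seed(99)
  sizes <- sample(2:500, 40, replace = TRUE)
  for (k in seq_along(sizes)) {
    f <- random_field(sizes[k], seed = 1000 + k)
    for (pair in list(c("A", "B"), c("tumor", "A"), c("A", "A"))) {
      expect_equal(
        nearest_neighbor_mean_distance(f, pair[1], pair[2]),
        oracle_nn(f, pair[1], pair[2]),
        tolerance = 0
      )
      for (r in c(20, 25, 30)) {
        expect_equal(
          fraction_within_radius(f, pair[1], pair[2], r),
          oracle_fwr(f, pair[1], pair[2], r),
          tolerance = 0
        )
      }
    }
  }
})

test_that("fraction-within-radius is non-decreasing in the radius", {
  f <- random_field(300, seed = 7)
  radii <- c(5, 10, 15, 20, 25, 30, 50, 100)
  vals <- vapply(radii, function(r) fraction_within_radius(f, "A", "B", r),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("nearest-neighbor distance is invariant under rigid motions", {
  f <- random_field(200, seed = 11)
  base <- nearest_neighbor_mean_distance(f, "A", "B")
  # translation
  ft <- f
  ft$x_um <- ft$x_um + 123.4
  ft$y_um <- ft$y_um + 55.5
  expect_equal(nearest_neighbor_mean_distance(ft, "A", "B"), base)
  # rotation by 37 degrees about the origin (shifted to stay positive)
  th <- 37 * pi / 180
  fr <- f
  xr <- f$x_um * cos(th) - f$y_um * sin(th)
  yr <- f$x_um * sin(th) + f$y_um * cos(th)
  fr$x_um <- xr - min(xr)
  fr$y_um <- yr - min(yr)
  expect_equal(nearest_neighbor_mean_distance(fr, "A", "B"), base,
               tolerance = 1e-12)
})

test_that("adding a target cell never increases any nearest distance", {
  f <- random_field(150, seed = 13)
  per_ref_nearest <- function(field) {
    refs <- which(vapply(field$phenotypes, function(p) "A" %in% p, logical(1)))
    vapply(refs, function(i) {
      tg <- which(vapply(field$phenotypes, function(p) "B" %in% p, logical(1)))
      tg <- setdiff(tg, i)
      min(sqrt((field$x_um[i] - field$x_um[tg])^2 +
                 (field$y_um[i] - field$y_um[tg])^2))
    }, numeric(1))
  }
  before <- per_ref_nearest(f)
  f2 <- dplyr::bind_rows(f, tibble::tibble(
    cell_id = max(f$cell_id) + 1L, x_um = 300, y_um = 250,
    compartment = "stroma", phenotypes = list("B")
  ))
  attr(f2, "phenotype_names") <- attr(f, "phenotype_names")
  after <- per_ref_nearest(f2)
  expect_true(all(after <= before + 1e-12))
})

test_that("patient aggregation of spatial metrics averages fields and tallies exclusions", {
  f1 <- toy_field(c(0, 0), c(0, 10), list("A", "B"))     # nn = 10
  f2 <- toy_field(c(0, 0), c(0, 20), list("A", "B"))     # nn = 20
  f3 <- toy_field(5, 5, list("A"))                       # excluded (no B)
  s <- toy_sample(list(f1, f2, f3))
  res <- aggregate_spatial_metric(s, "nn_mean_distance", "A", "B")
  expect_equal(res$value, 15)
  expect_equal(res$n_fields_used, 2L)
  expect_equal(res$n_fields_excluded, 1L)

  g1 <- toy_field(c(0, 0), c(0, 10), list("A", "B"))     # 100 %
  g2 <- toy_field(c(0, 0, 90), c(0, 10, 0), list("A", "B", "A")) # 50 %
  g3 <- toy_field(5, 5, list("B"))                       # excluded (no A)
  s2 <- toy_sample(list(g1, g2, g3))
  res2 <- aggregate_spatial_metric(s2, "fraction_within", "A", "B",
                                   radius_um = 20)
  expect_equal(res2$value, 75)
  expect_equal(res2$n_fields_excluded, 1L)

  # every field excluded: missing value, flagged, not an error
  s3 <- toy_sample(list(f3))
  res3 <- aggregate_spatial_metric(s3, "nn_mean_distance", "A", "B")
  expect_true(is.na(res3$value))
  expect_equal(res3$n_fields_excluded, 1L)
})
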