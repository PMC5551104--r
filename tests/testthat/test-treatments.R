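# A deterministic 10x10 toy world used throughout this file: four quadrant
# counties, a single linear covariate, and hand-placed records.
toy_world <- function() {
  memo("toy_world", function() {
    spec <- grid_spec(10, 10)
    labels <- matrix(0L, 10, 10)
    labels[1:5, 1:5] <- 1L; labels[6:10, 1:5] <- 2L
    labels[1:5, 6:10] <- 3L; labels[6:10, 6:10] <- 4L
    counties <- data.frame(
      county_id = 1:4,
      x = c(2.5, 2.5, 7.5, 7.5), y = c(2.5, 7.5, 2.5, 7.5),
      n_cells = rep(25L, 4),
      region = c("large-county region", "large-county region",
                 "small-county region", "small-county region"),
      stringsAsFactors = FALSE)
    part <- structure(list(spec = spec, labels = labels, counties = counties),
                      class = "county_partition")
    cc <- cell_centers(spec)
    comp <- env_stack(list(PC1 = cc$x, PC2 = cc$y), spec)
    attr(comp, "weights") <- c(0.7, 0.3)
    list(spec = spec, part = part, comp = comp, cc = cc)
  })
}

toy_record <- function(species, row, col, county, w) {
  data.frame(species_id = species, x = w$cc$x[row, col], y = w$cc$y[row, col],
             county_id = county, stringsAsFactors = FALSE)
}

test_that("record filtering applies its four steps in order and is idempotent", {
  w <- toy_world()
  raw <- rbind(
    toy_record("A", 2, 2, 1, w),          # valid
    toy_record("A", 2, 2, 1, w),          # duplicate cell -> dropped at step 2
    toy_record("A", 3, 3, 1, w),          # same county -> dropped at step 3
    toy_record("A", 8, 2, 2, w),          # valid, second county
    toy_record("A", 2, 8, 2, w),          # wrong claimed county -> step 1
    toy_record("B", 4, 4, 1, w))          # valid but below min_records
  f <- filter_records(raw, w$part, min_records = 2)
  expect_equal(nrow(f), 2)
  expect_true(all(f$species_id == "A"))
  expect_equal(sort(f$county_id), c(1, 2))
  # first-in-input-order record of county 1 won
  expect_equal(f$x[f$county_id == 1], w$cc$x[2, 2])
  # idempotent
  expect_identical(filter_records(f, w$part, min_records = 2), f)
  # min_records threshold drops species B entirely, then A too at 3
  expect_equal(nrow(filter_records(raw, w$part, min_records = 3)), 0)
  expect_equal(nrow(filter_records(raw[0, ], w$part)), 0)
})

test_that("the four-step order matters: a mismatched record cannot shield a later one", {
  w <- toy_world()
  # the mismatched record comes first in county 1; if filtering ran the
  # one-per-county step before the mismatch step it would survive instead
  raw <- rbind(
    toy_record("A", 2, 8, 1, w),          # claimed county 1, actually in 3
    toy_record("A", 2, 2, 1, w),
    toy_record("A", 8, 2, 2, w))
  f <- filter_records(raw, w$part, min_records = 1)
  expect_equal(nrow(f), 2)
  expect_equal(f$x[f$county_id == 1], w$cc$x[2, 2])
})

test_that("true-locality covariates are read at the record cells", {
  w <- toy_world()
  occ <- rbind(toy_record("A", 2, 3, 1, w), toy_record("A", 9, 2, 2, w))
  ts <- make_true_locality_dataset(occ, w$comp)
  expect_s3_class(ts, "training_set")
  expect_equal(ts$treatment, "true_locality")
  expect_equal(unname(ts$covariates[, 1]), occ$x)   # PC1 is the x coordinate
  expect_equal(unname(ts$covariates[, 2]), occ$y)
  expect_false(any(ts$records$converted))
})

test_that("centroid conversion moves every record to its county centroid", {
  w <- toy_world()
  occ <- rbind(toy_record("A", 2, 3, 1, w), toy_record("A", 9, 2, 2, w),
               toy_record("A", 3, 8, 3, w))
  ts <- make_centroid_dataset(occ, w$part, w$comp)
  expect_equal(ts$records$x, c(2.5, 2.5, 7.5))
  expect_equal(ts$records$y, c(2.5, 7.5, 2.5))
  expect_equal(unname(ts$covariates[, 1]), c(2.5, 2.5, 7.5))
  expect_true(all(ts$records$converted))
  # sample size is conserved under every treatment
  expect_equal(nrow(ts$records), nrow(occ))
  bad <- occ; bad$county_id[1] <- 99L
  expect_error(make_centroid_dataset(bad, w$part, w$comp), "absent")
})

test_that("county-average covariates equal the county mean of each component", {
  w <- toy_world()
  occ <- rbind(toy_record("A", 2, 3, 1, w), toy_record("A", 9, 2, 2, w))
  ts <- make_county_average_dataset(occ, w$part, w$comp)
  # county 1 spans columns 1..5, rows 1..5: mean x = 2.5, mean y = 2.5
  expect_equal(unname(ts$covariates[1, ]), c(2.5, 2.5))
  expect_equal(unname(ts$covariates[2, ]), c(2.5, 7.5))
  # hand example: county of cells with covariate {0, 4} averages to 2
  spec2 <- grid_spec(2, 1)
  part2 <- structure(list(spec = spec2, labels = matrix(1L, 2, 1),
                          counties = data.frame(county_id = 1L, x = 0.5, y = 1,
                                                n_cells = 2L,
                                                region = "small-county region")),
                     class = "county_partition")
  comp2 <- env_stack(list(PC1 = matrix(c(0, 4), 2, 1)), spec2)
  occ2 <- data.frame(species_id = "Z", x = 0.5, y = 0.5, county_id = 1L)
  expect_equal(unname(make_county_average_dataset(occ2, part2, comp2)$covariates[1, 1]), 2)
})

test_that("mixes convert the same floor(n/2) records in both variants", {
  w <- toy_world()
  occ <- rbind(toy_record("A", 2, 3, 1, w), toy_record("A", 9, 2, 2, w),
               toy_record("A", 3, 8, 3, w), toy_record("A", 8, 8, 4, w),
               toy_record("A", 4, 4, 1, w)[0, ])  # n = 4 base
  occ5 <- rbind(occ, toy_record("A", 4, 2, 1, w)) # will collide county 1? no:
  # records per county need not be unique for treatment construction
  mx4 <- make_mixed_datasets(occ, w$part, w$comp, seed = 7)
  expect_equal(sum(mx4$mix_centroid$records$converted), 2)   # floor(0.5*4)
  mx5 <- make_mixed_datasets(occ5, w$part, w$comp, seed = 7)
  expect_equal(sum(mx5$mix_centroid$records$converted), 2)   # floor(0.5*5)
  # identical conversion sets across the two variants
  expect_identical(mx5$mix_centroid$records$converted,
                   mx5$mix_average$records$converted)
  conv <- mx5$mix_centroid$records$converted
  # unconverted rows keep the true-locality covariates in both variants
  ts_true <- make_true_locality_dataset(occ5, w$comp)
  expect_equal(mx5$mix_centroid$covariates[!conv, ], ts_true$covariates[!conv, ])
  expect_equal(mx5$mix_average$covariates[!conv, ], ts_true$covariates[!conv, ])
  # converted rows match the full-conversion datasets
  ts_cen <- make_centroid_dataset(occ5, w$part, w$comp)
  ts_avg <- make_county_average_dataset(occ5, w$part, w$comp)
  expect_equal(mx5$mix_centroid$covariates[conv, ], ts_cen$covariates[conv, ])
  expect_equal(mx5$mix_average$covariates[conv, ], ts_avg$covariates[conv, ])
  # seeded: same seed reproduces, different seed may differ
  expect_identical(make_mixed_datasets(occ5, w$part, w$comp, seed = 7),
                   mx5)
  expect_error(make_mixed_datasets(occ5, w$part, w$comp, fraction = 0), "fraction")
})

test_that("east/west species classification is strict", {
  occ <- data.frame(
    species_id = c("e", "e", "w", "w", "straddle", "straddle"),
    x = c(8, 9, 1, 2, 1, 9), y = 1,
    county_id = 1L, stringsAsFactors = FALSE)
  sp <- split_east_west(occ, split_x = 5)
  expect_equal(sp$east, "e")
  expect_equal(sp$west, "w")
  expect_false("straddle" %in% c(sp$east, sp$west))
})

test_that("sample-size matching trims ranges then equalizes medians", {
  east <- c(a = 10L, b = 12L, c = 14L, d = 200L, e = 15L)
  west <- c(p = 11L, q = 13L, r = 16L)
  m <- match_sample_sizes(east, west, seed = 3, tol = 2)
  # the out-of-range eastern giant is dropped in the range-trim step
  expect_false("d" %in% names(m$east))
  expect_lte(abs(stats::median(m$east) - stats::median(m$west)), 2)
  # retained counts are untouched subsets of the inputs
  expect_true(all(m$east[names(m$east)] == east[names(m$east)]))
  expect_true(all(m$west[names(m$west)] == west[names(m$west)]))
  expect_identical(match_sample_sizes(east, west, seed = 3, tol = 2), m)
  # already-matched sides (equal medians, overlapping ranges) return whole
  same <- match_sample_sizes(c(x = 10L, y = 20L), c(u = 9L, v = 21L),
                             seed = 1, tol = 2)
  expect_length(same$east, 2)
  expect_length(same$west, 2)
  expect_error(match_sample_sizes(c(a = 5L), c(b = 50L), seed = 1), "overlap")
})
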