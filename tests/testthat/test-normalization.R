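test_that("the four transforms match their closed forms", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(range_transform(c(2, 4, 6), 0, 1), c(0, 0.5, 1))
  expect_equal(range_transform(c(2, 4, 6), -1, 1), c(-1, 0, 1))
  expect_equal(proportion_transform(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  # type-7 quantiles on 1..5: Q1 = 2, median = 3, Q3 = 4
  expect_equal(iqr_transform(1:5), c(-1, -0.5, 0, 0.5, 1))
})

test_that("transform post-conditions hold on random data", {
  set.seed(101)
  x <- rnorm(1000, mean = 200, sd = 40)
  z <- z_transform(x)
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(sd(z) - 1), 0.01)

  y <- range_transform(runif(100, 3, 9), lo = 0.2, hi = 0.9)
  expect_equal(min(y), 0.2)
  expect_equal(max(y), 0.9)

  p <- proportion_transform(runif(50, 1, 5))
  expect_equal(sum(p), 1)

  q <- iqr_transform(rnorm(101))
  expect_equal(median(q), 0)
  expect_equal(unname(diff(quantile(q, c(0.25, 0.75)))), 1)
})

test_that("z, range and iqr are idempotent", {
  set.seed(7)
  x <- rnorm(40, 10, 3)
  expect_equal(z_transform(z_transform(x)), z_transform(x))
  expect_equal(range_transform(range_transform(x, 0, 1), 0, 1),
               range_transform(x, 0, 1))
  expect_equal(iqr_transform(iqr_transform(x)), iqr_transform(x))
})

test_that("z and iqr are invariant under positive affine input maps", {
  set.seed(8)
  x <- rnorm(60, 50, 12)
  expect_equal(z_transform(3.2 * x + 7), z_transform(x))
  expect_equal(iqr_transform(3.2 * x + 7), iqr_transform(x))
})

test_that("negative-sum proportion reverses order with a warning", {
  expect_warning(y <- proportion_transform(c(-1, -1, -2)),
                 "reverses order")
  expect_equal(y, c(0.25, 0.25, 0.5))
})

test_that("iqr scaling resists an outlier that dominates range scaling", {
  set.seed(11)
  x <- rnorm(100, 50, 5)
  x_out <- x
  x_out[100] <- x[100] * 100
  keep <- 1:99
  d_iqr <- max(abs(iqr_transform(x_out)[keep] - iqr_transform(x)[keep]))
  d_range <- max(abs(range_transform(x_out)[keep] - range_transform(x)[keep]))
  expect_lt(d_iqr, d_range)
})

test_that("z clamping clips to [-b, b] after standardization", {
  set.seed(12)
  x <- c(rnorm(100), 50)
  z <- z_transform(x, clamp = 3)
  expect_lte(max(abs(z)), 3)
  expect_equal(z[1:100],
               pmin(pmax(z_transform(x)[1:100], -3), 3))
})

test_that("partition_groups enumerates the three scopes correctly", {
  t <- generate_study(synthetic_config(seed = 1, derive_extem = FALSE))$table
  g_attr <- partition_groups(t, "per_attribute")
  expect_length(g_attr, 3)
  expect_true(all(lengths(g_attr) == 60))
  g_tp <- partition_groups(t, "per_timepoint")
  expect_length(g_tp, 3)
  expect_true(all(lengths(g_tp) == 60))
  g_all <- partition_groups(t, "all")
  expect_length(g_all, 1)
  expect_length(g_all[[1]], 180)
})

test_that("groups partition the measurements exactly, every scope", {
  for (seed in 1:15) {
    t <- random_long_table(seed, n_patients = sample(3:8, 1),
                           n_attributes = sample(2:6, 1))
    for (scope in c("all", "per_attribute", "per_timepoint")) {
      g <- partition_groups(t, scope)
      idx <- sort(unlist(g, use.names = FALSE))
      expect_equal(idx, seq_len(nrow(t)))  # disjoint union of all rows
    }
  }
})

test_that("normalize meets its scope-wise post-conditions", {
  t <- generate_study(synthetic_config(seed = 9))$table

  nz <- normalize(t, normalization_spec("z", "per_attribute"))
  for (a in unique(nz$attribute)) {
    v <- nz$value[nz$attribute == a]
    expect_equal(mean(v), 0)
    expect_equal(sd(v), 1)
  }

  nr <- normalize(t, normalization_spec("range", "per_timepoint"))
  for (s in levels(nr$timepoint)) {
    v <- nr$value[nr$timepoint == s]
    expect_equal(range(v), c(0, 1))
  }

  np <- normalize(t, normalization_spec("proportion", "all"))
  expect_equal(sum(np$value), 1)

  # labels and row set unchanged
  expect_equal(as.data.frame(nz)[, c(1, 2, 3, 5)],
               as.data.frame(t)[, c(1, 2, 3, 5)])
})

test_that("all transforms preserve within-group ranks (monotone maps)", {
  t <- random_long_table(21, missing_rate = 0)
  t$value <- abs(t$value) + 1  # positive, so proportion is increasing
  for (m in c("z", "range", "proportion", "iqr")) {
    for (scope in c("all", "per_attribute", "per_timepoint")) {
      n <- normalize(t, normalization_spec(m, scope))
      for (g in partition_groups(t, scope)) {
        expect_equal(rank(n$value[g]), rank(t$value[g]),
                     info = paste(m, scope))
      }
    }
  }
})

test_that("degenerate groups follow the configured policy", {
  t <- long_table(data.frame(
    patient_id = rep(c("P1", "P2", "P3"), 2),
    timepoint = "S1",
    attribute = rep(c("flat", "ok"), each = 3),
    value = c(5, 5, 5, 1, 2, 3)))

  expect_warning(ns <- normalize(t, normalization_spec("z", "per_attribute")),
                 "degenerate group 'flat'")
  expect_true(all(is.na(ns$value[ns$attribute == "flat"])))
  expect_equal(ns$value[ns$attribute == "ok"], c(-1, 0, 1))

  suppressWarnings(
    nz <- normalize(t, normalization_spec("z", "per_attribute",
                                          degenerate = "zero")))
  expect_equal(nz$value[nz$attribute == "flat"], c(0, 0, 0))

  expect_error(
    normalize(t, normalization_spec("iqr", "per_attribute",
                                    degenerate = "error")),
    "degenerate group 'flat'")

  rep <- normalization_report(ns)
  expect_equal(rep$degenerate, "flat")
  expect_equal(rep$groups$ok$mean, 2)
})

test_that("spec construction rejects invalid parameters", {
  expect_error(normalization_spec("range", "all", range_lo = 1, range_hi = 0),
               "range_lo < range_hi")
  expect_error(normalization_spec("range", "all", clamp_z = 3), "z method")
  expect_error(normalization_spec("z", "all", clamp_z = -1), "must be > 0")
  expect_error(normalization_spec("median", "all"))
})

test_that("group statistics respect their ordering invariants", {
  for (seed in 1:10) {
    set.seed(seed)
    s <- group_statistics(rnorm(sample(5:50, 1)))
    expect_lte(s$min, s$q1)
    expect_lte(s$q1, s$median)
    expect_lte(s$median, s$q3)
    expect_lte(s$q3, s$max)
  }
})
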