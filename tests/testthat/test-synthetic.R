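test_that("Spearman/latent conversion matches its closed form", {
  expect_equal(spearman_to_latent(0), 0)
  expect_equal(spearman_to_latent(1), 1)
  expect_equal(spearman_to_latent(0.75), 2 * sin(0.125 * pi))
  expect_equal(spearman_to_latent(-1), -1)
  for (r in seq(-0.9, 0.9, by = 0.3)) {
    expect_equal(latent_to_spearman(spearman_to_latent(r)), r)
  }
})

test_that("attribute_spec reads a normal range as a central 95% interval", {
  a <- attribute_spec("PlatCt", 150, 450)
  expect_equal(a$mean, 300)
  expect_equal(a$sd, 300 / 3.92)
  b <- attribute_spec("x", mean = 10, sd = 2)
  expect_equal(b$sd, 2)
  expect_error(attribute_spec("x", 5, 1))
})

test_that("sample_copula is deterministic and respects the null", {
  marg <- list(attribute_spec("a", 10, 20), attribute_spec("b", 100, 200),
               attribute_spec("c", 35, 45))
  id <- diag(3)
  x1 <- sample_copula(id, marg, n = 400, seed = 7)
  x2 <- sample_copula(id, marg, n = 400, seed = 7)
  expect_identical(x1, x2)
  # independent latent: pairwise |rho| within the 3/sqrt(n) null bound
  r <- cor(apply(x1, 2, rank))
  expect_lt(max(abs(r[upper.tri(r)])), 3 / sqrt(400))
})

test_that("sample_copula converges to the target at n = 10000", {
  latent <- spearman_to_latent(matrix(c(1, .75, .75, 1), 2))
  diag(latent) <- 1
  x <- sample_copula(latent, list(attribute_spec("a", 150, 450),
                                  attribute_spec("b", 49, 71)),
                     n = 10000, seed = 5)
  expect_lt(abs(spearman_rho(x[, 1], x[, 2]) - 0.75), 0.02)
})

test_that("a non-PSD target matrix is repaired with a warning", {
  m <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3)
  expect_warning(
    x <- sample_copula(m, list(attribute_spec("a", 0, 1, lower = -Inf),
                               attribute_spec("b", 0, 1, lower = -Inf),
                               attribute_spec("c", 0, 1, lower = -Inf)),
                       n = 50, seed = 1),
    "nearest-PSD")
  expect_equal(dim(x), c(50, 3))
})

test_that("generate_study has the configured cardinality and units", {
  study <- generate_study(synthetic_config(seed = 1))
  t <- study$table
  # 20 patients x 3 timepoints x (3 drawn + 1 derived EXTEM) attributes
  expect_equal(nrow(t), 20 * 3 * 4)
  expect_equal(levels(t$timepoint), c("S1", "S2", "S3"))
  expect_equal(unique(t$unit[t$attribute == "PlatCt"]), "10^9/L")
  expect_equal(unique(t$unit[t$attribute == "MCF EXTEM"]), "mm")
  expect_equal(study$report$n_rows, 240)
})

test_that("the generated study is reproducible from its config", {
  s1 <- generate_study(synthetic_config(seed = 23, missing_rate = 0.1))
  s2 <- generate_study(synthetic_config(seed = 23, missing_rate = 0.1))
  expect_identical(as.data.frame(s1$table), as.data.frame(s2$table))
  expect_identical(s1$report$realized_spearman, s2$report$realized_spearman)
  expect_lt(nrow(s1$table), 240)
  # CSV artifact is byte-identical too
  p1 <- tempfile(); p2 <- tempfile()
  write_long_table(s1$table, p1)
  write_long_table(s2$table, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("EXTEM is the exact sum of FIBTEM and PLTEM", {
  t <- generate_study(synthetic_config(seed = 3))$table
  w <- pivot_wide(t)
  expect_identical(w[["MCF EXTEM"]], w[["MCF FIBTEM"]] + w[["MCF PLTEM"]])
})

test_that("derive_pltem recovers the generated PLTEM exactly", {
  t <- generate_study(synthetic_config(seed = 29))$table
  truth <- t[t$attribute == "MCF PLTEM", ]
  d <- derive_pltem(t[t$attribute != "MCF PLTEM", ], "MCF")
  got <- d[d$attribute == "MCF PLTEM", ]
  expect_identical(got$value, truth$value)
  expect_identical(paste(got$patient_id, got$timepoint),
                   paste(truth$patient_id, truth$timepoint))
})

test_that("an explicitly configured EXTEM conflicts with auto-derivation", {
  attrs <- c(default_attrs <- list(
    attribute_spec("PlatCt", 150, 450),
    attribute_spec("MCF FIBTEM", 9, 25),
    attribute_spec("MCF PLTEM", 35, 45)),
    list(attribute_spec("MCF EXTEM", 49, 71)))
  expect_error(synthetic_config(attributes = attrs), "conflict")
  cfg <- synthetic_config(attributes = attrs, derive_extem = FALSE)
  expect_s3_class(cfg, "synthetic_config")
})

test_that("the default study orders the two headline correlations", {
  study <- generate_study(synthetic_config(seed = 42))
  w <- pivot_wide(study$table)
  rho_extem <- spearman_rho(w$PlatCt, w[["MCF EXTEM"]])
  rho_pltem <- spearman_rho(w$PlatCt, w[["MCF PLTEM"]])
  expect_gt(rho_extem, rho_pltem)
  expect_equal(classify_strength(rho_extem), "strong")
})

test_that("inject_missing drops rows reproducibly at the requested rate", {
  t <- random_long_table(51, n_patients = 40, n_attributes = 9,
                         missing_rate = 0)  # 1080 rows
  big <- t[1:1000, ]
  class(big) <- class(t)
  expect_identical(inject_missing(big, 0, seed = 1), big)
  d1 <- inject_missing(big, 0.5, seed = 2)
  d2 <- inject_missing(big, 0.5, seed = 2)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  dropped <- nrow(big) - nrow(d1)
  expect_lt(abs(dropped - 500), 50)  # binomial 3-sigma bound ~ 47
  expect_error(inject_missing(big, 1, seed = 1), "rate")
})

test_that("solve_fibtem_target induces the requested EXTEM correlation", {
  sd_f <- attribute_spec("f", 9, 25)$sd
  sd_p <- attribute_spec("p", 35, 45)$sd
  tgt <- solve_fibtem_target(0.749, 0.067, sd_f, sd_p)
  # verify on the latent scale: corr(ref, F + P) equals the request
  r_f <- spearman_to_latent(tgt)
  r_p <- spearman_to_latent(0.067)
  r_sum <- (sd_f * r_f + sd_p * r_p) / sqrt(sd_f^2 + sd_p^2)
  expect_equal(latent_to_spearman(r_sum), 0.749)
  expect_error(solve_fibtem_target(0.999, -0.9, sd_f, sd_p),
               "unattainable")
})
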