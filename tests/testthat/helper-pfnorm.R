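# fixtures are built in code; nothing is stored on disk

tiny_table <- function() {
  long_table(data.frame(
    patient_id = rep(c("P01", "P02"), each = 6),
    timepoint = rep(rep(c("S1", "S2", "S3"), each = 2), 2),
    attribute = rep(c("PlatCt", "MCF EXTEM"), 6),
    value = c(310, 62, 180, 44, 240, 55,
              290, 60, 150, 40, 220, 52),
    unit = rep(c("10^9/L", "mm"), 6)))
}

# random valid long table, optionally with absent measurements
random_long_table <- function(seed, n_patients = 5, n_timepoints = 3,
                              n_attributes = 4, missing_rate = 0.15) {
  set.seed(seed)
  g <- expand.grid(patient_id = sprintf("P%02d", seq_len(n_patients)),
                   timepoint = paste0("S", seq_len(n_timepoints)),
                   attribute = paste0("attr", seq_len(n_attributes)),
                   stringsAsFactors = FALSE)
  g$value <- round(stats::rnorm(nrow(g), mean = 50, sd = 20), 3)
  if (missing_rate > 0) {
    g <- g[stats::runif(nrow(g)) >= missing_rate, , drop = FALSE]
  }
  long_table(g, timepoint_order = paste0("S", seq_len(n_timepoints)))
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# all permutations of 1..n, one per row (test-side enumeration,
# independent of the package's internals)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    left <- sub[, seq_len(pos - 1), drop = FALSE]
    right <- if (pos <= n - 1) sub[, pos:(n - 1), drop = FALSE]
             else sub[, 0, drop = FALSE]
    cbind(left, n, right)
  }))
}

# tie-free Spearman rho straight from the rank-difference identity;
# independent of the package's rank-Pearson route
oracle_rho_tiefree <- function(x, y) {
  n <- length(x)
  1 - 6 * sum((rank(x) - rank(y))^2) / (n * (n^2 - 1))
}
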