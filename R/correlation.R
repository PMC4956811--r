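#' Rank a value vector with average ties
#'
#' Ranks 1..n; tied values receive the average of the positions they occupy,
#' the convention under which Spearman's coefficient equals the Pearson
#' correlation of ranks.
#'
#' @param x non-empty numeric vector.
#' @export
rank_values <- function(x) {
  stopifnot(length(x) > 0)
  rank(x, ties.method = "average")
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of the average-tie ranks of `x` and `y`. Pairs with a
#' missing value on either side are removed first (pairwise deletion).
#'
#' @param x,y numeric vectors of equal length.
#' @return rho in `[-1, 1]`, or NA with a warning when fewer than 2 complete
#'   pairs remain or either rank vector is constant.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) {
    warning("fewer than 2 complete pairs: rho undefined")
    return(NA_real_)
  }
  rx <- rank_values(x); ry <- rank_values(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant ranks: rho undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

# all permutations of 1..n, one per row (n <= 8 guarded by callers)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, i] <- n
    out[rows, -i] <- sub
    r <- r + nrow(sub)
  }
  out
}

#' Two-sided p-value for a Spearman coefficient
#'
#' `"t_approx"` uses the Student-t statistic
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' `"exact_perm"` enumerates all `n!` rank permutations (the exact null for
#' tie-free data) and reports the proportion with `|rho|` at least as large
#' as observed; it is refused above `max_exact_n` because the enumeration is
#' factorial.
#'
#' @param rho observed coefficient, `|rho| <= 1`.
#' @param n number of complete pairs, `n >= 3`.
#' @param method `"t_approx"` or `"exact_perm"`.
#' @param max_exact_n largest n admitted for enumeration (default 8).
#' @export
spearman_p <- function(rho, n, method = c("t_approx", "exact_perm"),
                       max_exact_n = 8) {
  method <- match.arg(method)
  stopifnot(is.finite(rho), abs(rho) <= 1 + 1e-12, n >= 3)
  if (method == "t_approx") {
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    return(2 * stats::pt(-abs(tstat), df = n - 2))
  }
  if (n > max_exact_n) {
    stop("exact_perm refused for n = ", n, " (> max_exact_n = ",
         max_exact_n, "); use t_approx")
  }
  perms <- permutations(n)
  base <- seq_len(n)
  # tie-free rho via the sum-of-squared-rank-differences identity
  d2 <- rowSums((perms - matrix(base, nrow(perms), n, byrow = TRUE))^2)
  rho_null <- 1 - 6 * d2 / (n * (n^2 - 1))
  mean(abs(rho_null) >= abs(rho) - 1e-12)
}

#' Classify correlation strength with clinical thresholds
#'
#' Strong: `|rho| > 0.40`; moderate: `0.30 <= |rho| <= 0.40`; weak
#' otherwise. The moderate band is closed at 0.40 so the bands tile `[0, 1]`.
#'
#' @param rho coefficient(s) in `[-1, 1]`.
#' @return character vector of `"strong"`, `"moderate"`, `"weak"`.
#' @examples
#' classify_strength(c(0.741, 0.374, 0.067))
#' @export
classify_strength <- function(rho) {
  stopifnot(all(abs(rho) <= 1 + 1e-12, na.rm = TRUE))
  ifelse(is.na(rho), NA_character_,
         ifelse(abs(rho) > 0.40, "strong",
                ifelse(abs(rho) >= 0.30, "moderate", "weak")))
}

#' Spearman correlation test between two vectors
#'
#' @param x,y numeric vectors of equal length; incomplete pairs are dropped.
#' @param p_method `"t_approx"` (default) or `"exact_perm"`. The exact
#'   enumeration is only valid tie-free; with ties it falls back to the t
#'   approximation with a warning.
#' @param max_exact_n passed to [spearman_p()].
#' @return one-row data.frame: `rho`, `p_value`, `n`, `strength`.
#' @export
spearman_test <- function(x, y, p_method = c("t_approx", "exact_perm"),
                          max_exact_n = 8) {
  p_method <- match.arg(p_method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rho <- spearman_rho(x, y)
  p <- NA_real_
  if (!is.na(rho) && n >= 3) {
    if (p_method == "exact_perm" &&
        (anyDuplicated(x) || anyDuplicated(y))) {
      warning("ties present: exact permutation null is ill-defined, ",
              "falling back to t approximation")
      p_method <- "t_approx"
    }
    p <- spearman_p(rho, n, method = p_method, max_exact_n = max_exact_n)
  }
  data.frame(rho = rho, p_value = p, n = n,
             strength = classify_strength(rho), stringsAsFactors = FALSE)
}

#' Spearman correlations between target and reference attributes
#'
#' Computes one correlation per (target, reference) pair across all pooled
#' (patient, timepoint) samples, with pairwise deletion of incomplete pairs
#' — the natural choice in a small cohort, where listwise deletion would
#' discard most of the data.
#'
#' @param w a `wide_table` from [pivot_wide()] (a [long_table()] is pivoted
#'   automatically).
#' @param targets,references attribute names; every name must be a column.
#' @param p_method passed to [spearman_test()].
#' @return data.frame with one row per pair: `attribute_a` (target),
#'   `attribute_b` (reference), `rho`, `p_value`, `n`, `strength`.
#' @export
correlation_matrix <- function(w, targets, references,
                               p_method = c("t_approx", "exact_perm")) {
  p_method <- match.arg(p_method)
  if (inherits(w, "long_table")) w <- pivot_wide(w)
  stopifnot(inherits(w, "wide_table"))
  absent <- setdiff(unique(c(targets, references)), names(w))
  if (length(absent) > 0) {
    stop("attribute(s) not present: ", paste(absent, collapse = ", "))
  }
  grid <- expand.grid(attribute_a = targets, attribute_b = references,
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    spearman_test(w[[grid$attribute_a[i]]], w[[grid$attribute_b[i]]],
                  p_method = p_method)
  }))
  cbind(grid, res)
}
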