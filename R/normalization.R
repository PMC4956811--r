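#' Normalization specification
#'
#' Bundles a transform with the grouping scope over which its statistics are
#' computed. The scope is the scientifically decisive choice: statistics
#' pooled per attribute across time points preserve each attribute's rank
#' structure (and therefore Spearman correlation between attributes), while
#' statistics pooled per time point across attributes do not.
#'
#' @param method `"z"` (standardization, sample sd), `"range"` (min-max into
#'   `[range_lo, range_hi]`), `"proportion"` (divide by the group sum), or
#'   `"iqr"` (robust scaling, `(x - median) / (Q3 - Q1)`).
#' @param scope `"all"` (one group: every value), `"per_attribute"` (one
#'   group per attribute, pooling patients and time points), or
#'   `"per_timepoint"` (one group per time point, pooling patients and
#'   attributes).
#' @param range_lo,range_hi target interval for the range method
#'   (default `[0, 1]`), `range_lo < range_hi`.
#' @param clamp_z optional bound `b > 0`: z-scores are clipped to
#'   `[-b, +b]` after standardization. Off by default because clipping
#'   destroys monotonicity in the tails; `b = 3` retains ~99.9% of Gaussian
#'   data unclipped.
#' @param degenerate policy for groups whose transform is undefined
#'   (zero sd, `max == min`, zero interquartile range, zero sum, or fewer
#'   than 2 values): `"skip"` (default; group emitted as missing with a
#'   warning), `"zero"` (all outputs 0), or `"error"`.
#' @return a `normalization_spec` object.
#' @export
normalization_spec <- function(method = c("z", "range", "proportion", "iqr"),
                               scope = c("all", "per_attribute",
                                         "per_timepoint"),
                               range_lo = 0, range_hi = 1,
                               clamp_z = NULL,
                               degenerate = c("skip", "zero", "error")) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  degenerate <- match.arg(degenerate)
  if (method == "range" && !(is.numeric(range_lo) && is.numeric(range_hi) &&
                             range_lo < range_hi)) {
    stop("range method requires range_lo < range_hi")
  }
  if (!is.null(clamp_z)) {
    if (method != "z") stop("clamp_z applies to the z method only")
    if (!(is.numeric(clamp_z) && clamp_z > 0)) stop("clamp_z must be > 0")
  }
  structure(list(method = method, scope = scope,
                 range_lo = range_lo, range_hi = range_hi,
                 clamp_z = clamp_z, degenerate = degenerate),
            class = "normalization_spec")
}

#' @export
print.normalization_spec <- function(x, ...) {
  cat("<normalization_spec>", x$method, "/", x$scope)
  if (x$method == "range") cat(sprintf(" [%g, %g]", x$range_lo, x$range_hi))
  if (!is.null(x$clamp_z)) cat(sprintf(" clamp |z| <= %g", x$clamp_z))
  cat(" (degenerate:", x$degenerate, ")\n")
  invisible(x)
}

#' Partition the values of a long table by normalization scope
#'
#' @param t a [long_table()].
#' @param scope `"all"`, `"per_attribute"`, or `"per_timepoint"`.
#' @return named list of integer row-index vectors; the indices are disjoint
#'   and their union is every row of `t` (the non-missing measurements).
#' @export
partition_groups <- function(t, scope = c("all", "per_attribute",
                                          "per_timepoint")) {
  stopifnot(inherits(t, "long_table"))
  scope <- match.arg(scope)
  idx <- seq_len(nrow(t))
  switch(scope,
    all = list(all = idx),
    per_attribute = split(idx, t$attribute),
    per_timepoint = split(idx, t$timepoint, drop = TRUE))
}

degenerate_group <- function(reason) {
  structure(class = c("pfnorm_degenerate", "error", "condition"),
            list(message = reason, call = sys.call(-1)))
}

#' Z-score standardization of a value vector
#'
#' `Z = (X - u) / s` with the group mean `u` and the sample (n-1 denominator)
#' standard deviation `s`; the output has mean 0 and sd 1.
#'
#' @param x numeric vector with at least 2 values and positive sd.
#' @param clamp optional bound: clip output to `[-clamp, clamp]`.
#' @return standardized vector.
#' @export
z_transform <- function(x, clamp = NULL) {
  if (length(x) < 2) stop(degenerate_group("fewer than 2 values"))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop(degenerate_group("zero standard deviation"))
  z <- (x - mean(x)) / s
  if (!is.null(clamp)) z <- pmin(pmax(z, -clamp), clamp)
  z
}

#' Min-max scaling of a value vector into a target interval
#'
#' `y = lo + (x - min(x)) * (hi - lo) / (max(x) - min(x))`; the attained
#' extremes map exactly onto `lo` and `hi`.
#'
#' @param x numeric vector with `max(x) > min(x)`.
#' @param lo,hi target bounds, `lo < hi`.
#' @export
range_transform <- function(x, lo = 0, hi = 1) {
  stopifnot(lo < hi)
  if (length(x) < 1) stop(degenerate_group("empty group"))
  rng <- range(x)
  if (rng[1] == rng[2]) stop(degenerate_group("max equals min"))
  lo + (x - rng[1]) * (hi - lo) / (rng[2] - rng[1])
}

#' Proportion-of-total scaling of a value vector
#'
#' `y = x / sum(x)`; outputs sum to 1. With a negative group sum the map is
#' order-reversing, which is flagged with a warning because rank-based
#' statistics are then inverted.
#'
#' @param x numeric vector with non-zero sum.
#' @export
proportion_transform <- function(x) {
  s <- sum(x)
  if (s == 0) stop(degenerate_group("zero sum"))
  if (s < 0) warning("negative group sum: proportion transform reverses order")
  x / s
}

#' Robust scaling by median and interquartile range
#'
#' `y = (x - median(x)) / (Q3(x) - Q1(x))` with linear-interpolation
#' (type 7) quantiles; the output has median 0 and interquartile range 1.
#' Because only the middle 50% of the data enters the scale, the transform
#' is insensitive to outliers that dominate min-max scaling.
#'
#' @param x numeric vector with `Q3 > Q1`.
#' @export
iqr_transform <- function(x) {
  if (length(x) < 2) stop(degenerate_group("fewer than 2 values"))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (iqr == 0) stop(degenerate_group("zero interquartile range"))
  (x - q[2]) / iqr
}

#' Summary statistics of a normalization group
#'
#' @param x numeric vector.
#' @return list with `n`, `mean`, `sd`, `min`, `max`, `sum`, `q1`, `median`,
#'   `q3` (type-7 quantiles).
#' @export
group_statistics <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(x), mean = mean(x),
       sd = if (length(x) > 1) stats::sd(x) else NA_real_,
       min = min(x), max = max(x), sum = sum(x),
       q1 = q[1], median = q[2], q3 = q[3])
}

apply_transform <- function(x, spec) {
  switch(spec$method,
    z = z_transform(x, clamp = spec$clamp_z),
    range = range_transform(x, spec$range_lo, spec$range_hi),
    proportion = proportion_transform(x),
    iqr = iqr_transform(x))
}

#' Normalize a long table group-wise
#'
#' Replaces each value by the selected transform computed within its scope
#' group; patient, timepoint and attribute labels are untouched and absent
#' measurements stay absent. Degenerate groups are handled per the spec's
#' policy; under `"skip"` the group's values become NA in the output.
#'
#' @param t a [long_table()].
#' @param spec a [normalization_spec()].
#' @return the normalized `long_table` (possibly containing NA values for
#'   skipped degenerate groups). The run report — per-group
#'   [group_statistics()] plus any degenerate groups — is attached and
#'   retrievable with [normalization_report()].
#' @examples
#' t <- long_table(data.frame(
#'   patient_id = rep(c("P1", "P2", "P3"), 2), timepoint = "S1",
#'   attribute = rep(c("PlatCt", "MCF EXTEM"), each = 3),
#'   value = c(200, 300, 400, 50, 60, 70)))
#' n <- normalize(t, normalization_spec("z", "per_attribute"))
#' round(n$value, 3)
#' @export
normalize <- function(t, spec) {
  stopifnot(inherits(t, "long_table"), inherits(spec, "normalization_spec"))
  groups <- partition_groups(t, spec$scope)
  out <- t
  stats_by_group <- list()
  degenerate <- character(0)
  for (g in names(groups)) {
    idx <- groups[[g]]
    x <- t$value[idx]
    stats_by_group[[g]] <- group_statistics(x)
    y <- tryCatch(apply_transform(x, spec), pfnorm_degenerate = function(e) {
      if (spec$degenerate == "error") {
        stop("degenerate group '", g, "': ", conditionMessage(e),
             call. = FALSE)
      }
      warning("degenerate group '", g, "' (", conditionMessage(e), "): ",
              spec$degenerate, call. = FALSE)
      degenerate[[length(degenerate) + 1]] <<- g
      if (spec$degenerate == "zero") rep(0, length(x)) else
        rep(NA_real_, length(x))
    })
    out$value[idx] <- y
  }
  attr(out, "report") <- list(spec = spec, groups = stats_by_group,
                              degenerate = degenerate)
  out
}

#' Retrieve the run report attached by [normalize()]
#'
#' @param t a normalized long table.
#' @return list with elements `spec`, `groups` (per-group statistics) and
#'   `degenerate` (names of skipped/zeroed groups).
#' @export
normalization_report <- function(t) attr(t, "report")
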