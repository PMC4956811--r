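#' Fit a pooled polynomial trend for one attribute over time
#'
#' Ordinary least squares of the attribute's values against the integer time
#' index (0, 1, 2, ... in timepoint order), pooling every patient's points —
#' the construction used by dashboard trend lines drawn over all marks. With
#' exactly `degree + 1` distinct time indices the fitted curve interpolates
#' each index's pooled mean. Model degrees of freedom follow the
#' one-plus-degree convention.
#'
#' @param t a [long_table()].
#' @param attribute attribute name to fit.
#' @param degree polynomial degree, at least 1 and at most
#'   (number of distinct time indices) - 1. Default 2, the maximum a
#'   three-timepoint design supports.
#' @param per_patient if TRUE, patient means per time index are fitted
#'   instead of pooled raw points.
#' @return a `trend_fit`: `attribute`, `degree`, `coefficients` (ascending
#'   powers), `model_df = degree + 1`, `n_points`, `r_squared`,
#'   `residual_df`, plus the time grid and fitted values at the observed
#'   indices.
#' @export
fit_trend <- function(t, attribute, degree = 2, per_patient = FALSE) {
  stopifnot(inherits(t, "long_table"), degree >= 1)
  rows <- t[t$attribute == attribute, , drop = FALSE]
  if (nrow(rows) == 0) stop("attribute not present: ", attribute)
  x <- as.integer(rows$timepoint) - 1L
  y <- rows$value
  if (per_patient) {
    agg <- stats::aggregate(list(v = y),
                            list(patient = rows$patient_id, tix = x), mean)
    x <- agg$tix
    y <- agg$v
  }
  k <- length(unique(x))
  if (degree > k - 1) {
    stop("degree ", degree, " needs at least ", degree + 1,
         " distinct time points; ", k, " present (maximum admissible ",
         "degree ", k - 1, ")")
  }
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  fitted_vals <- drop(X %*% coefs)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted_vals)^2)
  r2 <- if (sst == 0) 0 else max(0, min(1, 1 - sse / sst))
  structure(list(attribute = attribute, degree = degree,
                 coefficients = unname(coefs),
                 model_df = degree + 1L, n_points = length(y),
                 r_squared = r2,
                 residual_df = length(y) - (degree + 1L),
                 time_index = x, fitted = fitted_vals,
                 max_index = max(x)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit>", x$attribute, "- degree", x$degree,
      "(model df", paste0(x$model_df, ","), "n", paste0(x$n_points, ")\n"))
  cat("  coefficients (ascending powers):",
      paste(signif(x$coefficients, 5), collapse = ", "), "\n")
  cat("  R-squared:", signif(x$r_squared, 4), "\n")
  invisible(x)
}

#' Evaluate a fitted trend on a grid of time indices
#'
#' @param f a `trend_fit` from [fit_trend()].
#' @param grid numeric vector of time indices; must lie within
#'   `[0, max index]` unless `extrapolate = TRUE`.
#' @param extrapolate allow evaluation outside the fitted range.
#' @export
evaluate_trend <- function(f, grid, extrapolate = FALSE) {
  stopifnot(inherits(f, "trend_fit"))
  if (!extrapolate && (any(grid < 0) || any(grid > f$max_index))) {
    stop("grid outside fitted range [0, ", f$max_index,
         "]; set extrapolate = TRUE to allow")
  }
  drop(outer(grid, 0:f$degree, `^`) %*% f$coefficients)
}

#' Fit trends for several attributes and tabulate them
#'
#' @param t a [long_table()].
#' @param attributes attribute names (default: all present).
#' @param degree passed to [fit_trend()].
#' @return data.frame, one row per attribute: degree, model and residual df,
#'   n, R-squared, and coefficient columns `c0..c<degree>`.
#' @export
trend_table <- function(t, attributes = NULL, degree = 2) {
  if (is.null(attributes)) attributes <- sort(unique(t$attribute))
  rows <- lapply(attributes, function(a) {
    f <- fit_trend(t, a, degree = degree)
    cf <- setNames(as.list(f$coefficients), paste0("c", 0:degree))
    cbind(data.frame(attribute = a, degree = degree,
                     model_df = f$model_df, residual_df = f$residual_df,
                     n_points = f$n_points, r_squared = f$r_squared,
                     stringsAsFactors = FALSE),
          as.data.frame(cf))
  })
  do.call(rbind, rows)
}
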