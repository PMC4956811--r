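#' Marginal specification for one synthetic attribute
#'
#' Marginals are truncated normal (truncation at physiologic zero). A
#' clinical normal range `[lo, hi]` is read as the central 95% interval:
#' mean at the midpoint, sd = (hi - lo) / 3.92. Mean and sd may instead be
#' given directly.
#'
#' @param name attribute name, e.g. `"PlatCt"` or `"MCF FIBTEM"`.
#' @param lo,hi normal-range bounds (used when mean/sd not given).
#' @param mean,sd explicit marginal moments (override lo/hi).
#' @param unit reporting unit string.
#' @param lower truncation bound (default 0; counts and clot amplitudes
#'   cannot be negative).
#' @export
attribute_spec <- function(name, lo = NULL, hi = NULL, mean = NULL,
                           sd = NULL, unit = "", lower = 0) {
  if (is.null(mean) || is.null(sd)) {
    stopifnot(!is.null(lo), !is.null(hi), lo < hi)
    mean <- (lo + hi) / 2
    sd <- (hi - lo) / 3.92
  }
  stopifnot(sd > 0)
  structure(list(name = name, mean = mean, sd = sd, unit = unit,
                 lower = lower),
            class = "attribute_spec")
}

#' Convert a target Spearman correlation to the latent Gaussian correlation
#'
#' Gaussian-copula samples with latent Pearson correlation
#' `r = 2 * sin(pi * rho_s / 6)` attain Spearman correlation `rho_s` in
#' expectation, for any continuous marginals.
#'
#' @param rho_s target Spearman correlation(s), `|rho_s| <= 1`.
#' @export
spearman_to_latent <- function(rho_s) {
  stopifnot(all(abs(rho_s) <= 1))
  2 * sin(pi * rho_s / 6)
}

#' Inverse conversion: latent Gaussian correlation to Spearman
#'
#' @param r latent Pearson correlation(s), `|r| <= 1`.
#' @export
latent_to_spearman <- function(r) {
  stopifnot(all(abs(r) <= 1))
  6 / pi * asin(r / 2)
}

#' FIBTEM correlation target inducing a desired EXTEM correlation
#'
#' The generator draws FIBTEM and PLTEM and emits EXTEM = FIBTEM + PLTEM, so
#' the correlation between a reference attribute (platelet count) and EXTEM
#' cannot be set directly. On the latent Gaussian scale the sum's
#' correlation with the reference is
#' `(sd_f * r_f + sd_p * r_p) / sqrt(sd_f^2 + sd_p^2 + 2 sd_f sd_p r_fp)`;
#' solving for `r_f` gives the FIBTEM target that induces the requested
#' EXTEM target (exact on the latent scale, approximate after the
#' near-affine truncated-normal marginals).
#'
#' @param target_extem desired Spearman between the reference and EXTEM.
#' @param target_pltem configured Spearman between the reference and PLTEM.
#' @param sd_f,sd_p marginal sds of FIBTEM and PLTEM.
#' @param rho_fp Spearman between FIBTEM and PLTEM (default 0).
#' @return the Spearman target for (reference, FIBTEM).
#' @export
solve_fibtem_target <- function(target_extem, target_pltem, sd_f, sd_p,
                                rho_fp = 0) {
  r_e <- spearman_to_latent(target_extem)
  r_p <- spearman_to_latent(target_pltem)
  r_fp <- spearman_to_latent(rho_fp)
  sd_sum <- sqrt(sd_f^2 + sd_p^2 + 2 * sd_f * sd_p * r_fp)
  r_f <- (r_e * sd_sum - sd_p * r_p) / sd_f
  if (abs(r_f) > 1) {
    stop("requested EXTEM correlation ", target_extem,
         " is unattainable with these marginal sds")
  }
  latent_to_spearman(r_f)
}

default_attributes <- function() {
  list(attribute_spec("PlatCt", 150, 450, unit = "10^9/L"),
       attribute_spec("MCF FIBTEM", 9, 25, unit = "mm"),
       attribute_spec("MCF PLTEM", 35, 45, unit = "mm"))
}

default_spearman_targets <- function(attributes) {
  sds <- setNames(vapply(attributes, `[[`, 0, "sd"),
                  vapply(attributes, `[[`, "", "name"))
  data.frame(
    a = c("PlatCt", "PlatCt"),
    b = c("MCF PLTEM", "MCF FIBTEM"),
    rho = c(0.067,
            solve_fibtem_target(0.749, 0.067,
                                sds[["MCF FIBTEM"]], sds[["MCF PLTEM"]])),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic perioperative study
#'
#' Defaults emulate the 20-patient cardiac-surgery cohort: 3 sampling
#' moments (S1 baseline, S2 after weaning from bypass, S3 at 24 h), platelet
#' count with normal range 150-450 x10^9/L, ROTEM MCF FIBTEM 9-25 mm and MCF
#' PLTEM 35-45 mm (EXTEM = FIBTEM + PLTEM then falls in the 49-71 mm normal
#' range), a strong platelet-count/EXTEM and weak platelet-count/PLTEM rank
#' correlation (targets 0.749 and 0.067), and a multiplicative time profile
#' 1.0, 0.6, 0.8 on the marginal means — the post-bypass dip with partial
#' recovery at 24 h.
#'
#' @param n_patients number of patients (default 20).
#' @param timepoints ordered sampling-moment labels.
#' @param attributes list of [attribute_spec()]s to draw from the copula.
#' @param spearman_targets data.frame `(a, b, rho)` of pairwise Spearman
#'   targets; unspecified pairs default to 0.
#' @param time_effect multiplicative profile on the marginal mean per
#'   timepoint: either one numeric vector (length = #timepoints, applied to
#'   every attribute) or a named list of such vectors per attribute.
#'   The default (for a 3-timepoint design) encodes the qualitative
#'   perioperative course: platelet count and unrecognized attributes dip to
#'   60% after bypass with partial recovery (1.0, 0.6, 0.8); FIBTEM dips
#'   with hemodilution and overshoots at 24 h with the acute-phase
#'   fibrinogen response (1.0, 0.8, 1.1); PLTEM is flat (1.0, 1.0, 1.0),
#'   keeping its pooled correlation with platelet count at the configured
#'   weak target.
#' @param missing_rate probability in `[0, 1)` that a measurement is
#'   dropped.
#' @param round_digits values are rounded to this many digits (default 0 —
#'   whole-unit clinical reporting resolution; it also makes the
#'   EXTEM = FIBTEM + PLTEM identity exact in floating point).
#' @param derive_extem emit `"X EXTEM" = "X FIBTEM" + "X PLTEM"` for every
#'   parameter family X with both operands configured.
#' @param seed RNG seed; the whole study is reproducible from the config.
#' @export
synthetic_config <- function(n_patients = 20,
                             timepoints = c("S1", "S2", "S3"),
                             attributes = default_attributes(),
                             spearman_targets = NULL,
                             time_effect = NULL,
                             missing_rate = 0,
                             round_digits = 0,
                             derive_extem = TRUE,
                             seed = 1L) {
  stopifnot(n_patients >= 1, length(timepoints) >= 1,
            missing_rate >= 0, missing_rate < 1)
  names(attributes) <- vapply(attributes, `[[`, "", "name")
  if (is.null(spearman_targets)) {
    spearman_targets <- if (all(c("PlatCt", "MCF FIBTEM", "MCF PLTEM") %in%
                                names(attributes))) {
      default_spearman_targets(attributes)
    } else {
      data.frame(a = character(), b = character(), rho = numeric())
    }
  }
  if (is.null(time_effect)) {
    time_effect <- lapply(names(attributes), function(a) {
      if (length(timepoints) != 3) return(rep(1, length(timepoints)))
      if (grepl(" PLTEM$", a)) c(1.0, 1.0, 1.0)
      else if (grepl(" FIBTEM$", a)) c(1.0, 0.8, 1.1)
      else c(1.0, 0.6, 0.8)
    })
    names(time_effect) <- names(attributes)
  }
  if (is.numeric(time_effect)) {
    stopifnot(length(time_effect) == length(timepoints))
    time_effect <- setNames(rep(list(time_effect), length(attributes)),
                            names(attributes))
  }
  stopifnot(all(names(attributes) %in% names(time_effect)),
            all(lengths(time_effect[names(attributes)]) ==
                  length(timepoints)))
  if (derive_extem) {
    fams <- pltem_families(names(attributes))
    clash <- paste(fams, "EXTEM")
    clash <- clash[clash %in% names(attributes)]
    if (length(clash) > 0) {
      stop("attribute(s) ", paste(clash, collapse = ", "),
           " conflict with EXTEM auto-derivation; drop them or set ",
           "derive_extem = FALSE")
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 timepoints = timepoints, attributes = attributes,
                 spearman_targets = spearman_targets,
                 time_effect = time_effect,
                 missing_rate = missing_rate,
                 round_digits = round_digits,
                 derive_extem = derive_extem, seed = as.integer(seed)),
            class = "synthetic_config")
}

# parameter families X with both "X FIBTEM" and "X PLTEM" configured
pltem_families <- function(attr_names) {
  fib <- sub(" FIBTEM$", "", grep(" FIBTEM$", attr_names, value = TRUE))
  plt <- sub(" PLTEM$", "", grep(" PLTEM$", attr_names, value = TRUE))
  intersect(fib, plt)
}

# complete a pairwise target data.frame into a full Spearman matrix
target_matrix <- function(targets, attr_names) {
  k <- length(attr_names)
  m <- diag(k)
  dimnames(m) <- list(attr_names, attr_names)
  for (i in seq_len(nrow(targets))) {
    a <- targets$a[i]; b <- targets$b[i]
    if (!a %in% attr_names || !b %in% attr_names) {
      stop("spearman target names unknown attribute: ", a, " / ", b)
    }
    m[a, b] <- m[b, a] <- targets$rho[i]
  }
  m
}

# nearest positive semi-definite repair: clip eigenvalues, rescale diagonal
nearest_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(m)
  warning("latent correlation matrix is not positive semi-definite; ",
          "applying nearest-PSD repair")
  v <- pmax(e$values, 1e-10)
  r <- e$vectors %*% diag(v, length(v)) %*% t(e$vectors)
  d <- 1 / sqrt(diag(r))
  r <- r * outer(d, d)
  (r + t(r)) / 2
}

# square-root factor L with L %*% t(L) = m, tolerant of semi-definiteness
psd_factor <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("latent matrix not PSD after repair")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m))
}

# correlated uniform scores from the current RNG stream
copula_uniforms <- function(latent, n) {
  k <- nrow(latent)
  z <- matrix(stats::rnorm(n * k), n, k) %*% t(psd_factor(latent))
  stats::pnorm(z)
}

# truncated-normal quantile function (truncation from below)
qtrunc_normal <- function(p, mean, sd, lower = 0) {
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + p * (1 - plo), mean, sd)
}

#' Draw correlated samples through a Gaussian copula
#'
#' Latent multivariate-normal scores are converted to uniforms and pushed
#' through each attribute's truncated-normal quantile function, imposing the
#' latent rank-correlation structure on arbitrary marginals.
#'
#' @param latent symmetric PSD latent correlation matrix (use
#'   [spearman_to_latent()] on Spearman targets).
#' @param marginals list of [attribute_spec()]s, one per latent column.
#' @param n number of samples.
#' @param seed RNG seed; identical seeds give identical matrices.
#' @return `n x length(marginals)` matrix, columns named by attribute.
#' @export
sample_copula <- function(latent, marginals, n, seed) {
  stopifnot(nrow(latent) == length(marginals), n >= 1)
  latent <- nearest_psd((latent + t(latent)) / 2)
  set.seed(seed)
  u <- copula_uniforms(latent, n)
  x <- vapply(seq_along(marginals), function(j) {
    m <- marginals[[j]]
    qtrunc_normal(u[, j], m$mean, m$sd, m$lower)
  }, numeric(n))
  if (n == 1) x <- matrix(x, 1)
  colnames(x) <- vapply(marginals, `[[`, "", "name")
  x
}

#' Generate a synthetic perioperative study
#'
#' Draws one copula sample per (patient, timepoint), applies the
#' multiplicative time profile to each attribute's marginal mean (the copula
#' — hence the within-timepoint rank structure — is untouched), rounds to
#' the configured reporting resolution, and emits EXTEM = FIBTEM + PLTEM for
#' each configured parameter family so that [derive_pltem()] recovers the
#' generated PLTEM values exactly.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `table` (a [long_table()]) and `report` (realized
#'   per-attribute means/sds, realized pooled pairwise Spearman matrix, the
#'   applied time profile, and the seed).
#' @examples
#' study <- generate_study(synthetic_config(seed = 7))
#' nrow(study$table)  # 20 patients x 3 timepoints x 4 attributes
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  attrs <- cfg$attributes
  k <- length(attrs)
  tps <- cfg$timepoints
  n <- cfg$n_patients * length(tps)
  latent <- nearest_psd(spearman_to_latent(
    target_matrix(cfg$spearman_targets, names(attrs))))
  diag(latent) <- 1
  set.seed(cfg$seed)
  u <- copula_uniforms(latent, n)
  patient <- rep(sprintf("P%02d", seq_len(cfg$n_patients)),
                 times = length(tps))
  tp <- rep(tps, each = cfg$n_patients)
  values <- matrix(NA_real_, n, k, dimnames = list(NULL, names(attrs)))
  for (j in seq_len(k)) {
    m <- attrs[[j]]
    eff <- cfg$time_effect[[m$name]][match(tp, tps)]
    values[, j] <- round(qtrunc_normal(u[, j], m$mean * eff, m$sd, m$lower),
                         cfg$round_digits)
  }
  units <- setNames(vapply(attrs, `[[`, "", "unit"), names(attrs))
  if (cfg$derive_extem) {
    for (fam in pltem_families(names(attrs))) {
      ext <- values[, paste(fam, "FIBTEM")] + values[, paste(fam, "PLTEM")]
      values <- cbind(values, ext)
      colnames(values)[ncol(values)] <- paste(fam, "EXTEM")
      units[paste(fam, "EXTEM")] <- units[[paste(fam, "FIBTEM")]]
    }
  }
  long <- do.call(rbind, lapply(colnames(values), function(a) {
    data.frame(patient_id = patient, timepoint = tp, attribute = a,
               value = values[, a], unit = units[[a]],
               stringsAsFactors = FALSE)
  }))
  tab <- long_table(long, timepoint_order = tps)
  if (cfg$missing_rate > 0) {
    tab <- inject_missing(tab, cfg$missing_rate,
                          seed = (cfg$seed + 1L) %% .Machine$integer.max)
  }
  realized_rho <- stats::cor(apply(values, 2, rank), method = "pearson")
  report <- list(
    seed = cfg$seed,
    n_rows = nrow(tab),
    attribute_means = colMeans(values),
    attribute_sds = apply(values, 2, stats::sd),
    realized_spearman = realized_rho,
    time_effect = cfg$time_effect,
    generated_values = values,
    patient = patient, timepoint = tp)
  list(table = tab, report = report)
}

#' Randomly drop measurements from a long table
#'
#' Each row is dropped independently with probability `rate`; the surviving
#' row set is deterministic under the seed.
#'
#' @param t a [long_table()].
#' @param rate drop probability in `[0, 1)`.
#' @param seed RNG seed.
#' @export
inject_missing <- function(t, rate, seed) {
  stopifnot(inherits(t, "long_table"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(t)
  set.seed(seed)
  keep <- stats::runif(nrow(t)) >= rate
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
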