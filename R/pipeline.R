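#' Configuration of a full pipeline run
#'
#' @param out_dir directory for artifacts (created if needed).
#' @param input path to a long-format CSV, or NULL to simulate a demo study
#'   with [generate_study()].
#' @param seed seed for the demo simulation and any other randomness.
#' @param methods normalization methods to run (default all four).
#' @param scopes grouping scopes to run (default all three).
#' @param targets,references attribute pairs for the correlation stage;
#'   defaults match the demo study (assays versus platelet count).
#' @param trend_degree polynomial degree for the trend stage.
#' @param plots render faceted comparison figures (SVG; requires cairo).
#' @param synthetic a [synthetic_config()] for the demo simulation; its seed
#'   is overridden by `seed`.
#' @param timepoint_order optional timepoint order for reading `input`.
#' @return a `run_config` object.
#' @export
run_config <- function(out_dir, input = NULL, seed = 42L,
                       methods = c("iqr", "range", "proportion", "z"),
                       scopes = c("per_attribute", "per_timepoint", "all"),
                       targets = NULL, references = "PlatCt",
                       trend_degree = 2, plots = TRUE,
                       synthetic = NULL, timepoint_order = NULL) {
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, input = input, seed = as.integer(seed),
                 methods = methods, scopes = scopes, targets = targets,
                 references = references, trend_degree = trend_degree,
                 plots = plots, synthetic = synthetic,
                 timepoint_order = timepoint_order),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys: `input`, `out_dir`, `seed`, `methods`, `scopes`,
#' `targets`, `references`, `trend_degree`, `plots`, `timepoint_order`, and
#' a `synthetic` block (`n_patients`, `timepoints`, `missing_rate`,
#' `round_digits`).
#'
#' @param path YAML file.
#' @param out_dir override for the output directory.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    syn_args <- y$synthetic[intersect(names(y$synthetic),
                                      c("n_patients", "timepoints",
                                        "missing_rate", "round_digits"))]
    syn <- do.call(synthetic_config, syn_args)
  }
  args <- y[intersect(names(y), c("input", "seed", "methods", "scopes",
                                  "targets", "references", "trend_degree",
                                  "plots", "timepoint_order"))]
  args$out_dir <- out_dir %||% y$out_dir %||% "."
  args$synthetic <- syn
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scope_slug <- function(scope) gsub("_", "-", scope)

#' Run the full normalization pipeline
#'
#' Stages: simulate (or read) the study table; run every requested
#' normalization method under every requested scope; correlate target
#' attributes against the references on the raw values; fit pooled
#' polynomial trends; render one faceted comparison figure per scope
#' (panels A interquartile range, B range, C proportion, D z, matching the
#' conventional method order) plus an unnormalized figure. All tables are
#' CSV, reports JSON; a manifest records the configuration, seed and package
#' version so a rerun reproduces the artifacts byte-identically.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the study `table`, the `artifacts` paths,
#'   and the correlation and trend data.frames.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(name) {
    path <- file.path(cfg$out_dir, name)
    artifacts[[length(artifacts) + 1]] <<- path
    path
  }

  if (is.null(cfg$input)) {
    study <- generate_study(cfg$synthetic)
    t <- study$table
    write_long_table(t, emit("study.csv"))
    rep <- study$report
    jsonlite::write_json(
      list(seed = rep$seed, n_rows = rep$n_rows,
           attribute_means = as.list(rep$attribute_means),
           attribute_sds = as.list(rep$attribute_sds),
           realized_spearman = rep$realized_spearman),
      emit("generator_report.json"), auto_unbox = TRUE, digits = NA)
  } else {
    t <- read_long_table(cfg$input, timepoint_order = cfg$timepoint_order)
  }

  normalized <- list()
  for (scope in cfg$scopes) {
    for (method in cfg$methods) {
      spec <- normalization_spec(method, scope)
      nt <- withCallingHandlers(normalize(t, spec),
                                warning = function(w) {
                                  message("[", method, "/", scope, "] ",
                                          conditionMessage(w))
                                  invokeRestart("muffleWarning")
                                })
      normalized[[paste(method, scope)]] <- nt
      slug <- paste0("normalized_", method, "_", scope_slug(scope))
      write_long_table(nt, emit(paste0(slug, ".csv")))
      rep <- normalization_report(nt)
      jsonlite::write_json(
        list(method = method, scope = scope, groups = rep$groups,
             degenerate = rep$degenerate),
        emit(paste0(slug, "_report.json")), auto_unbox = TRUE, digits = NA)
    }
  }

  targets <- cfg$targets %||%
    setdiff(sort(unique(t$attribute)), cfg$references)
  correlations <- correlation_matrix(t, targets, cfg$references)
  utils::write.csv(correlations, emit("correlations.csv"), row.names = FALSE)

  trends <- trend_table(t, degree = cfg$trend_degree)
  utils::write.csv(trends, emit("trends.csv"), row.names = FALSE)

  if (isTRUE(cfg$plots) && capabilities("cairo")) {
    plot_study(t, NULL, file.path(cfg$out_dir, "fig_no_normalization.svg"),
               degree = cfg$trend_degree)
    for (scope in cfg$scopes) {
      plot_normalization_grid(
        t, scope, methods = cfg$methods, degree = cfg$trend_degree,
        path = file.path(cfg$out_dir,
                         paste0("fig_scope_", scope_slug(scope), ".svg")))
    }
  }

  jsonlite::write_json(
    list(package = "pfnorm",
         version = as.character(utils::packageVersion("pfnorm")),
         seed = cfg$seed, input = cfg$input %||% "simulated",
         methods = cfg$methods, scopes = cfg$scopes,
         references = cfg$references, trend_degree = cfg$trend_degree,
         artifacts = basename(unlist(artifacts))),
    emit("manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(table = t, normalized = normalized,
                 correlations = correlations, trends = trends,
                 artifacts = unlist(artifacts)))
}

method_panel_labels <- c(iqr = "A InterQ", range = "B range",
                         proportion = "C prop", z = "D Z")

#' Faceted comparison figure for one normalization scope
#'
#' One panel per method (A interquartile range, B range, C proportion, D z):
#' patient-level points over the ordered time index with a pooled polynomial
#' trend line per attribute.
#'
#' @param t the raw [long_table()].
#' @param scope grouping scope to display.
#' @param methods methods to facet.
#' @param degree trend polynomial degree.
#' @param path output SVG path.
#' @export
plot_normalization_grid <- function(t, scope,
                                    methods = c("iqr", "range",
                                                "proportion", "z"),
                                    degree = 2, path) {
  pieces <- lapply(methods, function(m) {
    nt <- suppressWarnings(normalize(t, normalization_spec(m, scope)))
    data.frame(panel = method_panel_labels[[m]],
               time_index = as.integer(nt$timepoint) - 1L,
               attribute = nt$attribute, value = nt$value,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  df <- df[!is.na(df$value), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time_index, y = value,
                                        colour = attribute)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::stat_smooth(method = "lm",
                         formula = y ~ poly(x, degree, raw = TRUE),
                         se = FALSE, linewidth = 0.9) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = seq_len(nlevels(t$timepoint)) - 1,
                                labels = levels(t$timepoint)) +
    ggplot2::labs(x = "time point", y = "normalized value",
                  title = paste("normalization scope:", scope)) +
    ggplot2::theme_minimal()
  grDevices::svg(path, width = 10, height = 7)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Line/trend figure of the raw study values
#'
#' @param t a [long_table()].
#' @param attributes attributes to show (default all).
#' @param path output SVG path.
#' @param degree trend polynomial degree.
#' @export
plot_study <- function(t, attributes = NULL, path, degree = 2) {
  if (!is.null(attributes)) t <- t[t$attribute %in% attributes, ]
  df <- data.frame(time_index = as.integer(t$timepoint) - 1L,
                   attribute = t$attribute, value = t$value)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time_index, y = value,
                                        colour = attribute)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::stat_smooth(method = "lm",
                         formula = y ~ poly(x, degree, raw = TRUE),
                         se = FALSE, linewidth = 0.9) +
    ggplot2::scale_x_continuous(breaks = seq_len(nlevels(t$timepoint)) - 1,
                                labels = levels(t$timepoint)) +
    ggplot2::labs(x = "time point", y = "value",
                  title = "no normalization") +
    ggplot2::theme_minimal()
  grDevices::svg(path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}
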