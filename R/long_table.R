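#' Tidy long-format container for assay measurements
#'
#' The canonical record set: one row per (patient, timepoint, attribute)
#' measurement. Missing measurements are absent rows, never sentinel values,
#' so group statistics computed downstream are never contaminated. Timepoints
#' are an ordered factor; the default study axis is S1 (baseline, before
#' incision) < S2 (after weaning from cardiopulmonary bypass) < S3 (24 h
#' postoperative).
#'
#' @param x data.frame with columns `patient_id`, `timepoint`, `attribute`,
#'   `value` and optionally `unit`.
#' @param timepoint_order character vector giving the total order of
#'   timepoint levels. Default: S1 < S2 < S3 when exactly those labels are
#'   present, otherwise order of first appearance.
#' @return A `long_table`: a data.frame sorted by (patient, timepoint,
#'   attribute) with `timepoint` an ordered factor.
#' @examples
#' t <- long_table(data.frame(
#'   patient_id = "P01", timepoint = c("S1", "S2"),
#'   attribute = "PlatCt", value = c(310, 180)))
#' levels(t$timepoint)
#' @export
long_table <- function(x, timepoint_order = NULL) {
  required <- c("patient_id", "timepoint", "attribute", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"unit" %in% names(x)) x$unit <- NA_character_
  x <- x[, c("patient_id", "timepoint", "attribute", "value", "unit")]
  x$patient_id <- as.character(x$patient_id)
  x$attribute <- as.character(x$attribute)
  if (!is.numeric(x$value)) {
    bad <- suppressWarnings(is.na(as.numeric(as.character(x$value))) &
                              !is.na(x$value))
    if (any(bad)) {
      stop("non-numeric value(s) in rows: ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    }
    x$value <- suppressWarnings(as.numeric(as.character(x$value)))
  }
  if (anyNA(x$value)) {
    stop("NA values are not allowed; missing measurements are absent rows ",
         "(offending rows: ",
         paste(utils::head(which(is.na(x$value)), 5), collapse = ", "), ")")
  }
  tp <- as.character(x$timepoint)
  if (is.null(timepoint_order)) {
    timepoint_order <- if (setequal(unique(tp), c("S1", "S2", "S3"))) {
      c("S1", "S2", "S3")
    } else {
      unique(tp)
    }
  }
  unknown <- setdiff(unique(tp), timepoint_order)
  if (length(unknown) > 0) {
    stop("timepoint label(s) not in timepoint_order: ",
         paste(unknown, collapse = ", "))
  }
  x$timepoint <- factor(tp, levels = timepoint_order, ordered = TRUE)
  key <- paste(x$patient_id, tp, x$attribute, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (patient, timepoint, attribute) triple(s): ",
         paste(utils::head(gsub("\r", ", ", dups), 5), collapse = "; "))
  }
  x <- x[order(x$patient_id, x$timepoint, x$attribute), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("long_table", "data.frame")
  x
}

#' Read a long-format measurement table from delimited text
#'
#' @param source path to a delimited text file with a header row.
#' @param timepoint_order optional explicit order of timepoint levels.
#' @param col_map named list mapping canonical names (`patient_id`,
#'   `timepoint`, `attribute`, `value`, `unit`) to the file's column names.
#' @param delim field delimiter, default comma.
#' @return a validated [long_table()].
#' @export
read_long_table <- function(source, timepoint_order = NULL,
                            col_map = list(), delim = ",") {
  defaults <- list(patient_id = "patient", timepoint = "timepoint",
                   attribute = "attribute", value = "value", unit = "unit")
  # canonical column names in the file win over the legacy default "patient"
  map <- utils::modifyList(defaults, as.list(col_map))
  raw <- utils::read.csv(source, sep = delim, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!map$patient_id %in% names(raw) && "patient_id" %in% names(raw) &&
      !"patient_id" %in% unlist(col_map)) {
    map$patient_id <- "patient_id"
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in c("patient_id", "timepoint", "attribute", "value")) {
    src <- map[[canon]]
    if (!src %in% names(raw)) {
      stop("input is missing required column '", src, "' (mapped to ",
           canon, ")")
    }
    out[[canon]] <- raw[[src]]
  }
  if (map$unit %in% names(raw)) out$unit <- raw[[map$unit]]
  long_table(out, timepoint_order = timepoint_order)
}

#' Write a long table as CSV
#'
#' @param t a [long_table()].
#' @param path output file path.
#' @export
write_long_table <- function(t, path) {
  stopifnot(inherits(t, "long_table"))
  out <- as.data.frame(t)
  out$timepoint <- as.character(out$timepoint)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pivot a long table to one row per (patient, timepoint)
#'
#' @param t a [long_table()].
#' @return a `wide_table` data.frame: columns `patient_id`, `timepoint`,
#'   then one column per attribute; absent measurements become NA cells.
#' @export
pivot_wide <- function(t) {
  stopifnot(inherits(t, "long_table"))
  attrs <- sort(unique(t$attribute))
  keys <- unique(t[, c("patient_id", "timepoint")])
  keys <- keys[order(keys$patient_id, keys$timepoint), , drop = FALSE]
  rownames(keys) <- NULL
  wide <- keys
  rowkey <- paste(t$patient_id, as.character(t$timepoint), sep = "\r")
  widekey <- paste(keys$patient_id, as.character(keys$timepoint), sep = "\r")
  for (a in attrs) {
    sel <- t$attribute == a
    col <- rep(NA_real_, nrow(keys))
    col[match(rowkey[sel], widekey)] <- t$value[sel]
    wide[[a]] <- col
  }
  attr(wide, "timepoint_levels") <- levels(t$timepoint)
  attr(wide, "units") <- attribute_units(t)
  class(wide) <- c("wide_table", "data.frame")
  wide
}

#' Pivot a wide table back to long format
#'
#' NA cells are dropped, so `pivot_long(pivot_wide(t))` reproduces `t`
#' exactly (missing measurements stay absent rows).
#'
#' @param w a `wide_table` from [pivot_wide()].
#' @return a [long_table()].
#' @export
pivot_long <- function(w) {
  stopifnot(inherits(w, "wide_table"))
  attrs <- setdiff(names(w), c("patient_id", "timepoint"))
  units <- attr(w, "units")
  pieces <- lapply(attrs, function(a) {
    keep <- !is.na(w[[a]])
    data.frame(patient_id = w$patient_id[keep],
               timepoint = as.character(w$timepoint[keep]),
               attribute = a, value = w[[a]][keep],
               unit = if (!is.null(units) && a %in% names(units))
                 units[[a]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  long_table(do.call(rbind, pieces),
             timepoint_order = attr(w, "timepoint_levels"))
}

# per-attribute unit lookup (first non-missing unit wins)
attribute_units <- function(t) {
  has <- !is.na(t$unit) & nzchar(t$unit)
  if (!any(has)) return(NULL)
  u <- t[has, c("attribute", "unit")]
  u <- u[!duplicated(u$attribute), ]
  setNames(u$unit, u$attribute)
}

#' Derive the PLTEM platelet-contribution parameter
#'
#' PLTEM isolates the platelet contribution to clot firmness by subtracting
#' the fibrinogen-only channel from the tissue-factor channel:
#' `X PLTEM = X EXTEM - X FIBTEM` for each requested ROTEM parameter family
#' X. A PLTEM row is emitted only where both operands are measured; pairs
#' with a missing operand are skipped (and counted in the
#' `"skipped_pairs"` attribute of the result).
#'
#' @param t a [long_table()] containing `"X EXTEM"` / `"X FIBTEM"`
#'   attributes.
#' @param parameters ROTEM parameter families to derive. The default covers
#'   the amplitude and kinetics families for which a platelet contribution
#'   is clinically interpretable; clotting times and lysis are excluded.
#' @param overwrite if FALSE (default), an already-present `"X PLTEM"`
#'   attribute is an error; if TRUE its rows are replaced.
#' @return the input table with `"X PLTEM"` rows appended; existing rows are
#'   never mutated.
#' @examples
#' t <- long_table(data.frame(
#'   patient_id = "P01", timepoint = "S1",
#'   attribute = c("MCF EXTEM", "MCF FIBTEM"), value = c(60, 15)))
#' derive_pltem(t, "MCF")$value
#' @export
derive_pltem <- function(t, parameters = c("A5", "A10", "A20", "Alpha",
                                           "MCF"),
                         overwrite = FALSE) {
  stopifnot(inherits(t, "long_table"))
  out <- as.data.frame(t)
  out$timepoint <- as.character(out$timepoint)
  new_rows <- list()
  skipped <- 0L
  for (p in parameters) {
    a_ext <- paste(p, "EXTEM")
    a_fib <- paste(p, "FIBTEM")
    a_plt <- paste(p, "PLTEM")
    if (a_plt %in% out$attribute) {
      if (!overwrite) {
        stop("attribute '", a_plt, "' already present; ",
             "use overwrite = TRUE to replace it")
      }
      out <- out[out$attribute != a_plt, , drop = FALSE]
    }
    ext <- out[out$attribute == a_ext, c("patient_id", "timepoint", "value")]
    fib <- out[out$attribute == a_fib, c("patient_id", "timepoint", "value")]
    m <- merge(ext, fib, by = c("patient_id", "timepoint"),
               suffixes = c(".ext", ".fib"))
    n_possible <- length(unique(c(
      paste(ext$patient_id, ext$timepoint),
      paste(fib$patient_id, fib$timepoint))))
    skipped <- skipped + (n_possible - nrow(m))
    if (nrow(m) == 0) {
      warning("no computable EXTEM/FIBTEM pairs for parameter '", p, "'")
      next
    }
    unit <- out$unit[out$attribute == a_ext][1]
    new_rows[[p]] <- data.frame(
      patient_id = m$patient_id, timepoint = m$timepoint,
      attribute = a_plt, value = m$value.ext - m$value.fib,
      unit = unit, stringsAsFactors = FALSE)
  }
  res <- long_table(rbind(out, do.call(rbind, new_rows)),
                    timepoint_order = levels(t$timepoint))
  attr(res, "skipped_pairs") <- skipped
  res
}
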