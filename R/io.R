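## Plain-text I/O: long-table and wide plate-export dialects, fit reports.
## Comment lines starting with "#" may carry metadata ("# key: value"),
## e.g. units, and are propagated as attributes.

parse_hash_metadata <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      if (nzchar(key)) meta[[key]] <- val
    }
  }
  meta
}

detect_sep <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

#' Plate layout map for wide-format files
#'
#' Assigns each data column of a wide plate export an effector level, a
#' replicate id and a role. Roles: `"sample"` (a kinetic series),
#' `"control"` (the zero-effector series) and `"complete-lysis"` (the
#' water-lysed wells that define the optical density of total hemolysis).
#'
#' @param column column names of the data columns (everything except time).
#' @param effector effector level per column (`NA` allowed for
#'   complete-lysis wells).
#' @param replicate replicate identifier per column.
#' @param role per-column role.
#' @return A data frame usable as the `layout` of [read_kinetic_data()].
#' @export
plate_layout <- function(column, effector, replicate = 1,
                         role = "sample") {
  out <- data.frame(column = as.character(column),
                    effector = as.numeric(effector),
                    replicate = rep_len(replicate, length(column)),
                    role = rep_len(role, length(column)))
  bad <- setdiff(unique(out$role), c("sample", "control", "complete-lysis"))
  if (length(bad)) {
    abort_data(sprintf("unknown layout role(s): %s", paste(bad, collapse = ", ")))
  }
  out
}

read_table_checked <- function(path, sep = NULL) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  meta <- parse_hash_metadata(lines[is_comment])
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) < 2) abort_data(sprintf("no data rows in %s", path))
  if (is.null(sep)) sep <- detect_sep(lines[body_idx[1]])
  df <- utils::read.table(text = lines[body_idx], header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  list(df = df, meta = meta, body_lines = body_idx[-1])
}

to_numeric_col <- function(x, colname, file_lines, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !(trimws(x) %in% c("", "NA")))
  if (length(bad)) {
    abort_data(sprintf(
      "malformed numeric value(s) in column '%s' of %s at line(s) %s",
      colname, path, paste(file_lines[bad], collapse = ", ")))
  }
  v
}

#' Read a kinetic hemolysis dataset
#'
#' Reads plain-text kinetic readouts in either of two dialects:
#' \describe{
#'   \item{long}{header-named columns `time`, `response`, `effector` and
#'     optionally `replicate` and `role`, comma- or tab-separated; one row
#'     per observation.}
#'   \item{wide}{first column time, remaining columns one series per
#'     well/condition; a `layout` (see [plate_layout()]) must assign every
#'     data column an effector level, replicate and role exactly once.}
#' }
#' Comment lines prefixed `#` may declare metadata as `# key: value`
#' (e.g. `# units: time=min effector=uM`) and are attached as the `units`
#' attribute. The measurement mode is never guessed: `mode = "percent"`
#' takes the values as percent survival; `mode = "od"` takes them as
#' optical densities and converts each series through [survival_percent()],
#' using the series' earliest reading as `n_0` and, for `n_max`, the mean
#' of the complete-lysis wells (`lysis_reference = "wells"`) or each
#' series' own final-time reading (`lysis_reference = "plateau"`).
#'
#' @param path file path.
#' @param format `"long"` or `"wide"`.
#' @param mode `"percent"` or `"od"` (explicit, never autodetected).
#' @param layout a [plate_layout()]; required for `format = "wide"`.
#' @param lysis_reference where `n_max` comes from in OD mode.
#' @param sep field separator; default autodetects comma vs tab.
#' @return A data frame with columns `time`, `response` (percent),
#'   `effector`, `replicate`; attribute `units` carries any declared units.
#' @export
read_kinetic_data <- function(path, format = c("long", "wide"),
                              mode = c("percent", "od"), layout = NULL,
                              lysis_reference = c("wells", "plateau"),
                              sep = NULL) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  lysis_reference <- match.arg(lysis_reference)
  parsed <- read_table_checked(path, sep)
  df <- parsed$df
  if (format == "long") {
    need <- c("time", "response", "effector")
    if (!all(need %in% names(df))) {
      abort_data(sprintf("long format requires columns %s; found: %s",
                         paste(need, collapse = ", "),
                         paste(names(df), collapse = ", ")))
    }
    out <- data.frame(
      time = to_numeric_col(df$time, "time", parsed$body_lines, path),
      response = to_numeric_col(df$response, "response", parsed$body_lines, path),
      effector = to_numeric_col(df$effector, "effector", parsed$body_lines, path),
      replicate = if ("replicate" %in% names(df)) df$replicate else 1L)
    role <- if ("role" %in% names(df)) df$role else rep("sample", nrow(df))
  } else {
    if (is.null(layout)) abort_data("wide format requires a `layout`")
    data_cols <- setdiff(names(df), names(df)[1])
    unmapped <- setdiff(data_cols, layout$column)
    extra <- setdiff(layout$column, data_cols)
    dup <- layout$column[duplicated(layout$column)]
    if (length(unmapped) || length(extra) || length(dup)) {
      abort_data(sprintf(
        "layout mismatch: unmapped column(s) [%s], missing column(s) [%s], duplicated [%s]",
        paste(unmapped, collapse = ", "), paste(extra, collapse = ", "),
        paste(dup, collapse = ", ")))
    }
    time <- to_numeric_col(df[[1]], names(df)[1], parsed$body_lines, path)
    if (any(time < 0)) abort_data("times must be non-negative")
    pieces <- lapply(seq_len(nrow(layout)), function(i) {
      col <- layout$column[i]
      data.frame(time = time,
                 response = to_numeric_col(df[[col]], col, parsed$body_lines, path),
                 effector = layout$effector[i],
                 replicate = layout$replicate[i],
                 role = layout$role[i])
    })
    long <- do.call(rbind, pieces)
    out <- long[c("time", "response", "effector", "replicate")]
    role <- long$role
  }
  if (any(out$time < 0, na.rm = TRUE)) abort_data("times must be non-negative")

  if (mode == "od") {
    is_lysis <- role == "complete-lysis"
    if (lysis_reference == "wells") {
      if (!any(is_lysis)) {
        abort_data("OD mode with lysis_reference = 'wells' requires complete-lysis wells in the layout")
      }
      n_max <- mean(out$response[is_lysis])
    }
    keep <- !is_lysis
    series <- interaction(out$effector, out$replicate, drop = TRUE)
    converted <- out
    for (s in levels(series)) {
      idx <- which(series == s & keep)
      if (!length(idx)) next
      idx <- idx[order(out$time[idx])]
      n_0 <- out$response[idx[1]]
      nm <- if (lysis_reference == "plateau") {
        out$response[idx[length(idx)]]
      } else n_max
      converted$response[idx] <- survival_percent(out$response[idx], n_0, nm)
    }
    out <- converted[keep, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- out[role != "complete-lysis", , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "units") <- parsed$meta[["units"]]
  out
}

#' Write a kinetic dataset in the long dialect
#'
#' Writes `time, response, effector, replicate` rows, preceded by a
#' `# units:` comment when the data carry a units attribute. A dataset
#' written by this function reads back identically through
#' [read_kinetic_data()].
#'
#' @param data data frame with at least `time`, `response`, `effector`.
#' @param path output path.
#' @param sep `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_kinetic_data <- function(data, path, sep = ",") {
  need <- c("time", "response", "effector")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort_data("`data` must have columns time, response, effector")
  }
  df <- data.frame(time = data$time, response = data$response,
                   effector = data$effector,
                   replicate = if ("replicate" %in% names(data)) data$replicate else 1L)
  con <- file(path, "w")
  on.exit(close(con))
  units <- attr(data, "units")
  if (!is.null(units)) writeLines(paste0("# units: ", units), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fit report
#'
#' Writes an `oxhlia_fit` as JSON (full precision: parameter table,
#' goodness-of-fit and consistency statistics, residual diagnostics,
#' per-level table for bivariate fits) or as flat TSV (one row per
#' parameter, estimates to 4 significant figures).
#'
#' @param fit an `oxhlia_fit`.
#' @param path output path; when `NULL` the JSON string / TSV lines are
#'   returned instead of written.
#' @param format `"json"` or `"tsv"`.
#' @return `path` (or the serialized text when `path` is `NULL`), invisibly.
#' @export
write_fit_report <- function(fit, path = NULL, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (!inherits(fit, "oxhlia_fit")) abort_param("`fit` must be an oxhlia_fit")
  if (format == "json") {
    diag <- residual_diagnostics(fit$residuals)
    payload <- list(
      kind = fit$kind, base = fit$base,
      parameters = fit_parameter_table(fit),
      n_obs = fit$n_obs, dof = fit$dof, sse = fit$sse,
      r2 = fit$r2, r2_adj = fit$r2_adj,
      f_statistic = fit$f_statistic, f_pvalue = fit$f_pvalue,
      converged = fit$converged, iterations = fit$iterations,
      residual_diagnostics = diag)
    if (fit$kind == "bivariate") payload$level_table <- fit$level_table
    if (!is.null(fit$derived)) {
      payload$derived <- as.data.frame(fit$derived)
    }
    txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE, na = "null")
    if (is.null(path)) return(invisible(txt))
    writeLines(txt, path)
  } else {
    tab <- fit_parameter_table(fit)
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, 4)
    if (is.null(path)) {
      out <- utils::capture.output(
        utils::write.table(tab, stdout(), sep = "\t", row.names = FALSE,
                           quote = FALSE))
      return(invisible(out))
    }
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a flat key-value scenario file
#'
#' Scenario files drive the `simulate` CLI command: one `key = value` pair
#' per line, `#` comments allowed. Recognized keys: `control_K`,
#' `control_tau`, `control_alpha`, `tau_l1`, `tau_l2`, `alpha_l1`,
#' `alpha_l2` (linear dose modifiers), `times` (either `start:stop:step` or
#' a comma list), `levels` (comma list), `noise_sd`, `replicates`, `seed`.
#' Missing keys fall back to the defaults of [simulation_scenario()].
#'
#' @param path scenario file path.
#' @param seed optional seed overriding the file's.
#' @return A [simulation_scenario()].
#' @export
read_scenario_file <- function(path, seed = NULL) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort_data(sprintf("malformed scenario line (expected key = value): '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  parse_grid <- function(val, default) {
    if (is.null(val)) return(default)
    if (grepl(":", val, fixed = TRUE)) {
      parts <- as.numeric(strsplit(val, ":", fixed = TRUE)[[1]])
      if (length(parts) != 3 || any(is.na(parts))) {
        abort_data(sprintf("malformed grid '%s' (want start:stop:step)", val))
      }
      seq(parts[1], parts[2], by = parts[3])
    } else {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }
  }
  mods <- list()
  if (!is.null(kv$tau_l1) || !is.null(kv$tau_l2)) {
    mods$tau <- linear_modifier(num("tau_l1", 0), num("tau_l2", 0))
  }
  if (!is.null(kv$alpha_l1) || !is.null(kv$alpha_l2)) {
    mods$alpha <- linear_modifier(num("alpha_l1", 0), num("alpha_l2", 0))
  }
  default <- trolox_dose_model()
  model <- if (length(mods) || !is.null(kv$control_K) ||
               !is.null(kv$control_tau) || !is.null(kv$control_alpha)) {
    effector_model(kinetic_params(num("control_K", default$control$K),
                                  num("control_tau", default$control$tau),
                                  num("control_alpha", default$control$alpha)),
                   if (length(mods)) mods else default$modifiers)
  } else default
  file_seed <- if (!is.null(kv$seed)) as.integer(kv$seed) else NULL
  simulation_scenario(model = model,
                      time_grid = parse_grid(kv$times, seq(0, 180, by = 10)),
                      effector_levels = parse_grid(kv$levels, seq(0, 125, by = 25)),
                      noise_sd = num("noise_sd", 1.5),
                      replicates = num("replicates", 1),
                      seed = if (!is.null(seed)) seed else file_seed)
}
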