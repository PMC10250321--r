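#' Read a delimited measurement table with unit-aware headers
#'
#' Parses the package's plain-text interchange format: comma-delimited
#' columns with unit-suffixed names, preceded by `# key=value` metadata
#' lines. All lengths are converted to meters, pressures to Pa and creep
#' times to seconds on read, so downstream code never mixes um and m.
#'
#' Supported schemas and their required columns:
#' * `creep`: `time_s, length_um`; metadata `delta_p_pa` (required) and
#'   `rp_um` (default 3.5, a 7 um-diameter pipette).
#' * `indent_reduced`: `depth_um, load_nn`; optional metadata
#'   `spring_constant_n_m`, `tip_radius_um`, `max_depth_um`.
#' * `indent_raw`: `z_um, d_um`; same optional metadata.
#' * `tracks`: `cell_id, t_min, x_um, y_um` (long format, one row per
#'   frame); optional metadata `gradient_axis` ("x" or "y").
#' * `wound`: `day, area_mm2`.
#'
#' @param path File to read.
#' @param schema One of `"creep"`, `"indent_raw"`, `"indent_reduced"`,
#'   `"tracks"`, `"wound"`.
#' @return The corresponding domain object: a [creep_record()], an
#'   [indentation_curve()], a list of [trajectory()] objects, or a
#'   [wound_series()]. Parsed metadata is attached as attribute `"meta"`.
#' @export
read_mech_table <- function(path, schema = c("creep", "indent_raw",
                                             "indent_reduced", "tracks", "wound")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^\\s*#\\s*", "", ml)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  df <- tryCatch(
    utils::read.csv(textConnection(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]),
                    strip.white = TRUE),
    error = function(e) stop_domain(sprintf("%s: cannot parse table (%s)",
                                            path, conditionMessage(e))))
  names(df) <- tolower(names(df))

  need <- switch(schema,
                 creep = c("time_s", "length_um"),
                 indent_reduced = c("depth_um", "load_nn"),
                 indent_raw = c("z_um", "d_um"),
                 tracks = c("cell_id", "t_min", "x_um", "y_um"),
                 wound = c("day", "area_mm2"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_domain(sprintf("%s: missing required column(s) %s for schema '%s'",
                        path, paste(missing_cols, collapse = ", "), schema))
  for (cn in setdiff(need, "cell_id")) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop_domain(sprintf("%s: non-numeric value in column '%s', row %d",
                          path, cn, if (is.na(bad)) 1L else bad))
    }
    if (any(!is.finite(v)))
      stop_domain(sprintf("%s: non-finite value in column '%s', row %d",
                          path, cn, which(!is.finite(v))[1]))
  }

  obj <- switch(schema,
    creep = {
      if (is.null(meta$delta_p_pa))
        stop_domain(sprintf("%s: creep file needs '# delta_p_pa=...' metadata", path))
      rp_um <- meta$rp_um %||% 3.5
      bad <- which(diff(df$time_s) <= 0)
      if (length(bad))
        stop_domain(sprintf("%s: time_s not strictly increasing at row %d", path, bad[1] + 1L))
      creep_record(delta_p = meta$delta_p_pa, rp = rp_um * 1e-6,
                   times = df$time_s, lengths = df$length_um * 1e-6)
    },
    indent_reduced = {
      inst <- meta_instrument(meta)
      indentation_curve(depth = df$depth_um * 1e-6, load = df$load_nn * 1e-9,
                        mode = "reduced", instrument = inst)
    },
    indent_raw = {
      inst <- meta_instrument(meta)
      indentation_curve(z = df$z_um * 1e-6, d = df$d_um * 1e-6,
                        mode = "raw", instrument = inst)
    },
    tracks = {
      axis <- switch(as.character(meta$gradient_axis %||% "x"),
                     x = c(1, 0), y = c(0, 1),
                     stop_domain(sprintf("%s: gradient_axis must be 'x' or 'y'", path)))
      ids <- unique(as.character(df$cell_id))
      lapply(ids, function(id) {
        sub <- df[as.character(df$cell_id) == id, , drop = FALSE]
        bad <- which(diff(sub$t_min) <= 0)
        if (length(bad))
          stop_domain(sprintf("%s: t_min not strictly increasing for cell '%s' at its row %d",
                              path, id, bad[1] + 1L))
        trajectory(id, sub$t_min, sub$x_um, sub$y_um, gradient_axis = axis)
      })
    },
    wound = wound_series(df$day, df$area_mm2))
  attr(obj, "meta") <- meta
  obj
}

meta_instrument <- function(meta) {
  instrument_config(
    spring_constant = meta$spring_constant_n_m %||% 0.048,
    tip_radius = (meta$tip_radius_um %||% 9) * 1e-6,
    max_depth = (meta$max_depth_um %||% 5) * 1e-6,
    load_period = meta$load_period_s %||% 2)
}

#' Write a creep record to the delimited interchange format
#'
#' @param record A [creep_record()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_creep <- function(record, path) {
  if (!inherits(record, "creep_record")) stop_domain("`record` must be a creep_record")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# delta_p_pa=%.15g", record$delta_p),
               sprintf("# rp_um=%.15g", record$rp * 1e6),
               "time_s,length_um"), con)
  utils::write.table(data.frame(record$times, record$lengths * 1e6),
                     con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tabulate SLS fits for export
#'
#' @param fits A list of `sls_fit` objects (as returned by
#'   [fit_two_point()] or [fit_nls()]).
#' @param labels Optional record labels.
#' @return `data.frame` with columns `label`, `k1_pa`, `k2_pa`, `mu_pa_s`,
#'   `tau_s`, `residual_rms_m`, `method`, `converged`.
#' @export
sls_fit_table <- function(fits, labels = NULL) {
  if (inherits(fits, "sls_fit")) fits <- list(fits)
  labels <- labels %||% sprintf("record_%03d", seq_along(fits))
  rows <- Map(function(f, lab) {
    p <- f$params
    data.frame(label = lab,
               k1_pa = p$k1 %||% NA_real_, k2_pa = p$k2 %||% NA_real_,
               mu_pa_s = p$mu %||% NA_real_,
               tau_s = if (is.null(p)) NA_real_ else sls_time_constant(p),
               residual_rms_m = f$residual_rms, method = f$method,
               converged = f$converged, stringsAsFactors = FALSE)
  }, fits, labels)
  do.call(rbind, rows)
}

#' Write a results table with a reproducibility manifest
#'
#' Writes `results` as comma-delimited text and, alongside it, a JSON
#' manifest (`<path>.manifest.json`) recording the package version, the
#' seed and configuration echo supplied by the caller, and MD5 checksums
#' of any input files — enough to re-run the analysis bit-for-bit. Rows
#' whose `converged` column is `FALSE` (if present) are additionally
#' written to a `<path>.rejects.csv` file so failures are visible, not
#' buried.
#'
#' @param results A `data.frame`.
#' @param path Output CSV path.
#' @param config Optional named list echoed into the manifest.
#' @param seed Optional seed echoed into the manifest.
#' @param inputs Optional character vector of input file paths to checksum.
#' @return The manifest, invisibly.
#' @export
write_results <- function(results, path, config = list(), seed = NULL,
                          inputs = NULL) {
  if (!is.data.frame(results)) stop_domain("`results` must be a data.frame")
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0)
    abort_cellmech(sprintf("output directory not writable: %s", dir), "cellmech_io_error")
  utils::write.csv(results, path, row.names = FALSE)
  if ("converged" %in% names(results)) {
    rej <- results[!vapply(results$converged, isTRUE, logical(1)), , drop = FALSE]
    if (nrow(rej))
      utils::write.csv(rej, paste0(sub("\\.csv$", "", path), ".rejects.csv"),
                       row.names = FALSE)
  }
  manifest <- list(
    package = "cellmech",
    version = as.character(utils::packageVersion("cellmech")),
    seed = seed,
    config = config,
    n_rows = nrow(results),
    input_checksums = if (!is.null(inputs))
      as.list(tools::md5sum(inputs)) else NULL)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
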