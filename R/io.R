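#' Read a titration table
#'
#' Parses a delimited (comma or tab; auto-detected) titration table with a
#' header row and columns `step`, `added_volume_uL`, `stock_conc_uM`,
#' `F475`, `F535` and optionally `F600`. If a populated `F600` column is
#' present the file is interpreted as a dual-channel Ca2+ assay and a
#' [ca_assay_series()] is returned (requiring the indicator calibration
#' arguments); otherwise a [titration_series()].
#'
#' @param path Path to the file.
#' @param initial_volume Initial cuvette volume, µL.
#' @param biosensor_total Total biosensor concentration, µM.
#' @param indicator_f_min,indicator_f_max Indicator calibration endpoints
#'   (required when `F600` is present).
#' @param indicator_kd Indicator Ca2+ Kd, µM (default 1.6).
#' @param cam_total Saturating calmodulin concentration, µM (Ca2+ assays).
#' @param ... Further metadata forwarded to the series constructor.
#' @return A `titration_series` or `ca_assay_series`.
#' @export
read_titration_table <- function(path, initial_volume, biosensor_total = 0.5,
                                 indicator_f_min = NULL,
                                 indicator_f_max = NULL, indicator_kd = 1.6,
                                 cam_total = NA_real_, ...) {
  if (!file.exists(path))
    fb_stop(sprintf("file not found: %s", path), "fretbind_io_error")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("step", "added_volume_uL", "stock_conc_uM", "F475", "F535")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    fb_stop(paste0("titration table missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            "fretbind_schema_error")
  to_num <- function(col, allow_blank = FALSE) {
    x <- raw[[col]]
    if (allow_blank) x[x == "" | is.na(x)] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      fb_stop(sprintf("non-numeric value in column %s at data row %d (%s)",
                      col, bad[1], x[bad[1]]), "fretbind_parse_error")
    v
  }
  pts <- data.frame(
    step = to_num("step"),
    added_volume = to_num("added_volume_uL"),
    stock_conc = to_num("stock_conc_uM"),
    f_donor = to_num("F475"),
    f_acceptor = to_num("F535"))
  has_f600 <- "F600" %in% names(raw) &&
    any(!is.na(suppressWarnings(as.numeric(raw$F600))))
  if (has_f600) {
    pts$f_indicator <- to_num("F600", allow_blank = TRUE)
    if (is.null(indicator_f_min) || is.null(indicator_f_max))
      fb_stop("indicator calibration endpoints (indicator_f_min/indicator_f_max) are required for Ca2+ assay tables",
              "fretbind_config_error")
    ca_assay_series(pts, initial_volume = initial_volume,
                    indicator_f_min = indicator_f_min,
                    indicator_f_max = indicator_f_max,
                    indicator_kd = indicator_kd, cam_total = cam_total,
                    biosensor_total = biosensor_total, ...)
  } else {
    titration_series(pts, initial_volume = initial_volume,
                     biosensor_total = biosensor_total, ...)
  }
}

#' Write a titration table
#'
#' Inverse of [read_titration_table()]: writes the per-point records of a
#' series to a delimited text file in the standard column layout.
#'
#' @param series A `titration_series` or `ca_assay_series`.
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @export
write_titration_table <- function(series, path, sep = ",") {
  p <- series$points
  out <- data.frame(step = p$step, added_volume_uL = p$added_volume,
                    stock_conc_uM = p$stock_conc, F475 = p$f_donor,
                    F535 = p$f_acceptor)
  if (!is.null(p$f_indicator)) out$F600 <- p$f_indicator
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble an analysis report
#'
#' Structured record of one pipeline run: the construct analyzed, the fit
#' results, provenance (inputs, configuration, seed, package version) and
#' any warnings emitted during the run. Serializes losslessly to JSON via
#' [write_report()] / [read_report()].
#'
#' @param construct Construct name or label.
#' @param results Named list of fit results (`binding_fit`, `hill_fit`,
#'   `ca_sensitivity`, data frames, ...).
#' @param provenance Named list (input paths, config, seed, ...); the
#'   package version is added automatically.
#' @param warnings Character vector of warnings emitted during the run.
#' @return A list of class `analysis_report`.
#' @export
analysis_report <- function(construct, results, provenance = list(),
                            warnings = character()) {
  provenance$package_version <-
    as.character(utils::packageVersion("fretbind"))
  structure(list(construct = construct, results = results,
                 provenance = provenance, warnings = warnings),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s (%d result(s), %d warning(s))\n",
              x$construct, length(x$results), length(x$warnings)))
  for (nm in names(x$results)) {
    cat(" $", nm, ": ", sep = "")
    r <- x$results[[nm]]
    if (is.data.frame(r)) cat(sprintf("<data.frame %d x %d>\n", nrow(r), ncol(r)))
    else print(r)
  }
  invisible(x)
}

# Tag S3 classes so they survive the JSON round trip.
tag_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    cls <- class(x)
    x <- lapply(x, tag_classes)
    if (!identical(cls, "list")) x[[".class"]] <- cls
  }
  x
}

untag_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    cls <- x[[".class"]]
    x[[".class"]] <- NULL
    x <- lapply(x, untag_classes)
    if (!is.null(cls)) class(x) <- cls
  }
  x
}

#' Serialize an analysis report to JSON
#'
#' @param report An [analysis_report()].
#' @param path Output path (`.json`).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(tag_classes(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Deserialize an analysis report from JSON
#'
#' @param path Path written by [write_report()].
#' @return The reconstructed `analysis_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = TRUE,
                           simplifyMatrix = FALSE)
  untag_classes(x)
}

#' Run one pipeline command
#'
#' Single entry point tying the modules together. Commands:
#' \describe{
#'   \item{`fit-kd`}{Read (or take) a calmodulin titration, dilution-correct
#'     it and fit the apparent Kd ([fit_binding()]).}
#'   \item{`fit-ca`}{Read (or take) a dual-channel Ca2+ assay and run the
#'     Ca2+-sensitivity pipeline ([run_ca_assay()]).}
#'   \item{`simulate`}{Generate a synthetic titration or Ca2+ assay from
#'     `config$generator` and optionally write it as a titration table.}
#'   \item{`design`}{Enumerate a construct family from
#'     `config$base_construct`, `config$truncation_ends`,
#'     `config$gly_flank_options`.}
#' }
#' All warnings raised during the run (clamping, model auto-selection,
#' saturation) are captured into the report.
#'
#' @param command One of `"fit-kd"`, `"fit-ca"`, `"simulate"`, `"design"`.
#' @param config Named list of options; keys mirror the function arguments
#'   of the underlying module (e.g. `initial_volume`, `biosensor_total`,
#'   `model`, `response_model`, `breakpoint`, `indicator_f_min`, ...).
#' @param input Input file path, or an in-memory series object.
#' @param out Optional path: the report is written there as JSON (for
#'   `simulate`, `config$data_out` additionally writes the data table).
#' @param construct Label recorded in the report.
#' @return An [analysis_report()].
#' @export
run_pipeline <- function(command = c("fit-kd", "fit-ca", "simulate", "design"),
                         config = list(), input = NULL, out = NULL,
                         construct = config$construct %||% "unnamed") {
  command <- match.arg(command)
  warn_log <- character()
  results <- withCallingHandlers(
    tryCatch(
      switch(command,
        "fit-kd" = {
          series <- if (inherits(input, "titration_series")) input
            else read_titration_table(
              input, initial_volume = config$initial_volume,
              biosensor_total = config$biosensor_total %||% 0.5)
          resp <- apply_dilution_correction(series)
          fit <- fit_binding(resp,
                             model = config$model %||% "auto",
                             response_model = config$response_model %||%
                               "affine_ratio")
          list(binding = fit)
        },
        "fit-ca" = {
          series <- if (inherits(input, "ca_assay_series")) input
            else read_titration_table(
              input, initial_volume = config$initial_volume,
              biosensor_total = config$biosensor_total %||% 0.5,
              indicator_f_min = config$indicator_f_min,
              indicator_f_max = config$indicator_f_max,
              indicator_kd = config$indicator_kd %||% 1.6,
              cam_total = config$cam_total %||% NA_real_)
          res <- run_ca_assay(series,
                              breakpoint = config$breakpoint %||% 1.0)
          list(ca_sensitivity = res)
        },
        "simulate" = {
          gen <- config$generator
          if (!inherits(gen, "generator_config"))
            fb_stop("config$generator must be a generator_config",
                    "fretbind_config_error")
          series <- if (identical(config$type, "ca"))
            simulate_ca_assay(gen, buffers = config$buffers %||% list(),
                              indicator = config$indicator %||%
                                list(kd = 1.6, total = 2, f_min = 100,
                                     f_max = 1100))
          else simulate_cam_titration(gen)
          if (!is.null(config$data_out))
            write_titration_table(series, config$data_out)
          list(series = list(n_points = nrow(series$points),
                             type = class(series)[1],
                             data_out = config$data_out))
        },
        "design" = {
          base <- config$base_construct
          if (!inherits(base, "biosensor_construct"))
            fb_stop("config$base_construct must be a biosensor_construct",
                    "fretbind_config_error")
          fam <- enumerate_constructs(
            base, config$truncation_ends %||% integer(),
            config$gly_flank_options %||% 0L)
          manifest <- data.frame(
            name = vapply(fam, `[[`, character(1), "name"),
            linker_start = vapply(fam, `[[`, numeric(1), "linker_start"),
            linker_end = vapply(fam, `[[`, numeric(1), "linker_end"),
            n_flank_gly = vapply(fam, `[[`, numeric(1), "n_flank_gly"),
            c_flank_gly = vapply(fam, `[[`, numeric(1), "c_flank_gly"))
          list(manifest = manifest)
        }),
      error = function(e) {
        stop(errorCondition(
          sprintf("[%s] %s", command, conditionMessage(e)),
          class = c("fretbind_pipeline_error", "fretbind_error")))
      }),
    warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  report <- analysis_report(
    construct = construct, results = results,
    provenance = list(
      command = command,
      input = if (is.character(input)) input else class(input)[1],
      config = config[!vapply(config, is.object, logical(1))],
      seed = config$generator$seed %||% config$seed),
    warnings = warn_log)
  if (!is.null(out)) write_report(report, out)
  report
}
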