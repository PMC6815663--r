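# ---------------------------------------------------------------------------
# Recordings on disk, pipeline configuration, end-to-end run
# ---------------------------------------------------------------------------

#' Construct a continuous recording
#'
#' @param data channels x samples numeric matrix (a vector is treated as a
#'   single channel).
#' @param srate sampling rate in Hz, > 0.
#' @param labels channel labels; default `ch1..chN`.
#' @param provenance free-text provenance note.
#' @return an object of class `erp_recording`.
#' @export
recording <- function(data, srate, labels = NULL, provenance = "") {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(srate) || length(srate) != 1 || srate <= 0)
    stop("srate must be a single positive number")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(labels) == nrow(data))
  rownames(data) <- labels
  structure(list(data = data, srate = srate, labels = labels,
                 provenance = provenance),
            class = "erp_recording")
}

#' @export
print.erp_recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  invisible(x)
}

#' Load a continuous recording
#'
#' Supported formats: `delimited` -- a TSV with one column per channel
#' (header = channel labels) and one row per sample, with the sampling rate
#' in a JSON sidecar `<path>.json` (field `srate`) or passed as `srate`;
#' `binary` -- little-endian float64 samples (channel-major) in `<path>`
#' with a JSON header `<path>.json` carrying `srate`, `n_channels`,
#' `n_samples`, `labels`. An adapter for standard EEG containers
#' (EEGLAB SET / FIF) is deliberately kept outside the core; requesting
#' `format = "eeg-container"` raises an informative error rather than
#' degrading silently.
#'
#' @param path file path.
#' @param format `"delimited"` or `"binary"` (or `"eeg-container"`, see
#'   above).
#' @param srate sampling rate, overriding/replacing the sidecar value.
#' @return an `erp_recording`.
#' @export
load_recording <- function(path, format = c("delimited", "binary",
                                            "eeg-container"), srate = NULL) {
  format <- match.arg(format)
  if (format == "eeg-container")
    stop("no EEG-container adapter is installed; export the data to the ",
         "plain delimited or binary format instead")
  side <- paste0(path, ".json")
  hdr <- if (file.exists(side)) jsonlite::read_json(side,
                                                    simplifyVector = TRUE)
         else list()
  if (is.null(srate)) srate <- hdr$srate
  if (is.null(srate))
    stop("sampling rate missing: no 'srate' in ", side,
         " and none supplied")
  if (format == "delimited") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
    rec <- recording(t(as.matrix(d)), srate, labels = colnames(d),
                     provenance = path)
  } else {
    for (f in c("n_channels", "n_samples"))
      if (is.null(hdr[[f]])) stop("binary header missing field '", f, "'")
    v <- readBin(path, "double", n = hdr$n_channels * hdr$n_samples,
                 size = 8, endian = "little")
    rec <- recording(matrix(v, nrow = hdr$n_channels, byrow = TRUE),
                     srate, labels = hdr$labels, provenance = path)
  }
  rec
}

#' Write a continuous recording
#'
#' @param rec an `erp_recording`.
#' @param path output path.
#' @param format `"delimited"` or `"binary"` (see [load_recording()]).
#' @return the path, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "erp_recording"))
  if (format == "delimited") {
    d <- as.data.frame(t(rec$data))
    names(d) <- rec$labels
    utils::write.table(format(d, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    writeBin(as.numeric(t(rec$data)), path, size = 8, endian = "little")
  }
  jsonlite::write_json(list(srate = rec$srate, n_channels = nrow(rec$data),
                            n_samples = ncol(rec$data),
                            labels = rec$labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pipeline: config -> design -> expansion -> (blanking) -> solve -> export
# ---------------------------------------------------------------------------

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

parse_basis_config <- function(b) {
  if (is.null(b)) return(temporal_basis("stick"))
  temporal_basis(b$kind %||% "stick", n_basis = b$n_basis, K = b$K)
}

#' Run the full analysis pipeline from a configuration file
#'
#' Executes the complete flow described by a YAML configuration: load the
#' recording and event table, build and time-expand the per-event-type
#' designs, optionally detect and blank artifact intervals, solve for the
#' coefficients (LSMR or elastic net), optionally run the mass-univariate
#' twin fit, convert to waveforms (optionally baseline-corrected), and
#' write a long-format CSV per fit plus a JSON metadata file and a log.
#'
#' Configuration keys:
#' ```yaml
#' recording: {path: data.tsv, format: delimited, srate: 200}
#' events: events.tsv
#' model:
#'   - event_type: stim
#'     formula: "y ~ 1 + cat(cond) + spl(lum, 5)"
#'     window: [-0.1, 0.5]
#'     basis: {kind: stick}        # or {kind: fourier, K: 10} etc.
#' imputation: {method: mean, seed: 1}    # optional
#' artifacts: {threshold: 250, winlen: 2, step: 1}   # optional
#' solver: {method: lsmr, tol: 1.0e-10}   # or method: elasticnet, alpha, ...
#' mass_univariate: false
#' baseline: [-0.1, 0]             # optional, seconds
#' seed: 1
#' output: out_dir
#' ```
#'
#' @param config_path path to the YAML configuration.
#' @return invisibly, a list with the fit(s), waveform set(s), and output
#'   paths. Any stage error aborts with a stage-tagged condition.
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  out_dir <- cfg$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  lg <- function(stg, msg) pipeline_log(logcon, stg, msg)

  rec <- stage("import", {
    r <- load_recording(cfg$recording$path,
                        cfg$recording$format %||% "delimited",
                        srate = cfg$recording$srate)
    lg("import", sprintf("recording: %d ch x %d samples @ %g Hz",
                         nrow(r$data), ncol(r$data), r$srate))
    r
  })
  events <- stage("events", {
    ev <- read_events(cfg$events, duration = ncol(rec$data) / rec$srate)
    lg("events", sprintf("%d events, %d type(s)", nrow(ev),
                         length(unique(ev$type))))
    ev
  })
  if (!is.null(cfg$imputation)) events <- stage("imputation",
    impute_missing(events, cfg$imputation$method %||% "mean",
                   seed = cfg$imputation$seed %||% cfg$seed))
  specs <- stage("design", {
    if (is.null(cfg$model) || !length(cfg$model)) stop("no model specified")
    lapply(cfg$model, function(m)
      model_spec(m$event_type, m$formula, as.numeric(m$window),
                 basis = parse_basis_config(m$basis),
                 ref_levels = m$ref_levels,
                 coding = m$coding %||% "treatment"))
  })
  X <- stage("timeexpand", {
    x <- expand_model(events, specs, ncol(rec$data), rec$srate)
    lg("timeexpand", sprintf("expanded design: %d x %d, %d nonzero",
                             nrow(x$X), ncol(x$X), Matrix::nnzero(x$X)))
    x
  })
  n_blanked <- 0L
  if (!is.null(cfg$artifacts)) {
    X <- stage("artifacts", {
      iv <- detect_peak2peak(rec$data, cfg$artifacts$threshold,
                             cfg$artifacts$winlen,
                             cfg$artifacts$step %||%
                               (cfg$artifacts$winlen / 2), rec$srate)
      xb <- blank_rows(X, iv)
      n_blanked <- length(xb$blanked)   # promise evaluates in this frame
      lg("artifacts", sprintf("%d interval(s), %d row(s) blanked",
                              nrow(iv), n_blanked))
      xb
    })
  }
  solver <- cfg$solver %||% list(method = "lsmr")
  fit <- stage("solve", {
    f <- if ((solver$method %||% "lsmr") == "elasticnet")
      fit_elasticnet(X, rec$data, alpha = solver$alpha %||% 0,
                     lambdas = solver$lambdas,
                     cv_folds = solver$cv_folds %||% 5,
                     seed = solver$seed %||% cfg$seed %||% 1,
                     n_lambdas = solver$n_lambdas %||% 30)
    else
      fit_lsmr(X, rec$data, tol = solver$tol %||% 1e-10,
               max_iter = solver$max_iter)
    lg("solve", sprintf("%s fit: sigma = %s", f$info$method,
                        paste(signif(f$sigma, 4), collapse = ", ")))
    f
  })
  erps <- stage("results", extract_erps(fit))
  if (!is.null(cfg$baseline))
    erps <- stage("results",
                  baseline_correct(erps, as.numeric(cfg$baseline)))
  out_csv <- file.path(out_dir, "betas_long.csv")
  stage("export", export_long(erps, out_csv))
  lg("export", out_csv)
  results <- list(fit = fit, erps = erps, csv = out_csv)
  if (isTRUE(cfg$mass_univariate)) {
    mu <- stage("massuni", {
      fits <- lapply(specs, function(sp)
        fit_mass_univariate(build_design(events, sp), data = rec$data,
                            srate = rec$srate))
      sets <- lapply(fits, extract_erps)
      if (!is.null(cfg$baseline))
        sets <- lapply(sets, baseline_correct, window = as.numeric(cfg$baseline))
      merged <- sets[[1]]
      if (length(sets) > 1)
        for (s in sets[-1]) merged$components <- c(merged$components,
                                                   s$components)
      mu_csv <- file.path(out_dir, "massuni_long.csv")
      export_long(merged, mu_csv)
      lg("massuni", mu_csv)
      list(fits = fits, erps = merged, csv = mu_csv)
    })
    results$mass_univariate <- mu
  }
  meta <- list(solver = fit$info$method,
               tol = solver$tol %||% NULL,
               alpha = solver$alpha %||% NULL,
               lambda = fit$info$lambda %||% NULL,
               seed = cfg$seed %||% NULL,
               n_blanked_rows = n_blanked,
               sigma = as.numeric(fit$sigma),
               n_samples = ncol(rec$data), srate = rec$srate)
  jsonlite::write_json(meta, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
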