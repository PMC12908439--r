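#' Read uniformly sampled signals from a delimited text file
#'
#' Reads a comma- or tab-delimited file with a header containing a time
#' column (seconds) and one or more signal columns. Uniform sampling is
#' validated against a relative tolerance on the time step; the sampling
#' rate is inferred from the median step.
#'
#' @param path Path to the file. The delimiter (comma or tab) is detected
#'   from the header line.
#' @param columns Character vector of signal columns to read; defaults to
#'   every non-time column.
#' @param time_col Name of the time column (default `"time_s"`).
#' @param tolerance Maximum allowed relative deviation of any time step from
#'   the median step.
#' @return Named list of [prony_signal]s, one per requested column.
#' @export
read_timeseries <- function(path, columns = NULL, time_col = "time_s",
                            tolerance = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!time_col %in% names(df))
    stop("time column '", time_col, "' not found in ", path)
  if (is.null(columns)) columns <- setdiff(names(df), time_col)
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  tt <- df[[time_col]]
  if (length(tt) < 4L) stop("need at least 4 rows, got ", length(tt))
  dt <- diff(tt)
  med <- stats::median(dt)
  if (med <= 0) stop("time column is not strictly increasing")
  rel <- abs(dt - med) / med
  if (max(rel) > tolerance) {
    w <- which.max(rel)
    stop(sprintf(
      paste0("non-uniform sampling: step %d (t = %g -> %g) deviates from ",
             "the median step %g by a relative %g (tolerance %g)"),
      w, tt[w], tt[w + 1L], med, max(rel), tolerance))
  }
  sr <- 1 / med
  stats::setNames(
    lapply(columns, function(cl)
      prony_signal(df[[cl]], sr, label = cl, t0 = tt[1L])),
    columns)
}

#' Write signals to a delimited text file
#'
#' Writes a tab-separated table with a `time_s` column followed by one
#' column per signal (named by label), the format [read_timeseries()]
#' expects back.
#'
#' @param signals Named list of [prony_signal]s sharing length, sampling
#'   rate and start time.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(signals, path) {
  signals <- lapply(signals, as_prony_signal)
  if (length(signals) < 1L) stop("no signals to write")
  lens <- vapply(signals, function(s) length(s$samples), integer(1))
  srs <- vapply(signals, `[[`, numeric(1), "sampling_rate")
  if (length(unique(lens)) != 1L || length(unique(srs)) != 1L)
    stop("all signals must share length and sampling rate")
  df <- data.frame(time_s = signal_times(signals[[1L]]))
  for (s in signals) df[[s$label]] <- s$samples
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a Prony model to JSON
#'
#' Complex poles and coefficients are stored as `[re, im]` pairs to keep the
#' serialization language-neutral.
#'
#' @param model A [prony_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "prony_model"))
  obj <- list(
    label = model$label,
    n_components = model$n_components,
    scale_d = model$scale_d,
    sampling_rate = model$sampling_rate,
    source_length = model$source_length,
    r_squared = model$r_squared,
    poles = cbind(Re(model$poles), Im(model$poles)),
    coefficients = cbind(Re(model$coefficients), Im(model$coefficients)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Prony model serialized by [write_model_json()]
#'
#' @param path Path to the JSON file.
#' @return A [prony_model].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_cplx <- function(m) {
    if (length(m) == 0L) return(complex(0))
    m <- matrix(unlist(m), ncol = 2L, byrow = !is.matrix(m))
    complex(real = m[, 1L], imaginary = m[, 2L])
  }
  prony_model(as_cplx(obj$poles), as_cplx(obj$coefficients),
              scale_d = obj$scale_d, sampling_rate = obj$sampling_rate,
              source_length = obj$source_length, label = obj$label,
              r_squared = if (is.null(obj$r_squared)) NA_real_
                          else obj$r_squared)
}

#' Write the folded component table of a model as TSV
#'
#' Columns: `amplitude`, `damping_per_s`, `frequency_hz`, `phase_rad`,
#' `importance` (amplitude relative to the largest component).
#'
#' @param model A [prony_model].
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_components_tsv <- function(model, path) {
  comp <- .fold_model(model)
  out <- data.frame(amplitude = comp$amplitude,
                    damping_per_s = comp$damping_per_s,
                    frequency_hz = comp$frequency_hz,
                    phase_rad = comp$phase,
                    importance = if (max(comp$amplitude) > 0)
                      comp$amplitude / max(comp$amplitude) else 0)
  out <- out[order(-out$importance), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write the pole table of a model as TSV
#'
#' Columns: `re`, `im`, `radius`, `angle_deg`, `importance`, `stable`.
#'
#' @param model A [prony_model].
#' @param path Output path.
#' @param tol Stability boundary slack passed to [classify_poles()].
#' @return The table, invisibly.
#' @export
write_pole_table <- function(model, path, tol = 0) {
  stopifnot(inherits(model, "prony_model"))
  cmag <- Mod(model$coefficients)
  out <- data.frame(
    re = Re(model$poles), im = Im(model$poles),
    radius = Mod(model$poles), angle_deg = Arg(model$poles) * 180 / pi,
    importance = if (max(cmag) > 0) cmag / max(cmag) else 0,
    stable = classify_poles(model, tol))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Pipeline run configuration
#'
#' Bundles the inputs and tunables of [run_pipeline()].
#'
#' @param inputs Character vector of delimited time-series file paths.
#' @param out_dir Output directory (created if absent).
#' @param columns Signal columns to process (default: all non-time columns).
#' @param time_col Name of the time column.
#' @param n_poles Number of Prony terms or `"auto"`.
#' @param scale_d Time-scaling factor or `"auto"`.
#' @param subset Pole subset for metrics: `"stable"` or `"all"`.
#' @param threshold Off-circle distance threshold (> 0).
#' @param bode_grid Numeric `c(f_min, f_max, step)` in Hz.
#' @param verbose Emit progress messages.
#' @return Object of class `prony_run_config`.
#' @export
run_config <- function(inputs, out_dir, columns = NULL, time_col = "time_s",
                       n_poles = "auto", scale_d = "auto",
                       subset = c("stable", "all"), threshold = 0.2,
                       bode_grid = c(1, 100, 1), verbose = TRUE) {
  subset <- match.arg(subset)
  if (threshold <= 0) stop("'threshold' must be positive")
  if (length(bode_grid) != 3L || bode_grid[2L] <= bode_grid[1L] ||
      bode_grid[3L] <= 0)
    stop("'bode_grid' must be c(f_min, f_max, step) with f_max > f_min, step > 0")
  structure(
    list(inputs = inputs, out_dir = out_dir, columns = columns,
         time_col = time_col, n_poles = n_poles, scale_d = scale_d,
         subset = subset, threshold = threshold, bode_grid = bode_grid,
         verbose = verbose),
    class = "prony_run_config")
}

#' Run the full Prony pipeline on one or more input files
#'
#' For every signal column of every input: fits a Prony model (model JSON,
#' folded component TSV, R^2), writes the pole table and pole metrics
#' (JSON). When a file provides both a `pressure` and a `volume` column, the
#' pressure-to-volume transfer function (JSON) and its Bode curve (TSV) are
#' written as well. Stage failures are reported with the stage and input
#' label and do not stop the remaining work.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `results` (per input: fitted models,
#'   metrics, transfer function) and `failures` (data frame of input, stage,
#'   message; zero rows on full success).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "prony_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  failures <- list()
  fail <- function(input, stage, e) {
    failures[[length(failures) + 1L]] <<-
      data.frame(input = input, stage = stage,
                 message = conditionMessage(e))
    say("FAILED [%s / %s]: %s", input, stage, conditionMessage(e))
  }
  results <- list()

  for (path in config$inputs) {
    tag <- tools::file_path_sans_ext(basename(path))
    signals <- tryCatch(
      read_timeseries(path, config$columns, config$time_col),
      error = function(e) { fail(path, "read", e); NULL })
    if (is.null(signals)) next
    models <- list()
    for (lab in names(signals)) {
      res <- tryCatch({
        m <- prony_fit(signals[[lab]], n_poles = config$n_poles,
                       scale_d = config$scale_d)
        stem <- file.path(config$out_dir, paste0(tag, "_", lab))
        write_model_json(m, paste0(stem, "_model.json"))
        write_components_tsv(m, paste0(stem, "_components.tsv"))
        write_pole_table(m, paste0(stem, "_poles.tsv"))
        mets <- pole_metrics(m, subset = config$subset,
                             threshold = config$threshold)
        jsonlite::write_json(
          list(label = lab, subset = mets$subset,
               threshold = mets$threshold,
               mean_angle_deg = mets$mean_angle_deg,
               dispersion = mets$dispersion,
               top5_mean_distance = mets$top5_mean_distance,
               n_off_unit_circle = mets$n_off_unit_circle,
               n_stable = mets$n_stable, n_unstable = mets$n_unstable,
               r_squared = m$r_squared),
          paste0(stem, "_metrics.json"), auto_unbox = TRUE, digits = NA)
        say("fit [%s / %s]: N = %d, d = %.6g, R^2 = %.6f",
            tag, lab, m$n_components, m$scale_d, m$r_squared)
        list(model = m, metrics = mets)
      }, error = function(e) { fail(path, paste0("fit:", lab), e); NULL })
      if (!is.null(res)) models[[lab]] <- res
    }
    tfres <- NULL
    if (all(c("pressure", "volume") %in% names(models))) {
      tfres <- tryCatch({
        tf <- build_transfer_function(models$pressure$model,
                                      models$volume$model)
        stem <- file.path(config$out_dir, tag)
        jsonlite::write_json(
          list(numerator_components = tf$numerator_components,
               denominator_components = tf$denominator_components,
               pressure_poles = cbind(Re(tf$pressure_poles),
                                      Im(tf$pressure_poles)),
               volume_poles = cbind(Re(tf$volume_poles),
                                    Im(tf$volume_poles)),
               sampling_rate = tf$sampling_rate),
          paste0(stem, "_transfer.json"), auto_unbox = TRUE, digits = NA)
        bc <- bode(tf, config$bode_grid[1L], config$bode_grid[2L],
                   config$bode_grid[3L])
        utils::write.table(bc, paste0(stem, "_bode.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        say("transfer [%s]: Bode %g-%g Hz written", tag,
            config$bode_grid[1L], config$bode_grid[2L])
        list(transfer = tf, bode = bc)
      }, error = function(e) { fail(path, "transfer", e); NULL })
    }
    results[[tag]] <- list(models = models, transfer = tfres)
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(input = character(), stage = character(),
               message = character())
  invisible(list(results = results, failures = failures))
}
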