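#' Write / read acceleration traces as CSV
#'
#' The trace format has a header row `time_s,accel_g,pattern` and one row
#' per sample. Values round-trip at 15 significant digits.
#'
#' @param trace an [accel_trace()].
#' @param path CSV file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns the validated [accel_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  t <- (seq_along(trace$samples) - 1) / trace$sample_rate
  data.table::fwrite(
    data.table::data.table(time_s = t, accel_g = trace$samples,
                           pattern = trace$labels),
    path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- data.table::fread(path)
  need <- c("time_s", "accel_g", "pattern")
  if (!all(need %in% names(d))) {
    stop("malformed trace CSV: expected columns ",
         paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(d$accel_g) | !is.finite(d$time_s))
  if (length(bad)) {
    stop("non-finite value(s) in trace at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop("non-monotonic time column")
  rate <- 1 / stats::median(dt)
  if (max(abs(dt - 1 / rate)) > 1e-6 / rate) {
    stop("non-uniform sampling: timestamps deviate from a fixed rate")
  }
  pat <- unique(match_pattern(d$pattern))
  if (length(pat) != 1L) stop("labels must be constant within a trial")
  accel_trace(d$accel_g, rate, pat,
              provenance = list(file = path,
                                duration = nrow(d) / rate))
}

#' Write / read a cohort directory
#'
#' Writes one trace CSV per trial plus a JSON manifest recording the
#' trial specifications, seeds and file names.
#'
#' @param cohort a `gait_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns a list with `trials` and `manifest`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$file <- sprintf("subj%02d_speed%s_%s.csv", man$subject,
                      gsub("\\.", "", format(man$speed)), man$pattern)
  for (r in seq_len(nrow(man))) {
    write_trace(cohort$trials[[r]], file.path(dir, man$file[r]))
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(master_seed = cohort$master_seed, trials = man),
    mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mpath)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  trials <- lapply(man$trials$file, function(f) {
    read_trace(file.path(dir, f))
  })
  structure(list(trials = trials, manifest = man$trials,
                 master_seed = man$master_seed),
            class = "gait_cohort")
}

#' Write / read reservoir activations as CSV
#'
#' Header `timestep,node_1..node_N`; one row per timestep.
#'
#' @param res a `reservoir_trace` (see [run_reservoir()]).
#' @param path CSV file path.
#' @param timestep_rate activation update rate (Hz) to attach on read.
#' @return `write_activations()` returns `path` invisibly;
#'   `read_activations()` returns a `reservoir_trace`.
#' @export
write_activations <- function(res, path) {
  stopifnot(inherits(res, "reservoir_trace"))
  A <- t(res$activations)
  colnames(A) <- paste0("node_", seq_len(ncol(A)))
  data.table::fwrite(
    cbind(data.table::data.table(timestep = seq_len(nrow(A))), A), path)
  invisible(path)
}

#' @rdname write_activations
#' @export
read_activations <- function(path, timestep_rate = 1 / 7e-3) {
  d <- data.table::fread(path)
  if (names(d)[1] != "timestep") stop("malformed activation CSV")
  reservoir_trace(t(as.matrix(d[, -1])), timestep_rate)
}

#' Write / read a trained readout model as JSON
#'
#' Stores the output weights (row-major), the leaking rate, ridge
#' parameter, moving-average window and detection thresholds.
#'
#' @param model a [readout_model()].
#' @param path JSON file path.
#' @return `write_readout_model()` returns `path` invisibly;
#'   `read_readout_model()` returns the [readout_model()].
#' @export
write_readout_model <- function(model, path) {
  stopifnot(inherits(model, "readout_model"))
  jsonlite::write_json(
    list(W_out = as.numeric(t(model$W_out)), dim = dim(model$W_out),
         alpha = model$alpha, beta = model$beta,
         avg_window = model$avg_window,
         thresholds = as.numeric(model$thresholds)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_readout_model
#' @export
read_readout_model <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(d$W_out, d$dim[1], d$dim[2], byrow = TRUE)
  readout_model(W, alpha = d$alpha, beta = d$beta,
                avg_window = d$avg_window,
                thresholds = c(TO = d$thresholds[1], TL = d$thresholds[2]))
}

#' Downsample the reference acceleration channel
#'
#' Reproduces the reference-channel preprocessing: a linear-phase FIR
#' low-pass at the post-decimation Nyquist frequency (symmetric
#' Hamming-window taps, group delay compensated), then decimation.
#'
#' @param trace an [accel_trace()] at the raw rate.
#' @param factor decimation factor (default 100: 14285 Hz to 142.85 Hz).
#' @param order FIR order (symmetric, `order + 1` taps); the default is
#'   sharp enough to keep the 0.5-15 Hz gait band, and tones up to ~50 Hz,
#'   within 1%.
#' @return an `accel_trace` at `sample_rate / factor`.
#' @export
downsample_reference <- function(trace, factor = 100L, order = 2000L) {
  stopifnot(inherits(trace, "accel_trace"))
  if (factor <= 0) stop("decimation factor must be positive")
  factor <- as.integer(factor)
  if (factor == 1L) return(trace)
  new_rate <- trace$sample_rate / factor
  h <- fir_lowpass(new_rate / 2, trace$sample_rate, order)
  n <- length(trace$samples)
  gd <- order / 2
  pad <- c(rep(trace$samples[1], gd), trace$samples,
           rep(trace$samples[n], gd))
  y <- stats::convolve(pad, rev(h), type = "open")
  y <- y[(2 * gd + 1):(2 * gd + n)]     # compensate group delay
  keep <- seq(1L, n, by = factor)
  out <- accel_trace(y[keep], new_rate, trace$pattern,
                     provenance = c(trace$provenance,
                                    list(downsampled_by = factor)))
  out
}

#' Pipeline configuration
#'
#' Assembles the per-stage parameters of an end-to-end run with the
#' device/protocol defaults. Any element can be overridden.
#'
#' @param method classifier to evaluate: `"surrogate"` (fast reservoir
#'   stand-in), `"mems"` (full beam physics), `"esn"`, or `"lr"`.
#' @param n_subjects,speeds,patterns,duration,sample_rate cohort layout.
#' @param master_seed seed for all randomness of the run.
#' @param alpha,beta readout leaking rate and ridge parameter.
#' @param avg_window,transient,k smoothing window, transient discard and
#'   fold count of the evaluation protocol.
#' @param out_dir optional output directory for the report and manifest.
#' @return a named list (class `pipeline_config`).
#' @export
pipeline_config <- function(method = c("surrogate", "mems", "esn", "lr"),
                            n_subjects = 10, speeds = 0.54,
                            patterns = gait_patterns(), duration = 60,
                            sample_rate = 142.85, master_seed = 1L,
                            alpha = 0.02, beta = 1e-2, avg_window = 300L,
                            transient = 1000L, k = 4L, out_dir = NULL) {
  method <- match.arg(method)
  structure(list(method = method, n_subjects = n_subjects, speeds = speeds,
                 patterns = patterns, duration = duration,
                 sample_rate = sample_rate,
                 master_seed = as.integer(master_seed), alpha = alpha,
                 beta = beta, avg_window = as.integer(avg_window),
                 transient = as.integer(transient), k = as.integer(k),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configurations")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the end-to-end classification pipeline
#'
#' Generates the synthetic cohort, produces the chosen classifier's
#' feature streams, and evaluates them under the shared cross-validated
#' protocol. With an `out_dir`, a run manifest (config snapshot, seeds,
#' timestamps) is written before the report JSON.
#'
#' @param config a [pipeline_config()] (or a list of overrides passed to
#'   it).
#' @return list with `report` (a `gait_eval`), `config` and the cohort
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  cohort <- generate_cohort(config$n_subjects, config$speeds,
                            config$patterns, config$master_seed,
                            duration = config$duration,
                            sample_rate = config$sample_rate)
  labels <- as.list(cohort$manifest$pattern)
  inputs <- lapply(cohort$trials, function(tr) tr$samples)
  cfg <- multiplex_config(rng_seed = hash_seed(config$master_seed, 1002))

  report <- switch(
    config$method,
    surrogate = {
      acts <- lapply(cohort$trials, function(tr) {
        surrogate_reservoir(tr, cfg)$activations
      })
      evaluate_readout(acts, labels, alpha = config$alpha,
                       beta = config$beta, k = config$k,
                       avg_window = config$avg_window,
                       transient = config$transient)
    },
    mems = {
      acts <- lapply(cohort$trials, function(tr) {
        run_reservoir(tr, cfg)$activations
      })
      evaluate_readout(acts, labels, alpha = config$alpha,
                       beta = config$beta, k = config$k,
                       avg_window = config$avg_window,
                       transient = config$transient)
    },
    esn = {
      ep <- esn_params(rng_seed = hash_seed(config$master_seed, 1001))
      evaluate_esn(inputs, labels, params = ep, beta = config$beta,
                   k = config$k, avg_window = config$avg_window,
                   transient = config$transient)
    },
    lr = {
      evaluate_lr(inputs, labels, sample_rate = config$sample_rate,
                  k = config$k, avg_window = config$avg_window,
                  transient = config$transient)
    }
  )

  out <- list(report = report, config = config, manifest = cohort$manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(config = unclass(config), timestamp = format(Sys.time()),
           version = as.character(utils::packageVersion("memsgait"))),
      file.path(config$out_dir, "run_manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    jsonlite::write_json(
      list(mean_auc = as.list(report$mean_auc),
           per_split_auc = report$per_split_auc,
           thresholds = report$thresholds,
           confusion = report$confusion),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
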