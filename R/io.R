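#' Load and validate a run configuration
#'
#' Reads a JSON configuration with blocks `model` (membrane parameters),
#' `fractional` (gate, eta, dt, truncation, divergence_bound), `protocol`
#' (either a current step: amplitude/onset/duration/total_time, or a voltage
#' clamp: hold_V/hold_duration/target_V/target_duration), `output`
#' (dir, decimation) and `log_level`. Missing fields take the standard
#' defaults; the empty object `{}` yields exactly the default model (classic
#' dynamics, dt = 0.001 ms, V init -65 mV). Unknown keys are rejected with
#' their location.
#'
#' @param path path to a JSON file.
#' @return A `run_config` list: `model` (`hh_params`), `fractional`
#'   (`fractional_config`), `protocol`, `output`, `log_level`.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("config must be a JSON object")
  validateConfig(cfg)
}

#' @rdname loadConfig
#' @param cfg a list as parsed from JSON.
#' @export
validateConfig <- function(cfg) {
  known <- c("model", "fractional", "protocol", "output", "log_level")
  reject_unknown(cfg, known, "$")

  model_fields <- c("C", "gNa_bar", "gK_bar", "gm", "ENa", "EK", "EL", "V0")
  reject_unknown(cfg$model, model_fields, "$model")
  model <- do.call(hhParams, as.list(cfg$model %||% list()))

  frac_fields <- c("gate", "eta", "dt", "truncation", "divergence_bound")
  reject_unknown(cfg$fractional, frac_fields, "$fractional")
  fr <- as.list(cfg$fractional %||% list())
  if (!is.null(fr$eta) && (!is.numeric(fr$eta) || fr$eta <= 0 || fr$eta > 1))
    stop("$fractional.eta must be in (0, 1], got ", fr$eta)
  fractional <- fractionalConfig(
    fractional_gate = fr$gate %||% "none",
    eta = fr$eta %||% 1,
    dt = fr$dt %||% 0.001,
    truncation = fr$truncation %||% "full",
    divergence_bound = fr$divergence_bound %||% 10)

  pr <- as.list(cfg$protocol %||% list())
  if (!is.null(pr$target_V)) {
    reject_unknown(pr, c("hold_V", "hold_duration", "target_V",
                         "target_duration"), "$protocol")
    protocol <- voltageClampProtocol(
      hold_V = pr$hold_V %||% 0, hold_duration = pr$hold_duration %||% 25,
      target_V = pr$target_V, target_duration = pr$target_duration %||% 110)
  } else {
    reject_unknown(pr, c("amplitude", "onset", "duration", "total_time"),
                   "$protocol")
    protocol <- stepCurrentProtocol(
      amplitude = pr$amplitude %||% 0, onset = pr$onset %||% 0,
      duration = pr$duration %||% 500,
      total_time = pr$total_time %||% ((pr$onset %||% 0) + (pr$duration %||% 500)))
  }

  out_fields <- c("dir", "decimation")
  reject_unknown(cfg$output, out_fields, "$output")
  output <- list(dir = cfg$output$dir %||% ".",
                 decimation = cfg$output$decimation %||% 1L)
  structure(list(model = model, fractional = fractional, protocol = protocol,
                 output = output, log_level = cfg$log_level %||% "info"),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reject_unknown <- function(block, known, where) {
  if (is.null(block)) return(invisible())
  extra <- setdiff(names(block), known)
  if (length(extra))
    stop(sprintf("unknown config key%s at %s: %s (allowed: %s)",
                 if (length(extra) > 1) "s" else "", where,
                 paste(extra, collapse = ", "), paste(known, collapse = ", ")))
  invisible()
}

#' Write and read simulation traces as CSV
#'
#' Traces round-trip losslessly: numbers are written with 17 significant
#' digits, enough to restore every double bit-exactly. Column order is
#' `t_ms,V_mV,n,m,h,INa,IK,IL,Iin` plus `memtrace` for fractional runs.
#'
#' @param trace a `sim_trace`.
#' @param path output CSV path.
#' @param decimation keep every k-th sample (default 1 = all).
#' @return `writeTrace` returns `path` invisibly; `readTrace` returns a
#'   data frame of class `sim_trace` (simulation metadata attributes are
#'   not stored in the CSV).
#' @export
writeTrace <- function(trace, path, decimation = 1L) {
  stopifnot(is.data.frame(trace), decimation >= 1)
  if (decimation > 1)
    trace <- trace[seq(1, nrow(trace), by = decimation), , drop = FALSE]
  cols <- vapply(trace, function(col) formatC(col, digits = 17, format = "g"),
                 character(nrow(trace)))
  lines <- c(paste(names(trace), collapse = ","),
             apply(matrix(cols, nrow = nrow(trace)), 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  need <- c("t_ms", "V_mV")
  if (!all(need %in% header))
    stop("malformed trace CSV (line 1): expected at least columns ",
         paste(need, collapse = ","))
  df <- tryCatch(read.csv(path, colClasses = "numeric"),
                 error = function(e)
                   stop("malformed trace CSV: ", conditionMessage(e)))
  structure(df, class = c("sim_trace", "data.frame"))
}

#' Write an analysis summary as JSON
#'
#' @param x a list (spike features, fit tables, ...).
#' @param path output path.
#' @export
writeSummary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
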