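#' Run configuration
#'
#' All tunable constants of the pipeline live in one flat configuration:
#' `delta` (semantic decay factor, default 0.5), `gamma_d` / `gamma_m`
#' (kernel bandwidth parameters, default 1), `norm` (`"l2"` or `"l1"`,
#' default `"l2"`), `log_base` (default e), and `similarity_threshold`
#' (the strict cut for "has similarity" counting, default 0). The defaults
#' are echoed into every CLI output header for provenance.
#'
#' @param ... Overrides of the default fields.
#' @return Named list of class `mda_config`.
#' @export
#' @examples
#' mda_config(delta = 0.4)
mda_config <- function(...) {
  cfg <- modifyList(list(delta = 0.5, gamma_d = 1, gamma_m = 1,
                         norm = "l2", log_base = exp(1),
                         similarity_threshold = 0), list(...))
  validate_config(cfg)
  structure(cfg, class = "mda_config")
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$delta) || cfg$delta <= 0 || cfg$delta >= 1) {
    abort("config field 'delta' must lie in (0, 1)", class = "mirec_usage_error")
  }
  for (f in c("gamma_d", "gamma_m")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(sprintf("config field '%s' must be positive", f), class = "mirec_usage_error")
    }
  }
  if (!cfg$norm %in% c("l2", "l1")) {
    abort("config field 'norm' must be 'l2' or 'l1'", class = "mirec_usage_error")
  }
  if (!is.numeric(cfg$log_base) || cfg$log_base <= 1) {
    abort("config field 'log_base' must exceed 1", class = "mirec_usage_error")
  }
  if (!is.numeric(cfg$similarity_threshold) || cfg$similarity_threshold < 0) {
    abort("config field 'similarity_threshold' must be >= 0", class = "mirec_usage_error")
  }
  invisible(cfg)
}

#' Read / write a flat key:value configuration file
#'
#' One `key: value` pair per line; unknown keys raise a usage error, and
#' `load(save(config))` round-trips losslessly.
#'
#' @param path File path.
#' @return [mda_config()] for `read_run_config`; `path` invisibly for
#'   `write_run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- stringr::str_split_fixed(lines, ":", 2)
  keys <- trimws(kv[, 1]); vals <- trimws(kv[, 2])
  known <- names(mda_config())
  bad <- setdiff(keys, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
          class = "mirec_usage_error")
  }
  cfg <- as.list(setNames(vals, keys))
  for (f in setdiff(keys, "norm")) cfg[[f]] <- as.numeric(cfg[[f]])
  do.call(mda_config, cfg)
}

#' @rdname read_run_config
#' @param config An [mda_config()].
#' @export
write_run_config <- function(config, path) {
  fmt <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s: %s", k, if (is.numeric(v)) format(v, digits = 17) else v)
  }, character(1))
  readr::write_lines(fmt, path)
  invisible(path)
}
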