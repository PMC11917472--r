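# Minimal key:value run configuration, used by the command-line interface.
# Precedence: built-in defaults < config file < command-line flags.

#' Read a key:value run configuration file
#'
#' One `key: value` pair per line; `#` starts a comment. Values are returned
#' as strings; numeric coercion is the caller's job.
#'
#' @param path Path to the config file.
#' @return Named list of values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad) > 0) {
    stop("malformed config line(s): ", paste(bad, collapse = "; "),
         call. = FALSE)
  }
  stats::setNames(lapply(kv, function(x) trimws(x[[3]])),
                  vapply(kv, `[[`, character(1), 2))
}
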