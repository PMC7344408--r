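#' Read a segmentation configuration from a flat key-value file
#'
#' INI-style `key = value` lines; `#` starts a comment; unknown keys are an
#' error. Booleans are `true`/`false` (case-insensitive).
#'
#' @param path Path to the config file.
#' @return A [segmentation_config()].
#' @export
read_segmentation_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop(sprintf("malformed config line: '%s'", lines[bad][1L]), call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- formals(segmentation_config)
  unknown <- setdiff(keys, names(args))
  if (length(unknown)) {
    stop(sprintf("unknown config key: '%s'", unknown[1L]), call. = FALSE)
  }
  parsed <- lapply(seq_along(keys), function(i) {
    if (tolower(vals[i]) %in% c("true", "false")) {
      tolower(vals[i]) == "true"
    } else {
      as.numeric(vals[i])
    }
  })
  names(parsed) <- keys
  do.call(segmentation_config, parsed)
}

#' Write a segmentation configuration as a flat key-value file
#'
#' @param config A [segmentation_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_config <- function(config, path) {
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 15)
  }
  writeLines(
    vapply(names(config), function(k) paste(k, "=", fmt(config[[k]])), ""),
    path
  )
  invisible(path)
}
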