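#' Stage logging
#'
#' Every pipeline stage reports its input/output record counts to stderr,
#' mirroring the count-driven structure of a gene-family survey.  Logging is
#' controlled by `options(gfam.verbose = TRUE/FALSE)` (default `TRUE`).
#'
#' @param fmt `sprintf` format string.
#' @param ... values interpolated into `fmt`.
#' @return `invisible(NULL)`.
#' @keywords internal
gf_log <- function(fmt, ...) {
  if (isTRUE(getOption("gfam.verbose", TRUE)))
    message("[gfam] ", sprintf(fmt, ...))
  invisible(NULL)
}

gf_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}
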