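stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' @keywords internal
check_percent <- function(x, what = "methylation percentage") {
  if (any(is.na(x)) || any(x < 0 | x > 100))
    stopf("%s values must lie in [0, 100] and not be NA", what)
  invisible(x)
}
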