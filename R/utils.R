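# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clamp p-values away from zero
#'
#' @param p numeric vector of p-values.
#' @param min_p smallest allowed value.
#' @param warn emit a warning when clamping occurs.
#' @return p with values below `min_p` replaced by `min_p`.
#' @keywords internal
clamp_p <- function(p, min_p = 1e-300, warn = TRUE) {
  bad <- which(p < min_p)
  if (length(bad)) {
    if (warn) warning(sprintf("%d p-value(s) below %g clamped", length(bad), min_p))
    p[bad] <- min_p
  }
  p
}

# Polynomial rolling hash (mod the Mersenne prime 2^31 - 1) of a character
# scalar, returned as 8 hex digits.  Stamps output files with a config
# fingerprint without external digest packages; doubles hold every
# intermediate exactly (max value < 2^42 < 2^53).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Comment block prepended to every file the tool writes (version, config
# fingerprint, seed) so runs are auditable.
provenance_header <- function(params = list(), seed = NA) {
  cfg <- paste(names(params), vapply(params, function(x) paste(format(x), collapse = ","),
                                     character(1)), sep = "=", collapse = "; ")
  c(sprintf("# dese %s", as.character(utils::packageVersion("dese"))),
    sprintf("# config_hash=%s", config_hash(cfg)),
    sprintf("# seed=%s", format(seed)),
    if (nzchar(cfg)) paste0("# ", cfg))
}

write_tsv_with_header <- function(df, path, params = list(), seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_comments <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

# Input/validation failures carry a condition class so the CLI can map them
# to exit status 2 while real bugs surface as status 1.
stop_input <- function(...) {
  stop(structure(class = c("dese_input_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}
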