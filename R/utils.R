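# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write named sequences as multi-FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(sequences), "\n", unname(sequences)), con)
  invisible(path)
}

# stable small digest of a config: multiplicative rolling hash over the JSON
# encoding, in 31-bit arithmetic (products stay below 2^53) so the value is
# identical on every platform
config_digest <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- (h * 69069 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
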