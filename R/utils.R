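#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' ("half-up" for positive values), the convention used for all printed
#' percentages in this package. Base [round()] uses round-half-to-even,
#' which would print e.g. 0.25 as 0.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(100 * 544 / 1057)  # 51.5
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Shared error constructor: all package errors carry class "arvscan_error"
# plus a specific subclass so callers (and the CLI) can branch on them.
arv_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "arvscan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Write a data.frame as TSV with a '#'-prefixed provenance header.
# Header lines are deterministic (no timestamps) so re-runs are
# byte-identical.
write_tsv_provenance <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# arvscan schema=1 table=%s",
                     sub("\\.tsv$", "", basename(path))), con)
  for (nm in names(params)) {
    writeLines(sprintf("# %s=%s", nm, paste(params[[nm]], collapse = ";")),
               con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Read a TSV, skipping '#' comment/provenance lines.
read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
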