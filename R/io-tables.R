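#' Read a missense mutation table
#'
#' Accepts two CSV dialects and returns the same normalized record layout:
#' either explicit columns `protein, ref_aa, position, alt_aa, source`, or a
#' compact token form with columns `protein, mutation, source` where
#' `mutation` is e.g. `"G733R"` (ref residue, position, alt residue). Extra
#' columns are ignored. Missing `source` values are kept as `NA`.
#'
#' @param path path to a CSV file with a header row.
#' @return data.frame with columns `protein`, `ref_aa`, `position`,
#'   `alt_aa`, `source`.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  cols <- tolower(names(df))
  names(df) <- cols
  if (all(c("protein", "ref_aa", "position", "alt_aa") %in% cols)) {
    out <- data.frame(protein = as.character(df$protein),
                      ref_aa = toupper(df$ref_aa),
                      position = suppressWarnings(as.numeric(df$position)),
                      alt_aa = toupper(df$alt_aa),
                      source = if ("source" %in% cols)
                        as.character(df$source) else NA_character_,
                      stringsAsFactors = FALSE)
  } else if (all(c("protein", "mutation") %in% cols)) {
    m <- regmatches(df$mutation,
                    regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", df$mutation))
    bad <- which(lengths(m) != 4)
    if (length(bad) > 0) {
      stop(sprintf("row %d: cannot parse mutation token '%s'",
                   bad[1] + 1L, df$mutation[bad[1]]))
    }
    m <- do.call(rbind, m)
    out <- data.frame(protein = as.character(df$protein),
                      ref_aa = toupper(m[, 2]),
                      position = as.numeric(m[, 3]),
                      alt_aa = toupper(m[, 4]),
                      source = if ("source" %in% cols)
                        as.character(df$source) else NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    stop("mutation table needs columns (protein, ref_aa, position, alt_aa) ",
         "or (protein, mutation)")
  }
  bad <- which(!is.finite(out$position) | out$position <= 0 |
                 out$position != round(out$position))
  if (length(bad) > 0) {
    stop(sprintf("row %d: position must be a positive integer (got '%s')",
                 bad[1] + 1L, df$position[bad[1]]))
  }
  out$position <- as.integer(out$position)
  out
}

#' Write records to CSV or TSV
#'
#' Round-trips with [read_mutation_table()] (and the other readers) up to
#' column order. The delimiter follows the file extension (`.tsv` gives tabs).
#'
#' @param records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_records <- function(records, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(records, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
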