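#' @importFrom stats sd setNames
#' @importFrom utils read.table write.table head read.csv
NULL

ALN_ALPHABET <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X", "-")

#' Construct a reference alignment
#'
#' A `ref_alignment` holds gapped, equal-length protein sequences together
#' with (possibly nested and overlapping) group memberships. It is the
#' coordinate system for every downstream stage: topology codes, conservation
#' profiles, signatures, and mutation mapping are all expressed in its
#' columns.
#'
#' @param seqs named character vector of aligned sequences (names are ids).
#' @param groups named list mapping group name to a character vector of
#'   member ids. A sequence may belong to several nested groups.
#' @return An object of class `ref_alignment` with elements `ids`, `seqs`,
#'   `n_columns` and `groups`.
#' @export
ref_alignment <- function(seqs, groups = list()) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  seqs <- vapply(seqs, function(s) gsub(".", "-", toupper(s), fixed = TRUE),
                 character(1))
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1) {
    bad <- names(seqs)[widths != widths[1]][1]
    stop(sprintf("ragged alignment: sequence '%s' has width %d, expected %d",
                 bad, nchar(seqs[bad]), widths[1]))
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  unknown <- setdiff(chars, ALN_ALPHABET)
  if (length(unknown) > 0) {
    stop(sprintf("alphabet error: unknown symbol(s) %s",
                 paste(sQuote(unknown), collapse = ", ")))
  }
  groups <- lapply(groups, as.character)
  missing <- setdiff(unlist(groups), names(seqs))
  if (length(missing) > 0) {
    stop(sprintf("group table references absent id(s): %s",
                 paste(missing, collapse = ", ")))
  }
  structure(list(ids = names(seqs), seqs = seqs,
                 n_columns = unname(widths[1]), groups = groups),
            class = "ref_alignment")
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat(sprintf("Reference alignment: %d sequences x %d columns\n",
              length(x$ids), x$n_columns))
  if (length(x$groups) > 0) {
    cat("Groups:",
        paste(sprintf("%s (%d)", names(x$groups), lengths(x$groups)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param aln a `ref_alignment`.
#' @param ids optional subset of sequence ids (defaults to all, in order).
#' @return character matrix, one row per sequence, one column per alignment
#'   column.
#' @export
aln_matrix <- function(aln, ids = aln$ids) {
  stopifnot(inherits(aln, "ref_alignment"))
  missing <- setdiff(ids, aln$ids)
  if (length(missing) > 0) {
    stop("unknown sequence id(s): ", paste(missing, collapse = ", "))
  }
  m <- do.call(rbind, strsplit(aln$seqs[ids], ""))
  rownames(m) <- ids
  m
}

#' Members of a named group
#'
#' @param aln a `ref_alignment`.
#' @param group group name present in `aln$groups`, or a character vector of
#'   ids (passed through after validation).
#' @return character vector of sequence ids.
#' @export
group_members <- function(aln, group) {
  stopifnot(inherits(aln, "ref_alignment"))
  if (length(group) == 1 && group %in% names(aln$groups)) {
    return(aln$groups[[group]])
  }
  missing <- setdiff(group, aln$ids)
  if (length(missing) > 0) {
    stop(sprintf("unknown group or id(s): %s", paste(missing, collapse = ", ")))
  }
  group
}

parse_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^# STOCKHOLM", lines[1])) {
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  }
  seqs <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || grepl("^#", ln) || !nzchar(trimws(ln))) next
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(parts) != 2) stop("malformed Stockholm sequence line: ", ln)
    id <- parts[1]
    if (id %in% names(seqs)) {
      seqs[id] <- paste0(seqs[id], parts[2])  # interleaved blocks
    } else {
      seqs[id] <- parts[2]
    }
  }
  if (length(seqs) == 0) stop("Stockholm file contains no sequences: ", path)
  seqs
}

#' Read a reference alignment
#'
#' Reads a gapped protein alignment from FASTA or Stockholm and optionally
#' attaches group labels from a two-column TSV (`id`, `tag`); a sequence may
#' carry several tags (one row per tag). `.` gap characters are normalized to
#' `-`. Sequence order is preserved.
#'
#' @param path path to the alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @param group_table optional path to a headerless TSV with columns id, tag.
#' @return a [ref_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm"),
                           group_table = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(ss), sub("[ \t].*$", "", names(ss)))
  } else {
    seqs <- parse_stockholm(path)
  }
  groups <- list()
  if (!is.null(group_table)) {
    gt <- read.table(group_table, sep = "\t", header = FALSE,
                     col.names = c("id", "tag"), stringsAsFactors = FALSE)
    groups <- split(gt$id, gt$tag)
  }
  ref_alignment(seqs, groups)
}

#' Write an alignment to FASTA
#'
#' @param aln a `ref_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "ref_alignment"))
  writeLines(as.vector(rbind(paste0(">", aln$ids), unname(aln$seqs))), path)
  invisible(path)
}

#' Write group labels as a TSV
#'
#' One row per (id, tag) pair, the inverse of the `group_table` argument of
#' [read_alignment()].
#'
#' @param aln a `ref_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(aln, path) {
  stopifnot(inherits(aln, "ref_alignment"))
  rows <- do.call(rbind, lapply(names(aln$groups), function(g) {
    data.frame(id = aln$groups[[g]], tag = g, stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
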