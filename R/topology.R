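#' Parse a topology code
#'
#' Topology codes name structurally equivalent alignment positions as
#' `LOBE.KIND<index>.<position>[.<insertion>]`, e.g. `N.H7.2` is the second
#' position of the seventh helix of the N-lobe, and `C.H1.2.1` is the first
#' inserted column after `C.H1.2` (used where the alignment has no anchor
#' position).
#'
#' @param text a single code string.
#' @return object of class `topology_code`: list with `lobe` (`"N"`/`"C"`),
#'   `kind` (`"H"`/`"S"`/`"L"`), `sse_index`, `position`, `insertion_index`
#'   (`NA` when absent).
#' @export
parse_topology_code <- function(text) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  parts <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (length(parts) < 3 || length(parts) > 4) {
    stop("parse error in topology code '", text,
         "': expected LOBE.SSE.position[.insertion]")
  }
  lobe <- parts[1]
  if (!lobe %in% c("N", "C")) {
    stop("parse error in topology code '", text, "': unknown lobe '", lobe, "'")
  }
  kind <- substr(parts[2], 1, 1)
  if (!kind %in% c("H", "S", "L")) {
    stop("parse error in topology code '", text,
         "': unknown SSE kind '", kind, "'")
  }
  idx <- substr(parts[2], 2, nchar(parts[2]))
  if (!grepl("^[0-9]+$", idx) || as.integer(idx) < 1) {
    stop("parse error in topology code '", text,
         "': non-numeric SSE index '", idx, "'")
  }
  pos <- parts[3]
  if (!grepl("^[0-9]+$", pos) || as.integer(pos) < 1) {
    stop("parse error in topology code '", text,
         "': non-numeric position '", pos, "'")
  }
  ins <- NA_integer_
  if (length(parts) == 4) {
    if (!grepl("^[0-9]+$", parts[4]) || as.integer(parts[4]) < 1) {
      stop("parse error in topology code '", text,
           "': non-numeric insertion index '", parts[4], "'")
    }
    ins <- as.integer(parts[4])
  }
  structure(list(lobe = lobe, kind = kind, sse_index = as.integer(idx),
                 position = as.integer(pos), insertion_index = ins),
            class = "topology_code")
}

#' Format a topology code
#'
#' Inverse of [parse_topology_code()]: `format_topology_code(parse_topology_code(x))`
#' is `x` for every valid code.
#'
#' @param code a `topology_code`.
#' @return the canonical code string.
#' @export
format_topology_code <- function(code) {
  stopifnot(inherits(code, "topology_code"))
  base <- sprintf("%s.%s%d.%d", code$lobe, code$kind, code$sse_index,
                  code$position)
  if (!is.na(code$insertion_index)) {
    base <- sprintf("%s.%d", base, code$insertion_index)
  }
  base
}

#' @export
format.topology_code <- function(x, ...) format_topology_code(x)

#' @export
print.topology_code <- function(x, ...) {
  cat(format_topology_code(x), "\n")
  invisible(x)
}

#' Build the topology map from an anchored alignment
#'
#' Assigns one topology code to every alignment column at or after the first
#' column where the anchor sequence has a residue. Helix/strand spans are
#' supplied in anchor residue numbering; residues between annotated spans are
#' auto-assigned loop (`L`) codes. Within each lobe, helices, strands and
#' loops are independently numbered in order of appearance, and positions are
#' numbered 1..k within each element. Columns where the anchor is gapped
#' inherit the preceding anchored code with insertion indices 1, 2, ...;
#' columns before the first anchored column are rejected (trim the alignment).
#'
#' @param alignment a [ref_alignment()].
#' @param anchor_id id of the anchor sequence within `alignment`.
#' @param anchor_sse data.frame with columns `lobe` (`"N"`/`"C"`), `kind`
#'   (`"H"`/`"S"`), `start`, `end` (anchor residue numbers, ascending,
#'   non-overlapping).
#' @param anchor_domains data.frame with columns `domain`, `start`, `end`
#'   (anchor residue numbers) covering all anchor residues.
#' @return object of class `topology_map`: `codes` (character vector by
#'   column), `columns` (named integer vector by code), `domain_of` and
#'   `sse_of` (named character vectors by code), plus the anchor bookkeeping.
#' @export
build_topology_map <- function(alignment, anchor_id, anchor_sse,
                               anchor_domains) {
  stopifnot(inherits(alignment, "ref_alignment"))
  if (!anchor_id %in% alignment$ids) stop("anchor id not in alignment")
  stopifnot(all(c("lobe", "kind", "start", "end") %in% names(anchor_sse)))
  stopifnot(all(c("domain", "start", "end") %in% names(anchor_domains)))
  sse <- anchor_sse[order(anchor_sse$start), , drop = FALSE]
  if (any(sse$end < sse$start)) stop("input error: SSE span with end < start")
  if (nrow(sse) > 1 && any(sse$start[-1] <= sse$end[-nrow(sse)])) {
    stop("input error: overlapping SSE spans")
  }
  if (!all(sse$kind %in% c("H", "S"))) {
    stop("input error: anchor spans must be H or S (loops are derived)")
  }
  anchor_row <- strsplit(alignment$seqs[[anchor_id]], "")[[1]]
  is_res <- anchor_row != "-"
  n_anchor <- sum(is_res)
  if (max(sse$end) > n_anchor) {
    stop(sprintf("input error: span end %d beyond anchor length %d",
                 max(sse$end), n_anchor))
  }
  c_spans <- sse[sse$lobe == "C", , drop = FALSE]
  first_c <- if (nrow(c_spans) > 0) min(c_spans$start) else n_anchor + 1L
  lobe_of_res <- ifelse(seq_len(n_anchor) >= first_c, "C", "N")

  # segment id per anchor residue: annotated spans, loops in the gaps
  seg_kind <- rep("L", n_anchor)
  seg_id <- integer(n_anchor)
  for (i in seq_len(nrow(sse))) {
    seg_kind[sse$start[i]:sse$end[i]] <- sse$kind[i]
    seg_id[sse$start[i]:sse$end[i]] <- i
  }
  # distinct runs of (kind, seg_id, lobe)
  run_break <- c(TRUE, seg_kind[-1] != seg_kind[-n_anchor] |
                   seg_id[-1] != seg_id[-n_anchor] |
                   lobe_of_res[-1] != lobe_of_res[-n_anchor])
  run <- cumsum(run_break)
  counters <- list(N = c(H = 0L, S = 0L, L = 0L),
                   C = c(H = 0L, S = 0L, L = 0L))
  codes_res <- character(n_anchor)
  sse_res <- character(n_anchor)
  for (r in unique(run)) {
    idx <- which(run == r)
    kind <- seg_kind[idx[1]]
    lobe <- lobe_of_res[idx[1]]
    counters[[lobe]][kind] <- counters[[lobe]][kind] + 1L
    sse_name <- sprintf("%s.%s%d", lobe, kind, counters[[lobe]][kind])
    sse_res[idx] <- sse_name
    codes_res[idx] <- sprintf("%s.%d", sse_name, seq_along(idx))
  }
  dom_res <- rep(NA_character_, n_anchor)
  for (i in seq_len(nrow(anchor_domains))) {
    dom_res[anchor_domains$start[i]:anchor_domains$end[i]] <-
      anchor_domains$domain[i]
  }
  if (anyNA(dom_res)) {
    stop("input error: anchor residues without a domain assignment")
  }

  # expand to alignment columns
  ncol_aln <- alignment$n_columns
  res_at_col <- cumsum(is_res)          # anchor residue number at/before column
  if (!is_res[1]) {
    stop(sprintf(paste0(
      "mapping error: %d alignment column(s) precede the first anchored ",
      "column; trim the alignment before building the topology map"),
      which(is_res)[1] - 1L))
  }
  codes <- character(ncol_aln)
  sse_col <- character(ncol_aln)
  dom_col <- character(ncol_aln)
  ins <- 0L
  for (col in seq_len(ncol_aln)) {
    r <- res_at_col[col]
    if (is_res[col]) {
      ins <- 0L
      codes[col] <- codes_res[r]
    } else {
      ins <- ins + 1L
      codes[col] <- sprintf("%s.%d", codes_res[r], ins)
    }
    sse_col[col] <- sse_res[r]
    dom_col[col] <- dom_res[r]
  }
  if (anyDuplicated(codes)) stop("internal error: duplicate topology codes")
  structure(list(codes = codes,
                 columns = setNames(seq_len(ncol_aln), codes),
                 domain_of = setNames(dom_col, codes),
                 sse_of = setNames(sse_col, codes),
                 anchor_id = anchor_id),
            class = "topology_map")
}

#' @export
print.topology_map <- function(x, ...) {
  cat(sprintf("Topology map: %d columns, anchor %s, domains %s\n",
              length(x$codes), x$anchor_id,
              paste(unique(x$domain_of), collapse = "/")))
  invisible(x)
}

protein_columns <- function(alignment, protein_id) {
  if (!protein_id %in% alignment$ids) {
    stop("unknown protein id: ", protein_id)
  }
  row <- strsplit(alignment$seqs[[protein_id]], "")[[1]]
  which(row != "-")
}

#' Translate a residue number to its topology code
#'
#' Counts the protein's non-gap residues up to `aa_number` to find its
#' alignment column, then looks up the column's code.
#'
#' @param protein_id sequence id in `alignment`.
#' @param aa_number residue number (1-based, ungapped).
#' @param alignment a [ref_alignment()].
#' @param topology_map a [build_topology_map()] result on the same alignment.
#' @return the code string.
#' @export
map_residue <- function(protein_id, aa_number, alignment, topology_map) {
  cols <- protein_columns(alignment, protein_id)
  if (aa_number < 1 || aa_number > length(cols)) {
    stop(sprintf("range error: residue %d outside 1..%d of %s",
                 aa_number, length(cols), protein_id))
  }
  topology_map$codes[cols[aa_number]]
}

#' Translate a topology code to a residue number
#'
#' Inverse of [map_residue()]; returns `NA` when the protein has a gap at the
#' code's column.
#'
#' @inheritParams map_residue
#' @param code a code string or `topology_code`.
#' @return integer residue number, or `NA_integer_`.
#' @export
code_to_residue <- function(protein_id, code, alignment, topology_map) {
  if (inherits(code, "topology_code")) code <- format_topology_code(code)
  if (!code %in% names(topology_map$columns)) {
    stop("unknown topology code: ", code)
  }
  col <- topology_map$columns[[code]]
  row <- strsplit(alignment$seqs[[protein_id]], "")[[1]]
  if (is.null(row)) stop("unknown protein id: ", protein_id)
  if (row[col] == "-") return(NA_integer_)
  sum(row[seq_len(col)] != "-")
}

#' Export a topology map as TSV
#'
#' Columns: `column`, `code`, `domain`, `sse_id`.
#'
#' @param topology_map a `topology_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology_map <- function(topology_map, path) {
  df <- data.frame(column = seq_along(topology_map$codes),
                   code = topology_map$codes,
                   domain = unname(topology_map$domain_of[topology_map$codes]),
                   sse_id = unname(topology_map$sse_of[topology_map$codes]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
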