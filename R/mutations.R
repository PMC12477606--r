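#' Map mutation rows onto topology coordinates and annotate
#'
#' Translates each missense record (protein, ref residue, residue number, alt
#' residue, source) into its topology code via the reference alignment, then
#' annotates it with every applicable signature membership (nested sets all
#' reported), the nucleic-acid-interface flag, and the SSE and domain of the
#' position. When the protein is present in the alignment the reference
#' residue is checked against the aligned sequence; mismatches become
#' record-level errors listing both residues. Unmappable rows (protein absent
#' or residue out of range) are returned in the `unmapped` attribute rather
#' than silently dropped.
#'
#' @param rows data.frame from [read_mutation_table()].
#' @param alignment a `ref_alignment`.
#' @param topology_map the corresponding `topology_map`.
#' @param signatures named list of `signature_set`s (e.g. universal, eAgo,
#'   AGO, mAGO, vAGO).
#' @param na_interface_codes character vector of interface topology codes.
#' @return data.frame with the input columns plus `code`, `sse`, `domain`,
#'   `signatures` (comma-joined memberships), `na_interface`; attribute
#'   `unmapped` holds the unmappable rows with a `reason` column.
#' @export
map_and_annotate <- function(rows, alignment, topology_map,
                             signatures = list(),
                             na_interface_codes = character(0)) {
  stopifnot(inherits(alignment, "ref_alignment"))
  out <- rows
  out$code <- NA_character_
  reason <- rep(NA_character_, nrow(rows))
  for (i in seq_len(nrow(rows))) {
    p <- rows$protein[i]
    if (!p %in% alignment$ids) {
      reason[i] <- "protein not in alignment"
      next
    }
    row <- strsplit(alignment$seqs[[p]], "")[[1]]
    cols <- which(row != "-")
    pos <- rows$position[i]
    if (pos < 1 || pos > length(cols)) {
      reason[i] <- sprintf("residue %d outside 1..%d", pos, length(cols))
      next
    }
    seq_res <- row[cols[pos]]
    if (seq_res != "X" && toupper(rows$ref_aa[i]) != seq_res) {
      stop(sprintf(
        "ref mismatch for %s position %d: record says %s, sequence has %s",
        p, pos, rows$ref_aa[i], seq_res))
    }
    out$code[i] <- topology_map$codes[cols[pos]]
  }
  mapped <- !is.na(out$code)
  unmapped <- cbind(rows[!mapped, , drop = FALSE],
                    reason = reason[!mapped])
  out <- out[mapped, , drop = FALSE]
  sig_of <- function(code) {
    hits <- names(signatures)[vapply(signatures, function(s)
      code %in% s$entries$code, logical(1))]
    paste(hits, collapse = ",")
  }
  out$signatures <- vapply(out$code, sig_of, character(1))
  out$na_interface <- out$code %in% na_interface_codes
  out$sse <- unname(topology_map$sse_of[out$code])
  out$domain <- unname(topology_map$domain_of[out$code])
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Cancer-exclusive topology positions
#'
#' A topology position is cancer-exclusive when it carries at least one
#' somatic cancer mutation and NO population-variation mutation at that
#' position in ANY protein of the paralog set (e.g. the four human AGOs).
#'
#' @param cancer_records,variation_records annotated records (from
#'   [map_and_annotate()]) with `protein` and `code` columns.
#' @param paralog_set character vector of paralog protein ids; both record
#'   sets are restricted to these proteins.
#' @return sorted character vector of exclusive codes.
#' @export
cancer_exclusive <- function(cancer_records, variation_records, paralog_set) {
  if (length(paralog_set) == 0) stop("input error: empty paralog set")
  cc <- cancer_records[cancer_records$protein %in% paralog_set, , drop = FALSE]
  vv <- variation_records[variation_records$protein %in% paralog_set, ,
                          drop = FALSE]
  sort(setdiff(unique(cc$code), unique(vv$code)))
}

#' Mutation density per domain
#'
#' Density of records in a domain, normalized by domain size and dataset
#' size: `(records in domain / records total) / (positions in domain /
#' positions total)`. A uniform spread over positions gives density 1
#' everywhere. Computed separately per `source` when several are present.
#'
#' @param records annotated records with `code` and `source`.
#' @param topology_map the `topology_map` providing domain sizes (counted
#'   over anchored, non-insertion codes).
#' @return data.frame `source`, `domain`, `density`.
#' @export
domain_distribution <- function(records, topology_map) {
  if (nrow(records) == 0) stop("input error: empty record set")
  dom_all <- topology_map$domain_of
  n_total <- length(dom_all)
  dom_share <- table(dom_all) / n_total
  src <- if ("source" %in% names(records)) records$source else "all"
  src[is.na(src)] <- "unspecified"
  out <- list()
  for (s in unique(src)) {
    rec <- records[src == s, , drop = FALSE]
    rec_dom <- unname(dom_all[rec$code])
    rec_share <- table(factor(rec_dom, levels = names(dom_share))) / nrow(rec)
    out[[length(out) + 1]] <- data.frame(
      source = s, domain = names(dom_share),
      density = as.numeric(rec_share / as.numeric(dom_share)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Categorize speckle-formation outcomes for a variant panel
#'
#' For each variant, the per-image speckle counts are compared to the
#' wild-type control with a one-sided Wilcoxon rank-sum test (alternative:
#' mutant counts lower). P-values are Benjamini-Hochberg adjusted jointly
#' across the panel. With `ratio = mean(mutant)/mean(WT)` the category is:
#' Impaired (significant and ratio < 0.25), Reduced (significant and
#' 0.25 <= ratio < 0.50), Retained (all other cases). Ties are handled by
#' midranks with a normal approximation and continuity correction for more
#' than 8 images per arm; smaller panels use the exact distribution.
#'
#' @param mutant_counts named list: variant id -> integer vector of per-image
#'   speckle counts (>= 3 images).
#' @param wt_counts integer vector of per-image wild-type counts (>= 3).
#' @param alpha significance level for the adjusted p-value (default 0.05).
#' @return data.frame `variant`, `ratio`, `p_value`, `p_adjusted`,
#'   `category`.
#' @export
categorize_speckles <- function(mutant_counts, wt_counts, alpha = 0.05) {
  stopifnot(is.list(mutant_counts), length(mutant_counts) >= 1)
  if (length(wt_counts) < 3) stop("need >= 3 wild-type images")
  if (any(lengths(mutant_counts) < 3)) stop("need >= 3 images per variant")
  if (mean(wt_counts) == 0) stop("undefined ratio: all-zero WT counts")
  pvals <- vapply(mutant_counts, function(x) {
    exact <- length(x) <= 8 && length(wt_counts) <= 8 &&
      !any(duplicated(c(x, wt_counts)))
    suppressWarnings(
      stats::wilcox.test(x, wt_counts, alternative = "less",
                         exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  padj <- stats::p.adjust(pvals, method = "BH")
  ratio <- vapply(mutant_counts, mean, numeric(1)) / mean(wt_counts)
  category <- ifelse(padj < alpha & ratio < 0.25, "Impaired",
                     ifelse(padj < alpha & ratio < 0.50, "Reduced",
                            "Retained"))
  data.frame(variant = names(mutant_counts), ratio = unname(ratio),
             p_value = unname(pvals), p_adjusted = unname(padj),
             category = unname(category), stringsAsFactors = FALSE)
}
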