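#' Detect signature candidate columns
#'
#' A column is a candidate of a group's signature when its conservation
#' strictly exceeds the group's own mean plus `k` standard deviations
#' (default `k = 2`): `NCS_p > mNCS + k * sdNCS`.
#'
#' @param profile a [group_profile()] result.
#' @param k threshold multiplier (default 2).
#' @return ascending integer vector of candidate columns.
#' @export
detect_candidates <- function(profile, k = 2) {
  stopifnot(inherits(profile, "conservation_profile"))
  thr <- profile$mncs + k * profile$sdncs
  which(profile$ncs > thr)
}

column_consensus <- function(col) {
  col <- col[col != "-" & col != "X"]
  if (length(col) == 0) return(NA_character_)
  tab <- sort(table(col), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)  # tie
  names(tab)[1]
}

#' Construct a signature set
#'
#' Container for a group's signature positions: one row per position with its
#' alignment column, topology code (optional), consensus residue and group
#' NCS. Usually produced by [build_signature()] or [universal_signature()];
#' the constructor is exported so externally curated signatures can enter the
#' pipeline.
#'
#' @param group group name.
#' @param parents character vector of higher-order group names.
#' @param entries data.frame with columns `column`, `code`, `consensus`,
#'   `ncs`.
#' @return object of class `signature_set`.
#' @export
new_signature_set <- function(group, parents, entries) {
  stopifnot(all(c("column", "consensus") %in% names(entries)))
  if (anyDuplicated(entries$column)) {
    stop("signature entries must be unique by position")
  }
  if (!"code" %in% names(entries)) {
    entries$code <- rep(NA_character_, nrow(entries))
  }
  if (!"ncs" %in% names(entries)) entries$ncs <- rep(NA_real_, nrow(entries))
  structure(list(group = group, parents = parents, entries = entries),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("Signature set '%s': %d positions", x$group, nrow(x$entries)))
  if (length(x$parents) > 0) {
    cat(" (parents:", paste(x$parents, collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' Build a group signature with hierarchical exclusion
#'
#' For each candidate column the group consensus (modal non-gap residue;
#' ties exclude the position) is compared against every parent signature that
#' covers the same position. Positions conserved as the same residue in a
#' parent are excluded; positions with a different consensus are kept only
#' when the change is sufficient, i.e. `pBS(group consensus, parent
#' consensus) <= 0` for every parent that covers the position. Positions
#' absent from all parents are kept.
#'
#' @param group group name.
#' @param candidates integer vector of candidate columns
#'   (from [detect_candidates()]).
#' @param alignment a [ref_alignment()].
#' @param parent_signatures list of `signature_set`s of all higher-order
#'   groups, computed on the same alignment coordinates.
#' @param profile optional `conservation_profile` used to record each
#'   entry's NCS.
#' @param topology_map optional `topology_map` used to record codes.
#' @return a `signature_set`; `entries` has columns `column`, `code`,
#'   `consensus`, `ncs`.
#' @export
build_signature <- function(group, candidates, alignment,
                            parent_signatures = list(), profile = NULL,
                            topology_map = NULL) {
  stopifnot(inherits(alignment, "ref_alignment"))
  if (length(candidates) > 0 &&
      (min(candidates) < 1 || max(candidates) > alignment$n_columns)) {
    stop("input error: candidate column outside alignment")
  }
  members <- group_members(alignment, group)
  m <- aln_matrix(alignment, members)
  keep <- logical(length(candidates))
  consensus <- character(length(candidates))
  for (i in seq_along(candidates)) {
    cons <- column_consensus(m[, candidates[i]])
    consensus[i] <- if (is.na(cons)) NA_character_ else cons
    if (is.na(cons)) {
      keep[i] <- FALSE  # ambiguous consensus: excluded
      next
    }
    verdict <- TRUE
    for (ps in parent_signatures) {
      hit <- ps$entries[ps$entries$column == candidates[i], , drop = FALSE]
      if (nrow(hit) == 0) next
      if (hit$consensus[1] == cons) {
        verdict <- FALSE           # conserved as the same residue
        break
      }
      if (pbs(cons, hit$consensus[1]) > 0) {
        verdict <- FALSE           # not sufficiently changed
        break
      }
    }
    keep[i] <- verdict
  }
  cols <- candidates[keep]
  entries <- data.frame(
    column = cols,
    code = if (!is.null(topology_map)) topology_map$codes[cols]
           else rep(NA_character_, length(cols)),
    consensus = consensus[keep],
    ncs = if (!is.null(profile)) profile$ncs[cols]
          else rep(NA_real_, length(cols)),
    stringsAsFactors = FALSE)
  sig <- new_signature_set(group,
                           vapply(parent_signatures, function(p) p$group,
                                  character(1)),
                           entries)
  # hierarchy soundness, asserted post-hoc on every build
  for (ps in parent_signatures) {
    shared <- merge(sig$entries[, c("column", "consensus")],
                    ps$entries[, c("column", "consensus")], by = "column")
    stopifnot(all(shared$consensus.x != shared$consensus.y))
  }
  sig
}

#' Universal signature from kingdom ancestral sequences
#'
#' A position enters the universal signature when (a) the reconstructed
#' Bacteria, Archaea and Eukaryota ancestors all carry residues there whose
#' pairwise pBS scores are all strictly positive (`method = "min"`; with
#' `method = "mean"` the mean pairwise score must be positive), and (b) the
#' conservation over the full alignment exceeds `mNCS + k * sdNCS` with
#' `k = 1`. The consensus is the modal ancestor residue; three-way ties fall
#' back to the Eukaryota ancestor.
#'
#' @param ancestral_seqs named character vector of three aligned ancestral
#'   sequences; names must include `Bacteria`, `Archaea`, `Eukaryota`.
#' @param full_profile `conservation_profile` over all sequences.
#' @param k conservation threshold multiplier (default 1).
#' @param method `"min"` (all pairwise pBS > 0) or `"mean"`.
#' @param topology_map optional `topology_map` for code annotation.
#' @return a `signature_set` with group `"universal"` and no parents.
#' @export
universal_signature <- function(ancestral_seqs, full_profile, k = 1,
                                method = c("min", "mean"),
                                topology_map = NULL) {
  method <- match.arg(method)
  need <- c("Bacteria", "Archaea", "Eukaryota")
  if (!all(need %in% names(ancestral_seqs))) {
    stop("input error: ancestors must be named Bacteria, Archaea, Eukaryota")
  }
  width <- length(full_profile$ncs)
  rows <- lapply(ancestral_seqs[need], function(s) strsplit(toupper(s), "")[[1]])
  if (any(lengths(rows) != width)) {
    stop("input error: ancestor not aligned to reference width")
  }
  anc <- do.call(rbind, rows)
  thr <- full_profile$mncs + k * full_profile$sdncs
  cols <- integer(0); cons <- character(0)
  for (p in seq_len(width)) {
    res <- anc[, p]
    if (any(res == "-" | res == "X")) next
    scores <- c(pbs(res[1], res[2]), pbs(res[1], res[3]), pbs(res[2], res[3]))
    ok <- if (method == "min") all(scores > 0) else mean(scores) > 0
    if (!ok) next
    if (full_profile$ncs[p] <= thr) next
    tab <- sort(table(res), decreasing = TRUE)
    consensus <- if (tab[1] >= 2) names(tab)[1] else res[["Eukaryota"]]
    cols <- c(cols, p); cons <- c(cons, consensus)
  }
  entries <- data.frame(
    column = cols,
    code = if (!is.null(topology_map)) topology_map$codes[cols]
           else rep(NA_character_, length(cols)),
    consensus = cons, ncs = full_profile$ncs[cols],
    stringsAsFactors = FALSE)
  new_signature_set("universal", character(0), entries)
}

#' Score one aligned sequence against a signature set
#'
#' Mean over the signature entries of `pBS(consensus, residue)` at the
#' entry's column. A gap (or `X`) at a signature position is penalized with
#' the minimum value of the pBS matrix, so truncated sequences score low.
#'
#' @param seq an aligned sequence string (reference coordinates).
#' @param sig a `signature_set` with at least one entry.
#' @return a scalar mean score.
#' @export
score_sequence_against_signature <- function(seq, sig) {
  stopifnot(inherits(sig, "signature_set"))
  if (nrow(sig$entries) == 0) stop("input error: empty signature")
  row <- strsplit(toupper(seq), "")[[1]]
  if (max(sig$entries$column) > length(row)) {
    stop("input error: sequence shorter than signature coordinates")
  }
  floor_score <- min(pbs_matrix())
  scores <- mapply(function(col, cons) {
    r <- row[col]
    if (r == "-" || r == "X") floor_score else pbs(cons, r)
  }, sig$entries$column, sig$entries$consensus)
  mean(scores)
}

#' Cross-family signature and contact-network comparison
#'
#' Compares a second protein family (aligned in its own coordinates but
#' structurally anchored to the topology through `anchor_mapping`) against
#' Argonaute signature sets and SCNs: for each signature set the mean
#' [score_sequence_against_signature()] over all family sequences (signature
#' positions whose code is absent from the mapping are skipped), and for each
#' SCN the fraction of its edges present in the family's contact set.
#'
#' @param family_alignment `ref_alignment` of the second family.
#' @param anchor_mapping named integer vector: topology code -> family
#'   alignment column (from a structural alignment of one representative).
#' @param signature_sets named list of `signature_set`s (entries must carry
#'   codes).
#' @param scn_sets named list of `scn` objects.
#' @param family_contact_set data.frame with columns `code_i`, `code_j`
#'   (the family's residue contacts in topology coordinates).
#' @return data.frame with columns `set`, `kind`, `mean_score`,
#'   `contact_overlap`.
#' @export
cross_family_report <- function(family_alignment, anchor_mapping,
                                signature_sets = list(), scn_sets = list(),
                                family_contact_set = NULL) {
  stopifnot(inherits(family_alignment, "ref_alignment"))
  if (length(anchor_mapping) == 0) stop("input error: empty anchor mapping")
  rows <- list()
  for (nm in names(signature_sets)) {
    sig <- signature_sets[[nm]]
    mapped <- sig$entries[sig$entries$code %in% names(anchor_mapping), ,
                          drop = FALSE]
    if (nrow(mapped) == 0) {
      rows[[length(rows) + 1]] <- data.frame(set = nm, kind = "signature",
                                             mean_score = NA_real_,
                                             contact_overlap = NA_real_)
      next
    }
    fam_sig <- new_signature_set(sig$group, character(0), data.frame(
      column = unname(anchor_mapping[mapped$code]),
      code = mapped$code, consensus = mapped$consensus, ncs = mapped$ncs,
      stringsAsFactors = FALSE))
    scores <- vapply(family_alignment$seqs,
                     score_sequence_against_signature, numeric(1),
                     sig = fam_sig)
    rows[[length(rows) + 1]] <- data.frame(set = nm, kind = "signature",
                                           mean_score = mean(scores),
                                           contact_overlap = NA_real_)
  }
  for (nm in names(scn_sets)) {
    ov <- if (is.null(family_contact_set)) NA_real_ else
      scn_overlap(family_contact_set, scn_sets[[nm]])
    rows[[length(rows) + 1]] <- data.frame(set = nm, kind = "scn",
                                           mean_score = NA_real_,
                                           contact_overlap = ov)
  }
  do.call(rbind, rows)
}

#' Export a signature set as TSV
#'
#' Columns: `group`, `column`, `code`, `consensus`, `ncs`.
#'
#' @param sig a `signature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  df <- cbind(group = sig$group, sig$entries)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
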