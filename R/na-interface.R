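# Nucleotide backbone atoms (phosphate + sugar); O2' marks the ribose 2'-OH.
NA_BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "C5'", "C4'",
                       "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")

#' Label a guide nucleotide position
#'
#' Guide positions are numbered from the 5' end, except the last three, which
#' are counted from the 3' end as `3T`, `3T-1` and `3T-2` so that 3'-PAZ
#' anchoring stays comparable between guides of different lengths.
#'
#' @param guide_length guide length `n` (>= 4).
#' @param nucleotide_index position `i` from the 5' end (1-based).
#' @return label string.
#' @export
label_guide <- function(guide_length, nucleotide_index) {
  n <- guide_length; i <- nucleotide_index
  if (n < 4) stop("guide length must be >= 4")
  if (i < 1 || i > n) {
    stop(sprintf("nucleotide index %d out of range 1..%d", i, n))
  }
  if (i == n) return("3T")
  if (i == n - 1) return("3T-1")
  if (i == n - 2) return("3T-2")
  as.character(i)
}

#' Label target nucleotides from a pairing annotation
#'
#' A target position matched to guide position `k` is labelled `-k`; an
#' annotated bulge or mismatch opposite guide position `k` is labelled `B-k`
#' and flagged excluded (kept in outputs, dropped from aggregate statistics).
#' Base pairing is an input annotation; it is not inferred from geometry.
#'
#' @param pairing data.frame with columns `resno` (target residue number),
#'   `matched_guide_index`, `is_bulge` (logical).
#' @param guide_length guide length, used to validate indices.
#' @return data.frame `resno`, `label`, `excluded`.
#' @export
label_target <- function(pairing, guide_length) {
  if (nrow(pairing) == 0) {
    return(data.frame(resno = integer(0), label = character(0),
                      excluded = logical(0)))
  }
  k <- pairing$matched_guide_index
  if (any(k < 1 | k > guide_length)) {
    stop("pairing references guide index outside guide length")
  }
  data.frame(resno = pairing$resno,
             label = ifelse(pairing$is_bulge, paste0("B-", k),
                            paste0("-", k)),
             excluded = as.logical(pairing$is_bulge),
             stringsAsFactors = FALSE)
}

#' Parse a nucleotide position label
#'
#' Inverse of [label_guide()]/[label_target()]: `"5"` is guide index 5,
#' `"3T"/"3T-1"/"3T-2"` are 3'-anchored guide offsets 0/1/2, `"-5"` is the
#' target position matching guide 5, `"B-5"` a bulged target opposite
#' guide 5.
#'
#' @param label a label string.
#' @return list with `strand` (`"guide"`/`"target"`), `kind` (`"index"`,
#'   `"three_prime"`, `"target_match"`, `"bulge"`), `value`.
#' @export
parse_na_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  if (grepl("^3T(-[12])?$", label)) {
    off <- if (label == "3T") 0L else as.integer(sub("^3T-", "", label))
    return(list(strand = "guide", kind = "three_prime", value = off))
  }
  if (grepl("^[0-9]+$", label)) {
    return(list(strand = "guide", kind = "index", value = as.integer(label)))
  }
  if (grepl("^-[0-9]+$", label)) {
    return(list(strand = "target", kind = "target_match",
                value = as.integer(sub("^-", "", label))))
  }
  if (grepl("^B-[0-9]+$", label)) {
    return(list(strand = "target", kind = "bulge",
                value = as.integer(sub("^B-", "", label))))
  }
  stop("cannot parse nucleotide label: ", label)
}

#' Extract protein-nucleic-acid interface contacts
#'
#' Runs the same geometric engine as [detect_atomic_contacts()] between the
#' protein chains and the guide/target nucleic chains, maps protein residues
#' to topology codes and nucleotides to position labels, classifies each
#' contacted nucleotide atom as backbone (phosphate/sugar atoms) or base, and
#' flags ribose `O2'` contacts (`c2oh`; C2'-OH contacts are backbone by
#' construction). Contacts to bulge-labelled target nucleotides carry
#' `excluded = TRUE`. For predicted models both partners must reach
#' `plddt_min`.
#'
#' @param model a `structure_model` with at least one nucleic chain.
#' @param code_lookup data.frame `resno`, `code` (optional `chain`) for the
#'   protein residues.
#' @param guide_chain chain id of the guide strand.
#' @param target_chain optional chain id of the target strand.
#' @param pairing pairing annotation for the target strand (see
#'   [label_target()]).
#' @param config a `contact_config`.
#' @param plddt_min confidence floor for predicted models.
#' @return data.frame of class `na_contact_set` with columns `code`, `label`,
#'   `types`, `part`, `c2oh`, `excluded`; attributes `structure_id`,
#'   `protein_id`.
#' @export
extract_na_contacts <- function(model, code_lookup, guide_chain,
                                target_chain = NULL, pairing = NULL,
                                config = default_contact_config(),
                                plddt_min = 80) {
  stopifnot(inherits(model, "structure_model"))
  nuc_chains <- names(model$chain_class)[model$chain_class == "nucleic"]
  if (length(nuc_chains) == 0) stop("input error: no nucleic chain in ",
                                    model$id)
  if (!guide_chain %in% nuc_chains) {
    stop("input error: guide chain ", guide_chain, " is not nucleic")
  }
  prot_chains <- names(model$chain_class)[model$chain_class == "protein"]
  prot <- model$atoms[model$atoms$chain %in% prot_chains, , drop = FALSE]

  # nucleotide labels per (chain, resno)
  guide_res <- sort(unique(model$atoms$resno[model$atoms$chain == guide_chain]))
  n_guide <- length(guide_res)
  labels <- data.frame(chain = guide_chain, resno = guide_res,
                       label = vapply(seq_len(n_guide), label_guide,
                                      character(1), guide_length = n_guide),
                       excluded = FALSE, stringsAsFactors = FALSE)
  if (!is.null(target_chain)) {
    if (is.null(pairing)) {
      stop("input error: target chain given without pairing annotation")
    }
    tl <- label_target(pairing, n_guide)
    labels <- rbind(labels, data.frame(chain = target_chain, resno = tl$resno,
                                       label = tl$label,
                                       excluded = tl$excluded,
                                       stringsAsFactors = FALSE))
  }
  nuc <- model$atoms[model$atoms$chain %in% c(guide_chain, target_chain), ,
                     drop = FALSE]
  atomic <- detect_contacts_between(prot, nuc, config, same_set = FALSE,
                                    nucleic_b = TRUE)
  empty <- data.frame(code = character(0), label = character(0),
                      types = character(0), part = character(0),
                      c2oh = logical(0), excluded = logical(0),
                      stringsAsFactors = FALSE)
  finish <- function(df) {
    attr(df, "structure_id") <- model$id
    attr(df, "protein_id") <- model$id
    class(df) <- c("na_contact_set", "data.frame")
    df
  }
  if (is.null(atomic) || nrow(atomic) == 0) return(finish(empty))

  if (model$source == "predicted") {
    conf <- model$confidence
    ckey <- paste(conf$chain, conf$resno)
    ci <- conf$conf[match(paste(atomic$chain_i, atomic$resno_i), ckey)]
    cj <- conf$conf[match(paste(atomic$chain_j, atomic$resno_j), ckey)]
    atomic <- atomic[!is.na(ci) & !is.na(cj) &
                       ci >= plddt_min & cj >= plddt_min, , drop = FALSE]
    if (nrow(atomic) == 0) return(finish(empty))
  }

  lookup_code <- function(chain, resno) {
    if ("chain" %in% names(code_lookup)) {
      hit <- code_lookup$code[code_lookup$chain == chain &
                                code_lookup$resno == resno]
    } else {
      hit <- code_lookup$code[code_lookup$resno == resno]
    }
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  code <- mapply(lookup_code, atomic$chain_i, atomic$resno_i)
  lkey <- paste(labels$chain, labels$resno)
  hit <- match(paste(atomic$chain_j, atomic$resno_j), lkey)
  keep <- !is.na(code) & !is.na(hit)
  if (any(!keep)) {
    message(sprintf("extract_na_contacts: dropped %d contact(s) without code/label",
                    sum(!keep)))
  }
  atomic <- atomic[keep, , drop = FALSE]
  if (nrow(atomic) == 0) return(finish(empty))
  code <- code[keep]; hit <- hit[keep]
  label <- labels$label[hit]
  excluded <- labels$excluded[hit]
  part <- ifelse(atomic$atom_j %in% NA_BACKBONE_ATOMS, "backbone", "base")
  c2oh <- atomic$atom_j == "O2'"
  key <- paste(code, label, part, c2oh)
  df <- data.frame(
    code = tapply(code, key, `[`, 1),
    label = tapply(label, key, `[`, 1),
    types = tapply(atomic$type, key,
                   function(v) paste(sort(unique(v)), collapse = ",")),
    part = tapply(part, key, `[`, 1),
    c2oh = as.logical(tapply(c2oh, key, `[`, 1)),
    excluded = as.logical(tapply(excluded, key, `[`, 1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  finish(df[order(df$code, df$label), , drop = FALSE])
}

na_active <- function(set) set[!set$excluded, , drop = FALSE]

#' Shared nucleic-acid interface positions
#'
#' Protein topology positions that contact the nucleic acid in at least one
#' structure of EACH of the two groups (bulge-labelled contacts never count).
#'
#' @param sets_a,sets_b non-empty lists of `na_contact_set`s for the two
#'   groups (e.g. eukaryotic and prokaryotic structures).
#' @return sorted character vector of topology codes.
#' @export
shared_interface <- function(sets_a, sets_b) {
  if (length(sets_a) == 0 || length(sets_b) == 0) {
    stop("input error: empty group")
  }
  pos <- function(sets) unique(unlist(lapply(sets,
                                             function(s) na_active(s)$code)))
  sort(intersect(pos(sets_a), pos(sets_b)))
}

#' Signature nucleic-acid interface edges
#'
#' Signature positions whose contact to the SAME nucleotide label occurs in
#' at least one representative of each of the two required subgroups.
#'
#' @param signature a `signature_set` with code annotation.
#' @param sets_a,sets_b non-empty lists of `na_contact_set`s.
#' @return data.frame `code`, `label`.
#' @export
signature_na_interface <- function(signature, sets_a, sets_b) {
  stopifnot(inherits(signature, "signature_set"))
  if (length(sets_a) == 0 || length(sets_b) == 0) {
    stop("input error: empty group")
  }
  edges <- function(sets) {
    unique(unlist(lapply(sets, function(s) {
      s <- na_active(s)
      paste(s$code, s$label, sep = "|")
    })))
  }
  common <- intersect(edges(sets_a), edges(sets_b))
  if (length(common) == 0) {
    return(data.frame(code = character(0), label = character(0)))
  }
  parts <- do.call(rbind, strsplit(common, "|", fixed = TRUE))
  df <- data.frame(code = parts[, 1], label = parts[, 2],
                   stringsAsFactors = FALSE)
  df <- df[df$code %in% signature$entries$code, , drop = FALSE]
  rownames(df) <- NULL
  df[order(df$code, df$label), , drop = FALSE]
}

#' Per-protein interface charge
#'
#' Mean positional net charge (Henderson-Hasselbalch, pH 7) of each protein's
#' residues at the given interface positions. One value per protein (the
#' per-protein averaging mirrors how interface charge distributions are
#' compared between groups).
#'
#' @param alignment a `ref_alignment`.
#' @param protein_ids sequence ids to evaluate.
#' @param codes character vector of interface topology codes.
#' @param topology_map the `topology_map` binding codes to columns.
#' @return named numeric vector of mean charges.
#' @export
interface_charge <- function(alignment, protein_ids, codes, topology_map) {
  cols <- topology_map$columns[codes]
  if (anyNA(cols)) stop("unknown topology code(s) in interface")
  vapply(protein_ids, function(id) {
    row <- strsplit(alignment$seqs[[id]], "")[[1]]
    positional_charge(row[cols])
  }, numeric(1))
}

#' Fraction of C2'-OH contacts among backbone contacts at a guide position
#'
#' Pooled over all supplied structures: the number of backbone contact edges
#' to `label` that touch the ribose `O2'` divided by all backbone contact
#' edges to `label`. Bulge-flagged edges never enter. With
#' `per_structure = TRUE` the fraction is computed per structure and
#' averaged.
#'
#' @param sets list of `na_contact_set`s.
#' @param label a guide position label (e.g. `"13"`, `"3T"`).
#' @param per_structure average per-structure fractions instead of pooling.
#' @return fraction in \[0, 1\].
#' @export
c2oh_fraction <- function(sets, label, per_structure = FALSE) {
  frac <- function(s) {
    s <- na_active(s)
    bb <- s[s$label == label & s$part == "backbone", , drop = FALSE]
    if (nrow(bb) == 0) return(c(0, 0))
    c(sum(bb$c2oh), nrow(bb))
  }
  counts <- vapply(sets, frac, numeric(2))
  if (per_structure) {
    ok <- counts[2, ] > 0
    if (!any(ok)) stop(sprintf(
      "undefined value: no backbone contacts to label %s (0 of %d structures)",
      label, length(sets)))
    return(mean(counts[1, ok] / counts[2, ok]))
  }
  if (sum(counts[2, ]) == 0) {
    stop(sprintf(
      "undefined value: no backbone contacts to label %s (0 edges in %d structures)",
      label, length(sets)))
  }
  sum(counts[1, ]) / sum(counts[2, ])
}

#' Fraction of backbone contacts among all contacts at a position label
#'
#' @inheritParams c2oh_fraction
#' @return fraction in \[0, 1\].
#' @export
backbone_fraction <- function(sets, label, per_structure = FALSE) {
  frac <- function(s) {
    s <- na_active(s)
    at <- s[s$label == label, , drop = FALSE]
    if (nrow(at) == 0) return(c(0, 0))
    c(sum(at$part == "backbone"), nrow(at))
  }
  counts <- vapply(sets, frac, numeric(2))
  if (per_structure) {
    ok <- counts[2, ] > 0
    if (!any(ok)) stop(sprintf(
      "undefined value: no contacts to label %s (0 of %d structures)",
      label, length(sets)))
    return(mean(counts[1, ok] / counts[2, ok]))
  }
  if (sum(counts[2, ]) == 0) {
    stop(sprintf(
      "undefined value: no contacts to label %s (0 edges in %d structures)",
      label, length(sets)))
  }
  sum(counts[1, ]) / sum(counts[2, ])
}
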