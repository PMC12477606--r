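AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# Side-chain pKa values used for Henderson-Hasselbalch positional charge.
PKA_TABLE <- c(K = 10.54, R = 12.48, H = 6.04, D = 3.65, E = 4.25,
               C = 8.3, Y = 10.07)

# Kyte-Doolittle hydropathy scale; scaled positional hydropathy is (KD+4.5)/9.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

.argonet_env <- new.env(parent = emptyenv())

blosum62_raw <- function() {
  if (is.null(.argonet_env$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .argonet_env$b62 <- e$BLOSUM62[AA20, AA20]
  }
  .argonet_env$b62
}

#' Normalized BLOSUM62 substitution matrix (pBS)
#'
#' The pairwise normalized BLOSUM score is
#' `pBS(a, b) = B62(a, b) / sqrt(B62(a, a) * B62(b, b))`, which is symmetric,
#' preserves the sign of the raw BLOSUM62 entry, and fixes the diagonal at 1
#' so that an exact consensus match scores 1. For BLOSUM62 all entries lie in
#' \[-1, 1\]. `pBS <= 0` is the operational definition of a "sufficiently
#' changed" residue used by the signature exclusion rules.
#'
#' @return 20x20 numeric matrix over the standard amino-acid alphabet.
#' @export
pbs_matrix <- function() {
  if (is.null(.argonet_env$pbs)) {
    b <- blosum62_raw()
    .argonet_env$pbs <- b / sqrt(outer(diag(b), diag(b)))
  }
  .argonet_env$pbs
}

#' Pairwise normalized BLOSUM62 score
#'
#' @param a,b single residue letters from the 20-residue alphabet.
#' @return `pBS(a, b)` as described in [pbs_matrix()].
#' @export
pbs <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!a %in% AA20 || !b %in% AA20) {
    stop(sprintf("undefined pBS score for pair (%s, %s): ", a, b),
         "only the 20 standard residues are scored")
  }
  pbs_matrix()[a, b]
}

# max(0, pBS) matrix used for conservation scoring
pbs_clamped <- function() {
  if (is.null(.argonet_env$pbs_pos)) {
    .argonet_env$pbs_pos <- pmax(pbs_matrix(), 0)
  }
  .argonet_env$pbs_pos
}

#' Normalized conservation score of one alignment column
#'
#' Mean over all unordered sequence pairs of `max(0, pBS(a, b))`. Pairs where
#' exactly one member is a gap contribute 0 (and count in the mean); gap-gap
#' pairs are excluded; pairs involving `X` contribute 0 (and count). An
#' all-gap column scores 0. The clamping at zero keeps the score in \[0, 1\];
#' all signature thresholds are relative (mean + k sd over columns), so the
#' monotone rescaling is harmless.
#'
#' @param column character vector of residues/gaps (one per sequence, >= 2).
#' @return a number in \[0, 1\].
#' @export
column_ncs <- function(column) {
  if (length(column) < 2) stop("need at least 2 sequences per column")
  column <- toupper(column)
  counts <- table(factor(column, levels = c(AA20, "X", "-")))
  n_gap <- counts[["-"]]
  n_res <- sum(counts) - n_gap
  total_pairs <- choose(n_res, 2) + n_res * n_gap  # gap-gap excluded
  if (total_pairs == 0) return(0)
  cts <- counts[AA20]
  m <- pbs_clamped()
  score <- sum(choose(cts, 2) * diag(m))
  off <- outer(cts, cts)
  score <- score + sum(off[upper.tri(off)] * m[upper.tri(m)])
  as.numeric(score / total_pairs)
}

#' Per-group conservation profile
#'
#' Computes the normalized conservation score (NCS) for every alignment
#' column over the members of one group, together with the mean (mNCS) and
#' sample standard deviation (sdNCS) over all columns. These summary values
#' set the group-relative thresholds for signature candidate detection.
#'
#' @param alignment a [ref_alignment()].
#' @param group group name or character vector of member ids (>= 2 members).
#' @return object of class `conservation_profile`: `group`, `ncs` (length =
#'   alignment width), `mncs`, `sdncs`, `n_sequences`.
#' @export
group_profile <- function(alignment, group) {
  stopifnot(inherits(alignment, "ref_alignment"))
  members <- group_members(alignment, group)
  if (length(members) < 2) {
    stop("input error: group must have at least 2 members")
  }
  m <- aln_matrix(alignment, members)
  ncs <- apply(m, 2, column_ncs)
  structure(list(group = if (length(group) == 1) group else "custom",
                 ncs = as.numeric(ncs),
                 mncs = mean(ncs), sdncs = sd(ncs),
                 n_sequences = length(members)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("Conservation profile '%s': %d sequences, %d columns, mNCS %.4f, sdNCS %.4f\n",
              x$group, x$n_sequences, length(x$ncs), x$mncs, x$sdncs))
  invisible(x)
}

#' Positional net charge (Henderson-Hasselbalch, pH 7)
#'
#' Per-residue side-chain charge at fixed pH 7: `+1/(1 + 10^(pH - pKa))` for
#' K/R/H and `-1/(1 + 10^(pKa - pH))` for D/E/C/Y, 0 otherwise; the result is
#' the mean over the non-gap residues supplied. Termini are excluded because
#' the statistic is positional.
#'
#' @param residues character vector of residues (gaps are skipped).
#' @param ph pH, default 7.
#' @return mean net charge.
#' @export
positional_charge <- function(residues, ph = 7.0) {
  residues <- toupper(residues)
  residues <- residues[residues != "-"]
  if (length(residues) == 0) stop("undefined value: all-gap input")
  charge_one <- function(r) {
    if (r %in% c("K", "R", "H")) {
      +1 / (1 + 10^(ph - PKA_TABLE[[r]]))
    } else if (r %in% c("D", "E", "C", "Y")) {
      -1 / (1 + 10^(PKA_TABLE[[r]] - ph))
    } else 0
  }
  mean(vapply(residues, charge_one, numeric(1)))
}

#' Mean scaled Kyte-Doolittle hydropathy
#'
#' Per residue `(KD + 4.5) / 9`, so isoleucine scores 1 and arginine 0; the
#' result is the mean over non-gap residues.
#'
#' @param residues character vector of residues (gaps are skipped).
#' @return value in \[0, 1\].
#' @export
scaled_hydropathy <- function(residues) {
  residues <- toupper(residues)
  residues <- residues[residues != "-"]
  if (length(residues) == 0) stop("undefined value: all-gap input")
  unknown <- setdiff(residues, names(KD_SCALE))
  if (length(unknown) > 0) {
    stop("no hydropathy value for: ", paste(unknown, collapse = ", "))
  }
  mean((KD_SCALE[residues] + 4.5) / 9)
}

#' Export a conservation profile as TSV
#'
#' Columns: `column`, `code` (when a topology map is given), `group`, `ncs`.
#'
#' @param profile a `conservation_profile`.
#' @param path output path.
#' @param topology_map optional `topology_map` for code annotation.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, topology_map = NULL) {
  df <- data.frame(column = seq_along(profile$ncs),
                   code = if (!is.null(topology_map)) topology_map$codes
                          else NA_character_,
                   group = profile$group, ncs = profile$ncs,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
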