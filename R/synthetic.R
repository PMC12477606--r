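# Seeded generators producing every pipeline input with planted ground
# truth. One integer seed drives one named pseudo-random stream per
# generator, so modules can be regenerated independently; all generation is
# bit-reproducible for a fixed (seed, parameters) pair.

derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) * 7919 + sum(utf8ToInt(stream)) * 104729) %%
    2147483646
  as.integer(s) + 1L
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream))
  force(code)
}

# residues whose pBS against `residue` is <= 0 ("sufficiently changed")
divergent_residues <- function(residue) {
  m <- pbs_matrix()
  names(which(m[residue, ] <= 0))
}

#' Synthetic reference-like alignment with planted signatures
#'
#' Generates a gapped protein alignment with the nested group structure of
#' the Argonaute superfamily (pAgo and eAgo = PIWI + AGO, with mAGO nested in
#' AGO) plus a gap-free anchor sequence, and plants fully conserved
#' group-specific columns whose consensus is sufficiently diverged
#' (pBS <= 0) from the background consensus seen by the other sequences.
#' Universal columns are conserved across every sequence and are echoed in
#' three kingdom ancestor sequences; at all other columns the ancestors carry
#' a discordant residue pair (pBS <= 0), modelling kingdom divergence outside
#' the universal positions. Background columns are drawn i.i.d. at the stated
#' identity around a per-column consensus; gaps are sprinkled everywhere
#' except planted columns.
#'
#' @param n_per_group named integer vector with entries `pAgo`, `PIWI`,
#'   `AGO`, `mAGO` (`mAGO` counts sequences nested inside `AGO`).
#' @param width alignment width in columns.
#' @param n_planted named integer vector: planted column count per group
#'   (`universal`, `pAgo`, `eAgo`, `PIWI`, `AGO`, `mAGO`).
#' @param background_identity probability that a background cell carries its
#'   column consensus (default 0.30).
#' @param gap_rate per-cell gap probability at background columns (default
#'   0.05).
#' @param planted_noise probability that a group member's planted residue is
#'   replaced by a random residue (0 = noiseless).
#' @param include_anchor include the gap-free `anchor` sequence (default
#'   TRUE; required for [synth_topology_map()]).
#' @param seed integer seed.
#' @return list with `alignment` (a `ref_alignment`), `ancestors` (named
#'   character vector: Bacteria/Archaea/Eukaryota), and `truth` (list:
#'   `planted` data.frame `group`/`column`/`residue`/`parent_residue`,
#'   `seed`, `params`).
#' @export
synth_alignment <- function(n_per_group = c(pAgo = 40, PIWI = 20, AGO = 20,
                                            mAGO = 12),
                            width = 200,
                            n_planted = c(universal = 8, pAgo = 6, eAgo = 6,
                                          PIWI = 4, AGO = 4, mAGO = 3),
                            background_identity = 0.30,
                            gap_rate = 0.05,
                            planted_noise = 0,
                            include_anchor = TRUE,
                            seed = 1) {
  stopifnot(all(c("pAgo", "PIWI", "AGO") %in% names(n_per_group)))
  n_mago <- if ("mAGO" %in% names(n_per_group)) n_per_group[["mAGO"]] else 0
  if (n_mago > n_per_group[["AGO"]]) stop("mAGO must nest inside AGO")
  if (sum(n_planted) > width) stop("infeasible: more planted columns than width")
  with_stream(seed, "alignment", {
    ids <- list(
      pAgo = sprintf("pAgo_%02d", seq_len(n_per_group[["pAgo"]])),
      PIWI = sprintf("PIWI_%02d", seq_len(n_per_group[["PIWI"]])),
      AGO = sprintf("AGO_%02d", seq_len(n_per_group[["AGO"]])))
    all_ids <- unlist(ids, use.names = FALSE)
    groups <- list(pAgo = ids$pAgo, eAgo = c(ids$PIWI, ids$AGO),
                   PIWI = ids$PIWI, AGO = ids$AGO,
                   mAGO = ids$AGO[seq_len(n_mago)])
    n_seq <- length(all_ids)

    consensus <- sample(AA20, width, replace = TRUE)
    m <- matrix("", nrow = n_seq, ncol = width, dimnames = list(all_ids))
    for (p in seq_len(width)) {
      take <- stats::runif(n_seq) < background_identity
      m[, p] <- ifelse(take, consensus[p],
                       sample(AA20, n_seq, replace = TRUE))
    }

    # assign disjoint planted columns per group
    free <- sample(width)
    planted <- list()
    for (g in names(n_planted)) {
      k <- n_planted[[g]]
      if (k == 0) next
      cols <- free[seq_len(k)]
      free <- free[-seq_len(k)]
      members <- if (g == "universal") all_ids else groups[[g]]
      for (col in cols) {
        parent_res <- consensus[col]
        res <- sample(divergent_residues(parent_res), 1)
        m[members, col] <- res
        if (planted_noise > 0) {
          flip <- stats::runif(length(members)) < planted_noise
          if (any(flip)) {
            m[members[flip], col] <- sample(AA20, sum(flip), replace = TRUE)
          }
        }
        planted[[length(planted) + 1]] <- data.frame(
          group = g, column = col, residue = res,
          parent_residue = parent_res, stringsAsFactors = FALSE)
      }
    }
    planted <- if (length(planted) == 0) {
      data.frame(group = character(0), column = integer(0),
                 residue = character(0), parent_residue = character(0),
                 stringsAsFactors = FALSE)
    } else do.call(rbind, planted)
    planted_cols <- planted$column

    # gaps only at background columns
    bg_cols <- setdiff(seq_len(width), planted_cols)
    if (gap_rate > 0 && length(bg_cols) > 0) {
      gaps <- matrix(stats::runif(n_seq * length(bg_cols)) < gap_rate,
                     nrow = n_seq)
      m[, bg_cols][gaps] <- "-"
    }

    seqs <- setNames(apply(m, 1, paste, collapse = ""), all_ids)
    if (include_anchor) {
      anchor <- consensus
      uni <- planted[planted$group == "universal", , drop = FALSE]
      anchor[uni$column] <- uni$residue
      seqs <- c(anchor = paste(anchor, collapse = ""), seqs)
    }

    # kingdom ancestors: universal residue at universal columns, a
    # discordant residue pair everywhere else
    anc <- matrix("", nrow = 3, ncol = width,
                  dimnames = list(c("Bacteria", "Archaea", "Eukaryota")))
    for (p in seq_len(width)) {
      a <- sample(AA20, 1)
      b <- sample(divergent_residues(a), 1)
      anc[, p] <- c(a, b, sample(AA20, 1))
    }
    uni <- planted[planted$group == "universal", , drop = FALSE]
    if (nrow(uni) > 0) {
      anc[, uni$column] <- matrix(rep(uni$residue, each = 3), nrow = 3)
    }
    list(alignment = ref_alignment(seqs, groups),
         ancestors = apply(anc, 1, paste, collapse = ""),
         truth = list(seed = seed, planted = planted,
                      params = list(n_per_group = n_per_group, width = width,
                                    background_identity = background_identity,
                                    gap_rate = gap_rate,
                                    planted_noise = planted_noise)))
  })
}

#' Topology map for a synthetic alignment
#'
#' Builds a two-element topology (one N-lobe helix, one C-lobe helix split at
#' mid-width) anchored on the generator's gap-free `anchor` sequence, so that
#' synthetic alignments can exercise every code-based stage.
#'
#' @param alignment a synthetic `ref_alignment` containing an `anchor` row.
#' @return a `topology_map`.
#' @export
synth_topology_map <- function(alignment) {
  if (!"anchor" %in% alignment$ids) {
    stop("alignment has no 'anchor' sequence (generate with include_anchor)")
  }
  w <- nchar(gsub("-", "", alignment$seqs[["anchor"]]))
  half <- floor(w / 2)
  sse <- data.frame(lobe = c("N", "C"), kind = c("H", "H"),
                    start = c(1, half + 1), end = c(half, w))
  dom <- data.frame(domain = c("N", "PIWI"), start = c(1, half + 1),
                    end = c(half, w))
  build_topology_map(alignment, "anchor", sse, dom)
}

#' Hierarchical signature detection over a synthetic alignment
#'
#' Convenience wrapper running [group_profile()], [detect_candidates()],
#' [universal_signature()] and [build_signature()] in hierarchy order
#' (universal, then pAgo/eAgo, then PIWI/AGO, then mAGO) — the same call
#' sequence a user would make on real data.
#'
#' @param alignment a `ref_alignment` with groups `pAgo`, `eAgo`, `PIWI`,
#'   `AGO`, `mAGO`.
#' @param ancestors named character vector of the three kingdom ancestors.
#' @param topology_map optional `topology_map` for code annotation.
#' @return named list of `signature_set`s.
#' @export
signature_hierarchy <- function(alignment, ancestors, topology_map = NULL) {
  members <- setdiff(alignment$ids, "anchor")
  full <- group_profile(alignment, members)
  sigs <- list()
  sigs$universal <- universal_signature(ancestors, full,
                                        topology_map = topology_map)
  parent_chain <- list(pAgo = "universal", eAgo = "universal",
                       PIWI = c("universal", "eAgo"),
                       AGO = c("universal", "eAgo"),
                       mAGO = c("universal", "eAgo", "AGO"))
  for (g in names(parent_chain)) {
    if (!g %in% names(alignment$groups) ||
        length(alignment$groups[[g]]) < 2) next
    prof <- group_profile(alignment, g)
    cand <- detect_candidates(prof)
    sigs[[g]] <- build_signature(g, cand, alignment,
                                 parent_signatures = sigs[parent_chain[[g]]],
                                 profile = prof, topology_map = topology_map)
  }
  sigs
}

synth_code_lookup <- function(n_residues) {
  data.frame(resno = seq_len(n_residues),
             code = sprintf("N.L1.%d", seq_len(n_residues)),
             stringsAsFactors = FALSE)
}

#' Synthetic structure ensemble with planted contacts
#'
#' Builds an ensemble of minimal coordinate files in which specified residue
#' pairs are planted at controlled frequencies: an edge with frequency `f`
#' appears in exactly `ceiling(f * n)` of the `n` members. Residues have a
#' home atom on a wide grid (no incidental contacts); each planted edge gets
#' a dedicated pair of carbon atoms 3.5 A apart (inside the van der Waals
#' cutoff) at an isolated site. Optional per-residue confidence values
#' exercise the pLDDT filter of [aggregate_contacts()].
#'
#' @param n_structures ensemble size.
#' @param n_residues protein length (planted pairs must satisfy
#'   `|i - j| >= 2`).
#' @param edges data.frame with columns `i`, `j`, `freq` in \[0, 1\].
#' @param predicted generate predicted models (B-factor = confidence).
#' @param base_confidence default per-residue confidence for predicted
#'   models.
#' @param low_confidence optional data.frame `member`, `resno`, `conf`
#'   overriding single residues.
#' @param jitter coordinate noise sd in Angstrom (default 0).
#' @param seed integer seed.
#' @return list with `models` (list of `structure_model`, one protein each,
#'   protein ids `prot_01`...), `code_lookup`, and `truth` (planted edges
#'   with realized member lists and expected cc).
#' @export
synth_structure_ensemble <- function(n_structures = 10, n_residues = 20,
                                     edges = data.frame(i = c(3, 5, 8),
                                                        j = c(10, 12, 15),
                                                        freq = c(1, 0.5, 0.1)),
                                     predicted = FALSE,
                                     base_confidence = 95,
                                     low_confidence = NULL,
                                     jitter = 0, seed = 1) {
  stopifnot(all(c("i", "j", "freq") %in% names(edges)))
  if (any(edges$freq < 0 | edges$freq > 1)) {
    stop("edge frequency outside [0,1]")
  }
  if (any(abs(edges$i - edges$j) < 2)) {
    stop("planted pairs must be non-adjacent (|i - j| >= 2)")
  }
  with_stream(seed, "ensemble", {
    member_sets <- lapply(seq_len(nrow(edges)), function(e) {
      k <- ceiling(edges$freq[e] * n_structures)
      if (k == 0) integer(0) else sort(sample.int(n_structures, k))
    })
    lookup <- synth_code_lookup(n_residues)
    models <- vector("list", n_structures)
    for (s in seq_len(n_structures)) {
      atoms <- data.frame(
        chain = "A", resno = seq_len(n_residues), resname = "ALA",
        atom = "CA", element = "C",
        x = 10 * seq_len(n_residues), y = 0, z = 0,
        b = if (predicted) base_confidence else 0,
        stringsAsFactors = FALSE)
      for (e in seq_len(nrow(edges))) {
        if (!s %in% member_sets[[e]]) next
        site <- c(0, 20 * e, 40)
        extra <- data.frame(
          chain = "A", resno = c(edges$i[e], edges$j[e]), resname = "ALA",
          atom = c("CB", "CB"), element = "C",
          x = c(site[1], site[1] + 3.5), y = site[2], z = site[3],
          b = if (predicted) base_confidence else 0,
          stringsAsFactors = FALSE)
        atoms <- rbind(atoms, extra)
      }
      if (jitter > 0) {
        atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
        atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
        atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
      }
      if (predicted && !is.null(low_confidence)) {
        lc <- low_confidence[low_confidence$member == s, , drop = FALSE]
        for (r in seq_len(nrow(lc))) {
          atoms$b[atoms$resno == lc$resno[r]] <- lc$conf[r]
        }
      }
      models[[s]] <- structure_model(sprintf("prot_%02d", s), atoms,
                                     source = if (predicted) "predicted"
                                              else "experimental")
    }
    truth <- edges
    truth$code_i <- lookup$code[edges$i]
    truth$code_j <- lookup$code[edges$j]
    truth$members <- I(member_sets)
    truth$expected_cc <- vapply(member_sets, length, integer(1)) / n_structures
    list(models = models, code_lookup = lookup,
         truth = list(seed = seed, edges = truth))
  })
}

#' Synthetic protein-nucleic-acid complex with planted interface edges
#'
#' Builds one protein + guide (+ target) complex realizing each requested
#' (protein position, nucleotide label, part, c2oh) edge geometrically: the
#' protein residue contributes a backbone-type N atom and the nucleotide the
#' matching atom (`O2'` for C2'-OH edges, `OP1` for other backbone edges,
#' `N1` for base edges) 3.0 A away at an isolated site, inside the
#' hydrogen-bond cutoff. Target labels (`-k`, `B-k`) generate a target chain
#' and the pairing annotation.
#'
#' @param guide_length guide length (>= 4).
#' @param edges data.frame with columns `protein_pos`, `label`, `part`
#'   (`"backbone"`/`"base"`), `c2oh` (logical; implies backbone).
#' @param n_residues protein length.
#' @param seed integer seed (reserved; the construction is deterministic).
#' @return list with `model` (a `structure_model`), `code_lookup`, `pairing`
#'   (data.frame or NULL), `guide_chain`, `target_chain`, and `truth`.
#' @export
synth_na_complex <- function(guide_length = 21,
                             edges = data.frame(protein_pos = c(4, 7),
                                                label = c("13", "3T"),
                                                part = "backbone",
                                                c2oh = c(TRUE, FALSE)),
                             n_residues = 20, seed = 1) {
  stopifnot(all(c("protein_pos", "label", "part", "c2oh") %in% names(edges)))
  if (any(edges$c2oh & edges$part != "backbone")) {
    stop("c2oh edges are backbone by definition")
  }
  parsed <- lapply(edges$label, parse_na_label)
  guide_idx <- vapply(parsed, function(p) {
    if (p$strand != "guide") return(NA_integer_)
    as.integer(if (p$kind == "three_prime") guide_length - p$value
               else p$value)
  }, integer(1))
  if (any(!is.na(guide_idx) & (guide_idx < 1 | guide_idx > guide_length))) {
    stop("label inconsistent with guide length")
  }
  target_idx <- vapply(parsed, function(p) {
    if (p$strand == "target") p$value else NA_integer_
  }, integer(1))
  if (any(!is.na(target_idx) & target_idx > guide_length)) {
    stop("label inconsistent with guide length")
  }
  prot <- data.frame(chain = "A", resno = seq_len(n_residues),
                     resname = "ALA", atom = "CA", element = "C",
                     x = 10 * seq_len(n_residues), y = 0, z = 0, b = 0,
                     stringsAsFactors = FALSE)
  guide <- data.frame(chain = "G", resno = seq_len(guide_length),
                      resname = "U", atom = "C1'", element = "C",
                      x = 10 * seq_len(guide_length), y = 60, z = 0, b = 0,
                      stringsAsFactors = FALSE)
  atoms <- rbind(prot, guide)
  pairing <- NULL
  has_target <- any(!is.na(target_idx))
  # bulged target nucleotides get distinct residue numbers (offset by the
  # guide length) so a matched and a bulged position opposite the same guide
  # index are different nucleotides, as in a real duplex
  is_bulge_edge <- vapply(parsed, function(p) identical(p$kind, "bulge"),
                          logical(1))
  target_resno <- ifelse(is_bulge_edge, target_idx + guide_length, target_idx)
  if (has_target) {
    sel <- !is.na(target_idx)
    tdf <- unique(data.frame(resno = target_resno[sel],
                             matched_guide_index = target_idx[sel],
                             is_bulge = is_bulge_edge[sel]))
    tdf <- tdf[order(tdf$resno), , drop = FALSE]
    atoms <- rbind(atoms, data.frame(
      chain = "T", resno = tdf$resno, resname = "A", atom = "C1'",
      element = "C", x = 10 * tdf$resno, y = 120, z = 0, b = 0,
      stringsAsFactors = FALSE))
    pairing <- tdf
  }
  for (e in seq_len(nrow(edges))) {
    site <- c(0, -30 * e, 50)
    na_atom <- if (edges$c2oh[e]) "O2'" else
      if (edges$part[e] == "backbone") "OP1" else "N1"
    na_elem <- if (edges$part[e] == "base") "N" else "O"
    if (!is.na(guide_idx[e])) {
      na_chain <- "G"; na_resno <- guide_idx[e]; na_resname <- "U"
    } else {
      na_chain <- "T"; na_resno <- target_resno[e]; na_resname <- "A"
    }
    atoms <- rbind(atoms,
                   data.frame(chain = "A", resno = edges$protein_pos[e],
                              resname = "ALA", atom = "N", element = "N",
                              x = site[1], y = site[2], z = site[3], b = 0,
                              stringsAsFactors = FALSE),
                   data.frame(chain = na_chain, resno = na_resno,
                              resname = na_resname, atom = na_atom,
                              element = na_elem,
                              x = site[1] + 3.0, y = site[2], z = site[3],
                              b = 0, stringsAsFactors = FALSE))
  }
  model <- structure_model(sprintf("na_complex_seed%d", seed), atoms,
                           source = "experimental")
  list(model = model, code_lookup = synth_code_lookup(n_residues),
       pairing = pairing, guide_chain = "G",
       target_chain = if (has_target) "T" else NULL,
       truth = list(seed = seed, edges = edges))
}

#' Synthetic mutation tables with planted cancer-exclusive positions
#'
#' Emits cancer and population-variation mutation tables over a paralog set
#' such that the cancer-exclusive positions are exactly the planted codes:
#' every other cancer-hit code also receives a variation record (possibly in
#' a different paralog), and additional variation-only codes are added.
#'
#' @param planted_exclusive character vector of topology codes to keep
#'   cancer-exclusive.
#' @param alignment a `ref_alignment` containing the paralogs.
#' @param topology_map the matching `topology_map`.
#' @param paralogs character vector of protein ids (>= 1).
#' @param n_shared number of cancer codes that also get variation records.
#' @param n_variation_only number of variation-only codes.
#' @param seed integer seed.
#' @return list with `cancer`, `variation` (mutation-table data.frames) and
#'   `truth` (the planted exclusive codes).
#' @export
synth_mutation_tables <- function(planted_exclusive, alignment, topology_map,
                                  paralogs, n_shared = 8,
                                  n_variation_only = 10, seed = 1) {
  if (length(paralogs) == 0) stop("input error: empty paralog set")
  with_stream(seed, "mutations", {
    # codes where every paralog has a residue, so any paralog can carry a row
    usable <- names(topology_map$columns)[vapply(
      names(topology_map$columns), function(code) {
        all(vapply(paralogs, function(p)
          !is.na(code_to_residue(p, code, alignment, topology_map)),
          logical(1)))
      }, logical(1))]
    if (!all(planted_exclusive %in% usable)) {
      stop("planted exclusive code(s) not coverable by all paralogs")
    }
    pool <- setdiff(usable, planted_exclusive)
    if (length(pool) < n_shared + n_variation_only) {
      stop("not enough usable codes for the requested table sizes")
    }
    shared <- sample(pool, n_shared)
    var_only <- sample(setdiff(pool, shared), n_variation_only)
    row_for <- function(code, source) {
      p <- sample(paralogs, 1)
      aa <- code_to_residue(p, code, alignment, topology_map)
      ref <- substr(gsub("-", "", alignment$seqs[[p]]), aa, aa)
      data.frame(protein = p, ref_aa = ref, position = aa,
                 alt_aa = sample(setdiff(AA20, ref), 1), source = source,
                 stringsAsFactors = FALSE)
    }
    cancer <- do.call(rbind, lapply(c(planted_exclusive, shared), row_for,
                                    source = "cancer"))
    variation <- do.call(rbind, lapply(c(shared, var_only), row_for,
                                       source = "variation"))
    list(cancer = cancer, variation = variation,
         truth = list(seed = seed,
                      exclusive = sort(planted_exclusive),
                      shared = sort(shared)))
  })
}

#' Synthetic speckle-count panel
#'
#' Draws per-image speckle counts from a negative binomial model: wild type
#' at `wt_mean`, each variant at `ratio * wt_mean` with common dispersion.
#' Defaults mirror a three-replicate, three-images-per-replicate imaging
#' design (9 images per arm).
#'
#' @param effect_ratios named numeric vector: variant -> mean ratio vs WT.
#' @param n_images images per arm (default 9).
#' @param wt_mean wild-type mean speckle count (default 40).
#' @param dispersion negative-binomial size parameter (default 8).
#' @param seed integer seed.
#' @return list with `wt` (integer vector), `mutants` (named list of integer
#'   vectors) and `truth` (the effect ratios).
#' @export
synth_speckle_counts <- function(effect_ratios, n_images = 9, wt_mean = 40,
                                 dispersion = 8, seed = 1) {
  stopifnot(!is.null(names(effect_ratios)), all(effect_ratios >= 0))
  with_stream(seed, "speckles", {
    wt <- stats::rnbinom(n_images, size = dispersion, mu = wt_mean)
    mutants <- lapply(effect_ratios, function(r) {
      stats::rnbinom(n_images, size = dispersion, mu = r * wt_mean)
    })
    list(wt = wt, mutants = mutants,
         truth = list(seed = seed, effect_ratios = effect_ratios))
  })
}
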