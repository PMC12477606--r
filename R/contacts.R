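# Atom chemistry tables for the geometric contact predicates.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

ANIONIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
CATIONIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                       HIS = c("ND1", "NE2"))
AROMATIC_RING <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
HB_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG")
HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
  MET = "SD", CYS = "SG")

#' Default contact-detection configuration
#'
#' Distance and angle thresholds for the six noncovalent contact types.
#' Defaults follow the published defaults of the GetContacts engine:
#' salt bridge 4.0 A (anionic side-chain O to cationic side-chain N),
#' hydrogen bond 3.5 A donor-acceptor heavy-atom distance (the donor-H-A
#' angle criterion only applies when hydrogens are present), pi-cation 6.0 A
#' cation-to-ring-centroid, pi-stacking 7.0 A centroid distance with ring
#' normals within 30 degrees, t-stacking 5.0 A with normals at 60-90
#' degrees, and van der Waals `d < r1 + r2 + 0.5` A with the shipped
#' element-radius table. Every threshold is overridable.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `contact_config`.
#' @export
default_contact_config <- function(...) {
  cfg <- list(saltbridge_max = 4.0, hbond_max = 3.5, pication_max = 6.0,
              pistack_max = 7.0, pistack_angle_max = 30,
              tstack_max = 5.0, tstack_angle = c(60, 90),
              vdw_pad = 0.5, vdw_radii = VDW_RADII)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "contact_config"
  cfg
}

dist_xyz <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
         outer(a[, 3], b[, 3], "-")^2)
}

atom_xyz <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

# pseudo-atoms for aromatic rings: centroid coordinates + unit normal
ring_table <- function(atoms) {
  rows <- list()
  prot <- atoms[atoms$resname %in% names(AROMATIC_RING), , drop = FALSE]
  if (nrow(prot) == 0) return(NULL)
  for (key in unique(paste(prot$chain, prot$resno))) {
    sub <- prot[paste(prot$chain, prot$resno) == key, , drop = FALSE]
    ring_atoms <- AROMATIC_RING[[sub$resname[1]]]
    ra <- sub[sub$atom %in% ring_atoms, , drop = FALSE]
    if (nrow(ra) < 3) next
    xyz <- atom_xyz(ra)
    ctr <- colMeans(xyz)
    sv <- svd(sweep(xyz, 2, ctr))
    normal <- sv$v[, 3]
    rows[[length(rows) + 1]] <- data.frame(
      chain = sub$chain[1], resno = sub$resno[1], resname = sub$resname[1],
      atom = ra$atom[1], cx = ctr[1], cy = ctr[2], cz = ctr[3],
      nx = normal[1], ny = normal[2], nz = normal[3],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

is_hb_donor <- function(atoms, nucleic_all = FALSE) {
  if (nucleic_all) return(atoms$element %in% c("N", "O"))
  (atoms$atom %in% HB_DONORS$backbone & !(atoms$resname == "PRO")) |
    mapply(function(rn, an) an %in% (HB_DONORS[[rn]] %||% character(0)),
           atoms$resname, atoms$atom)
}

is_hb_acceptor <- function(atoms, nucleic_all = FALSE) {
  if (nucleic_all) return(atoms$element %in% c("N", "O"))
  (atoms$atom %in% HB_ACCEPTORS$backbone) |
    mapply(function(rn, an) an %in% (HB_ACCEPTORS[[rn]] %||% character(0)),
           atoms$resname, atoms$atom)
}

is_anionic <- function(atoms, nucleic = FALSE) {
  if (nucleic) return(atoms$atom %in% c("OP1", "OP2", "O1P", "O2P"))
  mapply(function(rn, an) an %in% (ANIONIC_ATOMS[[rn]] %||% character(0)),
         atoms$resname, atoms$atom)
}

is_cationic <- function(atoms) {
  mapply(function(rn, an) an %in% (CATIONIC_ATOMS[[rn]] %||% character(0)),
         atoms$resname, atoms$atom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

contact_rows <- function(atoms_a, atoms_b, idx, type, d) {
  data.frame(chain_i = atoms_a$chain[idx[, 1]], resno_i = atoms_a$resno[idx[, 1]],
             resname_i = atoms_a$resname[idx[, 1]], atom_i = atoms_a$atom[idx[, 1]],
             chain_j = atoms_b$chain[idx[, 2]], resno_j = atoms_b$resno[idx[, 2]],
             resname_j = atoms_b$resname[idx[, 2]], atom_j = atoms_b$atom[idx[, 2]],
             type = type, distance = d, stringsAsFactors = FALSE)
}

# drops pairs within the same residue and (optionally) keeps each unordered
# pair once when a and b are the same atom set
prune_pairs <- function(idx, atoms_a, atoms_b, same_set) {
  if (nrow(idx) == 0) return(idx)
  keep <- !(atoms_a$chain[idx[, 1]] == atoms_b$chain[idx[, 2]] &
              atoms_a$resno[idx[, 1]] == atoms_b$resno[idx[, 2]])
  idx <- idx[keep, , drop = FALSE]
  if (same_set && nrow(idx) > 0) {
    key1 <- paste(atoms_a$chain[idx[, 1]], atoms_a$resno[idx[, 1]],
                  atoms_a$atom[idx[, 1]])
    key2 <- paste(atoms_b$chain[idx[, 2]], atoms_b$resno[idx[, 2]],
                  atoms_b$atom[idx[, 2]])
    idx <- idx[key1 < key2, , drop = FALSE]
  }
  idx
}

pairs_within <- function(d, cutoff) {
  which(d <= cutoff & d > 0, arr.ind = TRUE)
}

# shared geometric engine: typed atomic contacts between two atom tables
detect_contacts_between <- function(atoms_a, atoms_b, config, same_set,
                                    nucleic_b = FALSE) {
  out <- list()
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0) return(NULL)

  # salt bridges
  an_a <- atoms_a[is_anionic(atoms_a), , drop = FALSE]
  cat_b <- atoms_b[is_cationic(atoms_b), , drop = FALSE]
  cat_a <- atoms_a[is_cationic(atoms_a), , drop = FALSE]
  an_b <- atoms_b[is_anionic(atoms_b, nucleic = nucleic_b), , drop = FALSE]
  for (pair in list(list(an_a, cat_b), list(cat_a, an_b))) {
    p <- pair[[1]]; q <- pair[[2]]
    if (nrow(p) == 0 || nrow(q) == 0) next
    d <- dist_xyz(atom_xyz(p), atom_xyz(q))
    idx <- prune_pairs(pairs_within(d, config$saltbridge_max), p, q, FALSE)
    if (nrow(idx) > 0) {
      out[[length(out) + 1]] <- contact_rows(p, q, idx, "saltbridge",
                                             d[idx])
    }
  }

  # hydrogen bonds (heavy-atom criterion; no hydrogens in our inputs)
  don_a <- atoms_a[is_hb_donor(atoms_a), , drop = FALSE]
  acc_b <- atoms_b[is_hb_acceptor(atoms_b, nucleic_all = nucleic_b), , drop = FALSE]
  acc_a <- atoms_a[is_hb_acceptor(atoms_a), , drop = FALSE]
  don_b <- atoms_b[is_hb_donor(atoms_b, nucleic_all = nucleic_b), , drop = FALSE]
  for (pair in list(list(don_a, acc_b), list(acc_a, don_b))) {
    p <- pair[[1]]; q <- pair[[2]]
    if (nrow(p) == 0 || nrow(q) == 0) next
    d <- dist_xyz(atom_xyz(p), atom_xyz(q))
    idx <- prune_pairs(pairs_within(d, config$hbond_max), p, q, FALSE)
    if (nrow(idx) > 0) {
      out[[length(out) + 1]] <- contact_rows(p, q, idx, "hbond", d[idx])
    }
  }

  # pi-cation and ring stacking (protein aromatics only)
  rings_a <- ring_table(atoms_a)
  rings_b <- if (same_set) rings_a else ring_table(atoms_b)
  ring_df <- function(r) {
    data.frame(chain = r$chain, resno = r$resno, resname = r$resname,
               atom = r$atom, x = r$cx, y = r$cy, z = r$cz,
               stringsAsFactors = FALSE)
  }
  if (!is.null(rings_b) && nrow(cat_a) > 0) {
    d <- dist_xyz(atom_xyz(cat_a), as.matrix(rings_b[, c("cx", "cy", "cz")]))
    idx <- prune_pairs(pairs_within(d, config$pication_max), cat_a,
                       ring_df(rings_b), FALSE)
    if (nrow(idx) > 0) {
      out[[length(out) + 1]] <- contact_rows(cat_a, ring_df(rings_b), idx,
                                             "pication", d[idx])
    }
  }
  if (!same_set && !is.null(rings_a) && nrow(cat_b) > 0) {
    d <- dist_xyz(as.matrix(rings_a[, c("cx", "cy", "cz")]), atom_xyz(cat_b))
    idx <- prune_pairs(pairs_within(d, config$pication_max), ring_df(rings_a),
                       cat_b, FALSE)
    if (nrow(idx) > 0) {
      out[[length(out) + 1]] <- contact_rows(ring_df(rings_a), cat_b, idx,
                                             "pication", d[idx])
    }
  }
  if (!is.null(rings_a) && !is.null(rings_b)) {
    d <- dist_xyz(as.matrix(rings_a[, c("cx", "cy", "cz")]),
                  as.matrix(rings_b[, c("cx", "cy", "cz")]))
    na <- as.matrix(rings_a[, c("nx", "ny", "nz")])
    nb <- as.matrix(rings_b[, c("nx", "ny", "nz")])
    cosang <- abs(tcrossprod(na, nb))
    cosang <- pmin(cosang, 1)
    ang <- acos(cosang) * 180 / pi
    idx <- prune_pairs(pairs_within(d, config$pistack_max), ring_df(rings_a),
                       ring_df(rings_b), same_set)
    if (nrow(idx) > 0) {
      sel <- ang[idx] <= config$pistack_angle_max
      if (any(sel)) {
        out[[length(out) + 1]] <- contact_rows(
          ring_df(rings_a), ring_df(rings_b),
          idx[sel, , drop = FALSE], "pistack", d[idx][sel])
      }
    }
    idx <- prune_pairs(pairs_within(d, config$tstack_max), ring_df(rings_a),
                       ring_df(rings_b), same_set)
    if (nrow(idx) > 0) {
      sel <- ang[idx] >= config$tstack_angle[1] &
        ang[idx] <= config$tstack_angle[2]
      if (any(sel)) {
        out[[length(out) + 1]] <- contact_rows(
          ring_df(rings_a), ring_df(rings_b),
          idx[sel, , drop = FALSE], "tstack", d[idx][sel])
      }
    }
  }

  # van der Waals
  known_a <- atoms_a$element %in% names(config$vdw_radii)
  known_b <- atoms_b$element %in% names(config$vdw_radii)
  if (any(!known_a) || any(!known_b)) {
    warning(sprintf("skipping %d atom(s) with unknown element for vdw",
                    sum(!known_a) + if (same_set) 0 else sum(!known_b)))
  }
  va <- atoms_a[known_a & atoms_a$element != "H", , drop = FALSE]
  vb <- atoms_b[known_b & atoms_b$element != "H", , drop = FALSE]
  if (nrow(va) > 0 && nrow(vb) > 0) {
    d <- dist_xyz(atom_xyz(va), atom_xyz(vb))
    cutoff <- outer(config$vdw_radii[va$element],
                    config$vdw_radii[vb$element], "+") + config$vdw_pad
    idx <- which(d < cutoff & d > 0, arr.ind = TRUE)
    idx <- prune_pairs(idx, va, vb, same_set)
    if (nrow(idx) > 0) {
      out[[length(out) + 1]] <- contact_rows(va, vb, idx, "vdw", d[idx])
    }
  }

  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  # one row per unordered atom pair and type (donor/acceptor and
  # anion/cation sweeps can find the same pair from both directions)
  a_key <- paste(res$chain_i, res$resno_i, res$atom_i)
  b_key <- paste(res$chain_j, res$resno_j, res$atom_j)
  canon <- paste(pmin(a_key, b_key), pmax(a_key, b_key), res$type)
  res <- res[!duplicated(canon), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Detect atomic noncovalent contacts within the protein chains
#'
#' Evaluates the geometric predicates of [default_contact_config()] over all
#' protein atoms of a structure and returns one row per atomic contact
#' (salt bridge, hydrogen bond, pi-cation, pi-stacking, t-stacking, van der
#' Waals) with its distance. Pairs within one residue are never emitted.
#'
#' @param model a [structure_model()].
#' @param config a `contact_config` (default [default_contact_config()]).
#' @return data.frame of atomic contacts (possibly 0 rows) with columns
#'   `chain_i/resno_i/resname_i/atom_i`, same for `j`, `type`, `distance`.
#' @export
detect_atomic_contacts <- function(model, config = default_contact_config()) {
  stopifnot(inherits(model, "structure_model"))
  prot_chains <- names(model$chain_class)[model$chain_class == "protein"]
  if (length(prot_chains) == 0) stop("no protein chains in ", model$id)
  atoms <- model$atoms[model$atoms$chain %in% prot_chains, , drop = FALSE]
  res <- detect_contacts_between(atoms, atoms, config, same_set = TRUE)
  if (is.null(res)) {
    res <- contact_rows(atoms[0, ], atoms[0, ],
                        matrix(integer(0), 0, 2), character(0), numeric(0))
  }
  res
}

#' Aggregate atomic contacts to topology-coded residue contacts
#'
#' Collapses atomic contacts to unique residue-residue edges in topology
#' coordinates: one edge per unordered code pair, with the union of observed
#' contact types and the minimum distance. Residues that cannot be mapped to
#' a code are dropped (count reported via message). For predicted models,
#' edges where either residue's confidence is below `plddt_min` (default 80)
#' are dropped; the filter does not apply to experimental structures.
#' Sequence-adjacent pairs (same chain, |delta resno| <= 1) are excluded.
#'
#' @param atomic data.frame from [detect_atomic_contacts()].
#' @param model the `structure_model` the contacts came from.
#' @param code_lookup data.frame with columns `resno`, `code` (and optional
#'   `chain`) mapping the protein residues to topology codes.
#' @param protein_id protein identifier recorded on the result.
#' @param plddt_min minimum per-residue confidence for predicted models.
#' @return data.frame of class `residue_contact_set` with columns `code_i`,
#'   `code_j`, `types`, `distance_min`; attributes `structure_id`,
#'   `protein_id`, `source`.
#' @export
aggregate_contacts <- function(atomic, model, code_lookup,
                               protein_id = model$id, plddt_min = 80) {
  stopifnot(all(c("resno", "code") %in% names(code_lookup)))
  lookup_code <- function(chain, resno) {
    if ("chain" %in% names(code_lookup)) {
      hit <- code_lookup$code[code_lookup$chain == chain &
                                code_lookup$resno == resno]
    } else {
      hit <- code_lookup$code[code_lookup$resno == resno]
    }
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  empty <- data.frame(code_i = character(0), code_j = character(0),
                      types = character(0), distance_min = numeric(0),
                      stringsAsFactors = FALSE)
  finish <- function(df) {
    attr(df, "structure_id") <- model$id
    attr(df, "protein_id") <- protein_id
    attr(df, "source") <- model$source
    attr(df, "mean_confidence") <- if (!is.null(model$confidence))
      mean(model$confidence$conf) else NA_real_
    class(df) <- c("residue_contact_set", "data.frame")
    df
  }
  if (nrow(atomic) == 0) return(finish(empty))

  # adjacency exclusion
  adj <- atomic$chain_i == atomic$chain_j &
    abs(atomic$resno_i - atomic$resno_j) <= 1
  atomic <- atomic[!adj, , drop = FALSE]
  if (nrow(atomic) == 0) return(finish(empty))

  # confidence filter for predicted models
  if (model$source == "predicted") {
    conf <- model$confidence
    ckey <- paste(conf$chain, conf$resno)
    ci <- conf$conf[match(paste(atomic$chain_i, atomic$resno_i), ckey)]
    cj <- conf$conf[match(paste(atomic$chain_j, atomic$resno_j), ckey)]
    atomic <- atomic[!is.na(ci) & !is.na(cj) &
                       ci >= plddt_min & cj >= plddt_min, , drop = FALSE]
    if (nrow(atomic) == 0) return(finish(empty))
  }

  code_i <- mapply(lookup_code, atomic$chain_i, atomic$resno_i)
  code_j <- mapply(lookup_code, atomic$chain_j, atomic$resno_j)
  unmapped <- is.na(code_i) | is.na(code_j)
  if (any(unmapped)) {
    message(sprintf("aggregate_contacts: dropped %d contact(s) with unmappable residues",
                    sum(unmapped)))
  }
  atomic <- atomic[!unmapped, , drop = FALSE]
  code_i <- code_i[!unmapped]; code_j <- code_j[!unmapped]
  if (nrow(atomic) == 0) return(finish(empty))
  swap <- code_i > code_j
  tmp <- code_i[swap]; code_i[swap] <- code_j[swap]; code_j[swap] <- tmp
  self <- code_i == code_j
  atomic <- atomic[!self, , drop = FALSE]
  code_i <- code_i[!self]; code_j <- code_j[!self]
  if (nrow(atomic) == 0) return(finish(empty))
  key <- paste(code_i, code_j)
  df <- data.frame(
    code_i = tapply(code_i, key, `[`, 1),
    code_j = tapply(code_j, key, `[`, 1),
    types = tapply(atomic$type, key,
                   function(v) paste(sort(unique(v)), collapse = ",")),
    distance_min = as.numeric(tapply(atomic$distance, key, min)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  finish(df[order(df$code_i, df$code_j), , drop = FALSE])
}

edge_keys <- function(set) {
  if (nrow(set) == 0) return(character(0))
  paste(set$code_i, set$code_j, sep = "|")
}

#' Select one structural representative per protein
#'
#' Deterministic default policy: experimental structures beat predicted
#' models; then a guide-bound state (attribute `guide_bound`, if recorded)
#' beats unbound; then higher mean confidence; ties broken by structure id
#' (ascending).
#'
#' @param sets list of `residue_contact_set`s.
#' @return sub-list with one set per distinct `protein_id`.
#' @export
select_representatives <- function(sets) {
  proteins <- vapply(sets, function(s) attr(s, "protein_id"), character(1))
  chosen <- integer(0)
  for (p in unique(proteins)) {
    idx <- which(proteins == p)
    score <- vapply(idx, function(i) {
      s <- sets[[i]]
      exp_rank <- if (identical(attr(s, "source"), "experimental")) 0 else 1
      gb <- attr(s, "guide_bound")
      gb_rank <- if (isTRUE(gb)) 0 else 1
      conf <- attr(s, "mean_confidence")
      conf_rank <- if (is.na(conf)) 0 else -conf
      exp_rank * 1e6 + gb_rank * 1e3 + conf_rank
    }, numeric(1))
    ids <- vapply(idx, function(i) attr(sets[[i]], "structure_id"), character(1))
    chosen <- c(chosen, idx[order(score, ids)][1])
  }
  sets[chosen]
}

#' Contact conservation over a group of structures
#'
#' Contact conservation of an edge is the exact fraction of the group's
#' structural representatives (one per protein, see
#' [select_representatives()]) that contain the edge: an edge present in 5 of
#' 10 representatives has CC = 0.5. The mean (mCC) and sample standard
#' deviation (sdCC) are taken over all edges observed in at least one
#' representative.
#'
#' @param sets list of `residue_contact_set`s (>= 2 distinct proteins after
#'   representative selection).
#' @param group group name recorded on the result.
#' @param select apply the one-representative-per-protein policy (default
#'   TRUE).
#' @return object of class `contact_network`: `group`, `edges` (data.frame
#'   `code_i`, `code_j`, `cc`, `k`, `n`), `n_structures`, `mcc`, `sdcc`.
#' @export
contact_conservation <- function(sets, group = "group", select = TRUE) {
  if (select) sets <- select_representatives(sets)
  proteins <- vapply(sets, function(s) attr(s, "protein_id"), character(1))
  if (length(unique(proteins)) < 2) {
    stop("input error: need at least 2 distinct proteins")
  }
  n <- length(sets)
  keys <- lapply(sets, edge_keys)
  tab <- table(unlist(keys))
  if (length(tab) == 0) {
    return(structure(list(group = group,
                          edges = data.frame(code_i = character(0),
                                             code_j = character(0),
                                             cc = numeric(0), k = integer(0),
                                             n = integer(0)),
                          n_structures = n, mcc = NA_real_, sdcc = NA_real_),
                     class = "contact_network"))
  }
  split_keys <- strsplit(names(tab), "|", fixed = TRUE)
  edges <- data.frame(
    code_i = vapply(split_keys, `[`, character(1), 1),
    code_j = vapply(split_keys, `[`, character(1), 2),
    k = as.integer(tab), n = n, stringsAsFactors = FALSE)
  edges$cc <- edges$k / edges$n
  edges <- edges[order(-edges$cc, edges$code_i, edges$code_j), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(group = group,
                 edges = edges[, c("code_i", "code_j", "cc", "k", "n")],
                 n_structures = n,
                 mcc = mean(edges$cc), sdcc = sd(edges$cc)),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("Contact network '%s': %d edges over %d representatives, mCC %.4f, sdCC %.4f\n",
              x$group, nrow(x$edges), x$n_structures, x$mcc, x$sdcc))
  invisible(x)
}

#' Extract the signature contact network (SCN)
#'
#' Keeps edges whose contact conservation strictly exceeds `mCC + k * sdCC`
#' (default `k = 1`) of the parent network AND that touch at least one
#' signature position.
#'
#' @param network a [contact_conservation()] result.
#' @param signature a `signature_set` with code-annotated entries.
#' @param k threshold multiplier (default 1).
#' @return object of class `scn`: `group`, `edges`, `signature_group`.
#' @export
extract_scn <- function(network, signature, k = 1) {
  stopifnot(inherits(network, "contact_network"),
            inherits(signature, "signature_set"))
  sig_codes <- signature$entries$code
  if (length(sig_codes) == 0 || all(is.na(sig_codes))) {
    stop("input error: empty (or code-less) signature")
  }
  thr <- network$mcc + k * network$sdcc
  e <- network$edges
  keep <- e$cc > thr & (e$code_i %in% sig_codes | e$code_j %in% sig_codes)
  structure(list(group = network$group, edges = e[keep, , drop = FALSE],
                 signature_group = signature$group),
            class = "scn")
}

#' Universal SCN from both subgroup networks
#'
#' An edge belongs to the universal SCN only when it passes the
#' `CC > mCC + k*sdCC` test in BOTH subgroup networks (each against its own
#' mean and sd) and touches at least one universal-signature position. The
#' reported cc/k/n are those of the first network.
#'
#' @param network_a,network_b the two subgroup `contact_network`s (e.g.
#'   eukaryotic and prokaryotic).
#' @param signature the universal `signature_set`.
#' @param k threshold multiplier (default 1).
#' @return an `scn`.
#' @export
universal_scn <- function(network_a, network_b, signature, k = 1) {
  scn_a <- extract_scn(network_a, signature, k)
  thr_b <- network_b$mcc + k * network_b$sdcc
  pass_b <- edge_keys(network_b$edges[network_b$edges$cc > thr_b, ,
                                      drop = FALSE])
  keep <- edge_keys(scn_a$edges) %in% pass_b
  structure(list(group = "universal",
                 edges = scn_a$edges[keep, , drop = FALSE],
                 signature_group = signature$group),
            class = "scn")
}

#' @export
print.scn <- function(x, ...) {
  cat(sprintf("SCN '%s' (signature %s): %d edges\n", x$group,
              x$signature_group, nrow(x$edges)))
  invisible(x)
}

#' Mean contact conservation of a position
#'
#' Mean cc over all edges of the network incident to the given topology
#' code; positions with no incident edge score 0 (reported via message).
#'
#' @param network a `contact_network`.
#' @param position a topology code string.
#' @return mean cc.
#' @export
position_mean_cc <- function(network, position) {
  e <- network$edges
  inc <- e$code_i == position | e$code_j == position
  if (!any(inc)) {
    message("position ", position, " has no incident contacts; mean cc = 0")
    return(0)
  }
  mean(e$cc[inc])
}

#' Fraction of SCN edges present in a contact set
#'
#' @param set a `residue_contact_set` (or any data.frame with `code_i`,
#'   `code_j`).
#' @param scn an `scn` with at least one edge.
#' @return `|edges(set) intersect edges(scn)| / |edges(scn)|`.
#' @export
scn_overlap <- function(set, scn) {
  stopifnot(inherits(scn, "scn"))
  if (nrow(scn$edges) == 0) stop("input error: empty SCN")
  mean(edge_keys(scn$edges) %in% edge_keys(set))
}

#' Most conserved contacts of a network
#'
#' Stable selection of the `n` most conserved edges, ordered by cc
#' descending with ties broken by code pair (ascending).
#'
#' @param network a `contact_network`.
#' @param n number of edges.
#' @return data.frame of edges.
#' @export
top_contacts <- function(network, n = 500) {
  e <- network$edges[order(-network$edges$cc, network$edges$code_i,
                           network$edges$code_j), , drop = FALSE]
  head(e, n)
}

#' Export a contact network as TSV
#'
#' Columns: `code_i`, `code_j`, `cc`, `k`, `n`.
#'
#' @param network a `contact_network` or `scn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
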