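# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results from first principles (pairwise
# enumeration, direct geometry) and never call the code paths they check.

AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# raw BLOSUM62 entries needed by hand-derived expectations
b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA, AA]
})
pbs_oracle <- function(a, b) b62[a, b] / sqrt(b62[a, a] * b62[b, b])

# brute-force column conservation: loop over all unordered pairs
brute_ncs <- function(column) {
  n <- length(column)
  scores <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- column[i]; b <- column[j]
      if (a == "-" && b == "-") next
      if (a == "-" || b == "-" || a == "X" || b == "X") {
        scores <- c(scores, 0)
      } else {
        scores <- c(scores, max(0, pbs_oracle(a, b)))
      }
    }
  }
  if (length(scores) == 0) 0 else mean(scores)
}

# brute-force geometric contact detection over every atom pair; reimplements
# the distance predicates directly (no ring geometry: the random structures
# used with this oracle contain no aromatic residues)
brute_contacts <- function(model, config = default_contact_config()) {
  a <- model$atoms[model$atoms$chain %in%
                     names(model$chain_class)[model$chain_class == "protein"], ]
  anion <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  cation <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                 HIS = c("ND1", "NE2"))
  donors <- list(ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
                 HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
                 TRP = "NE1", TYR = "OH", CYS = "SG")
  acceptors <- list(ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"),
                    GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), SER = "OG",
                    THR = "OG1", TYR = "OH", MET = "SD", CYS = "SG")
  in_tab <- function(tab, rn, an) an %in% tab[[rn]]
  is_don <- function(k) (a$atom[k] == "N" && a$resname[k] != "PRO") ||
    in_tab(donors, a$resname[k], a$atom[k])
  is_acc <- function(k) a$atom[k] %in% c("O", "OXT") ||
    in_tab(acceptors, a$resname[k], a$atom[k])
  out <- list()
  n <- nrow(a)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (a$chain[i] == a$chain[j] && a$resno[i] == a$resno[j]) next
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                       c(a$x[j], a$y[j], a$z[j]))^2))
      types <- character(0)
      sb <- (in_tab(anion, a$resname[i], a$atom[i]) &&
               in_tab(cation, a$resname[j], a$atom[j])) ||
        (in_tab(cation, a$resname[i], a$atom[i]) &&
           in_tab(anion, a$resname[j], a$atom[j]))
      if (sb && d <= config$saltbridge_max) types <- c(types, "saltbridge")
      hb <- (is_don(i) && is_acc(j)) || (is_acc(i) && is_don(j))
      if (hb && d <= config$hbond_max) types <- c(types, "hbond")
      r1 <- config$vdw_radii[a$element[i]]
      r2 <- config$vdw_radii[a$element[j]]
      if (!is.na(r1) && !is.na(r2) && a$element[i] != "H" &&
          a$element[j] != "H" && d < r1 + r2 + config$vdw_pad) {
        types <- c(types, "vdw")
      }
      for (tp in types) {
        out[[length(out) + 1]] <- data.frame(
          res_i = paste(a$chain[i], a$resno[i]), atom_i = a$atom[i],
          res_j = paste(a$chain[j], a$resno[j]), atom_j = a$atom[j],
          type = tp, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(res_i = character(0), atom_i = character(0),
                      res_j = character(0), atom_j = character(0),
                      type = character(0)))
  }
  do.call(rbind, out)
}

# canonical multiset of typed atomic contacts for comparison
contact_fingerprint <- function(df, from_argonet = FALSE) {
  if (nrow(df) == 0) return(character(0))
  if (from_argonet) {
    key <- apply(df, 1, function(r) {
      a <- paste(r[["chain_i"]], r[["resno_i"]], r[["atom_i"]])
      b <- paste(r[["chain_j"]], r[["resno_j"]], r[["atom_j"]])
      paste(sort(c(a, b))[1], sort(c(a, b))[2], r[["type"]])
    })
  } else {
    key <- apply(df, 1, function(r) {
      a <- paste(r[["res_i"]], r[["atom_i"]])
      b <- paste(r[["res_j"]], r[["atom_j"]])
      paste(sort(c(a, b))[1], sort(c(a, b))[2], r[["type"]])
    })
  }
  sort(key)
}

# random small structure over hbond/saltbridge/vdw-capable residues
random_structure <- function(n_res = 8, box = 12, seed = 1) {
  set.seed(seed)
  resnames <- sample(c("ALA", "SER", "LYS", "ASP", "GLU", "ARG", "THR",
                       "GLY"), n_res, replace = TRUE)
  side <- list(ALA = "CB", SER = "OG", LYS = "NZ", ASP = "OD1", GLU = "OE1",
               ARG = "NH1", THR = "OG1", GLY = NULL)
  rows <- list()
  for (i in seq_len(n_res)) {
    base <- runif(3, 0, box)
    rows[[length(rows) + 1]] <- data.frame(
      chain = "A", resno = i, resname = resnames[i], atom = "N",
      element = "N", x = base[1], y = base[2], z = base[3], b = 0)
    rows[[length(rows) + 1]] <- data.frame(
      chain = "A", resno = i, resname = resnames[i], atom = "O",
      element = "O", x = base[1] + runif(1, -2, 2),
      y = base[2] + runif(1, -2, 2), z = base[3] + runif(1, -2, 2), b = 0)
    sc <- side[[resnames[i]]]
    if (!is.null(sc)) {
      el <- substr(sc, 1, 1)
      rows[[length(rows) + 1]] <- data.frame(
        chain = "A", resno = i, resname = resnames[i], atom = sc,
        element = el, x = base[1] + runif(1, -3, 3),
        y = base[2] + runif(1, -3, 3), z = base[3] + runif(1, -3, 3), b = 0)
    }
  }
  structure_model(sprintf("rand_%d", seed), do.call(rbind, rows),
                  source = "experimental")
}

# tiny alignment builder: seqs is a named character vector
tiny_alignment <- function(seqs, groups = list()) ref_alignment(seqs, groups)

canon_edges <- function(ci, cj) paste(pmin(ci, cj), pmax(ci, cj), sep = "|")
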