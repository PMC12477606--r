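NUCLEIC_RESNAMES <- c("A", "C", "G", "U", "DA", "DC", "DG", "DT")

#' Construct a structure model
#'
#' Thin container for one coordinate file: a flat atom table plus per-chain
#' molecule classification and, for predicted models, per-residue confidence
#' (pLDDT-style, 0-100) taken from the B-factor column.
#'
#' @param id structure identifier.
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`, `b`.
#' @param source `"experimental"` or `"predicted"`.
#' @return object of class `structure_model` with elements `id`, `source`,
#'   `atoms`, `chain_class` (named vector, `"protein"`/`"nucleic"`) and
#'   `confidence` (data.frame chain/resno/conf, predicted models only).
#' @export
structure_model <- function(id, atoms, source = c("experimental", "predicted")) {
  source <- match.arg(source)
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z", "b")
  if (!all(need %in% names(atoms))) {
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("parse error: non-finite coordinates in structure ", id)
  }
  # unique residue numbers within each chain (one resname per (chain, resno))
  key <- paste(atoms$chain, atoms$resno)
  byres <- tapply(atoms$resname, key, function(v) length(unique(v)))
  if (any(byres > 1)) {
    stop("residue numbers not unique within a chain in structure ", id)
  }
  chain_class <- vapply(split(atoms, atoms$chain), function(a) {
    res <- unique(paste(a$chain, a$resno))
    resn <- a$resname[!duplicated(paste(a$chain, a$resno))]
    frac_na <- mean(resn %in% NUCLEIC_RESNAMES)
    if (frac_na >= 0.5 && frac_na < 1) {
      warning(sprintf("chain %s of %s is mixed; classified as nucleic by majority",
                      a$chain[1], id))
    }
    if (frac_na > 0 && frac_na < 0.5) {
      warning(sprintf("chain %s of %s is mixed; classified as protein by majority",
                      a$chain[1], id))
    }
    if (frac_na >= 0.5) "nucleic" else "protein"
  }, character(1))
  confidence <- NULL
  if (source == "predicted") {
    idx <- !duplicated(key)
    confidence <- data.frame(chain = atoms$chain[idx], resno = atoms$resno[idx],
                             conf = atoms$b[idx], stringsAsFactors = FALSE)
    if (any(confidence$conf < 0 | confidence$conf > 100)) {
      stop("confidence outside [0,100] in predicted model ", id)
    }
  }
  structure(list(id = id, source = source, atoms = atoms,
                 chain_class = chain_class, confidence = confidence),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure %s (%s): %d atoms, chains %s\n", x$id, x$source,
              nrow(x$atoms),
              paste(sprintf("%s[%s]", names(x$chain_class), x$chain_class),
                    collapse = " ")))
  invisible(x)
}

#' Read a PDB coordinate file
#'
#' Parses a PDB file via bio3d, classifies each chain as protein or nucleic
#' by majority residue name (A/C/G/U and DA/DC/DG/DT count as nucleic), and
#' for predicted models copies the per-residue B-factor into the confidence
#' slot. With `source_hint = "auto"` the file is treated as predicted when
#' every B-factor lies in \[0, 100\] and is constant within each residue,
#' which is the fingerprint of a pLDDT-annotated model.
#'
#' @param path path to a PDB file.
#' @param source_hint `"experimental"`, `"predicted"` or `"auto"`.
#' @param id structure id; defaults to the file name without extension.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, source_hint = c("auto", "experimental",
                                                 "predicted"),
                           id = sub("\\.pdb$", "", basename(path))) {
  source_hint <- match.arg(source_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (nrow(a) == 0) stop("parse error: no atoms in ", path)
  element <- a$elesy
  if (is.null(element) || all(is.na(element)) || all(!nzchar(trimws(element)))) {
    element <- substr(gsub("[^A-Za-z].*$", "", a$elety), 1, 1)
  }
  element <- toupper(trimws(element))
  atoms <- data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
                      resno = a$resno, resname = trimws(a$resid),
                      atom = trimws(a$elety), element = element,
                      x = a$x, y = a$y, z = a$z,
                      b = ifelse(is.na(a$b), 0, a$b),
                      stringsAsFactors = FALSE)
  if (source_hint == "auto") {
    key <- paste(atoms$chain, atoms$resno)
    const_b <- all(tapply(atoms$b, key, function(v) length(unique(v)) == 1))
    in_range <- all(atoms$b >= 0 & atoms$b <= 100)
    source_hint <- if (const_b && in_range) "predicted" else "experimental"
  }
  structure_model(id, atoms, source = source_hint)
}

#' Write a structure model to PDB
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resname,
                   elety = a$atom, elesy = a$element,
                   o = rep(1, nrow(a)), b = a$b)
  invisible(path)
}

#' Residue table of a structure
#'
#' One row per residue: chain, residue number, residue name, chain class and
#' (predicted models) confidence.
#'
#' @param model a `structure_model`.
#' @return data.frame.
#' @export
residue_table <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  idx <- !duplicated(paste(a$chain, a$resno))
  out <- data.frame(chain = a$chain[idx], resno = a$resno[idx],
                    resname = a$resname[idx], stringsAsFactors = FALSE)
  out$class <- unname(model$chain_class[out$chain])
  if (!is.null(model$confidence)) {
    key <- paste(out$chain, out$resno)
    ckey <- paste(model$confidence$chain, model$confidence$resno)
    out$conf <- model$confidence$conf[match(key, ckey)]
  } else {
    out$conf <- NA_real_
  }
  out
}
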