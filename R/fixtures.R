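#' Load the bundled synthetic hAGO2 anchor fixture
#'
#' The package ships a small synthetic two-sequence alignment (an hAGO
#' consensus anchor plus an hAGO2 row) with secondary-structure and domain
#' span tables constructed so that the published hAGO2 topology codes (e.g.
#' residue 733 = C.L21.16, 573 = C.L11.2, 597 = C.S8.7, 358 = N.H7.2) are
#' reproduced by [build_topology_map()]. The sequences and spans are
#' synthetic stand-ins — they reproduce the coordinate bookkeeping, not real
#' hAGO2 structure.
#'
#' @return list with `alignment` (a `ref_alignment`), `topology_map`,
#'   `anchor_sse` and `anchor_domains`.
#' @export
hago2_fixture <- function() {
  dir <- system.file("extdata", "hago2_synthetic", package = "argonet",
                     mustWork = TRUE)
  aln <- read_alignment(file.path(dir, "hago2_synthetic_alignment.fasta"),
                        "fasta",
                        group_table = file.path(dir,
                                                "hago2_synthetic_groups.tsv"))
  sse <- read.table(file.path(dir, "hago2_synthetic_sse.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  dom <- read.table(file.path(dir, "hago2_synthetic_domains.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  tmap <- build_topology_map(aln, "hAGO_consensus", sse, dom)
  list(alignment = aln, topology_map = tmap, anchor_sse = sse,
       anchor_domains = dom)
}

#' Read the bundled hAGO2 mutagenesis panel
#'
#' The panel lists the 22 hAGO2 mutant constructs used in the functional
#' assays, with their signature category, residue number, topology code and
#' amino-acid change (`"D-A"` means ref D mutated to A).
#'
#' @param path CSV path; defaults to the bundled copy.
#' @return data.frame with columns `mutant_id`, `category`, `aa_number`,
#'   `code`, `ref_aa`, `alt_aa`.
#' @export
read_primer_panel <- function(path = system.file("extdata",
                                                 "hago2_mutant_panel.csv",
                                                 package = "argonet",
                                                 mustWork = TRUE)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mutant_id", "category", "aa_number", "code", "aa_change")
  if (!all(need %in% names(df))) {
    stop("panel needs columns: ", paste(need, collapse = ", "))
  }
  parts <- strsplit(df$aa_change, "-", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed aa_change entry")
  df$ref_aa <- vapply(parts, `[`, character(1), 1)
  df$alt_aa <- vapply(parts, `[`, character(1), 2)
  df$mutant_id <- as.character(df$mutant_id)
  df[, c("mutant_id", "category", "aa_number", "code", "ref_aa", "alt_aa")]
}
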