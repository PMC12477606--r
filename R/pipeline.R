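#' Precision/recall of a recovered set against a planted truth
#'
#' @param found vector of recovered items.
#' @param truth vector of planted items.
#' @return list with `precision`, `recall`, `f1`, `n_found`, `n_truth`.
#' @export
recovery_stats <- function(found, truth) {
  found <- unique(found); truth <- unique(truth)
  tp <- length(intersect(found, truth))
  precision <- if (length(found) == 0) NA_real_ else tp / length(found)
  recall <- if (length(truth) == 0) NA_real_ else tp / length(truth)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_found = length(found), n_truth = length(truth))
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates every input type with planted ground truth (alignment with
#' nested group signatures, structure ensemble with planted contact
#' frequencies, protein-nucleic-acid complex, mutation tables, speckle
#' counts), runs all analysis stages over them in dependency order, writes
#' the stage outputs (TSV/JSON) plus a run manifest under `out_dir`, and
#' returns the recovery report comparing every stage against its planted
#' truth. All randomness flows from the single `seed`.
#'
#' @param config list (or path to a YAML file) with optional entries `seed`
#'   (default 1), `out_dir` (default a fresh temporary directory), and
#'   overrides for the generator defaults (`alignment`, `ensemble`,
#'   `na_complex`, `mutations`, `speckles` sub-lists passed to the
#'   generators).
#' @return list with `recovery` (data.frame stage/precision/recall),
#'   `signatures`, `networks`, `scn`, `na`, `mutations`, `speckles`,
#'   `out_dir`; written files include `manifest.json`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("argonet_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- alignment + signatures ----------------------------------------------
  aln_args <- config$alignment %||% list()
  aln_args$seed <- seed
  sa <- do.call(synth_alignment, aln_args)
  tmap <- synth_topology_map(sa$alignment)
  sigs <- signature_hierarchy(sa$alignment, sa$ancestors, tmap)
  sig_recovery <- lapply(names(sigs), function(g) {
    truth_cols <- sa$truth$planted$column[sa$truth$planted$group == g]
    rs <- recovery_stats(sigs[[g]]$entries$column, truth_cols)
    data.frame(stage = paste0("signature_", g), precision = rs$precision,
               recall = rs$recall)
  })
  for (g in names(sigs)) {
    write_signature(sigs[[g]], file.path(out_dir,
                                         sprintf("signature_%s.tsv", g)))
  }

  # --- contact ensemble + SCN ----------------------------------------------
  ens_args <- config$ensemble %||% list()
  ens_args$seed <- seed
  ens <- do.call(synth_structure_ensemble, ens_args)
  sets <- lapply(ens$models, function(m) {
    aggregate_contacts(detect_atomic_contacts(m), m, ens$code_lookup)
  })
  net <- contact_conservation(sets, group = "synthetic")
  # signature over the planted high-frequency edges' endpoints
  high <- ens$truth$edges[ens$truth$edges$freq >= 1, , drop = FALSE]
  sig_codes <- unique(c(high$code_i, high$code_j))
  scn_sig <- new_signature_set("synthetic", character(0), data.frame(
    column = seq_along(sig_codes), code = sig_codes,
    consensus = "A", ncs = 1, stringsAsFactors = FALSE))
  scn <- extract_scn(net, scn_sig)
  canon <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  scn_truth <- canon(high$code_i, high$code_j)
  rs <- recovery_stats(canon(scn$edges$code_i, scn$edges$code_j), scn_truth)
  scn_recovery <- data.frame(stage = "scn", precision = rs$precision,
                             recall = rs$recall)
  write_network(net, file.path(out_dir, "contact_network.tsv"))
  write_network(scn, file.path(out_dir, "scn.tsv"))

  # --- NA interface ---------------------------------------------------------
  na_args <- config$na_complex %||% list()
  na_args$seed <- seed
  nac <- do.call(synth_na_complex, na_args)
  na_set <- extract_na_contacts(nac$model, nac$code_lookup, nac$guide_chain,
                                nac$target_chain, nac$pairing)
  truth_edges <- nac$truth$edges
  truth_key <- paste(sprintf("N.L1.%d", truth_edges$protein_pos),
                     truth_edges$label)
  rs <- recovery_stats(paste(na_set$code, na_set$label), truth_key)
  na_recovery <- data.frame(stage = "na_interface", precision = rs$precision,
                            recall = rs$recall)
  write_table_records(as.data.frame(na_set),
                      file.path(out_dir, "na_contacts.tsv"))

  # --- mutations ------------------------------------------------------------
  mut_args <- config$mutations %||% list()
  mut_args$seed <- seed
  paralogs <- utils::head(sa$alignment$groups$AGO, 4)
  usable <- names(tmap$columns)
  planted_codes <- mut_args$planted_exclusive %||% {
    cols_ok <- which(vapply(seq_len(sa$alignment$n_columns), function(col) {
      all(vapply(paralogs, function(p) {
        substr(sa$alignment$seqs[[p]], col, col) != "-"
      }, logical(1)))
    }, logical(1)))
    tmap$codes[with_stream(seed, "mutpick", sample(cols_ok, 5))]
  }
  mut_args$planted_exclusive <- NULL
  mt <- do.call(synth_mutation_tables,
                c(list(planted_exclusive = planted_codes,
                       alignment = sa$alignment, topology_map = tmap,
                       paralogs = paralogs), mut_args))
  ann_cancer <- map_and_annotate(mt$cancer, sa$alignment, tmap, sigs)
  ann_var <- map_and_annotate(mt$variation, sa$alignment, tmap, sigs)
  excl <- cancer_exclusive(ann_cancer, ann_var, paralogs)
  rs <- recovery_stats(excl, mt$truth$exclusive)
  mut_recovery <- data.frame(stage = "cancer_exclusive",
                             precision = rs$precision, recall = rs$recall)
  write_table_records(ann_cancer, file.path(out_dir,
                                            "cancer_annotated.csv"))
  write_table_records(ann_var, file.path(out_dir,
                                         "variation_annotated.csv"))

  # --- speckles ------------------------------------------------------------
  spk_args <- config$speckles %||% list()
  spk_args$seed <- seed
  spk_args$effect_ratios <- spk_args$effect_ratios %||%
    c(impaired_like = 0.1, reduced_like = 0.35, retained_like = 1.0)
  spk <- do.call(synth_speckle_counts, spk_args)
  spk_res <- categorize_speckles(spk$mutants, spk$wt)
  write_table_records(spk_res, file.path(out_dir, "speckle_categories.csv"))

  recovery <- do.call(rbind, c(sig_recovery,
                               list(scn_recovery, na_recovery, mut_recovery)))
  write_table_records(recovery, file.path(out_dir, "recovery.tsv"))

  manifest <- list(
    package = "argonet",
    version = as.character(utils::packageVersion("argonet")),
    seed = seed,
    config = config[setdiff(names(config), c("seed", "out_dir"))],
    stages = c("alignment", "signatures", "contacts", "scn", "na_interface",
               "mutations", "speckles"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(recovery = recovery, signatures = sigs, network = net, scn = scn,
       na = na_set, mutations = list(exclusive = excl, truth = mt$truth),
       speckles = spk_res, out_dir = out_dir)
}
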