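# Builds the synthetic hAGO2 anchor fixture under inst/extdata/hago2_synthetic
# and the bundled mutagenesis panel CSV. The anchor ("hAGO_consensus") is a
# synthetic 862-residue sequence; hAGO2 is a synthetic 859-residue sequence
# gapped at alignment columns 758-760. The SSE/domain spans are constructed so
# that the published topology codes of the hAGO2 mutant panel are reproduced;
# no real secondary structure is claimed.

suppressMessages(devtools::load_all("."))

out_dir <- "inst/extdata/hago2_synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sse_n <- data.frame(
  lobe = "N",
  kind = c("H", "S", "H", "S", "H", "S", "S", "S", "S", "S", "S", "S", "S",
           "S", "S", "H", "H", "S", "H", "S", "S", "S", "H", "S", "H", "S"),
  start = c(1, 31, 45, 69, 83, 109, 121, 133, 145, 157, 175, 185, 191, 207,
            213, 231, 256, 281, 295, 321, 335, 349, 357, 381, 395, 421),
  end = c(20, 36, 60, 74, 100, 114, 126, 138, 150, 168, 180, 190, 196, 212,
          218, 245, 270, 286, 310, 326, 340, 356, 372, 386, 410, 426))
sse_c <- data.frame(
  lobe = "C",
  kind = c("H", "S", "H", "S", "H", "S", "H", "H", "S", "S", "S", "S", "H",
           "S", "S", "S", "H", "S", "S", "H", "S", "S", "H", "S", "S", "S",
           "S", "H", "S", "H"),
  start = c(446, 466, 476, 492, 501, 515, 524, 538, 555, 563, 570, 580, 586,
            591, 604, 611, 626, 649, 661, 675, 702, 715, 737, 749, 766, 779,
            799, 803, 829, 841),
  end = c(460, 470, 487, 496, 510, 519, 533, 550, 558, 566, 571, 583, 588,
          599, 610, 617, 640, 653, 668, 695, 708, 717, 746, 751, 770, 790,
          802, 820, 834, 855))
anchor_sse <- rbind(sse_n, sse_c)

anchor_domains <- data.frame(
  domain = c("N", "L1", "PAZ", "L2", "MID", "PIWI"),
  start = c(1, 161, 227, 351, 446, 581),
  end = c(160, 226, 350, 445, 580, 862))

n_anchor <- 862
gap_cols <- 758:760  # columns where hAGO2 is gapped (anchor-only positions)

# synthetic hAGO2 sequence: deterministic background + the reference residues
# of the bundled mutant panel at their published positions
set.seed(20260920)
aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
hago2 <- sample(aa20, 859, replace = TRUE)
panel_refs <- c(`193` = "G", `215` = "L", `358` = "D", `573` = "G",
                `597` = "D", `600` = "H", `622` = "P", `673` = "E",
                `679` = "V", `700` = "P", `710` = "R", `714` = "R",
                `733` = "G", `753` = "H", `757` = "Q", `758` = "G",
                `790` = "Y", `792` = "R", `804` = "Y", `812` = "R")
hago2[as.integer(names(panel_refs))] <- panel_refs

anchor <- character(n_anchor)
anchor[setdiff(1:n_anchor, gap_cols)] <- hago2
anchor[gap_cols] <- c("G", "S", "G")

hago2_row <- anchor
hago2_row[gap_cols] <- "-"

aln_path <- file.path(out_dir, "hago2_synthetic_alignment.fasta")
writeLines(c(">hAGO_consensus", paste(anchor, collapse = ""),
             ">hAGO2", paste(hago2_row, collapse = "")), aln_path)
gt_path <- file.path(out_dir, "hago2_synthetic_groups.tsv")
writeLines(c("hAGO_consensus\teAgo", "hAGO2\teAgo", "hAGO2\tAGO",
             "hAGO2\tmAGO", "hAGO2\tvAGO"), gt_path)
write.table(anchor_sse, file.path(out_dir, "hago2_synthetic_sse.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(anchor_domains, file.path(out_dir, "hago2_synthetic_domains.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# bundled hAGO2 mutagenesis panel (22 constructs)
panel <- data.frame(
  mutant_id = c("1", "2", "3", "4", "5", "6", "7", "8CANCER", "9", "9CANCER",
                "10CANCER", "11", "12", "13", "14", "14CANCER", "20", "21",
                "22", "23", "24", "25"),
  category = c("Universal", "Universal", "Universal", "Universal",
               "Eukaryota", "Eukaryota", "Eukaryota", "Eukaryota",
               "Eukaryota", "Eukaryota", "AGO-like", "AGO-like", "AGO-like",
               "AGO-like", "Animal", "Animal", "Universal", "Universal",
               "Eukaryota", "Eukaryota", "AGO-like", "Animal"),
  aa_number = c(597, 758, 714, 733, 790, 710, 600, 757, 673, 673, 812, 792,
                804, 753, 358, 358, 573, 215, 700, 679, 193, 622),
  code = c("C.S8.7", "C.L23.10", "C.L20.6", "C.L21.16", "C.L25.3", "C.L20.2",
           "C.L14.1", "C.L23.6", "C.L18.5", "C.L18.5", "C.H10.13", "C.L25.5",
           "C.H10.5", "C.L23.2", "N.H7.2", "N.H7.2", "C.L11.2", "N.S12.3",
           "C.L19.5", "C.H8.5", "N.S10.3", "N.L15.5"),
  aa_change = c("D-A", "G-A", "R-A", "G-R", "Y-A", "R-A", "H-A", "Q-L",
                "E-A", "E-K", "R-W", "R-A", "Y-A", "H-A", "D-A", "D-G",
                "G-W", "L-F", "P-S", "V-K", "G-W", "P-S"),
  stringsAsFactors = FALSE)
panel$code[panel$aa_number == 622] <- "C.L15.5"
write.csv(panel, "inst/extdata/hago2_mutant_panel.csv", row.names = FALSE)

# --- verification: every published code must be reproduced -----------------
aln <- read_alignment(aln_path, "fasta", group_table = gt_path)
tmap <- build_topology_map(aln, "hAGO_consensus", anchor_sse, anchor_domains)
expected <- setNames(panel$code, panel$aa_number)
ok <- TRUE
for (i in seq_len(nrow(panel))) {
  got <- map_residue("hAGO2", panel$aa_number[i], aln, tmap)
  if (got != panel$code[i]) {
    ok <- FALSE
    cat(sprintf("MISMATCH: %d -> %s (expected %s)\n",
                panel$aa_number[i], got, panel$code[i]))
  }
}
stopifnot(ok)
stopifnot(map_residue("hAGO2", 364, aln, tmap) == "N.H7.8")
stopifnot(identical(code_to_residue("hAGO2", "C.L21.16", aln, tmap), 733L))
cat("fixture OK:", length(tmap$codes), "columns,",
    nrow(panel), "panel rows\n")
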