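profile_from <- function(ncs, group = "g", n = 5) {
  structure(list(group = group, ncs = ncs, mncs = mean(ncs), sdncs = sd(ncs),
                 n_sequences = n), class = "conservation_profile")
}

test_that("candidate detection uses the strict mNCS + 2 sdNCS rule", {
  pr <- profile_from(c(0.9, rep(0.1, 9)))
  expect_equal(pr$mncs + 2 * pr$sdncs, 0.686, tolerance = 1e-3)
  expect_equal(detect_candidates(pr), 1L)
  # constant profile: sd 0, nothing strictly exceeds the mean
  expect_equal(detect_candidates(profile_from(rep(0.5, 10))), integer(0))
  expect_equal(detect_candidates(profile_from(rep(1, 10))), integer(0))
})

test_that("hierarchical exclusion follows the pBS <= 0 rule", {
  # group g conserves W (parent also W), D (parent K), I (parent L)
  seqs <- c(g1 = "WDI", g2 = "WDI", g3 = "WDI",
            p1 = "WKL", p2 = "WKL", p3 = "WKL")
  aln <- tiny_alignment(seqs, groups = list(child = c("g1", "g2", "g3")))
  parent <- new_signature_set("parent", character(0), data.frame(
    column = 1:3, code = NA_character_, consensus = c("W", "K", "L"),
    ncs = 1))
  sig <- build_signature("child", candidates = 1:3, alignment = aln,
                         parent_signatures = list(parent))
  # W/W same consensus -> excluded; D vs K pBS < 0 -> included;
  # I vs L pBS = 0.5 > 0 -> excluded
  expect_equal(sig$entries$column, 2L)
  expect_equal(sig$entries$consensus, "D")
})

test_that("candidates absent from all parents are kept; ties are excluded", {
  seqs <- c(a = "DA", b = "DC", c = "DA")  # col2 tie A/C after modal count?
  aln <- tiny_alignment(c(a = "DA", b = "DA", c = "DC", d = "DC"),
                        groups = list(g = c("a", "b", "c", "d")))
  sig <- build_signature("g", candidates = 1:2, alignment = aln)
  expect_equal(sig$entries$column, 1L)  # column 2 consensus tie -> excluded
  expect_equal(sig$entries$consensus, "D")
  expect_error(build_signature("g", candidates = 99L, alignment = aln),
               "outside alignment")
})

test_that("universal signature applies ancestor and conservation rules", {
  # cols: 1 unanimous L (high ncs) -> in; 2 unanimous M (high) -> in;
  # 3 ancestors L,D,D with pbs(L,D) < 0 (high ncs) -> out;
  # 4 unanimous V but ncs below mNCS + sdNCS -> out; 5-10 discordant + low
  anc <- c(Bacteria = "LMLVDDDDDD", Archaea = "LMDVKKKKKK",
           Eukaryota = "LMDVDDDDDD")
  ncs <- c(0.9, 0.9, 0.9, rep(0.05, 7))
  full <- profile_from(ncs, "all")
  thr <- full$mncs + full$sdncs
  expect_true(thr < 0.9 && thr > 0.05)
  sig <- universal_signature(anc, full)
  expect_equal(sig$entries$column, c(1, 2))
  expect_equal(sig$entries$consensus, c("L", "M"))
  expect_error(universal_signature(anc[c(1, 2)], full), "named")
  expect_error(
    universal_signature(c(Bacteria = "LM", Archaea = "LM", Eukaryota = "LM"),
                        full), "aligned to reference width")
})

test_that("universal signature is ancestor-order invariant up to the tie rule", {
  full <- profile_from(c(0.9, 0.9, rep(0.1, 8)))
  anc <- c(Bacteria = "LVWWWWWWWW", Archaea = "IVWWWWWWWW",
           Eukaryota = "VVWWWWWWWW")
  # col1: L, I, V all pairwise positive, three-way tie -> Eukaryota residue V
  sig <- universal_signature(anc, full)
  expect_equal(sig$entries$consensus[sig$entries$column == 1], "V")
  # swapping Bacteria/Archaea leaves the result unchanged
  anc2 <- anc[c(2, 1, 3)]
  names(anc2) <- c("Bacteria", "Archaea", "Eukaryota")
  anc2[["Eukaryota"]] <- anc[["Eukaryota"]]
  sig2 <- universal_signature(anc2, full)
  expect_equal(sig$entries$column, sig2$entries$column)
  # mean-based criterion is available behind the switch
  sig3 <- universal_signature(anc, full, method = "mean")
  expect_true(all(sig$entries$column %in% sig3$entries$column))
})

test_that("sequence scoring against a signature averages pBS", {
  sig <- new_signature_set("g", character(0), data.frame(
    column = c(1, 2), code = NA_character_, consensus = c("D", "I"),
    ncs = 1))
  expect_equal(score_sequence_against_signature("DI", sig), 1.0)
  expect_equal(score_sequence_against_signature("KI", sig),
               mean(c(pbs("D", "K"), 1)))
  expect_equal(score_sequence_against_signature("DL", sig),
               mean(c(1, 0.5)))
  # gap penalized with the matrix minimum
  expect_equal(score_sequence_against_signature("-I", sig),
               mean(c(min(pbs_matrix()), 1)))
  empty <- new_signature_set("g", character(0),
                             data.frame(column = integer(0),
                                        consensus = character(0)))
  expect_error(score_sequence_against_signature("DI", empty), "empty")
})

test_that("cross-family reports score signatures and SCN overlap", {
  sig <- new_signature_set("universal", character(0), data.frame(
    column = 1:2, code = c("N.H1.1", "N.H1.2"), consensus = c("D", "I"),
    ncs = 1))
  fam <- tiny_alignment(c(f1 = "DI", f2 = "DI"))
  mapping <- c(N.H1.1 = 1L, N.H1.2 = 2L)
  scn <- structure(list(group = "g", edges = data.frame(
    code_i = paste0("N.H1.", 1:10), code_j = paste0("N.H1.", 11:20),
    cc = 1, k = 1, n = 1), signature_group = "universal"), class = "scn")
  fam_contacts <- data.frame(code_i = paste0("N.H1.", 1:7),
                             code_j = paste0("N.H1.", 11:17))
  rep <- cross_family_report(fam, mapping, list(universal = sig),
                             list(universal = scn), fam_contacts)
  expect_equal(rep$mean_score[rep$kind == "signature"], 1.0)
  expect_equal(rep$contact_overlap[rep$kind == "scn"], 0.7)
  # family sharing no SCN edges
  rep0 <- cross_family_report(fam, mapping, list(),
                              list(universal = scn),
                              data.frame(code_i = "Z", code_j = "Z"))
  expect_equal(rep0$contact_overlap, 0.0)
  expect_error(cross_family_report(fam, integer(0)), "empty")
})

test_that("planted signatures are recovered exactly on synthetic alignments", {
  sa <- synth_alignment(seed = 101)
  tm <- synth_topology_map(sa$alignment)
  sigs <- signature_hierarchy(sa$alignment, sa$ancestors, tm)
  for (g in names(sigs)) {
    truth <- sa$truth$planted$column[sa$truth$planted$group == g]
    rs <- recovery_stats(sigs[[g]]$entries$column, truth)
    expect_equal(rs$precision, 1, info = g)
    expect_equal(rs$recall, 1, info = g)
    # planted consensus residues are recovered too
    planted <- sa$truth$planted[sa$truth$planted$group == g, ]
    got <- sigs[[g]]$entries$consensus[match(planted$column,
                                             sigs[[g]]$entries$column)]
    expect_equal(got, planted$residue, info = g)
  }
})
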