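test_that("mutation mapping and annotation reproduce the worked cases", {
  fx <- hago2_fixture()
  uni <- new_signature_set("universal", character(0), data.frame(
    column = unname(fx$topology_map$columns[c("C.L21.16", "C.L11.2")]),
    code = c("C.L21.16", "C.L11.2"), consensus = "G", ncs = 1))
  rows <- data.frame(protein = "hAGO2", ref_aa = c("G", "D"),
                     position = c(733L, 358L), alt_aa = c("R", "G"),
                     source = c("germline", "cancer"),
                     stringsAsFactors = FALSE)
  ann <- map_and_annotate(rows, fx$alignment, fx$topology_map,
                          signatures = list(universal = uni),
                          na_interface_codes = "N.H7.2")
  expect_equal(ann$code, c("C.L21.16", "N.H7.2"))
  expect_equal(ann$signatures, c("universal", ""))
  expect_equal(ann$na_interface, c(FALSE, TRUE))
  expect_equal(ann$domain, c("PIWI", "L2"))
  expect_equal(ann$sse, c("C.L21", "N.H7"))
})

test_that("reference mismatches error and unmappable rows are reported", {
  fx <- hago2_fixture()
  bad <- data.frame(protein = "hAGO2", ref_aa = "A", position = 733L,
                    alt_aa = "R", source = "x")
  expect_error(map_and_annotate(bad, fx$alignment, fx$topology_map),
               "ref mismatch.*A.*G")
  odd <- data.frame(protein = c("hAGO2", "nope"), ref_aa = c("G", "A"),
                    position = c(733L, 5L), alt_aa = "R", source = "x")
  ann <- map_and_annotate(odd, fx$alignment, fx$topology_map)
  expect_equal(nrow(ann), 1)
  unmapped <- attr(ann, "unmapped")
  expect_equal(unmapped$protein, "nope")
  expect_match(unmapped$reason, "not in alignment")
})

test_that("cancer-exclusive positions are the exact paralog-wide set difference", {
  cancer <- data.frame(protein = c("AGO2", "AGO2", "AGO1"),
                       code = c("X1", "X2", "X3"))
  variation <- data.frame(protein = c("AGO1", "AGO3"),
                          code = c("X1", "X4"))
  # X1 has variation in another paralog -> not exclusive
  expect_equal(cancer_exclusive(cancer, variation,
                                c("AGO1", "AGO2", "AGO3")),
               c("X2", "X3"))
  expect_error(cancer_exclusive(cancer, variation, character(0)), "empty")

  # brute-force planted property over random tables
  for (s in 1:200) {
    set.seed(s)
    codes <- sprintf("C.H1.%d", 1:40)
    paralogs <- paste0("AGO", 1:4)
    canc <- data.frame(protein = sample(paralogs, 60, TRUE),
                       code = sample(codes, 60, TRUE))
    vari <- data.frame(protein = sample(paralogs, 60, TRUE),
                       code = sample(codes, 60, TRUE))
    want <- sort(setdiff(unique(canc$code), unique(vari$code)))
    expect_equal(cancer_exclusive(canc, vari, paralogs), want)
  }
})

test_that("planted exclusive mutations are recovered through the full path", {
  sa <- synth_alignment(seed = 31)
  tm <- synth_topology_map(sa$alignment)
  paralogs <- sa$alignment$groups$AGO[1:4]
  ok_cols <- which(vapply(seq_len(sa$alignment$n_columns), function(col)
    all(vapply(paralogs, function(p)
      substr(sa$alignment$seqs[[p]], col, col) != "-", logical(1))),
    logical(1)))
  planted <- tm$codes[sample(ok_cols, 6)]
  mt <- synth_mutation_tables(planted, sa$alignment, tm, paralogs, seed = 31)
  ann_c <- map_and_annotate(mt$cancer, sa$alignment, tm)
  ann_v <- map_and_annotate(mt$variation, sa$alignment, tm)
  expect_equal(cancer_exclusive(ann_c, ann_v, paralogs), sort(planted))
})

test_that("domain densities normalize by domain size and dataset size", {
  fx <- hago2_fixture()
  tm <- fx$topology_map
  # records uniform over all positions -> density 1 in every domain
  rec <- data.frame(code = tm$codes, source = "variation")
  dd <- domain_distribution(rec, tm)
  expect_equal(dd$density, rep(1, nrow(dd)))
  # all records in one domain covering half the positions -> density 2
  half <- floor(length(tm$codes) / 2)
  tm2 <- tm
  tm2$domain_of[] <- rep(c("A", "B"), each = half)[seq_along(tm$codes)]
  recA <- data.frame(code = names(tm2$domain_of)[tm2$domain_of == "A"][1:10],
                     source = "cancer")
  ddA <- domain_distribution(recA, tm2)
  expect_equal(ddA$density[ddA$domain == "A"], 2, tolerance = 1e-9)
  expect_equal(ddA$density[ddA$domain == "B"], 0)
  expect_error(domain_distribution(rec[0, ], tm), "empty")
  # invariant: sum over domains of density * position share = 1 per source
  share <- table(tm$domain_of) / length(tm$domain_of)
  dd <- domain_distribution(data.frame(code = sample(tm$codes, 50),
                                       source = "cancer"), tm)
  expect_equal(sum(dd$density * as.numeric(share[dd$domain])), 1)
})

test_that("speckle categories follow the ratio and significance rules", {
  wt <- c(40, 42, 38, 41, 39, 40, 43, 37, 40)
  res <- categorize_speckles(
    list(strong = round(wt * 0.2), mid = round(wt * 0.4), same = wt),
    wt)
  expect_equal(res$category, c("Impaired", "Reduced", "Retained"))
  expect_lt(res$ratio[1], 0.25)
  expect_true(res$ratio[2] >= 0.25 && res$ratio[2] < 0.5)
  # a non-significant reduction stays Retained even below the ratio band
  noisy_wt <- c(5, 80, 40, 10, 70, 30, 90, 2, 33)
  res2 <- categorize_speckles(list(v = c(4, 60, 30, 8, 50, 25, 70, 1, 30)),
                              noisy_wt)
  expect_equal(res2$category, "Retained")
  # BH adjustment matches the hand step-up rule on the returned p-values
  padj_hand <- {
    p <- res$p_value
    n <- length(p)
    o <- order(p)
    adj <- pmin(1, p[o] * n / seq_len(n))
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n); out[o] <- adj; out
  }
  expect_equal(res$p_adjusted, padj_hand)
  expect_error(categorize_speckles(list(v = c(1, 2, 3)), c(0, 0, 0)),
               "all-zero WT")
  expect_error(categorize_speckles(list(v = c(1, 2)), wt), ">= 3")
})

test_that("categorization is monotone when mutant counts drop", {
  wt <- c(30, 35, 33, 31, 36, 34, 32, 30, 35)
  rank_of <- c(Impaired = 1, Reduced = 2, Retained = 3)
  base <- c(20, 22, 18, 21, 19, 23, 20, 22, 21)
  cats <- vapply(c(1, 0.6, 0.3, 0.1), function(f) {
    categorize_speckles(list(v = round(base * f)), wt)$category
  }, character(1))
  expect_true(all(diff(rank_of[cats]) <= 0))
})
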