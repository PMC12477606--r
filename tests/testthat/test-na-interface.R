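test_that("guide labels count the last three positions from the 3' end", {
  expect_equal(label_guide(22, 22), "3T")
  expect_equal(label_guide(22, 21), "3T-1")
  expect_equal(label_guide(22, 20), "3T-2")
  expect_equal(label_guide(22, 5), "5")
  # length dependence: position 19 is 3T-2 in a 21-mer but plain 19 in a 22-mer
  expect_equal(label_guide(21, 19), "3T-2")
  expect_equal(label_guide(22, 19), "19")
  expect_error(label_guide(22, 0), "out of range")
  expect_error(label_guide(22, 23), "out of range")
  expect_error(label_guide(3, 1), ">= 4")
})

test_that("guide labels round-trip through the parser for n in 18..30", {
  for (n in 18:30) {
    for (i in seq_len(n)) {
      lab <- label_guide(n, i)
      p <- parse_na_label(lab)
      expect_equal(p$strand, "guide")
      back <- if (p$kind == "three_prime") n - p$value else p$value
      expect_equal(back, i, info = sprintf("n=%d i=%d", n, i))
    }
  }
})

test_that("target labels encode matches and bulges", {
  pairing <- data.frame(resno = c(5, 9), matched_guide_index = c(5, 5),
                        is_bulge = c(FALSE, TRUE))
  tl <- label_target(pairing, guide_length = 21)
  expect_equal(tl$label, c("-5", "B-5"))
  expect_equal(tl$excluded, c(FALSE, TRUE))
  expect_equal(parse_na_label("-5"),
               list(strand = "target", kind = "target_match", value = 5L))
  expect_equal(parse_na_label("B-5")$kind, "bulge")
  expect_error(label_target(data.frame(resno = 1, matched_guide_index = 30,
                                       is_bulge = FALSE), 21),
               "outside guide length")
  expect_equal(nrow(label_target(pairing[0, ], 21)), 0)
})

test_that("NA contact extraction classifies backbone, base and C2'-OH", {
  nac <- synth_na_complex(
    guide_length = 21,
    edges = data.frame(protein_pos = c(4, 7, 9, 11),
                       label = c("13", "3T", "-5", "B-5"),
                       part = c("backbone", "backbone", "base", "backbone"),
                       c2oh = c(TRUE, FALSE, FALSE, FALSE)),
    seed = 2)
  set <- extract_na_contacts(nac$model, nac$code_lookup, nac$guide_chain,
                             nac$target_chain, nac$pairing)
  df <- as.data.frame(set)
  expect_setequal(paste(df$code, df$label),
                  c("N.L1.4 13", "N.L1.7 3T", "N.L1.9 -5", "N.L1.11 B-5"))
  r13 <- df[df$label == "13", ]
  expect_equal(r13$part, "backbone")
  expect_true(r13$c2oh)
  expect_false(df$c2oh[df$label == "3T"])
  expect_equal(df$part[df$label == "-5"], "base")
  expect_true(df$excluded[df$label == "B-5"])
  expect_false(any(df$excluded[df$label != "B-5"]))
  expect_error(extract_na_contacts(nac$model, nac$code_lookup, "A"),
               "not nucleic")
})

test_that("C2'-OH implies backbone and bulges never enter aggregates", {
  nac <- synth_na_complex(
    guide_length = 21,
    edges = data.frame(protein_pos = c(4, 5, 6),
                       label = c("13", "13", "B-5"),
                       part = c("backbone", "backbone", "backbone"),
                       c2oh = c(TRUE, FALSE, TRUE)),
    seed = 3)
  set <- extract_na_contacts(nac$model, nac$code_lookup, nac$guide_chain,
                             nac$target_chain, nac$pairing)
  expect_true(all(set$part[set$c2oh] == "backbone"))
  # pooled fraction at guide 13: one c2oh of two backbone edges
  expect_equal(c2oh_fraction(list(set), "13"), 0.5)
  expect_equal(backbone_fraction(list(set), "13"), 1.0)
  # the bulge edge exists but is invisible to the aggregate statistics
  expect_error(c2oh_fraction(list(set), "B-5"), "undefined value")
  expect_error(backbone_fraction(list(set), "B-5"), "undefined value")
  expect_error(c2oh_fraction(list(set), "7"), "undefined value")
})

na_set_from <- function(codes, labels, excluded = FALSE) {
  df <- data.frame(code = codes, label = labels, types = "hbond",
                   part = "backbone", c2oh = FALSE,
                   excluded = excluded, stringsAsFactors = FALSE)
  class(df) <- c("na_contact_set", "data.frame")
  df
}

test_that("shared interface requires presence in both groups", {
  ea <- list(na_set_from(c("N.H1.1", "N.H1.2"), c("7", "9")))
  pa <- list(na_set_from(c("N.H1.1", "N.H1.3"), c("9", "2")))
  expect_equal(shared_interface(ea, pa), "N.H1.1")
  expect_error(shared_interface(list(), pa), "empty group")
  # bulge-flagged contacts never make a position shared
  ea2 <- list(na_set_from("N.H1.4", "B-5", excluded = TRUE))
  pa2 <- list(na_set_from("N.H1.4", "B-5", excluded = TRUE))
  expect_equal(length(shared_interface(ea2, pa2)), 0)
})

test_that("signature NA interface needs the same label in both groups", {
  sig <- new_signature_set("eAgo", character(0), data.frame(
    column = 1:2, code = c("N.H1.1", "N.H1.2"), consensus = "K", ncs = 1))
  # N.H1.1 contacts guide 7 in both groups; N.H1.2 contacts 7 in one group
  # and 9 in the other -> shared position but not a signature-interface edge
  ea <- list(na_set_from(c("N.H1.1", "N.H1.2"), c("7", "7")))
  pa <- list(na_set_from(c("N.H1.1", "N.H1.2"), c("7", "9")))
  res <- signature_na_interface(sig, ea, pa)
  expect_equal(res$code, "N.H1.1")
  expect_equal(res$label, "7")
  # subset property: every edge is a signature position and a shared position
  expect_true(all(res$code %in% sig$entries$code))
  expect_true(all(res$code %in% shared_interface(ea, pa)))
})

test_that("interface charge averages per protein over interface residues", {
  aln <- tiny_alignment(c(anchor = "KRDG", p1 = "KRDG", p2 = "GGDG"))
  sse <- data.frame(lobe = "N", kind = "H", start = 1, end = 4)
  dom <- data.frame(domain = "N", start = 1, end = 4)
  tm <- build_topology_map(aln, "anchor", sse, dom)
  ch <- interface_charge(aln, c("p1", "p2"), c("N.H1.1", "N.H1.2"), tm)
  expect_equal(unname(ch["p1"]), positional_charge(c("K", "R")))
  expect_gt(ch[["p1"]], 0.99)
  expect_equal(unname(ch["p2"]), 0)
})
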