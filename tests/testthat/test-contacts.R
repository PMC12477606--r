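mini_model <- function(rows, id = "mini", source = "experimental") {
  structure_model(id, do.call(rbind, rows), source = source)
}

atom_row <- function(resno, resname, atom, element, x, y = 0, z = 0,
                     chain = "A", b = 0) {
  data.frame(chain = chain, resno = resno, resname = resname, atom = atom,
             element = element, x = x, y = y, z = z, b = b,
             stringsAsFactors = FALSE)
}

test_that("salt bridges respect the 4.0 A threshold", {
  m <- mini_model(list(atom_row(1, "LYS", "NZ", "N", 0),
                       atom_row(5, "ASP", "OD1", "O", 3.5)))
  ct <- detect_atomic_contacts(m)
  expect_true("saltbridge" %in% ct$type)
  m2 <- mini_model(list(atom_row(1, "LYS", "NZ", "N", 0),
                        atom_row(5, "ASP", "OD1", "O", 4.5)))
  expect_false("saltbridge" %in% detect_atomic_contacts(m2)$type)
})

test_that("vdw uses the element radius table", {
  # two carbons: cutoff 1.7 + 1.7 + 0.5 = 3.9
  m <- mini_model(list(atom_row(1, "ALA", "CB", "C", 0),
                       atom_row(5, "ALA", "CB", "C", 3.8)))
  expect_true("vdw" %in% detect_atomic_contacts(m)$type)
  m2 <- mini_model(list(atom_row(1, "ALA", "CB", "C", 0),
                        atom_row(5, "ALA", "CB", "C", 3.95)))
  expect_false("vdw" %in% detect_atomic_contacts(m2)$type)
})

test_that("hydrogen bonds pair donors with acceptors within 3.5 A", {
  m <- mini_model(list(atom_row(1, "SER", "OG", "O", 0),
                       atom_row(5, "ASN", "OD1", "O", 3.2)))
  expect_true("hbond" %in% detect_atomic_contacts(m)$type)
  # two pure donors do not hydrogen bond (LYS NZ vs backbone-less ASN ND2
  # is donor-donor); they may still register vdw
  m2 <- mini_model(list(atom_row(1, "LYS", "NZ", "N", 0),
                        atom_row(5, "ASN", "ND2", "N", 3.2)))
  expect_false("hbond" %in% detect_atomic_contacts(m2)$type)
})

test_that("aromatic geometry drives pi-cation and stacking calls", {
  hexagon <- function(resno, cx, cy, cz, tilt = 0) {
    ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    rows <- lapply(seq_along(ring), function(k) {
      x <- 1.4 * cos(ang[k]); y <- 1.4 * sin(ang[k])
      # tilt about the x axis
      yy <- y * cos(tilt); zz <- y * sin(tilt)
      atom_row(resno, "PHE", ring[k], "C", cx + x, cy + yy, cz + zz)
    })
    do.call(rbind, rows)
  }
  m <- mini_model(list(hexagon(1, 0, 0, 0),
                       atom_row(5, "LYS", "NZ", "N", 0, 0, 4.5)))
  expect_true("pication" %in% detect_atomic_contacts(m)$type)
  # parallel rings 4 A apart stack; same rings tilted 75 degrees t-stack
  m2 <- mini_model(list(hexagon(1, 0, 0, 0), hexagon(5, 0, 0, 4)))
  expect_true("pistack" %in% detect_atomic_contacts(m2)$type)
  m3 <- mini_model(list(hexagon(1, 0, 0, 0),
                        hexagon(5, 0, 0, 4, tilt = 75 * pi / 180)))
  expect_true("tstack" %in% detect_atomic_contacts(m3)$type)
})

test_that("detection equals brute-force enumeration on random structures", {
  for (s in 1:200) {
    m <- random_structure(n_res = 6, box = 10, seed = s)
    got <- detect_atomic_contacts(m)
    want <- brute_contacts(m)
    expect_identical(contact_fingerprint(got, from_argonet = TRUE),
                     contact_fingerprint(want), info = paste("seed", s))
  }
})

test_that("rigid-body motion leaves residue contact sets unchanged", {
  rot <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)
  lookup <- synth_code_lookup <- data.frame(resno = 1:8,
                                            code = sprintf("N.L1.%d", 1:8))
  m <- random_structure(n_res = 8, box = 9, seed = 77)
  set1 <- aggregate_contacts(detect_atomic_contacts(m), m, lookup)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% rot(0.83)
  m2 <- m
  m2$atoms$x <- xyz[, 1] + 11.3
  m2$atoms$y <- xyz[, 2] - 4.2
  m2$atoms$z <- xyz[, 3] + 0.5
  set2 <- aggregate_contacts(detect_atomic_contacts(m2), m2, lookup)
  expect_equal(set1$code_i, set2$code_i)
  expect_equal(set1$code_j, set2$code_j)
  expect_equal(set1$types, set2$types)
})

test_that("aggregation applies the pLDDT >= 80 filter to predicted models only", {
  rows <- list(atom_row(1, "ALA", "CB", "C", 0, b = 85),
               atom_row(1, "ALA", "CA", "C", -2, b = 85),
               atom_row(5, "ALA", "CB", "C", 3.5, b = 79),
               atom_row(5, "ALA", "CA", "C", 6, b = 79))
  lookup <- data.frame(resno = c(1, 5), code = c("N.H1.1", "N.H1.5"))
  pred <- mini_model(rows, id = "af", source = "predicted")
  set_pred <- aggregate_contacts(detect_atomic_contacts(pred), pred, lookup)
  expect_equal(nrow(set_pred), 0)  # one partner below 80 -> dropped
  expt <- mini_model(rows, id = "xtal", source = "experimental")
  set_expt <- aggregate_contacts(detect_atomic_contacts(expt), expt, lookup)
  expect_equal(nrow(set_expt), 1)  # filter does not apply
  # raising the low partner to 80 keeps the edge in the predicted model
  rows80 <- rows
  rows80[[3]]$b <- 80; rows80[[4]]$b <- 80
  pred80 <- mini_model(rows80, id = "af80", source = "predicted")
  expect_equal(nrow(aggregate_contacts(detect_atomic_contacts(pred80),
                                       pred80, lookup)), 1)
})

test_that("aggregation unions types, drops adjacent pairs and unmappables", {
  rows <- list(atom_row(1, "LYS", "NZ", "N", 0),
               atom_row(5, "ASP", "OD1", "O", 3.2),
               atom_row(5, "ASP", "OD2", "O", 3.4),
               atom_row(2, "ALA", "CB", "C", 0, y = 20),
               atom_row(3, "ALA", "CB", "C", 3.0, y = 20))
  lookup <- data.frame(resno = 1:5, code = sprintf("C.H1.%d", 1:5))
  m <- mini_model(rows)
  set <- aggregate_contacts(detect_atomic_contacts(m), m, lookup)
  # residues 2-3 are sequence-adjacent: excluded; 1-5 remains with unioned
  # types (saltbridge + hbond + vdw from several atom pairs)
  expect_equal(nrow(set), 1)
  expect_equal(set$code_i, "C.H1.1")
  expect_equal(set$code_j, "C.H1.5")
  expect_true(all(c("saltbridge", "vdw") %in%
                    strsplit(set$types, ",")[[1]]))
  # unmappable residues are dropped with a message
  lookup2 <- data.frame(resno = 1, code = "C.H1.1")
  expect_message(
    set2 <- aggregate_contacts(detect_atomic_contacts(m), m, lookup2),
    "unmappable")
  expect_equal(nrow(set2), 0)
})

test_that("contact conservation is the exact representative fraction", {
  ens <- synth_structure_ensemble(n_structures = 10, seed = 5)
  sets <- lapply(ens$models, function(m)
    aggregate_contacts(detect_atomic_contacts(m), m, ens$code_lookup))
  net <- contact_conservation(sets, "syn")
  key <- canon_edges(net$edges$code_i, net$edges$code_j)
  truth_key <- canon_edges(ens$truth$edges$code_i, ens$truth$edges$code_j)
  expect_setequal(key, truth_key)
  expect_equal(net$edges$cc[match(truth_key, key)],
               ens$truth$edges$expected_cc)
  # conservation of counts: sum k equals total edges over representatives
  expect_equal(sum(net$edges$k), sum(vapply(sets, nrow, integer(1))))
  expect_error(contact_conservation(sets[1]), "2 distinct proteins")
})

test_that("one representative per protein, experimental preferred", {
  ens <- synth_structure_ensemble(n_structures = 4, seed = 9,
                                  edges = data.frame(i = 3, j = 10, freq = 1))
  sets <- lapply(ens$models, function(m)
    aggregate_contacts(detect_atomic_contacts(m), m, ens$code_lookup))
  # give protein 1 a second, predicted structure with NO planted edge
  dup <- sets[[2]][0, ]
  attr(dup, "structure_id") <- "prot_01_model"
  attr(dup, "protein_id") <- attr(sets[[1]], "protein_id")
  attr(dup, "source") <- "predicted"
  attr(dup, "mean_confidence") <- 90
  class(dup) <- class(sets[[1]])
  net <- contact_conservation(c(sets, list(dup)), "syn")
  expect_equal(net$n_structures, 4)  # extra structure did not add a column
  expect_equal(net$edges$cc, 1)      # experimental representative won
})

test_that("SCN extraction follows the mCC + sdCC and signature-node rules", {
  edges <- data.frame(code_i = c("N.H1.1", "N.H1.2", "N.H1.3"),
                      code_j = c("N.H1.5", "N.H1.6", "N.H1.7"),
                      cc = c(1.0, 0.2, 0.2), k = c(5, 1, 1), n = 5)
  net <- structure(list(group = "g", edges = edges, n_structures = 5,
                        mcc = mean(edges$cc), sdcc = sd(edges$cc)),
                   class = "contact_network")
  expect_equal(net$mcc, 0.4667, tolerance = 1e-4)
  expect_equal(net$sdcc, 0.4619, tolerance = 1e-4)
  sig <- new_signature_set("g", character(0), data.frame(
    column = 1, code = "N.H1.1", consensus = "A", ncs = 1))
  scn <- extract_scn(net, sig)
  expect_equal(nrow(scn$edges), 1)
  expect_equal(scn$edges$cc, 1.0)
  # eligible edge without a signature endpoint is excluded
  sig2 <- new_signature_set("g", character(0), data.frame(
    column = 1, code = "N.H1.9", consensus = "A", ncs = 1))
  expect_equal(nrow(extract_scn(net, sig2)$edges), 0)
  expect_error(extract_scn(net, new_signature_set("g", character(0),
                                                  data.frame(column = integer(0),
                                                             consensus = character(0)))),
               "empty")
})

test_that("universal SCN requires the threshold in both subgroups", {
  e1 <- data.frame(code_i = c("N.H1.1", "N.H1.2"),
                   code_j = c("N.H1.5", "N.H1.6"),
                   cc = c(1.0, 0.1), k = c(10, 1), n = 10)
  e2 <- data.frame(code_i = c("N.H1.1", "N.H1.2"),
                   code_j = c("N.H1.5", "N.H1.6"),
                   cc = c(0.9, 0.9), k = c(9, 9), n = 10)
  net1 <- structure(list(group = "a", edges = e1, n_structures = 10,
                         mcc = 0.5, sdcc = 0.2),
                    class = "contact_network")
  net2 <- structure(list(group = "b", edges = e2, n_structures = 10,
                         mcc = 0.5, sdcc = 0.2), class = "contact_network")
  sig <- new_signature_set("universal", character(0), data.frame(
    column = 1:2, code = c("N.H1.1", "N.H1.2"), consensus = "A", ncs = 1))
  # edge 1 passes in both; edge 2 passes in net2 only
  u <- universal_scn(net1, net2, sig)
  expect_equal(nrow(u$edges), 1)
  expect_equal(u$edges$code_i, "N.H1.1")
})

test_that("position mean cc and SCN overlap are simple exact fractions", {
  edges <- data.frame(code_i = c("N.H1.1", "N.H1.1"),
                      code_j = c("N.H1.5", "N.H1.6"),
                      cc = c(1.0, 0.5), k = c(2, 1), n = 2)
  net <- structure(list(group = "g", edges = edges, n_structures = 2,
                        mcc = 0.75, sdcc = 0.35), class = "contact_network")
  expect_equal(position_mean_cc(net, "N.H1.1"), 0.75)
  expect_message(z <- position_mean_cc(net, "N.H1.9"), "no incident")
  expect_equal(z, 0)
  scn <- structure(list(group = "g", edges = edges,
                        signature_group = "g"), class = "scn")
  expect_equal(scn_overlap(edges, scn), 1.0)
  expect_equal(scn_overlap(edges[1, ], scn), 0.5)
})
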