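mini_structure <- function() {
  lines <- c(
    pdb_atom(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom(2, "CB", "ALA", "A", 1, 1, 0, 0),
    pdb_atom(3, "CA", "GLY", "A", 2, 10, 0, 0),
    pdb_atom(4, "CA", "LEU", "B", 10, 3, 4, 0),
    pdb_atom(5, "CA", "VAL", "B", 11, 40, 0, 0))
  cm <- data.frame(chain = c("A", "B"), gene = c("cox1", "cox4"),
                   genome = c("mt", "nuclear"))
  parse_structure(write_mini_pdb(lines), cm)
}

test_that("structure parsing extracts chains, residues and heavy atoms", {
  st <- mini_structure()
  expect_equal(sort(names(st$chains)), c("A", "B"))
  expect_equal(st$chains$A, "AG")
  expect_equal(st$chains$B, "LV")
  expect_equal(st$residue_numbers$B, c(10, 11))
  # hydrogens are dropped
  lines_h <- c(pdb_atom(1, "CA", "ALA", "A", 1, 0, 0, 0),
               pdb_atom(2, "H", "ALA", "A", 1, 0.5, 0, 0, element = "H"))
  st_h <- parse_structure(write_mini_pdb(lines_h),
                          data.frame(chain = "A", gene = "g", genome = "mt"))
  expect_equal(nrow(st_h$atoms), 1)
  # HETATM-only file is an error
  het <- pdb_atom(1, "FE", "HEM", "A", 1, 0, 0, 0, record = "HETATM",
                  element = "FE")
  expect_error(parse_structure(write_mini_pdb(het),
                               data.frame(chain = "A", gene = "g",
                                          genome = "mt")),
               "ATOM")
})

test_that("alternate locations keep one atom, the highest occupancy", {
  fmt <- "ATOM  %5d  CA %1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C"
  l1 <- sprintf(fmt, 1, "A", "ALA", "A", 1, 0, 0, 0, 0.40, 0)
  l2 <- sprintf(fmt, 2, "B", "ALA", "A", 1, 2, 0, 0, 0.60, 0)
  st <- parse_structure(write_mini_pdb(c(l1, l2)),
                        data.frame(chain = "A", gene = "g", genome = "mt"))
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$x, 2.0)
})

test_that("contact detection uses an inclusive 5 A minimum-distance rule", {
  st <- mini_structure()
  pairs <- find_contact_pairs(st, cutoff = 5)
  # A1..B10: closest atoms (1,0,0)-(3,4,0) at sqrt(4+16) < 5; and
  # (0,0,0)-(3,4,0) = 5.0 exactly -> boundary included via the closer atom
  expect_true(any(pairs$mt_residue == 1 & pairs$n_residue == 10))
  expect_equal(pairs$distance[pairs$mt_residue == 1 & pairs$n_residue == 10],
               sqrt(2^2 + 4^2))
  # the exact 5.0 boundary is inclusive
  one <- parse_structure(write_mini_pdb(c(
    pdb_atom(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom(2, "CA", "LEU", "B", 9, 3, 4, 0))),
    data.frame(chain = c("A", "B"), gene = c("m", "n"),
               genome = c("mt", "nuclear")))
  expect_equal(nrow(find_contact_pairs(one, cutoff = 5)), 1)
  # 5.01 A is out
  out <- parse_structure(write_mini_pdb(c(
    pdb_atom(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom(2, "CA", "LEU", "B", 9, 5.01, 0, 0))),
    data.frame(chain = c("A", "B"), gene = c("m", "n"),
               genome = c("mt", "nuclear")))
  expect_equal(nrow(find_contact_pairs(out, cutoff = 5)), 0)
})

test_that("intra-genome proximity is never reported as a contact", {
  st <- parse_structure(write_mini_pdb(c(
    pdb_atom(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom(2, "CA", "LEU", "B", 9, 2, 0, 0))),
    data.frame(chain = c("A", "B"), gene = c("n1", "n2"),
               genome = c("nuclear", "nuclear")))
  expect_equal(nrow(find_contact_pairs(st, cutoff = 5)), 0)
})

test_that("an unmapped chain is a configuration error naming the chain", {
  st <- mini_structure()
  st$chain_map <- st$chain_map[1, ]
  expect_error(find_contact_pairs(st), "B")
})

test_that("contacts shrink monotonically with the cutoff", {
  st <- mini_structure()
  p4 <- find_contact_pairs(st, cutoff = 4)
  p5 <- find_contact_pairs(st, cutoff = 5)
  keys <- function(p) paste(p$mt_residue, p$n_residue)
  expect_true(all(keys(p4) %in% keys(p5)))
})

test_that("contact pairs equal an all-pairs brute-force scan", {
  set.seed(17)
  lines <- character(0)
  serial <- 0
  resinfo <- list()
  for (chain in c("A", "B", "C")) {
    for (res in 1:8) {
      centre <- runif(3, 0, 18)
      for (k in 1:3) {
        serial <- serial + 1
        xyz <- centre + runif(3, -1, 1)
        lines <- c(lines, pdb_atom(serial, c("N", "CA", "C")[k], "ALA",
                                   chain, res, xyz[1], xyz[2], xyz[3]))
        resinfo[[serial]] <- c(chain = chain, res = res, xyz)
      }
    }
  }
  cm <- data.frame(chain = c("A", "B", "C"), gene = c("mtg", "ng1", "ng2"),
                   genome = c("mt", "nuclear", "nuclear"))
  st <- parse_structure(write_mini_pdb(lines), cm)
  pairs <- find_contact_pairs(st, cutoff = 5)
  # brute force over every atom pair
  info <- do.call(rbind, lapply(resinfo, function(x)
    data.frame(chain = x[1], res = as.integer(x[2]),
               x = as.numeric(x[3]), y = as.numeric(x[4]),
               z = as.numeric(x[5]))))
  found <- character(0)
  for (i in seq_len(nrow(info))) for (j in seq_len(nrow(info))) {
    gi <- cm$genome[cm$chain == info$chain[i]]
    gj <- cm$genome[cm$chain == info$chain[j]]
    if (gi != "mt" || gj != "nuclear") next
    d <- sqrt(sum((info[i, 3:5] - info[j, 3:5])^2))
    if (d <= 5) found <- c(found, paste(info$chain[i], info$res[i],
                                        info$chain[j], info$res[j]))
  }
  found <- sort(unique(found))
  mine <- sort(paste(pairs$mt_chain, pairs$mt_residue, pairs$n_chain,
                     pairs$n_residue))
  expect_equal(mine, found)
})

test_that("residues map through gaps to the right alignment column", {
  aln <- mn_alignment(c(ref = "AC-DE", other = "ACKDE"), "amino")
  expect_equal(map_residue_to_column("ACDE", 3, aln, "ref"), 4L)
  # identical sequences: column = position of the ungapped residue
  aln2 <- mn_alignment(c(ref = "ACDE", o = "ACDE"), "amino")
  for (i in 1:4) expect_equal(map_residue_to_column("ACDE", i, aln2, "ref"), i)
  # N-terminal extension of 10 residues: residue 11 -> column 1
  ext <- paste0(strrep("G", 10), "ACDEFGHIKLMNPQRSTVWY")
  aln3 <- mn_alignment(c(ref = "ACDEFGHIKLMNPQRSTVWY",
                         o = "ACDEFGHIKLMNPQRSTVWY"), "amino")
  expect_equal(map_residue_to_column(ext, 11, aln3, "ref"), 1L)
  expect_error(map_residue_to_column("ACDE", 2, aln, "missing_taxon"),
               "reference")
  # low identity refuses with a diagnostic
  expect_error(
    map_residue_to_column("WWWWWWWWWW", 2,
                          mn_alignment(c(ref = "ACDEFGHIKL", o = "ACDEFGHIKL"),
                                       "amino"), "ref"),
    "identity")
})

test_that("genes are classified by contact membership with fractions", {
  pairs <- data.frame(mt_gene = "cox1", mt_chain = "A",
                      mt_residue = c(5, 5, 9, 12, 30, 31, 32),
                      n_gene = "cox4", n_chain = "B",
                      n_residue = c(1, 2, 3, 4, 5, 6, 7),
                      distance = 4)
  cls <- classify_contact_genes(pairs, c("cox1", "cox4", "cox5a"),
                                n_residues = c(cox1 = 100, cox4 = 70,
                                               cox5a = 50))
  expect_equal(unname(cls$status[c("cox1", "cox4", "cox5a")]),
               c("contact", "contact", "non-contact"))
  # cox1 has 6 distinct contact residues of 100
  expect_equal(unname(cls$contact_fraction["cox1"]), 0.06)
  expect_equal(unname(cls$contact_fraction["cox4"]), 0.10)
  expect_equal(unname(cls$contact_fraction["cox5a"]), 0)
})
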