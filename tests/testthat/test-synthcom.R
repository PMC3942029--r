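test_that("family spec validation rejects inconsistent geometry", {
  expect_error(family_spec("f", triad_positions = c(200, 130, 321)),
               "strictly increasing")
  expect_error(family_spec("f", insert_length = 100), "inconsistent")
  expect_error(family_spec("f", cdh_offset = 21), "cdh_offset")
  # extra block overlapping the N2 anchor
  expect_error(family_spec("f", extra_blocks = list(c(70, 90))),
               "overlapping conserved blocks")
})

test_that("zero substitution rate reproduces the ancestor exactly", {
  fam <- generate_protein_families(
    list(family_spec("f", n_members = 3, substitution_rate = 0)), seed = 1)
  s <- as.character(fam$proteins)
  expect_length(unique(s), 1)
})

test_that("family generation is deterministic and separates families", {
  f1 <- five_family_set(seed = 42, n_members = 4, rate = 0.3)
  f2 <- five_family_set(seed = 42, n_members = 4, rate = 0.3)
  expect_identical(as.character(f1$proteins), as.character(f2$proteins))

  s <- as.character(f1$proteins)
  fam_of <- f1$truth$family_id
  within <- c(); between <- c()
  for (i in seq_along(s)[-length(s)]) {
    for (j in (i + 1):length(s)) {
      id <- seq_identity(s[i], s[j])
      if (fam_of[i] == fam_of[j]) within <- c(within, id)
      else between <- c(between, id)
    }
  }
  expect_gt(mean(within), mean(between))
  # two branches at rate 0.3 plus the exempt blocks: ~55% pairwise identity
  expect_gt(mean(within), 0.5)
  expect_lt(mean(between), 0.25)
})

test_that("every member carries the DDE triad and C/D(2)H motif", {
  fam <- five_family_set(seed = 7, n_members = 5, rate = 0.35)
  for (i in seq_len(nrow(fam$truth))) {
    tr <- fam$truth[i, ]
    ch <- strsplit(as.character(fam$proteins[[tr$protein_id]]), "")[[1]]
    expect_identical(ch[tr$d1], "D")
    expect_identical(ch[tr$d2], "D")
    expect_identical(ch[tr$e], "E")
    cdh <- tr$d2 + tr$cdh_offset
    expect_true(ch[cdh] %in% c("C", "D"))
    expect_identical(ch[cdh + 3], "H")
    expect_identical(tr$e - tr$d2 - 1L, tr$insert_length)
  }
})

test_that("planted elements respect IR, terminal-base and length accounting", {
  set.seed(5)
  te <- random_te("TE1", ir_length = 24, complementarity = 1, dr_length = 9)
  expect_identical(substr(te$sequence, 1, 1), "C")
  expect_identical(substr(te$sequence, nchar(te$sequence),
                          nchar(te$sequence)), "G")
  expect_identical(te$ir_right,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(te$ir_left))))

  pl <- plant_insertions(20000, te, site_model("uniform"), n_insertions = 1,
                         seed = 2)
  expect_identical(Biostrings::width(pl$genome)[1],
                   20000L + nchar(te$sequence) + te$dr_length)
})

test_that("imperfect IRs stay within the configured complementarity", {
  set.seed(9)
  te <- random_te("TE2", ir_length = 30, complementarity = 0.87)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(te$ir_left)))
  idem <- seq_identity(rc, te$ir_right)
  expect_gte(idem, 0.85)
  expect_lt(idem, 1)
})

test_that("truth rows are complete: re-extraction and DR fidelity", {
  set.seed(3)
  te <- random_te("TE1", tpase_aa_length = 250)
  pl <- plant_insertions(60000, te, site_model("uniform"), n_insertions = 8,
                         seed = 4)
  g <- as.character(pl$genome[[1]])
  tr <- pl$truth
  expect_identical(nrow(tr), 8L)
  for (i in seq_len(nrow(tr))) {
    planted <- substr(g, tr$start[i], tr$end[i])
    if (tr$strand[i] == "-") {
      planted <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(planted)))
    }
    expect_identical(planted, te$sequence)
    L <- tr$dr_length[i]
    expect_identical(substr(g, tr$start[i] - L, tr$start[i] - 1),
                     substr(g, tr$end[i] + 1, tr$end[i] + L))
    expect_identical(substr(g, tr$start[i] - L, tr$start[i] - 1),
                     tr$dr_sequence[i])
  }
})

test_that("degenerate offset distribution pins every truth offset", {
  set.seed(1)
  te <- random_te("TEp", tpase_aa_length = 220)
  pl <- plant_insertions(30000, te,
                         site_model("promoter_offset",
                                    offset_distribution = c(`16` = 1)),
                         n_insertions = 5, seed = 6)
  expect_true(all(pl$truth$promoter_offset == 16L))
})

test_that("AT-rich motif model duplicates a motif-matching target site", {
  set.seed(1)
  te <- random_te("TEh", dr_length = 8, tpase_aa_length = 220)
  pl <- plant_insertions(40000, te, site_model("at_rich_motif"),
                         n_insertions = 6, seed = 8)
  expect_true(all(nchar(pl$truth$dr_sequence) == 8))
  expect_true(all(grepl("^AA[ACGT]AT[ACGT]TT$", pl$truth$dr_sequence)))
})

test_that("circular junction abuts the IRs around a flank-derived linker", {
  set.seed(2)
  te <- random_te("TEc", ir_length = 24)
  flanks <- list(left = random_dna(50), right = random_dna(50))
  j <- emit_circular_junction(te, 6, "left", flanks)
  expect_identical(Biostrings::width(j)[1], 24L + 6L + 24L)
  j10 <- emit_circular_junction(te, 10, "left", flanks)
  expect_identical(substr(as.character(j10[[1]]), 25, 34),
                   substr(flanks$left, 1, 10))
  expect_error(emit_circular_junction(te, 5, "left", flanks), "linker")
  expect_error(emit_circular_junction(te, 11, "left", flanks), "linker")

  # the circle junction is detectable as an IR pair (terminal C rule does
  # not apply on the circle: the conserved termini abut at the junction)
  ir <- find_inverted_repeats(as.character(
    emit_circular_junction(te, 8, "right", flanks)[[1]]),
    require_terminal_c = FALSE)
  expect_false(is.null(ir))
  # chance-complementary linker bases may extend the repeat by a base
  expect_gte(ir$length, 24L)
  expect_lte(ir$length, 26L)
})
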