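test_that("flank extraction arithmetic, truncation and back-mapping", {
  g <- Biostrings::DNAStringSet(c(chr = mulekit:::random_dna(10000)))
  rec <- extract_with_flanks(g, 1001, 2000, flank = 400)
  expect_identical(nchar(rec$seq), 1000L + 800L)
  expect_false(rec$truncated_left || rec$truncated_right)
  # back-mapping: window position p maps to genome position p + offset - 1
  p <- 137
  expect_identical(substr(rec$seq, p, p),
                   substr(as.character(g[[1]]), p + rec$offset - 1,
                          p + rec$offset - 1))

  rec2 <- extract_with_flanks(g, 51, 500, flank = 400)
  expect_true(rec2$truncated_left)
  expect_identical(rec2$offset, 1L)
  expect_error(extract_with_flanks(g, 9000, 10500), "outside genome")
})

test_that("majority boundaries take modes with the documented tie rules", {
  hits <- data.frame(q_start = c(12, 12, 12, 300),
                     q_end = c(2400, 2400, 2400, 900))
  mb <- majority_boundaries(hits)
  expect_identical(mb$start, 12L)
  expect_identical(mb$end, 2400L)
  expect_identical(mb$status, "ok")

  # bimodal tie: maximal element
  tie <- data.frame(q_start = c(10, 10, 20, 20), q_end = c(90, 90, 80, 80))
  mb2 <- majority_boundaries(tie)
  expect_identical(mb2$start, 10L)
  expect_identical(mb2$end, 90L)

  two <- data.frame(q_start = c(1, 1), q_end = c(50, 50))
  expect_identical(majority_boundaries(two)$status, "insufficient_copies")
  expect_error(majority_boundaries(two[0, ]), "no hits")
})

test_that("IR detection finds planted repeats and enforces its filters", {
  set.seed(6)
  # keep the IR interior free of early cytosines so no shifted sub-repeat
  # can re-anchor the terminal-base rule
  inner <- paste(sample(c("A", "G", "T"), 23, replace = TRUE), collapse = "")
  irl <- paste0("C", inner)
  irr <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(irl)))
  rec <- paste0(irl, mulekit:::random_dna(500), irr)
  ir <- find_inverted_repeats(rec)
  expect_identical(ir$length, 24L)
  expect_identical(ir$mismatches, 0L)
  expect_identical(ir$ir_left$start, 1L)
  expect_identical(ir$ir_right$end, nchar(rec))

  # terminal G instead of C: rejected under the terminal-base rule
  recG <- paste0("G", substr(rec, 2, nchar(rec) - 1), "C")
  expect_null(find_inverted_repeats(recG))
  expect_false(is.null(find_inverted_repeats(recG,
                                             require_terminal_c = FALSE)))

  # 17 bp IR sits below the length band (exact matching; the bases just
  # inside the flanks are built to mismatch so the repeat cannot extend)
  irl17 <- paste0("C", paste(sample(c("A", "G", "T"), 16, replace = TRUE),
                             collapse = ""))
  rec17 <- paste0(irl17, "A", mulekit:::random_dna(400), "A",
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(irl17))))
  expect_null(find_inverted_repeats(rec17, max_mismatch_frac = 0))
})

test_that("IR detection is strand-symmetric", {
  set.seed(7)
  irl <- paste0("C", mulekit:::random_dna(27, gc = 0.5))
  irr <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(irl)))
  rec <- paste0(irl, mulekit:::random_dna(600), irr)
  ir <- find_inverted_repeats(rec)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rec)))
  ir2 <- find_inverted_repeats(rc)
  n <- nchar(rec)
  expect_identical(ir2$length, ir$length)
  expect_identical(ir2$ir_left$start, n - ir$ir_right$end + 1L)
  expect_identical(ir2$ir_right$end, n - ir$ir_left$start + 1L)
  expect_identical(ir2$ir_left$seq, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ir$ir_right$seq))))
})

test_that("DR detection requires exact flanking duplications, longest first", {
  set.seed(8)
  dr <- mulekit:::random_dna(9)
  g <- paste0(mulekit:::random_dna(100), dr, mulekit:::random_dna(500),
              dr, mulekit:::random_dna(100))
  d <- detect_dr(g, 110, 609)
  expect_identical(d$length, 9L)
  expect_identical(d$left_seq, d$right_seq)
  expect_identical(d$left_seq, dr)

  expect_null(detect_dr(mulekit:::random_dna(1000), 300, 700))
})

test_that("IR complementarity percentages match hand arithmetic", {
  set.seed(9)
  irl <- mulekit:::random_dna(24)
  irr <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(irl)))
  expect_equal(ir_complementarity(irl, irr), 100)

  # one mismatch in 24 bp -> 23/24
  ch <- strsplit(irr, "")[[1]]
  ch[12] <- setdiff(c("A", "C", "G", "T"), ch[12])[1]
  expect_equal(round(ir_complementarity(irl, paste(ch, collapse = "")), 1),
               95.8)

  # unrelated 20-mers score low
  vals <- vapply(1:15, function(i) {
    ir_complementarity(mulekit:::random_dna(20), mulekit:::random_dna(20))
  }, numeric(1))
  expect_true(all(vals >= 0 & vals <= 100))
  expect_lt(mean(vals), 75)
})

test_that("-1 frameshift detection fires on split transposases only", {
  set.seed(10)
  te <- random_te("TEf", frameshift_split = TRUE, tpase_aa_length = 320)
  fs <- detect_minus1_frameshift(te$sequence)
  expect_true(fs$frameshift)
  # the planted slip lies inside the detected ORF overlap window
  expect_gte(te$slip_site, fs$orf2$start - 3)
  expect_lte(te$slip_site, fs$orf1$end)

  plain <- random_te("TEn", frameshift_split = FALSE, tpase_aa_length = 320)
  expect_false(detect_minus1_frameshift(plain$sequence)$frameshift)

  # two ORFs in the same frame separated by a stop
  set.seed(11)
  orf <- reverse_translate(mulekit:::random_aa(150))
  rec <- paste0(orf, orf)
  found <- find_orfs(rec, min_nt = 300)
  expect_gte(nrow(found), 2)
  expect_false(detect_minus1_frameshift(rec)$frameshift)
})

test_that("multi-copy elements are annotated to planted boundaries", {
  set.seed(12)
  te <- random_te("TE1", ir_length = 26, dr_length = 9, tpase_aa_length = 300)
  pl <- plant_insertions(120000, te, site_model("uniform"), n_insertions = 5,
                         seed = 13, copy_substitution_rate = 0.01)
  tr <- pl$truth
  i <- which(tr$strand == "+")[1]
  ann <- annotate_te(pl$genome, tr$start[i] + te$cds_start - 1,
                     tr$start[i] + te$cds_end - 1, te_id = "TE1")
  expect_identical(attr(ann, "status"), "ok")
  expect_identical(nrow(ann), 5L)
  for (r in seq_len(nrow(ann))) {
    expect_lte(min(abs(ann$start[r] - tr$start)), 2)
    expect_lte(min(abs(ann$end[r] - tr$end)), 2)
  }
  expect_true(all(ann$dr_length == 9))
  expect_true(all(ann$ir_length >= 18 & ann$ir_length <= 39))
  expect_true(all(!ann$frameshift))
})

test_that("window extension reaches the boundaries of a large element", {
  set.seed(14)
  te <- random_te("ICE1", tpase_aa_length = 300,
                  passenger_aa_lengths = c(420, 400, 380, 350))
  expect_gt(nchar(te$sequence), 5500)
  pl <- plant_insertions(150000, te, site_model("uniform"), n_insertions = 4,
                         seed = 15)
  tr <- pl$truth
  i <- which(tr$strand == "+")[1]
  # the initial 400 bp flank covers only a fraction of the element
  ann <- annotate_te(pl$genome, tr$start[i] + te$cds_start - 1,
                     tr$start[i] + te$cds_end - 1, te_id = "ICE1")
  expect_identical(nrow(ann), 4L)
  for (r in seq_len(nrow(ann))) {
    expect_lte(min(abs(ann$start[r] - tr$start)), 2)
    expect_lte(min(abs(ann$end[r] - tr$end)), 2)
  }
})
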