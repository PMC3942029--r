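test_that("promoter scanning honours box spacing and score threshold", {
  set.seed(1)
  bg <- mulekit:::random_dna(60, gc = 0.6)
  seq17 <- paste0(bg, "TTGACA", mulekit:::random_dna(17, gc = 0.6), "TATAAT",
                  mulekit:::random_dna(60, gc = 0.6))
  h <- scan_sigma_promoters(seq17, score_min = 10)
  expect_identical(nrow(h), 1L)
  expect_identical(h$spacer, 17L)
  expect_identical(h$pos_minus35, 60L)

  # spacer outside 15-19 is never paired
  seq14 <- paste0(bg, "TTGACA", mulekit:::random_dna(14, gc = 0.6), "TATAAT",
                  mulekit:::random_dna(60, gc = 0.6))
  expect_identical(nrow(scan_sigma_promoters(seq14, score_min = 10)), 0L)

  polyA <- paste(rep("A", 200), collapse = "")
  expect_identical(nrow(scan_sigma_promoters(polyA, score_min = 14)), 0L)
})

test_that("junction flanks: two per element, deduplicated, truncated at ends", {
  set.seed(2)
  g <- Biostrings::DNAStringSet(c(chr = mulekit:::random_dna(5000)))
  ann <- data.frame(te_id = paste0("t", 1:3),
                    copy_id = paste0("t", 1:3),
                    genome_id = "chr",
                    start = c(1000, 2000, 3000),
                    end = c(1400, 2400, 3400), strand = "+")
  fl <- extract_junction_flanks(ann, g)
  expect_identical(nrow(fl), 6L)
  expect_setequal(unique(fl$side), c("IRl", "IRr"))
  expect_true(all(nchar(fl$sequence) == 300))

  # identical insertions collapse to one flank pair
  rep10 <- ann[rep(1, 10), ]
  rep10$copy_id <- paste0("c", 1:10)
  expect_identical(nrow(extract_junction_flanks(rep10, g)), 2L)

  # truncation near the contig end
  edge <- data.frame(te_id = "e", copy_id = "e", genome_id = "chr",
                     start = 4950, end = 4990, strand = "+")
  fe <- extract_junction_flanks(edge, g)
  expect_identical(nchar(fe$sequence[fe$side == "IRr"]), 10L)
  expect_true(fe$truncated[fe$side == "IRr"])
})

test_that("flanks read away from the element on the outward strand", {
  set.seed(3)
  left <- mulekit:::random_dna(300)
  right <- mulekit:::random_dna(300)
  te <- mulekit:::random_dna(400)
  g <- Biostrings::DNAStringSet(c(chr = paste0(left, te, right)))
  ann <- data.frame(te_id = "t", copy_id = "t", genome_id = "chr",
                    start = 301, end = 700, strand = "+")
  fl <- extract_junction_flanks(ann, g)
  expect_identical(fl$sequence[fl$side == "IRr"], right)
  expect_identical(fl$sequence[fl$side == "IRl"],
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(left))))
  # on the minus strand the same genomic flanks swap side labels
  ann$strand <- "-"
  fl2 <- extract_junction_flanks(ann, g)
  expect_identical(fl2$sequence[fl2$side == "IRl"], right)
})

test_that("positional enrichment normalizes, peaks and handles empties", {
  hits <- data.frame(pos_minus35 = rep(16L, 12), side = "IRr",
                     copy_id = paste0("c", 1:12), te_id = "t")
  prof <- positional_enrichment(hits)
  expect_equal(prof$profile$ratio[prof$profile$position == 16], 1.0)
  expect_identical(prof$peak_position, 16L)
  expect_equal(sum(prof$profile$ratio), 1, tolerance = 1e-12)

  # uniform hits over the 61 signed positions: every ratio near 1/61
  set.seed(4)
  signed <- sample(-30:30, 6100, replace = TRUE)
  u <- data.frame(pos_minus35 = abs(signed),
                  side = ifelse(signed < 0, "IRl", "IRr"),
                  copy_id = "c", te_id = "t")
  pu <- positional_enrichment(u)
  p0 <- 1 / 61
  sigma <- sqrt(p0 * (1 - p0) / 6100)
  expect_true(all(abs(pu$profile$ratio - p0) < 4 * sigma))
  expect_equal(sum(pu$profile$ratio), 1, tolerance = 1e-12)

  none <- data.frame(pos_minus35 = integer(0), side = character(0),
                     copy_id = character(0), te_id = character(0))
  expect_true(positional_enrichment(none)$undefined)
})

test_that("mirroring the genome mirrors the junction profile", {
  set.seed(5)
  te <- random_te("TEp", tpase_aa_length = 220)
  pl <- plant_insertions(60000, te,
                         site_model("promoter_offset",
                                    offset_distribution = c(`16` = 1)),
                         n_insertions = 25, seed = 6)
  run_profile <- function(genome, truth) {
    fl <- extract_junction_flanks(truth, genome)
    positional_enrichment(scan_junction_flanks(fl), n_junctions = nrow(fl))
  }
  p1 <- run_profile(pl$genome, pl$truth)
  n <- Biostrings::width(pl$genome)[1]
  rcg <- Biostrings::DNAStringSet(setNames(as.character(
    Biostrings::reverseComplement(pl$genome[[1]])), "synthetic_genome"))
  tr2 <- pl$truth
  tr2$start <- n - pl$truth$end + 1L
  tr2$end <- n - pl$truth$start + 1L

  # ignoring element orientation, mirroring swaps the junction sides and
  # negates the peak
  p2 <- run_profile(rcg, tr2)
  expect_identical(p2$peak_position, -p1$peak_position)
  expect_equal(p2$n_promoters_total, p1$n_promoters_total)

  # tracking element orientation through the mirror leaves the profile
  # unchanged (sides are labelled in element coordinates)
  tr3 <- tr2
  tr3$strand <- ifelse(pl$truth$strand == "+", "-", "+")
  p3 <- run_profile(rcg, tr3)
  expect_identical(p3$peak_position, p1$peak_position)
})

test_that("orientation bias separates oriented from unbiased insertions", {
  set.seed(7)
  te <- random_te("TEo", tpase_aa_length = 220)
  oriented <- plant_insertions(80000, te, site_model("promoter_offset"),
                               n_insertions = 30, seed = 8)
  fl <- extract_junction_flanks(oriented$truth, oriented$genome)
  ob <- orientation_bias(scan_junction_flanks(fl),
                         annotations = oriented$truth)
  expect_gt(ob$fraction, 0.9)

  unb <- plant_insertions(80000, te,
                          site_model("promoter_offset",
                                     orientation_rule = "unbiased"),
                          n_insertions = 40, seed = 9)
  flu <- extract_junction_flanks(unb$truth, unb$genome)
  obu <- orientation_bias(scan_junction_flanks(flu))
  expect_gt(obu$fraction, 0.2)
  expect_lt(obu$fraction, 0.8)

  single <- data.frame(pos_minus35 = 16L, side = "IRr", copy_id = "c1",
                       te_id = "t")
  expect_true(orientation_bias(single)$fraction %in% c(0, 1))
})

test_that("DR consensus covers observed bases with IUPAC codes", {
  drs <- c(rep("AAGATCTT", 10), rep("AATATTTT", 10))
  cons <- dr_consensus(drs)
  ch <- strsplit(cons$consensus, "")[[1]]
  # fixed positions agree with the family motif AANATNTT
  expect_identical(ch[c(1, 2, 4, 5, 7, 8)], c("A", "A", "A", "T", "T", "T"))
  # degenerate positions cover exactly the observed bases
  expect_setequal(mulekit:::iupac_bases(ch[3]), c("G", "T"))
  expect_setequal(mulekit:::iupac_bases(ch[6]), c("C", "T"))

  expect_identical(dr_consensus(rep("ACGTACGT", 3))$consensus, "ACGTACGT")

  set.seed(10)
  rnd <- vapply(1:200, function(i) mulekit:::random_dna(8, gc = 0.5),
                character(1))
  cr <- strsplit(dr_consensus(rnd)$consensus, "")[[1]]
  covered <- vapply(cr, function(x) length(mulekit:::iupac_bases(x)),
                    integer(1))
  # no sharp consensus emerges from random sites: positions stay degenerate
  expect_gte(mean(covered), 2)
  expect_gte(sum(covered >= 2), 6)

  expect_error(dr_consensus(character(0)), "no DR")
})

test_that("uniform insertions produce no spurious positional peak", {
  set.seed(11)
  te <- random_te("TEu", tpase_aa_length = 220)
  pl <- plant_insertions(100000, te, site_model("uniform"),
                         n_insertions = 40, seed = 12)
  fl <- extract_junction_flanks(pl$truth, pl$genome)
  # permissive threshold so the null has enough background detections
  jh <- scan_junction_flanks(fl, score_min = 5)
  prof <- positional_enrichment(jh, n_junctions = nrow(fl))
  expect_false(prof$undefined)
  baseline <- 1 / 61
  expect_lt(prof$peak_ratio, baseline + 3 / sqrt(prof$n_promoters_total))
})
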