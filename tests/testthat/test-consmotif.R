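test_that("gap-column filtering uses a strict threshold", {
  aln <- c(a = "AC-D", b = "AC-D", c = "A--D", d = "ACWD")
  f <- filter_gap_columns(aln, max_gap_frac = 0.6)
  # column 3 has 75% gaps and is removed; others kept
  expect_identical(f$column_map, c(1L, 2L, 4L))

  # exactly at the threshold: kept
  aln2 <- c(a = "A-", b = "A-", c = "AW", d = "AW", e = "AW")
  f2 <- filter_gap_columns(aln2, max_gap_frac = 0.4)
  expect_identical(f2$column_map, c(1L, 2L))

  expect_error(filter_gap_columns(c(a = "--", b = "--"), 0.6), "all columns")

  gap_free <- c(a = "ACDEF", b = "ACDEF")
  expect_identical(filter_gap_columns(gap_free)$column_map, 1:5)
})

test_that("windowed conservation matches substitution-matrix arithmetic", {
  b62 <- mulekit:::blosum62()
  expect_equal(as.numeric(windowed_conservation(c(a = "WWW", b = "WWW"))),
               rep(b62["W", "W"], 3))
  # F vs P scores -4 everywhere
  expect_equal(as.numeric(windowed_conservation(c(a = "FFFF", b = "PPPP"))),
               rep(-4, 4))
  # window 1 returns the raw column scores
  set.seed(1)
  aln <- c(a = mulekit:::random_aa(30), b = mulekit:::random_aa(30))
  p1 <- windowed_conservation(aln, window = 1)
  expect_equal(as.numeric(p1), as.numeric(attr(p1, "column_scores")))
})

test_that("windowed profiles equal a brute-force recomputation exactly", {
  b62 <- mulekit:::blosum62()
  brute <- function(m, window, gap = -4) {
    L <- ncol(m); n <- nrow(m)
    col <- sapply(seq_len(L), function(j) {
      sc <- c()
      for (i in seq_len(n - 1)) for (k in (i + 1):n) {
        a <- m[i, j]; b <- m[k, j]
        if (a == "-" && b == "-") next
        sc <- c(sc, if (a == "-" || b == "-") gap else b62[a, b])
      }
      if (length(sc)) mean(sc) else NA_real_
    })
    half <- (window - 1) / 2
    sapply(seq_len(L), function(p) {
      mean(col[max(1, ceiling(p - half)):min(L, floor(p + half))],
           na.rm = TRUE)
    })
  }
  for (s in 1:3) {
    set.seed(s)
    m <- matrix(sample(c(mulekit:::AA_ALPHABET20, "-"), 5 * 60,
                       replace = TRUE, prob = c(rep(0.045, 20), 0.1)),
                nrow = 5, dimnames = list(paste0("s", 1:5), NULL))
    for (w in c(1, 10, 15)) {
      expect_equal(as.numeric(windowed_conservation(m, window = w)),
                   brute(m, w))
    }
  }
})

test_that("profiles are invariant to row order", {
  set.seed(2)
  m <- matrix(sample(mulekit:::AA_ALPHABET20, 6 * 40, replace = TRUE),
              nrow = 6, dimnames = list(paste0("s", 1:6), NULL))
  p1 <- windowed_conservation(m)
  p2 <- windowed_conservation(m[sample(6), ])
  expect_equal(p1, p2)
})

test_that("triad anchoring recovers generator truth on family alignments", {
  fam <- generate_protein_families(
    list(family_spec("f", n_members = 10, substitution_rate = 0.3)),
    seed = 3)
  aln <- as_alignment(setNames(as.character(fam$proteins),
                               names(fam$proteins)))
  tr <- fam$truth[1, ]
  calls <- anchor_triad(aln, "f_01", c(tr$d1, tr$d2, tr$e))
  expect_gte(mean(!calls$flagged), 0.95)
  expect_true(all(calls$d1 == tr$d1 & calls$d2 == tr$d2 & calls$e == tr$e))
  expect_true(all(calls$insert_length == tr$insert_length))
  expect_true(all(calls$cdh_offset >= 11 & calls$cdh_offset <= 19))
  expect_true(all(calls$cdh_offset == tr$cdh_offset))

  # reference aligned with itself
  self <- anchor_triad(aln[1, , drop = FALSE][c(1, 1), ], "f_01",
                       c(tr$d1, tr$d2, tr$e))
  expect_true(all(self$d2 == tr$d2))
})

test_that("a gap at the D2 column flags the row", {
  aln <- c(ref = "ADWDKE", hit = "AD-DKE")
  # make D2 of the reference fall where the hit is gapped
  calls <- anchor_triad(aln, "ref", c(2, 3, 6))
  expect_true(calls$flagged[calls$id == "hit"])
  expect_true(is.na(calls$cdh_offset[calls$id == "hit"]))
})

test_that("C/D(2)H scanning respects the offset window", {
  set.seed(4)
  mk <- function(offset, first = "C") {
    ch <- strsplit(mulekit:::random_aa(80), "")[[1]]
    ch[ch == "H"] <- "A"; ch[ch == "C"] <- "S"; ch[ch == "D"] <- "N"
    d2 <- 20
    ch[d2] <- "D"
    ch[d2 + offset] <- first
    ch[d2 + offset + 3] <- "H"
    paste(ch, collapse = "")
  }
  expect_identical(scan_cdh_motif(mk(14), 20), 14L)
  expect_identical(scan_cdh_motif(mk(11, "D"), 20), 11L)
  expect_true(is.na(scan_cdh_motif(mk(25), 20)))
})

test_that("differential conservation isolates a group-specific block", {
  set.seed(100)
  anc <- mulekit:::random_aa(400)
  blk <- list(c(44, 59))
  gen <- function(id, blocks, sd) {
    generate_protein_families(list(
      family_spec(id, n_members = 10, substitution_rate = 0.3,
                  extra_blocks = blocks, ancestor = anc)), seed = sd)
  }
  nm <- function(f) setNames(as.character(f$proteins), names(f$proteins))
  fA <- gen("gA", blk, 1001)
  fB1 <- gen("gB1", blk, 1002)
  fB2 <- gen("gB2", list(), 1003)
  a1 <- as_alignment(c(nm(fA), nm(fB1)))
  a2 <- as_alignment(c(nm(fA), nm(fB2)))

  reg <- differential_conservation(a1, a2, reference_id = "gA_01")
  expect_identical(nrow(reg), 1L)
  expect_lte(reg$start, 59)
  expect_gte(reg$end, 44)
  pfms <- attr(reg, "pfms")
  expect_identical(length(pfms), 1L)
  expect_identical(nrow(pfms[[1]]), 20L)

  # identical second groups give zero regions
  expect_identical(nrow(differential_conservation(a1, a1,
                                                  reference_id = "gA_01")),
                   0L)

  # antisymmetry: swapping the alignments negates the difference
  swapped <- differential_conservation(a2, a1, reference_id = "gA_01")
  expect_identical(nrow(swapped), 0L)
  expect_equal(attr(swapped, "delta"), -attr(reg, "delta"))

  # a delta_min above the maximal difference returns nothing
  expect_identical(nrow(differential_conservation(
    a1, a2, reference_id = "gA_01",
    delta_min = max(attr(reg, "delta")) + 1)), 0L)
})

test_that("anchor-domain location finds planted plateaus greedily", {
  prof <- rep(0, 200)
  prof[20:40] <- 5
  prof[90:110] <- 4
  prof[160:180] <- 6
  doms <- locate_anchor_domains(prof, n_domains = 3, width = 15,
                                min_score = 2)
  expect_identical(nrow(doms), 3L)
  expect_true(all(diff(doms$start) > 0))
  expect_true(doms$start[1] >= 15 && doms$end[1] <= 45)
  expect_true(doms$start[3] >= 155 && doms$end[3] <= 185)
  # non-overlap
  for (i in seq_len(nrow(doms) - 1)) {
    expect_lt(doms$end[i], doms$start[i + 1])
  }

  expect_identical(nrow(locate_anchor_domains(rep(0.5, 100))), 0L)
})
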