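# Alignment-based conservation profiling and motif discovery.
#
# Profiles follow the plotcon convention: the column score is the mean of
# all pairwise substitution-matrix scores at that column, and the profile
# value is the mean column score over a centered window (shrunk at the
# alignment edges). Gap-vs-residue pairs score a fixed penalty;
# gap-vs-gap pairs are excluded from the pair average.

#' Coerce an alignment to a character matrix (rows = sequences)
#'
#' Accepts an aligned [Biostrings::AAStringSet], a named character vector
#' of equal-length gapped strings, or an existing character matrix.
#' @param aln alignment in any of the supported forms.
#' @return character matrix with rownames.
#' @export
as_alignment <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is(aln, "XStringSet")) aln <- setNames(as.character(aln), names(aln))
  stopifnot(is.character(aln))
  w <- unique(nchar(aln))
  if (length(w) != 1) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Read an aligned FASTA file into an alignment matrix
#' @param path aligned FASTA path.
#' @return character matrix.
#' @export
read_alignment <- function(path) {
  as_alignment(Biostrings::readAAStringSet(path))
}

#' Remove alignment columns dominated by gaps
#'
#' Drops columns whose gap fraction strictly exceeds `max_gap_frac`
#' (a column with exactly the threshold fraction is kept).
#'
#' @param aln alignment (see [as_alignment()]).
#' @param max_gap_frac maximum tolerated gap fraction (default 0.6).
#' @return list with `aln` (filtered matrix) and `column_map` (original
#'   column index of each kept column).
#' @export
filter_gap_columns <- function(aln, max_gap_frac = 0.6) {
  m <- as_alignment(aln)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) == 0) stop("all columns removed by gap filter")
  list(aln = m[, keep, drop = FALSE], column_map = keep)
}

#' Windowed conservation profile of an alignment
#'
#' Column score = mean over all row pairs of the substitution-matrix score
#' of their residues (gap-vs-residue scored `gap_penalty`, gap-vs-gap
#' excluded); profile value = mean column score over a centered window of
#' `window` columns, shrunk at the edges.
#'
#' @param aln alignment (>= 2 rows).
#' @param window window size in aa (default 15; 1 returns the raw column
#'   scores).
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_penalty score of a gap-vs-residue pair (default -4).
#' @return numeric vector of length = column count, with attribute
#'   `column_scores`.
#' @export
windowed_conservation <- function(aln, window = 15, matrix = "BLOSUM62",
                                  gap_penalty = -4) {
  m <- as_alignment(aln)
  if (nrow(m) < 2) stop("need at least two aligned rows")
  sm <- resolve_submatrix(matrix)
  L <- ncol(m)
  n <- nrow(m)
  sums <- rep(0, L)
  cnts <- rep(0, L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- m[i, ]; b <- m[j, ]
      ga <- a == "-"; gb <- b == "-"
      both <- ga & gb
      one <- xor(ga, gb)
      res <- !(ga | gb)
      sc <- rep(0, L)
      sc[one] <- gap_penalty
      if (any(res)) sc[res] <- sm[cbind(a[res], b[res])]
      sums <- sums + ifelse(both, 0, sc)
      cnts <- cnts + !both
    }
  }
  col_scores <- ifelse(cnts > 0, sums / cnts, NA_real_)
  half <- (window - 1) / 2
  prof <- vapply(seq_len(L), function(p) {
    lo <- max(1, ceiling(p - half))
    hi <- min(L, floor(p + half))
    mean(col_scores[lo:hi], na.rm = TRUE)
  }, numeric(1))
  attr(prof, "column_scores") <- col_scores
  prof
}

# map: for each row, the ungapped residue index at each alignment column
# (NA at gaps)
residue_index_map <- function(row_chars) {
  idx <- cumsum(row_chars != "-")
  idx[row_chars == "-"] <- NA_integer_
  idx
}

#' Anchor the DDE catalytic triad across an alignment
#'
#' Maps a reference row's triad (D1, D2, E; 1-based positions in the
#' ungapped reference) through the alignment columns to every row. A call
#' is flagged when the column holds a gap or a residue outside `{D, E}`.
#' For unflagged rows the D2-to-E insert length and the C/D(2)H motif
#' offset (via [scan_cdh_motif()]) are reported.
#'
#' @param aln alignment.
#' @param reference_id row name of the reference sequence.
#' @param reference_triad integer vector `(D1, D2, E)` in ungapped
#'   reference coordinates.
#' @param cdh_range offset range scanned for the C/D(2)H motif.
#' @return data.frame, one row per sequence: `id`, `d1`, `d2`, `e`
#'   (ungapped per-row indices, NA at gaps), `flagged`, `insert_length`,
#'   `cdh_offset`.
#' @export
anchor_triad <- function(aln, reference_id, reference_triad,
                         cdh_range = c(11L, 19L)) {
  m <- as_alignment(aln)
  if (!(reference_id %in% rownames(m))) stop("reference row absent")
  ref <- m[reference_id, ]
  ref_map <- residue_index_map(ref)
  cols <- vapply(reference_triad, function(p) {
    w <- which(ref_map == p)
    if (length(w) != 1) stop("reference triad position not in alignment")
    w
  }, integer(1))

  rows <- lapply(rownames(m), function(id) {
    r <- m[id, ]
    rmap <- residue_index_map(r)
    res <- r[cols]
    idx <- rmap[cols]
    flagged <- any(is.na(idx)) ||
      !(res[1] %in% "D") || !(res[2] %in% "D") || !(res[3] %in% c("D", "E"))
    ins <- if (!any(is.na(idx[2:3]))) idx[3] - idx[2] - 1L else NA_integer_
    cdh <- NA_integer_
    if (!is.na(idx[2]) && !flagged) {
      ungapped <- paste(r[r != "-"], collapse = "")
      cdh <- scan_cdh_motif(ungapped, idx[2], offset_range = cdh_range)
    }
    data.frame(id = id, d1 = idx[1], d2 = idx[2], e = idx[3],
               flagged = flagged, insert_length = ins, cdh_offset = cdh,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Scan for the C/D(2)H motif downstream of the second catalytic aspartate
#'
#' Searches offsets `offset_range` downstream of D2 for the pattern
#' `[CD]xxH` (Cys or Asp, two arbitrary residues, His). The nearest match
#' is returned.
#'
#' @param seq ungapped protein sequence (character).
#' @param d2_index 1-based position of D2 in `seq`.
#' @param offset_range allowed motif-start offsets (default 11-19 aa).
#' @return the offset (integer) or `NA` when no match lies in range.
#' @export
scan_cdh_motif <- function(seq, d2_index, offset_range = c(11L, 19L)) {
  ch <- seq_chars(seq)
  for (off in seq(offset_range[1], offset_range[2])) {
    p <- d2_index + off
    if (p + 3 > length(ch)) break
    if (ch[p] %in% c("C", "D") && ch[p + 3] == "H") return(off)
  }
  NA_integer_
}

project_profile <- function(m, prof, reference_id) {
  ref_map <- residue_index_map(m[reference_id, ])
  keep <- which(!is.na(ref_map))
  list(positions = ref_map[keep], values = prof[keep], columns = keep)
}

#' Differential conservation signature between two alignments
#'
#' Computes windowed conservation profiles for two alignments sharing a
#' reference row (e.g. "targeting" families versus "non-targeting"
#' families each aligned with the same core group), projects both onto the
#' reference's ungapped residue coordinates, and returns maximal runs
#' where `profile1 - profile2 > delta_min` for at least `run_min`
#' positions, each with a consensus position frequency matrix over the
#' first alignment's rows.
#'
#' @param aln1,aln2 alignments sharing at least one row name.
#' @param reference_id shared reference row (default: first shared name).
#' @param window window size in aa (default 10).
#' @param matrix substitution matrix.
#' @param delta_min minimum profile difference (matrix units, default 1;
#'   calibrated on synthetic truth so chance fluctuations between
#'   exchangeable groups stay below threshold).
#' @param run_min minimum run length in positions (default 8).
#' @return data.frame of signature regions (`start`, `end` in reference
#'   residue coordinates, `mean_delta`), with attributes `delta`
#'   (positionwise difference), `positions` and `pfms` (per-region 20-row
#'   residue count matrices from `aln1`).
#' @export
differential_conservation <- function(aln1, aln2, reference_id = NULL,
                                      window = 10, matrix = "BLOSUM62",
                                      delta_min = 1, run_min = 8) {
  m1 <- as_alignment(aln1)
  m2 <- as_alignment(aln2)
  shared <- intersect(rownames(m1), rownames(m2))
  if (length(shared) == 0) stop("alignments share no rows")
  if (is.null(reference_id)) reference_id <- shared[1]
  if (!(reference_id %in% shared)) stop("reference not shared")

  p1 <- project_profile(m1, windowed_conservation(m1, window, matrix),
                        reference_id)
  p2 <- project_profile(m2, windowed_conservation(m2, window, matrix),
                        reference_id)
  pos <- intersect(p1$positions, p2$positions)
  v1 <- p1$values[match(pos, p1$positions)]
  v2 <- p2$values[match(pos, p2$positions)]
  delta <- v1 - v2

  above <- delta > delta_min
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values & r$lengths >= run_min)
  regions <- data.frame(start = pos[starts[sel]], end = pos[ends[sel]],
                        mean_delta = vapply(sel, function(k) {
                          mean(delta[starts[k]:ends[k]])
                        }, numeric(1)))
  pfms <- lapply(sel, function(k) {
    cols <- p1$columns[match(pos[starts[k]:ends[k]], p1$positions)]
    sub <- m1[, cols, drop = FALSE]
    t(vapply(AA_ALPHABET20, function(a) colSums(sub == a),
             numeric(ncol(sub))))
  })
  attr(regions, "delta") <- delta
  attr(regions, "positions") <- pos
  attr(regions, "pfms") <- pfms
  regions
}

#' Locate the top conserved domains of a conservation profile
#'
#' Returns up to `n_domains` highest-mean non-overlapping windows whose
#' mean conservation exceeds `min_score`, greedily best-first, reported in
#' alignment order (for Mutator-like transposases typically N1, N2 and the
#' catalytic domain).
#'
#' @param profile numeric profile from [windowed_conservation()].
#' @param n_domains number of domains requested (default 3).
#' @param width domain window width in columns (default 15).
#' @param min_score minimum windowed mean to accept (default 2 matrix
#'   units).
#' @return data.frame `start`, `end`, `mean_score`, ordered by position;
#'   fewer rows than requested when the profile has fewer regions.
#' @export
locate_anchor_domains <- function(profile, n_domains = 3, width = 15,
                                  min_score = 2) {
  L <- length(profile)
  if (L < width) width <- L
  wm <- vapply(seq_len(L - width + 1), function(i) {
    mean(profile[i:(i + width - 1)])
  }, numeric(1))
  taken <- rep(FALSE, L)
  out <- list()
  ord <- order(-wm)
  for (i in ord) {
    if (length(out) == n_domains) break
    if (wm[i] < min_score) break
    span <- i:(i + width - 1)
    if (any(taken[span])) next
    taken[span] <- TRUE
    out[[length(out) + 1]] <- data.frame(start = i, end = i + width - 1,
                                         mean_score = wm[i])
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_score = numeric(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
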