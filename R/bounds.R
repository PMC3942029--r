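# TE boundary calling from multi-copy genomic evidence.
#
# A transposase CDS plus flanking DNA is mapped back to its genome with a
# seed-and-extend nucleotide aligner; element boundaries are the modal
# start/end of the high-scoring pairs, extended while they touch the query
# window edge; boundaries are validated by terminal inverted repeat (IR)
# and direct repeat (DR) detection, IR complementarity and -1 frameshift
# analysis. All coordinates are 1-based inclusive.

genome_as_character <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    list(seq = as.character(genome[[1]]),
         id = if (!is.null(names(genome))) names(genome)[1] else "genome")
  } else if (is(genome, "DNAString")) {
    list(seq = as.character(genome), id = "genome")
  } else {
    list(seq = as.character(genome)[1],
         id = if (!is.null(names(genome))) names(genome)[1] else "genome")
  }
}

#' Extract a CDS together with flanking sequence
#'
#' Returns the window `[cds_start - flank, cds_end + flank]`, truncated at
#' contig ends (with flags), and the offset needed to map window positions
#' back to genome coordinates (`genome_pos = window_pos + offset - 1`).
#'
#' @param genome genome sequence ([Biostrings::DNAStringSet], DNAString or
#'   character).
#' @param cds_start,cds_end 1-based inclusive CDS coordinates.
#' @param flank flank length in bp (default 400).
#' @return list with `seq` (character), `offset`, `truncated_left`,
#'   `truncated_right`, `genome_id`.
#' @export
extract_with_flanks <- function(genome, cds_start, cds_end, flank = 400) {
  g <- genome_as_character(genome)
  n <- nchar(g$seq)
  if (cds_start < 1 || cds_end > n || cds_start > cds_end) {
    stop("CDS coordinates outside genome")
  }
  from <- as.integer(max(1, cds_start - flank))
  to <- as.integer(min(n, cds_end + flank))
  list(seq = substr(g$seq, from, to), offset = from,
       truncated_left = from > cds_start - flank,
       truncated_right = to < cds_end + flank,
       genome_id = g$id)
}

nuc_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = TRUE)
    }
    cache
  }
})

seed_clusters <- function(qpos, spos, diag_tol = 20, gap_tol = 1000) {
  d <- spos - qpos
  ord <- order(d, spos)
  qpos <- qpos[ord]; spos <- spos[ord]; d <- d[ord]
  groups <- list()
  cur <- 1
  for (i in seq_along(d)[-1]) {
    if (d[i] - d[i - 1] > diag_tol ||
        (d[i] - d[i - 1] <= diag_tol && spos[i] - spos[i - 1] > gap_tol)) {
      groups[[length(groups) + 1]] <- cur
      cur <- i
    }
  }
  groups[[length(groups) + 1]] <- cur
  starts <- unlist(groups)
  ends <- c(starts[-1] - 1, length(d))
  lapply(seq_along(starts), function(k) {
    idx <- starts[k]:ends[k]
    list(qmin = min(qpos[idx]), qmax = max(qpos[idx]),
         smin = min(spos[idx]), smax = max(spos[idx]), n = length(idx))
  })
}

#' Map a query sequence to a genome with a seed-and-extend aligner
#'
#' Exact k-mer seeds (non-overlapping, both strands) are clustered by
#' diagonal and each candidate locus is refined by local alignment.
#' Subject coordinates are always reported on the forward strand; query
#' coordinates are in the original query orientation.
#'
#' @param query query sequence (character or DNAString).
#' @param genome genome ([Biostrings::DNAStringSet] or character).
#' @param k seed length (default 12).
#' @param min_seeds minimum seed matches per candidate locus.
#' @param min_identity discard refined hits below this percent identity.
#' @param min_hit_frac discard refined hits covering less than this
#'   fraction of the query.
#' @return data.frame of hits: `query_id`, `genome_id`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `strand`, `identity`, `score`.
#' @export
map_query_hits <- function(query, genome, k = 12, min_seeds = 2,
                           min_identity = 75, min_hit_frac = 0.25) {
  g <- genome_as_character(genome)
  gseq <- Biostrings::DNAString(g$seq)
  q <- as.character(query)
  qlen <- nchar(q)
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  if (qlen < k) stop("query shorter than seed length")

  one_strand <- function(qstr, strand) {
    starts <- seq(1L, qlen - k + 1L, by = k)
    seeds <- Biostrings::DNAStringSet(vapply(starts, function(s) {
      substr(qstr, s, s + k - 1L)
    }, character(1)))
    ok <- !grepl("[^ACGT]", as.character(seeds))
    starts <- starts[ok]; seeds <- seeds[ok]
    if (length(seeds) == 0) return(NULL)
    pd <- Biostrings::matchPDict(Biostrings::PDict(seeds), gseq)
    qpos <- integer(0); spos <- integer(0)
    for (i in seq_along(pd)) {
      st <- Biostrings::start(pd[[i]])
      if (length(st) > 0) {
        qpos <- c(qpos, rep(starts[i], length(st)))
        spos <- c(spos, st)
      }
    }
    if (length(qpos) == 0) return(NULL)
    cl <- seed_clusters(qpos, spos)
    cl <- Filter(function(c) c$n >= min_seeds, cl)
    if (length(cl) == 0) return(NULL)
    rows <- lapply(cl, function(c) {
      ws <- max(1L, c$smin - (c$qmin - 1L) - 50L)
      we <- min(nchar(g$seq), c$smax + k - 1L + (qlen - (c$qmax + k - 1L)) + 50L)
      win <- Biostrings::DNAString(substr(g$seq, ws, we))
      pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(qstr), win,
                                          type = "local",
                                          substitutionMatrix = nuc_submat(),
                                          gapOpening = 5, gapExtension = 2)
      pr <- Biostrings::pattern(pa); sr <- Biostrings::subject(pa)
      qs <- Biostrings::start(pr); qe <- Biostrings::end(pr)
      if (strand == "-") {
        tmp <- qs
        qs <- qlen - qe + 1L
        qe <- qlen - tmp + 1L
      }
      data.frame(query_id = qid, genome_id = g$id,
                 q_start = qs, q_end = qe,
                 s_start = ws + Biostrings::start(sr) - 1L,
                 s_end = ws + Biostrings::end(sr) - 1L,
                 strand = strand, identity = Biostrings::pid(pa),
                 score = Biostrings::score(pa), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  hits <- rbind(one_strand(q, "+"), one_strand(revcomp(q), "-"))
  if (is.null(hits) || nrow(hits) == 0) {
    return(data.frame(query_id = character(0), genome_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand = character(0), identity = numeric(0),
                      score = numeric(0)))
  }
  hits <- hits[hits$identity >= min_identity &
               (hits$q_end - hits$q_start + 1) >= min_hit_frac * qlen, ,
               drop = FALSE]
  # collapse overlapping loci (same region found from both strands or
  # neighbouring seed clusters): keep the best-scoring hit
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      ov <- min(hits$s_end[i], hits$s_end[j]) -
            max(hits$s_start[i], hits$s_start[j]) + 1
      if (ov > 0.5 * (hits$s_end[i] - hits$s_start[i] + 1)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits[order(hits$s_start), , drop = FALSE]
}

#' Majority-vote TE boundaries from multi-copy hits
#'
#' When an element is present in enough copies, its boundaries are the
#' modal start and end of the high-scoring pairs in query coordinates.
#' Bimodal ties resolve to the smaller start and the larger end (maximal
#' element). With `copy count <= min_copies` the result is flagged
#' `insufficient_copies` so the caller can bring in related isolates.
#'
#' @param hits data.frame from [map_query_hits()] (one shared query).
#' @param min_copies automatic calling requires strictly more hits than
#'   this (default 3, i.e. at least 4 copies).
#' @return list with `start`, `end` (query coordinates), `n` and `status`
#'   (`"ok"` or `"insufficient_copies"`).
#' @export
majority_boundaries <- function(hits, min_copies = 3) {
  if (nrow(hits) == 0) stop("no hits")
  list(start = as.integer(modal_value(hits$q_start, "min")),
       end = as.integer(modal_value(hits$q_end, "max")),
       n = nrow(hits),
       status = if (nrow(hits) > min_copies) "ok" else "insufficient_copies")
}

#' Extend a query window until element boundaries fall inside it
#'
#' When the modal hit boundaries touch the first or last base of the query
#' window the element extends beyond it; the window grows by `step` on
#' that side and the genome is re-mapped, until the boundaries are
#' strictly interior or the contig end is reached.
#'
#' @param genome genome sequence.
#' @param window_start,window_end current window (genome coordinates).
#' @param step growth increment in bp.
#' @param max_rounds safety cap on extension rounds.
#' @param ... passed to [map_query_hits()].
#' @return list with `start`, `end` (genome coordinates of the modal
#'   element locus in the window), `hits`, `boundaries` (query-coordinate
#'   majority call), `window` and `truncated` flag.
#' @export
extend_boundaries <- function(genome, window_start, window_end, step = 400,
                              max_rounds = 25, ...) {
  g <- genome_as_character(genome)
  n <- nchar(g$seq)
  truncated <- FALSE
  for (r in seq_len(max_rounds)) {
    qseq <- substr(g$seq, window_start, window_end)
    hits <- map_query_hits(qseq, genome, ...)
    mb <- majority_boundaries(hits, min_copies = 0)
    at_left <- mb$start <= 1
    at_right <- mb$end >= nchar(qseq)
    if (!at_left && !at_right) break
    grew <- FALSE
    if (at_left && window_start > 1) {
      window_start <- max(1L, window_start - step)
      grew <- TRUE
    }
    if (at_right && window_end < n) {
      window_end <- min(n, window_end + step)
      grew <- TRUE
    }
    if (!grew) { truncated <- TRUE; break }
  }
  list(start = window_start + mb$start - 1L,
       end = window_start + mb$end - 1L,
       hits = hits, boundaries = mb,
       window = c(window_start, window_end), truncated = truncated)
}

#' Detect terminal inverted repeats of an element
#'
#' Scans the two terminal windows of the record for the highest-scoring
#' reverse-complement match pair (matches scored +1, mismatches -3 so that
#' chance extension beyond the true repeat loses; ties go to the longer,
#' then the more terminal pair) within the length band. With
#' `require_terminal_c`, the outward-facing terminus of each IR must be a
#' cytosine read into the element on its own strand (record starts with C
#' and ends with G on the top strand).
#'
#' @param record element sequence (character or DNAString).
#' @param search_window terminal window size in bp.
#' @param min_len,max_len allowed IR length band (default 18-39 bp).
#' @param max_mismatch_frac maximum fraction of mismatched IR positions.
#' @param require_terminal_c enforce the conserved terminal cytosine.
#' @return `NULL` when nothing qualifies, else a list with `ir_left`,
#'   `ir_right` (each `start`, `end`, `seq`), `length`, `mismatches`.
#' @export
find_inverted_repeats <- function(record, search_window = 60,
                                  min_len = 18, max_len = 39,
                                  max_mismatch_frac = 0.17,
                                  require_terminal_c = TRUE) {
  s <- as.character(record)
  n <- nchar(s)
  if (n <= 2 * search_window) {
    search_window <- floor(n / 2)
  }
  if (search_window < min_len) return(NULL)
  lw <- seq_chars(substr(s, 1, search_window))
  rcw <- seq_chars(revcomp(substr(s, n - search_window + 1, n)))
  # rcw position a corresponds to a right candidate ending at record
  # position n - a + 1 (revcomp orientation)
  best <- NULL
  for (L in min_len:max_len) {
    if (L > search_window) break
    for (i in seq_len(search_window - L + 1)) {
      if (require_terminal_c && lw[i] != "C") next
      li <- lw[i:(i + L - 1)]
      for (a in seq_len(search_window - L + 1)) {
        if (require_terminal_c && rcw[a] != "C") next
        mm <- sum(li != rcw[a:(a + L - 1)])
        if (mm / L > max_mismatch_frac) next
        sc <- (L - mm) - 3 * mm
        if (is.null(best) || sc > best$sc ||
            (sc == best$sc && L > best$L) ||
            (sc == best$sc && L == best$L && (i + a) < (best$i + best$a))) {
          best <- list(sc = sc, L = L, i = i, a = a, mm = mm)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  jend <- n - best$a + 1L
  list(ir_left = list(start = best$i, end = best$i + best$L - 1L,
                      seq = substr(s, best$i, best$i + best$L - 1L)),
       ir_right = list(start = jend - best$L + 1L, end = jend,
                       seq = substr(s, jend - best$L + 1L, jend)),
       length = best$L, mismatches = best$mm)
}

#' Detect the direct repeat (target-site duplication) flanking an element
#'
#' Tests each candidate length: the suffix of the left flank against the
#' prefix of the right flank. Exact match required by default; the longest
#' matching length wins.
#'
#' @param genome genome sequence.
#' @param start,end element coordinates (1-based inclusive).
#' @param lengths candidate DR lengths (default 8 and 9 bp).
#' @param max_mismatch allowed mismatches (default 0, exact).
#' @return `NULL` or a list with `length`, `left_seq`, `right_seq`.
#' @export
detect_dr <- function(genome, start, end, lengths = c(8L, 9L),
                      max_mismatch = 0) {
  g <- genome_as_character(genome)
  n <- nchar(g$seq)
  for (L in sort(as.integer(lengths), decreasing = TRUE)) {
    if (start - L < 1 || end + L > n) next
    left <- substr(g$seq, start - L, start - 1)
    right <- substr(g$seq, end + 1, end + L)
    mm <- sum(seq_chars(left) != seq_chars(right))
    if (mm <= max_mismatch) {
      return(list(length = L, left_seq = left, right_seq = right))
    }
  }
  NULL
}

#' Percent complementarity between the two terminal IRs
#'
#' Global alignment of IR-left against the reverse complement of IR-right;
#' returns `100 * matches / aligned columns`.
#'
#' @param ir_left_seq,ir_right_seq IR sequences (top strand, character).
#' @return a percentage in `[0, 100]`.
#' @export
ir_complementarity <- function(ir_left_seq, ir_right_seq) {
  stopifnot(nchar(ir_left_seq) > 0, nchar(ir_right_seq) > 0)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ir_left_seq),
    Biostrings::reverseComplement(Biostrings::DNAString(ir_right_seq)),
    type = "global", substitutionMatrix = nuc_submat(),
    gapOpening = 2, gapExtension = 1)
  p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  q <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  100 * sum(p == q & p != "-") / length(p)
}

#' Find open reading frames (stop-free intervals) on the forward strand
#'
#' @param seq nucleotide sequence.
#' @param min_nt minimum ORF length in nucleotides.
#' @return data.frame `start`, `end`, `frame` (0-2, `(start - 1) %% 3`).
#' @export
find_orfs <- function(seq, min_nt = 300) {
  s <- as.character(seq)
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < 1) next
    aa <- seq_chars(as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1 + f, f + 3 * ncod)),
      if.fuzzy.codon = "X")))
    isstop <- aa == "*"
    bounds <- c(0, which(isstop), length(aa) + 1)
    for (b in seq_len(length(bounds) - 1)) {
      c1 <- bounds[b] + 1
      c2 <- bounds[b + 1] - 1
      if (c2 < c1) next
      st <- 1 + f + 3 * (c1 - 1)
      en <- f + 3 * c2
      if (en - st + 1 >= min_nt) {
        out[[length(out) + 1]] <- data.frame(start = st, end = en, frame = f)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0), frame = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start), , drop = FALSE]
}

#' Detect a -1 programmed translational frameshift joining two ORFs
#'
#' True when two consecutive same-strand ORFs overlap or abut such that a
#' single -1 ribosomal slip within the junction yields one contiguous
#' stop-free read through both (the hallmark of split transposase genes).
#' The downstream ORF must lie in the -1 frame relative to the upstream
#' one.
#'
#' @param record element sequence.
#' @param min_orf_nt minimum ORF length considered.
#' @param max_gap maximum distance (bp) between ORF1 end and ORF2 start.
#' @return list with `frameshift` (logical) and, when true, `junction`
#'   (the slip position) plus the two ORF records.
#' @export
detect_minus1_frameshift <- function(record, min_orf_nt = 300, max_gap = 30) {
  s <- as.character(record)
  orfs <- find_orfs(s, min_nt = min_orf_nt)
  if (nrow(orfs) < 2) return(list(frameshift = FALSE))
  for (i in seq_len(nrow(orfs) - 1)) {
    for (j in (i + 1):nrow(orfs)) {
      o1 <- orfs[i, ]; o2 <- orfs[j, ]
      if (o2$frame != (o1$frame + 2) %% 3) next
      if (o2$start > o1$end + max_gap) next
      if (o2$end <= o1$end) next
      lo <- max(o1$start + 2, o2$start - 3)
      cand <- seq(lo, o1$end)
      cand <- cand[(cand - o1$start + 1) %% 3 == 0]
      for (sl in cand) {
        joined <- paste0(substr(s, o1$start, sl), substr(s, sl, o2$end))
        ncod <- nchar(joined) %/% 3
        aa <- seq_chars(as.character(Biostrings::translate(
          Biostrings::DNAString(substr(joined, 1, 3 * ncod)),
          if.fuzzy.codon = "X")))
        nstop <- sum(aa == "*")
        if (nstop == 0 || (nstop == 1 && aa[length(aa)] == "*")) {
          return(list(frameshift = TRUE, junction = sl,
                      orf1 = o1, orf2 = o2))
        }
      }
    }
  }
  list(frameshift = FALSE)
}

#' Annotate a transposable element from its transposase CDS
#'
#' End-to-end boundary calling: extracts the CDS with flanks, maps it
#' across the genome, determines majority boundaries (extending the window
#' while hits reach its edges), transfers the boundaries to every copy,
#' and validates each copy by IR detection, DR detection and frameshift
#' analysis.
#'
#' @param genome genome sequence.
#' @param cds_start,cds_end transposase CDS coordinates (1-based).
#' @param flank initial flank (default 400 bp).
#' @param min_copies see [majority_boundaries()].
#' @param te_id label for the element.
#' @param family_id optional family label.
#' @param ir_args,dr_args optional argument lists for
#'   [find_inverted_repeats()] / [detect_dr()].
#' @param ... passed to [map_query_hits()].
#' @return a data.frame with one row per copy: coordinates, strand, IR
#'   pair coordinates/sequences, DR, complementarity, frameshift flag and
#'   `copy_count`; attribute `status` carries the majority-call status.
#' @export
annotate_te <- function(genome, cds_start, cds_end, flank = 400,
                        min_copies = 3, te_id = "TE1",
                        family_id = NA_character_,
                        ir_args = list(), dr_args = list(), ...) {
  g <- genome_as_character(genome)
  rec <- extract_with_flanks(genome, cds_start, cds_end, flank = flank)
  ext <- extend_boundaries(genome, rec$offset,
                           rec$offset + nchar(rec$seq) - 1L, step = flank, ...)
  hits <- ext$hits
  mb <- ext$boundaries
  mb$status <- if (nrow(hits) > min_copies) "ok" else "insufficient_copies"

  rows <- list()
  slack <- 15L  # HSPs may stop short of / extend past the modal ends
  for (h in seq_len(nrow(hits))) {
    hit <- hits[h, ]
    if (hit$q_start > mb$start + slack || hit$q_end < mb$end - slack) next
    if (hit$strand == "+") {
      cs <- hit$s_start + (mb$start - hit$q_start)
      ce <- hit$s_end - (hit$q_end - mb$end)
    } else {
      cs <- hit$s_start + (hit$q_end - mb$end)
      ce <- hit$s_end - (mb$start - hit$q_start)
    }
    if (cs < 1 || ce > nchar(g$seq)) next
    cseq <- substr(g$seq, cs, ce)
    if (hit$strand == "-") cseq <- revcomp(cseq)
    ir <- do.call(find_inverted_repeats, c(list(cseq), ir_args))
    # boundary validation: conserved target motifs let HSPs creep into the
    # target-site duplication, so snap boundaries to the detected IR
    # termini when they sit a short distance inside the called window
    if (!is.null(ir)) {
      lead <- ir$ir_left$start - 1L
      trail <- nchar(cseq) - ir$ir_right$end
      if ((lead > 0 || trail > 0) && lead <= 2L * slack && trail <= 2L * slack) {
        if (hit$strand == "+") {
          cs <- cs + lead
          ce <- ce - trail
        } else {
          cs <- cs + trail
          ce <- ce - lead
        }
        cseq <- substr(g$seq, cs, ce)
        if (hit$strand == "-") cseq <- revcomp(cseq)
        ir <- do.call(find_inverted_repeats, c(list(cseq), ir_args))
      }
    }
    dr <- do.call(detect_dr, c(list(genome, cs, ce), dr_args))
    fs <- detect_minus1_frameshift(cseq)
    rows[[length(rows) + 1]] <- data.frame(
      te_id = te_id, copy_id = sprintf("%s_copy%02d", te_id, h),
      genome_id = g$id, start = cs, end = ce, strand = hit$strand,
      ir_length = if (is.null(ir)) NA_integer_ else ir$length,
      ir_mismatches = if (is.null(ir)) NA_integer_ else ir$mismatches,
      ir_left_seq = if (is.null(ir)) NA_character_ else ir$ir_left$seq,
      ir_right_seq = if (is.null(ir)) NA_character_ else ir$ir_right$seq,
      ir_complementarity = if (is.null(ir)) NA_real_ else
        ir_complementarity(ir$ir_left$seq, ir$ir_right$seq),
      dr_length = if (is.null(dr)) NA_integer_ else dr$length,
      dr_seq = if (is.null(dr)) NA_character_ else dr$left_seq,
      frameshift = fs$frameshift, family_id = family_id,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  if (nrow(out) > 0) out$copy_count <- nrow(out)
  attr(out, "status") <- mb$status
  attr(out, "boundaries") <- mb
  out
}
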