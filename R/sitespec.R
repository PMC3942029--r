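# Insertion-site specificity around IR/genome junctions.
#
# 300 bp flanks are extracted on both sides of validated elements
# (identical insertions deduplicated), scanned for sigma-A promoters with
# a paired -35/-10 weight-matrix model (spacer 15-19 bp), and summarized
# as the per-position ratio of promoter detections within 30 bp of the
# junction; IR-left-side distances are negative, IR-right-side positive.

#' Position weight matrix for one sigma-A promoter box
#'
#' Consensus-seeded log-odds matrix: the consensus base takes probability
#' `(1 + pseudocount) / (1 + 4 * pseudocount)` per column, the others
#' `pseudocount / (1 + 4 * pseudocount)`; scores are log2 odds against the
#' background. Matrices are user-replaceable wherever a scan accepts them.
#'
#' @param consensus consensus string (e.g. `"TTGACA"` for the -35 box,
#'   `"TATAAT"` for the -10 box).
#' @param pseudocount per-base pseudocount (default 0.1).
#' @param background named base probabilities (default uniform).
#' @return a 4 x L numeric matrix, rows `A`, `C`, `G`, `T`.
#' @export
sigma_pwm <- function(consensus, pseudocount = 0.1,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  ch <- seq_chars(consensus)
  m <- matrix(pseudocount, nrow = 4, ncol = length(ch),
              dimnames = list(DNA_BASES, NULL))
  for (j in seq_along(ch)) m[ch[j], j] <- m[ch[j], j] + 1
  m <- sweep(m, 2, colSums(m), "/")
  log2(m / background[DNA_BASES])
}

pwm_scores <- function(chars, pwm) {
  L <- ncol(pwm)
  n <- length(chars)
  if (n < L) return(numeric(0))
  idx <- match(chars, DNA_BASES)
  sc <- rep(0, n - L + 1)
  ok <- rep(TRUE, n - L + 1)
  for (j in seq_len(L)) {
    v <- pwm[cbind(idx[j:(j + n - L)], j)]
    bad <- is.na(v)
    v[bad] <- min(pwm[, j])
    sc <- sc + v
  }
  sc
}

#' Scan a sequence for sigma-A promoters (paired -35/-10 boxes)
#'
#' Slides the -35 matrix along the sequence; for every candidate tries all
#' spacers in range for the -10 matrix and emits hits whose combined
#' log-odds reaches `score_min`. Overlapping hits are resolved to the best
#' score.
#'
#' @param sequence character or DNAString.
#' @param pwm35,pwm10 weight matrices from [sigma_pwm()]; defaults use the
#'   canonical `TTGACA` / `TATAAT` consensus hexamers.
#' @param spacer_range allowed -35/-10 spacer lengths (default 15-19 bp).
#' @param score_min minimum combined log2-odds score.
#' @param resolve_overlaps keep only the best of mutually overlapping hits.
#' @return data.frame of promoter hits: `pos_minus35` (0-based offset of
#'   the -35 box start, i.e. bp between the sequence origin and the box),
#'   `spacer`, `score`, `strand` (`"+"`: the scanned strand).
#' @export
scan_sigma_promoters <- function(sequence,
                                 pwm35 = sigma_pwm("TTGACA"),
                                 pwm10 = sigma_pwm("TATAAT"),
                                 spacer_range = c(15L, 19L),
                                 score_min = 14,
                                 resolve_overlaps = TRUE) {
  s <- as.character(sequence)
  ch <- seq_chars(s)
  L35 <- ncol(pwm35); L10 <- ncol(pwm10)
  if (length(ch) < L35 + spacer_range[1] + L10) {
    return(data.frame(pos_minus35 = integer(0), spacer = integer(0),
                      score = numeric(0), strand = character(0)))
  }
  s35 <- pwm_scores(ch, pwm35)
  s10 <- pwm_scores(ch, pwm10)
  rows <- list()
  for (sp in seq(spacer_range[1], spacer_range[2])) {
    # -10 box starts at i + L35 + sp for a -35 box starting at i
    imax <- length(s10) - L35 - sp
    if (imax < 1) next
    i <- seq_len(imax)
    tot <- s35[i] + s10[i + L35 + sp]
    hit <- which(tot >= score_min)
    if (length(hit) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        pos_minus35 = hit - 1L, spacer = sp, score = tot[hit],
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pos_minus35 = integer(0), spacer = integer(0),
                      score = numeric(0), strand = character(0)))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score), , drop = FALSE]
  if (resolve_overlaps && nrow(hits) > 1) {
    span_s <- hits$pos_minus35
    span_e <- hits$pos_minus35 + L35 + hits$spacer + L10 - 1
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(hits))[-1]) {
      for (j in which(keep[seq_len(i - 1)])) {
        if (span_s[i] <= span_e[j] && span_e[i] >= span_s[j]) {
          keep[i] <- FALSE
          break
        }
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$pos_minus35), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Extract junction flanks on both sides of annotated elements
#'
#' Two flanks per element, each read 5'-to-3' on the strand pointing away
#' from the element (genome-right flank: top strand; genome-left flank:
#' reverse complement). Sides are labelled in element orientation: for a
#' minus-strand element the genome-right flank is its IR-left side.
#' Identical insertions (same side and flank sequence) collapse to one
#' record so multi-copy identical insertions cannot fabricate positional
#' peaks.
#'
#' @param annotations data.frame with `te_id`, `genome_id`, `start`,
#'   `end`, `strand` (truth table or [annotate_te()] output).
#' @param genomes named [Biostrings::DNAStringSet].
#' @param flank flank length (default 300 bp).
#' @param dedup drop duplicate (side, sequence) pairs (default TRUE).
#' @return data.frame: `te_id`, `copy_id`, `side` (`"IRl"`/`"IRr"`),
#'   `sequence`, `truncated`.
#' @export
extract_junction_flanks <- function(annotations, genomes, flank = 300,
                                    dedup = TRUE) {
  rows <- list()
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    if (!(a$genome_id %in% names(genomes))) {
      warning("genome not found: ", a$genome_id)
      next
    }
    g <- as.character(genomes[[a$genome_id]])
    n <- nchar(g)
    if (a$start < 1 || a$end > n) {
      warning("boundary outside genome for ", a$te_id)
      next
    }
    lf_from <- max(1, a$start - flank)
    left_seq <- revcomp(substr(g, lf_from, a$start - 1))
    rt_to <- min(n, a$end + flank)
    right_seq <- substr(g, a$end + 1, rt_to)
    sides <- if (identical(a$strand, "-")) c("IRr", "IRl") else c("IRl", "IRr")
    cid <- if ("copy_id" %in% names(a)) a$copy_id else a$te_id
    rows[[length(rows) + 1]] <- data.frame(
      te_id = a$te_id, copy_id = cid, side = sides,
      sequence = c(left_seq, right_seq),
      truncated = c(nchar(left_seq) < flank, nchar(right_seq) < flank),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(te_id = character(0), copy_id = character(0),
                      side = character(0), sequence = character(0),
                      truncated = logical(0)))
  }
  fl <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (dedup) {
    fl <- fl[!duplicated(paste(fl$side, fl$sequence, sep = "\r")), ,
             drop = FALSE]
    rownames(fl) <- NULL
  }
  fl
}

#' Scan junction flanks for sigma-A promoters
#'
#' Runs [scan_sigma_promoters()] on every flank (which is already oriented
#' away from the element, so `pos_minus35` is the distance in bp from the
#' junction to the -35 box).
#'
#' @param flanks data.frame from [extract_junction_flanks()].
#' @param ... passed to [scan_sigma_promoters()].
#' @return data.frame of hits with `te_id`, `copy_id`, `side`,
#'   `pos_minus35`, `spacer`, `score`.
#' @export
scan_junction_flanks <- function(flanks, ...) {
  out <- list()
  for (i in seq_len(nrow(flanks))) {
    h <- scan_sigma_promoters(flanks$sequence[i], ...)
    if (nrow(h) > 0) {
      h$te_id <- flanks$te_id[i]
      h$copy_id <- flanks$copy_id[i]
      h$side <- flanks$side[i]
      out[[length(out) + 1]] <- h
    }
  }
  if (length(out) == 0) {
    return(data.frame(pos_minus35 = integer(0), spacer = integer(0),
                      score = numeric(0), strand = character(0),
                      te_id = character(0), copy_id = character(0),
                      side = character(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Positional enrichment profile of promoter detections around junctions
#'
#' The ratio `r(d)` of promoters whose -35 box starts `d` bp from the
#' junction to the total number of promoters within the horizon; IR-left
#' side distances are negative, IR-right side positive. `sum(r) = 1`
#' whenever any promoter is found.
#'
#' @param junction_hits data.frame from [scan_junction_flanks()].
#' @param horizon maximum distance from the junction (default 30 bp).
#' @param n_junctions optional number of junctions scanned (bookkeeping).
#' @return a `junction_profile`: list with `profile` (data.frame
#'   `position`, `count`, `ratio` for `d` in `-horizon..horizon`),
#'   `n_promoters_total`, `n_junctions`, `peak_position`, `peak_ratio`,
#'   `undefined` (TRUE when no promoter lies within the horizon).
#' @export
positional_enrichment <- function(junction_hits, horizon = 30,
                                  n_junctions = NA_integer_) {
  pos <- ifelse(junction_hits$side == "IRr", 1, -1) * junction_hits$pos_minus35
  pos <- pos[abs(pos) <= horizon]
  grid <- seq(-horizon, horizon)
  counts <- tabulate(match(pos, grid), nbins = length(grid))
  total <- sum(counts)
  ratio <- if (total > 0) counts / total else rep(NA_real_, length(grid))
  prof <- data.frame(position = grid, count = counts, ratio = ratio)
  peak <- if (total > 0) grid[which.max(ratio)] else NA_integer_
  structure(list(profile = prof, n_promoters_total = total,
                 n_junctions = n_junctions,
                 peak_position = peak,
                 peak_ratio = if (total > 0) max(ratio) else NA_real_,
                 undefined = total == 0),
            class = "junction_profile")
}

#' @export
print.junction_profile <- function(x, ...) {
  if (x$undefined) {
    cat("junction_profile: no promoters within horizon\n")
  } else {
    cat("junction_profile:", x$n_promoters_total, "promoters;",
        "peak r(", x$peak_position, ") =", round(x$peak_ratio, 3), "\n")
  }
  invisible(x)
}

#' Orientation bias of elements toward their nearest promoter
#'
#' Fraction of elements whose IR-right side carries the nearest qualifying
#' promoter within the horizon. Elements without any promoter in range are
#' excluded; ties (equal distance both sides) are excluded too.
#'
#' @param junction_hits data.frame from [scan_junction_flanks()].
#' @param horizon maximum distance considered (default 30 bp).
#' @param annotations optional annotation data.frame with `copy_id` and
#'   `family_id` for the per-family breakdown.
#' @return list with `fraction`, `n` (elements with a usable promoter)
#'   and `by_family` (data.frame or NULL).
#' @export
orientation_bias <- function(junction_hits, horizon = 30, annotations = NULL) {
  h <- junction_hits[junction_hits$pos_minus35 <= horizon, , drop = FALSE]
  if (nrow(h) == 0) {
    return(list(fraction = NA_real_, n = 0L, by_family = NULL))
  }
  per <- split(h, h$copy_id)
  verdict <- vapply(per, function(d) {
    best <- tapply(d$pos_minus35, d$side, min)
    rl <- best["IRr"]; ll <- best["IRl"]
    if (is.na(rl)) return(0)
    if (is.na(ll)) return(1)
    if (rl < ll) 1 else if (rl > ll) 0 else NA_real_
  }, numeric(1))
  verdict <- verdict[!is.na(verdict)]
  out <- list(fraction = mean(verdict), n = length(verdict), by_family = NULL)
  if (!is.null(annotations) && "family_id" %in% names(annotations)) {
    fam <- annotations$family_id[match(names(verdict), annotations$copy_id)]
    tab <- tapply(verdict, fam, mean)
    out$by_family <- data.frame(family_id = names(tab),
                                fraction = as.numeric(tab))
  }
  out
}

#' Consensus and position frequency matrix of direct-repeat sequences
#'
#' Per-position base frequencies across equal-length DRs; the consensus
#' letter at each position is the IUPAC code covering every base with
#' frequency >= `min_freq` (N when all four qualify). Mixed lengths are
#' grouped by length and the largest group is summarized.
#'
#' @param drs character vector of DR sequences (>= 2 of equal length).
#' @param min_freq frequency threshold for a base to enter the consensus
#'   code (default 0.25).
#' @return list with `consensus` (IUPAC string), `pfm` (4 x L count
#'   matrix) and `n` (sequences used).
#' @export
dr_consensus <- function(drs, min_freq = 0.25) {
  drs <- drs[!is.na(drs) & nchar(drs) > 0]
  if (length(drs) == 0) stop("no DR sequences")
  by_len <- split(drs, nchar(drs))
  grp <- by_len[[which.max(lengths(by_len))]]
  if (length(grp) < 2) stop("need at least two DRs of equal length")
  L <- nchar(grp[1])
  mat <- do.call(rbind, strsplit(grp, "", fixed = TRUE))
  pfm <- vapply(seq_len(L), function(j) {
    vapply(DNA_BASES, function(b) sum(mat[, j] == b), numeric(1))
  }, numeric(4))
  rownames(pfm) <- DNA_BASES
  cons <- vapply(seq_len(L), function(j) {
    freq <- pfm[, j] / sum(pfm[, j])
    bases_to_iupac(DNA_BASES[freq >= min_freq])
  }, character(1))
  list(consensus = paste(cons, collapse = ""), pfm = pfm, n = length(grp))
}

#' Write a position frequency matrix as plain text
#'
#' Minimal MEME-like format: one line per position, counts for A, C, G, T.
#'
#' @param pfm 4 x L matrix (rows A, C, G, T).
#' @param path output path.
#' @param id motif identifier line.
#' @return invisibly, the path.
#' @export
write_pfm <- function(pfm, path, id = "motif") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", id), con)
  for (j in seq_len(ncol(pfm))) {
    writeLines(paste(pfm[, j], collapse = "\t"), con)
  }
  invisible(path)
}
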