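# Synthetic genomes with planted transposable elements.
#
# Elements carry terminal inverted repeats (18-39 bp, conserved terminal
# cytosine read into the element on each strand: the emitted element starts
# with C and ends with G on the top strand), generate 8-9 bp target-site
# duplications on insertion, and can target fixed offsets upstream planted
# sigma-A promoters, AT-rich target motifs, or uniform-random sites.

#' Insertion-site model for the synthetic genome generator
#'
#' Three target-site regimes are supported, emulating the observed
#' specificities of Mutator-like element families:
#' `promoter_offset` places each element a sampled number of bp upstream of
#' a planted sigma-A promoter's -35 box (the Tn*GBS*/IS*Kra4*-like model);
#' `at_rich_motif` inserts into sites matching an AT-rich IUPAC motif whose
#' duplication becomes the DR (the IS*H6*-like model, default `AANATNTT`);
#' `uniform` inserts anywhere (IS*256*/ICE-like).
#'
#' @param kind one of `"promoter_offset"`, `"at_rich_motif"`, `"uniform"`.
#' @param offset_distribution named numeric vector mapping junction-to--35
#'   distances (bp, names) to probabilities; must sum to 1. Default places
#'   half the mass at 16 bp and a quarter each at 15 and 17 bp.
#' @param motif IUPAC motif for `at_rich_motif`; its length sets the DR
#'   length it induces.
#' @param orientation_rule `"irr_toward_promoter"` (element oriented with
#'   IR-right facing the targeted promoter) or `"unbiased"`.
#' @return a `site_model` object.
#' @export
site_model <- function(kind = c("promoter_offset", "at_rich_motif", "uniform"),
                       offset_distribution = c(`15` = 0.25, `16` = 0.5, `17` = 0.25),
                       motif = "AANATNTT",
                       orientation_rule = c("irr_toward_promoter", "unbiased")) {
  kind <- match.arg(kind)
  orientation_rule <- match.arg(orientation_rule)
  if (kind == "promoter_offset") {
    if (abs(sum(offset_distribution) - 1) > 1e-9) {
      stop("offset probabilities must sum to 1")
    }
    if (is.null(names(offset_distribution))) {
      stop("offset_distribution must be named by distance (bp)")
    }
  }
  structure(list(kind = kind, offset_distribution = offset_distribution,
                 motif = motif, orientation_rule = orientation_rule),
            class = "site_model")
}

#' Construct one synthetic transposable element
#'
#' Assembles IR-left + spacer + transposase CDS (+ passengers) + spacer +
#' IR-right. IR-left starts with the conserved terminal C; IR-right is its
#' (optionally imperfect) reverse complement, so the element ends with G on
#' the top strand. With `frameshift_split`, the transposase is encoded as
#' two overlapping ORFs in relative frames 0/-1 joined by a slippery site,
#' so a single -1 ribosomal frameshift restores the full-length product.
#'
#' @param te_id element label.
#' @param family_id transposase family label (or `NA`).
#' @param ir_length IR length in bp (18-39).
#' @param complementarity target reverse-complement identity between the
#'   two IRs, in `[0.83, 1]`.
#' @param dr_length direct-repeat (target-site duplication) length, 8 or 9.
#' @param transposase optional transposase protein sequence (character);
#'   a random one of `tpase_aa_length` residues is drawn otherwise.
#' @param tpase_aa_length transposase length in aa when drawn at random.
#' @param passenger_aa_lengths integer vector: one passenger CDS per entry.
#' @param frameshift_split encode the transposase as two ORFs joined by a
#'   -1 programmed frameshift.
#' @return a `planted_te` object; fields include `sequence`, `cds_start`,
#'   `cds_end` (1-based, element-local) and `slip_site` when split.
#' @export
random_te <- function(te_id, family_id = NA_character_,
                      ir_length = 24, complementarity = 1.0,
                      dr_length = 9, transposase = NULL,
                      tpase_aa_length = 330,
                      passenger_aa_lengths = integer(),
                      frameshift_split = FALSE) {
  stopifnot(ir_length >= 18, ir_length <= 39,
            complementarity >= 0.83, complementarity <= 1,
            dr_length %in% c(8L, 9L))
  ir_left <- paste0("C", random_dna(ir_length - 1, gc = 0.5))
  ir_right <- revcomp(ir_left)
  n_mm <- round((1 - complementarity) * ir_length)
  if (n_mm > 0) {
    ch <- seq_chars(ir_right)
    # never touch the terminal G (outward-facing conserved C on the
    # bottom strand)
    pos <- sample(seq_len(ir_length - 1), n_mm)
    for (i in pos) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
    ir_right <- paste(ch, collapse = "")
  }

  if (is.null(transposase)) transposase <- random_aa(tpase_aa_length)
  slip <- NULL
  if (frameshift_split) {
    fs <- frameshift_cds(transposase)
    cds <- fs$cds
    slip <- fs$slip
  } else {
    cds <- reverse_translate(transposase)
  }
  passengers <- vapply(passenger_aa_lengths, function(n) {
    reverse_translate(random_aa(n))
  }, character(1))

  left_spacer <- random_dna(30)
  right_spacer <- random_dna(30)
  inner <- if (length(passengers)) {
    paste(c(cds, vapply(passengers, function(p) {
      paste0(random_dna(20), p)
    }, character(1))), collapse = "")
  } else {
    cds
  }
  sequence <- paste0(ir_left, left_spacer, inner, right_spacer, ir_right)
  cds_start <- nchar(ir_left) + nchar(left_spacer) + 1L

  structure(list(te_id = te_id, family_id = family_id,
                 ir_left = ir_left, ir_right = ir_right,
                 dr_length = as.integer(dr_length),
                 transposase_cds = cds,
                 passenger_genes = passengers,
                 frameshift_split = frameshift_split,
                 sequence = sequence,
                 cds_start = cds_start,
                 cds_end = cds_start + nchar(cds) - 1L,
                 slip_site = if (is.null(slip)) NA_integer_ else cds_start + slip - 1L),
            class = "planted_te")
}

# Encode a protein as two ORFs joined by a -1 programmed frameshift.
# Residues k and k+1 are fixed to lysine (AAA codons) to create the
# slippery site; the nucleotide after the slip codon is deleted so that
# re-reading one base at the slip restores the original codon series.
# ORF1 reads in frame 0 and terminates at the first chance stop after the
# slip; ORF2 occupies the -1 frame through to the terminal stop.
frameshift_cds <- function(protein) {
  aa <- seq_chars(protein)
  k <- floor(length(aa) / 2)
  aa[k] <- "K"; aa[k + 1] <- "K"
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), gc_tab)
  for (attempt in 1:50) {
    codons <- vapply(aa, function(a) sample(by_aa[[a]], 1), character(1))
    codons[k] <- "AAA"; codons[k + 1] <- "AAA"
    f <- paste(codons, collapse = "")
    s <- 3L * k                               # slip point: codon k boundary
    cds <- paste0(substr(f, 1, s), substr(f, s + 2, nchar(f)), "TAA")
    # ORF1 must terminate: require a frame-0 stop within 75 codons of the
    # slip (resample synonymous codons otherwise; vanishingly rare).
    tail0 <- substr(cds, s + 1, min(nchar(cds), s + 225))
    aa0 <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(tail0, 1, 3 * (nchar(tail0) %/% 3))),
      if.fuzzy.codon = "X"))
    if (grepl("*", aa0, fixed = TRUE)) {
      return(list(cds = cds, slip = s))
    }
  }
  stop("failed to place a frame-0 stop after the slippery site")
}

#' Plant transposable elements into a random genome with known truth
#'
#' Generates an i.i.d. background genome, plants `n_insertions` elements
#' under the given [site_model()], and duplicates the target site so every
#' emitted element is flanked by identical direct repeats. Under
#' `promoter_offset`, a -35/-10 promoter (consensus hexamers with per-base
#' corruption, spacer 15-19 bp) is written into the background and the
#' element is placed so the sampled number of bases separates the
#' IR/genome junction from the -35 box, on the side set by the
#' orientation rule. Under `at_rich_motif`, existing motif matches are
#' used as target sites; when too few exist in the random background, the
#' shortfall is resampled by writing concrete motif instances into the
#' background before insertion. Deterministic for a fixed seed.
#'
#' @param genome_length background genome length in bp (pre-insertion).
#' @param tes a `planted_te` or list of them; cycled across insertions.
#' @param site_model a [site_model()].
#' @param n_insertions number of insertions.
#' @param seed integer seed.
#' @param gc background GC fraction.
#' @param promoter_corruption per-base corruption probability of the
#'   consensus promoter hexamers (default 0.1).
#' @param promoter_spacer_range allowed -35/-10 spacer lengths.
#' @param copy_substitution_rate per-site substitution rate applied to the
#'   interior (non-IR) of each inserted copy, emulating copy divergence.
#' @param min_spacing minimum distance between insertion target sites in
#'   the background (keeps junction flanks distinct).
#' @param genome_id name of the emitted genome record.
#' @return a list with `genome` (a named [Biostrings::DNAStringSet] of
#'   length 1) and `truth`, a data.frame with one row per insertion:
#'   `te_id`, `copy_id`, `genome_id`, `start`, `end` (1-based inclusive on
#'   the emitted genome), `strand`, `dr_sequence`, `dr_length`,
#'   `promoter_offset` (bp from junction to the -35 box, `NA` unless the
#'   promoter model was used) and `family_id`.
#' @export
plant_insertions <- function(genome_length, tes, site_model, n_insertions,
                             seed, gc = 0.40,
                             promoter_corruption = 0.1,
                             promoter_spacer_range = c(15L, 19L),
                             copy_substitution_rate = 0,
                             min_spacing = 400L,
                             genome_id = "synthetic_genome") {
  if (is(tes, "planted_te")) tes <- list(tes)
  stopifnot(is(site_model, "site_model"), n_insertions >= 1)
  set.seed(derive_seed(seed, "plant"))
  genome <- random_dna(genome_length, gc = gc)

  max_te <- max(vapply(tes, function(t) nchar(t$sequence), integer(1)))
  margin <- 400L
  if (genome_length < n_insertions * min_spacing + 2L * margin) {
    stop("genome too short for ", n_insertions,
         " non-overlapping insertions at spacing ", min_spacing)
  }

  pick_spaced <- function(candidates, n, spacing) {
    candidates <- sort(candidates)
    chosen <- integer(0)
    last <- -Inf
    for (x in candidates) {
      if (x - last >= spacing) {
        chosen <- c(chosen, x)
        last <- x
      }
      if (length(chosen) == n) break
    }
    chosen
  }

  kind <- site_model$kind
  promoters <- NULL

  if (kind == "promoter_offset") {
    cand <- sample(seq(margin, genome_length - margin), n_insertions * 5)
    anchors <- pick_spaced(cand, n_insertions, min_spacing)
    if (length(anchors) < n_insertions) stop("could not place spaced promoters")
    spacers <- sample(seq(promoter_spacer_range[1], promoter_spacer_range[2]),
                      n_insertions, replace = TRUE)
    for (i in seq_len(n_insertions)) {
      prom <- paste0(corrupt_box("TTGACA", promoter_corruption),
                     random_dna(spacers[i], gc = gc),
                     corrupt_box("TATAAT", promoter_corruption))
      substr(genome, anchors[i], anchors[i] + nchar(prom) - 1L) <- prom
    }
    offs <- as.integer(names(site_model$offset_distribution))
    offsets <- offs[sample.int(length(offs), n_insertions, replace = TRUE,
                               prob = site_model$offset_distribution)]
    promoters <- data.frame(minus35 = anchors, spacer = spacers)
  } else if (kind == "at_rich_motif") {
    motif <- site_model$motif
    L <- nchar(motif)
    hits <- Biostrings::start(Biostrings::matchPattern(
      motif, Biostrings::DNAString(genome), fixed = FALSE))
    hits <- hits[hits > margin & hits < genome_length - margin]
    sites <- pick_spaced(hits, n_insertions, min_spacing)
    if (length(sites) < n_insertions) {
      # background lacks enough motif matches: resample by writing
      # concrete instances into free, spaced positions
      need <- n_insertions - length(sites)
      cand <- sample(seq(margin, genome_length - margin), n_insertions * 5)
      cand <- cand[vapply(cand, function(x) {
        all(abs(x - sites) >= min_spacing)
      }, logical(1))]
      extra <- pick_spaced(cand, need, min_spacing)
      if (length(extra) < need) stop("could not place spaced motif sites")
      for (x in extra) {
        substr(genome, x, x + L - 1L) <- sample_iupac_instance(motif)
      }
      sites <- sort(c(sites, extra))
    }
    anchors <- sites
  } else {
    cand <- sample(seq(margin, genome_length - margin), n_insertions * 5)
    anchors <- pick_spaced(cand, n_insertions, min_spacing)
    if (length(anchors) < n_insertions) stop("could not place spaced insertions")
  }

  # one row per insertion, in ascending target order
  ord <- order(anchors)
  anchors <- anchors[ord]
  if (kind == "promoter_offset") {
    offsets <- offsets[ord]
    spacers <- spacers[ord]
    promoters <- promoters[ord, , drop = FALSE]
  }

  rows <- vector("list", n_insertions)
  pieces <- character(0)
  prev <- 1L
  shift <- 0L
  for (i in seq_len(n_insertions)) {
    te <- tes[[((i - 1L) %% length(tes)) + 1L]]
    L <- if (kind == "at_rich_motif") nchar(site_model$motif) else te$dr_length

    strand <- "+"
    if (kind == "promoter_offset") {
      d <- offsets[i]
      x <- anchors[i] - d - 1L                 # target site is [x+1, x+L]
      if (site_model$orientation_rule == "unbiased" && runif(1) < 0.5) {
        strand <- "-"
      }
      prom_offset <- d
    } else {
      x <- anchors[i] - 1L
      prom_offset <- NA_integer_
      if (kind == "uniform") strand <- sample(c("+", "-"), 1)
    }
    dr_seq <- substr(genome, x + 1L, x + L)

    te_seq <- te$sequence
    if (copy_substitution_rate > 0) {
      irl <- nchar(te$ir_left); irr <- nchar(te$ir_right)
      body <- substr(te_seq, irl + 1L, nchar(te_seq) - irr)
      te_seq <- paste0(te$ir_left, mutate_dna(body, copy_substitution_rate),
                       te$ir_right)
    }
    if (strand == "-") te_seq <- revcomp(te_seq)

    pieces <- c(pieces, substr(genome, prev, x + L), te_seq)
    prev <- x + 1L
    start <- x + L + 1L + shift
    rows[[i]] <- data.frame(
      te_id = te$te_id, copy_id = sprintf("%s_c%03d", te$te_id, i),
      genome_id = genome_id, start = start,
      end = start + nchar(te_seq) - 1L, strand = strand,
      dr_sequence = dr_seq, dr_length = L,
      promoter_offset = prom_offset, family_id = te$family_id,
      stringsAsFactors = FALSE)
    # downstream coordinates gain the element plus the duplicated target
    shift <- shift + nchar(te_seq) + L
  }
  pieces <- c(pieces, substr(genome, prev, genome_length))
  emitted <- paste(pieces, collapse = "")

  out <- Biostrings::DNAStringSet(setNames(emitted, genome_id))
  list(genome = out,
       truth = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       promoters = promoters)
}

#' Emit the circular transposition-intermediate junction of an element
#'
#' Transposition proceeds through an extrachromosomal circle in which the
#' two terminal IRs abut, separated by a 6-10 bp linker copied from one of
#' the element's two flanking sequences at its prior insertion site.
#' Returns the abutted IR-right + linker + IR-left junction sequence.
#'
#' @param te a `planted_te`.
#' @param linker_length linker length in bp (6-10).
#' @param flank_source `"left"` or `"right"`: which flank donates the linker.
#' @param flanks list with `left` and `right` flanking sequences from a
#'   prior insertion context; the linker is the first `linker_length` bases
#'   of the chosen flank.
#' @return a named [Biostrings::DNAStringSet] of length 1.
#' @export
emit_circular_junction <- function(te, linker_length,
                                   flank_source = c("left", "right"),
                                   flanks) {
  flank_source <- match.arg(flank_source)
  if (linker_length < 6 || linker_length > 10) {
    stop("linker_length must lie in [6, 10]")
  }
  flank <- as.character(flanks[[flank_source]])
  if (nchar(flank) < linker_length) stop("flank shorter than linker")
  linker <- substr(flank, 1, linker_length)
  junction <- paste0(te$ir_right, linker, te$ir_left)
  Biostrings::DNAStringSet(setNames(junction, paste0(te$te_id, "_circle")))
}

#' Write the synthetic truth table as GFF3 plus a TSV mirror
#'
#' @param truth truth data.frame from [plant_insertions()].
#' @param gff_path,tsv_path output paths.
#' @return invisibly, the GFF3 path.
#' @export
write_truth <- function(truth, gff_path, tsv_path = NULL) {
  write_gff3(truth, gff_path, type = "mobile_genetic_element")
  if (!is.null(tsv_path)) {
    write.table(truth, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(gff_path)
}
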