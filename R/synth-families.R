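# Synthetic transposase family generator.
#
# Families descend from a random (or supplied) ancestor by i.i.d. per-site
# substitution. Positions that are diagnostic of Mutator-like transposases
# are exempt from substitution: the DDE catalytic triad, the C/D(2)H
# signature 11-19 aa downstream of D2, and two N-terminal anchor blocks
# (N1, N2) standing in for the conserved N-terminal/IR-binding domains.

#' Specification of one synthetic transposase family
#'
#' Describes how to derive a family of homologous transposase-like proteins
#' from one ancestor. The catalytic triad consists of two aspartates (D1,
#' D2) and a glutamate (E) with an alpha-helical insert of 99-138 aa
#' between D2 and E; a C/D(2)H motif (`[CD]xxH`) sits 11-19 aa downstream
#' of D2. Conserved blocks are exempt from substitution in every member.
#'
#' @param family_id family label.
#' @param n_members number of members to emit (>= 1).
#' @param ancestor_length ancestor length in aa (ignored when `ancestor`
#'   is supplied).
#' @param substitution_rate expected substitutions per site on the branch
#'   from ancestor to each member, in `[0, 1)`.
#' @param triad_positions 1-based aa indices of D1, D2 and E, strictly
#'   increasing; E must equal `D2 + insert_length + 1`.
#' @param cdh_offset aa distance of the C/D(2)H motif start downstream of
#'   D2 (11-19).
#' @param insert_length aa length of the segment strictly between D2 and E
#'   (99-138).
#' @param n1_block,n2_block 1-based `(start, end)` ranges of the two
#'   N-terminal conserved anchor blocks.
#' @param extra_blocks optional list of additional conserved `(start, end)`
#'   ranges (e.g. a promoter-targeting signature between N1 and N2).
#' @param indel_rate per-site indel probability (default 0: substitutions
#'   only, which keeps truth coordinates alignment-free).
#' @param ancestor optional explicit ancestor sequence (character).
#' @return a `family_spec` object (list).
#' @seealso [generate_protein_families()]
#' @export
family_spec <- function(family_id,
                        n_members = 8,
                        ancestor_length = 400,
                        substitution_rate = 0.2,
                        triad_positions = c(130, 200, 321),
                        cdh_offset = 14,
                        insert_length = 120,
                        n1_block = c(20, 34),
                        n2_block = c(60, 79),
                        extra_blocks = list(),
                        indel_rate = 0,
                        ancestor = NULL) {
  stopifnot(n_members >= 1,
            substitution_rate >= 0, substitution_rate < 1,
            length(triad_positions) == 3)
  if (!is.null(ancestor)) ancestor_length <- nchar(ancestor)
  d1 <- triad_positions[1]; d2 <- triad_positions[2]; e <- triad_positions[3]
  if (!(d1 < d2 && d2 < e)) stop("triad positions must be strictly increasing")
  if (e != d2 + insert_length + 1) {
    stop("E position inconsistent with insert_length: expected D2 + insert_length + 1")
  }
  if (insert_length < 99 || insert_length > 138) {
    stop("insert_length must lie in [99, 138]")
  }
  if (cdh_offset < 11 || cdh_offset > 19) stop("cdh_offset must lie in [11, 19]")
  if (e > ancestor_length) stop("triad exceeds ancestor length")

  blocks <- c(list(d1, d2, e, c(d2 + cdh_offset, d2 + cdh_offset + 3),
                   n1_block, n2_block), extra_blocks)
  ivs <- lapply(blocks, function(b) if (length(b) == 1) c(b, b) else b)
  ord <- order(vapply(ivs, `[`, numeric(1), 1))
  ivs <- ivs[ord]
  for (i in seq_along(ivs)[-1]) {
    if (ivs[[i]][1] <= ivs[[i - 1]][2]) {
      stop("overlapping conserved blocks in family spec")
    }
  }
  if (max(vapply(ivs, `[`, numeric(1), 2)) > ancestor_length) {
    stop("conserved block exceeds ancestor length")
  }

  structure(list(family_id = family_id, n_members = n_members,
                 ancestor_length = ancestor_length,
                 substitution_rate = substitution_rate,
                 triad_positions = c(d1 = d1, d2 = d2, e = e),
                 cdh_offset = cdh_offset, insert_length = insert_length,
                 n1_block = n1_block, n2_block = n2_block,
                 extra_blocks = extra_blocks, indel_rate = indel_rate,
                 ancestor = ancestor),
            class = "family_spec")
}

exempt_positions <- function(spec) {
  tp <- spec$triad_positions
  cdh <- tp[["d2"]] + spec$cdh_offset
  unique(c(tp, cdh:(cdh + 3),
           spec$n1_block[1]:spec$n1_block[2],
           spec$n2_block[1]:spec$n2_block[2],
           unlist(lapply(spec$extra_blocks, function(b) b[1]:b[2]))))
}

#' Generate synthetic transposase protein families with known truth
#'
#' Each family descends from one random (or supplied) ancestor by
#' independent per-site substitution; triad residues (D, D, E), the
#' C/D(2)H motif letters and the N1/N2 anchor blocks are exempt, so every
#' member carries the diagnostic Mutator-like features at known positions.
#' Deterministic for a fixed seed.
#'
#' @param specs a list of [family_spec()] objects (or a single one).
#' @param seed integer seed.
#' @return a list with `proteins` (an [Biostrings::AAStringSet]) and
#'   `truth`, a data.frame with one row per member: `protein_id`,
#'   `family_id`, triad positions `d1`, `d2`, `e`, `cdh_offset` and
#'   `insert_length`.
#' @examples
#' fam <- generate_protein_families(list(family_spec("famA", n_members = 3)), seed = 1)
#' names(fam$proteins)
#' @export
generate_protein_families <- function(specs, seed) {
  if (is(specs, "family_spec")) specs <- list(specs)
  set.seed(derive_seed(seed, "families"))
  seqs <- character(0)
  truth <- list()
  for (spec in specs) {
    anc <- spec$ancestor
    if (is.null(anc)) anc <- random_aa(spec$ancestor_length)
    ch <- seq_chars(anc)
    tp <- spec$triad_positions
    ch[tp[["d1"]]] <- "D"; ch[tp[["d2"]]] <- "D"; ch[tp[["e"]]] <- "E"
    cdh <- tp[["d2"]] + spec$cdh_offset
    ch[cdh] <- sample(c("C", "D"), 1)
    ch[cdh + 3] <- "H"
    anc <- paste(ch, collapse = "")
    ex <- exempt_positions(spec)
    for (m in seq_len(spec$n_members)) {
      s <- if (spec$substitution_rate > 0) {
        mutate_protein(anc, spec$substitution_rate, exempt = ex)
      } else {
        anc
      }
      if (spec$indel_rate > 0) s <- apply_indels(s, spec$indel_rate, exempt = ex)
      id <- sprintf("%s_%02d", spec$family_id, m)
      seqs[id] <- s
      truth[[id]] <- data.frame(protein_id = id, family_id = spec$family_id,
                                d1 = tp[["d1"]], d2 = tp[["d2"]], e = tp[["e"]],
                                cdh_offset = spec$cdh_offset,
                                insert_length = spec$insert_length,
                                stringsAsFactors = FALSE)
    }
  }
  list(proteins = Biostrings::AAStringSet(seqs),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

# Optional indel mode: per site, delete with prob rate/2 or insert one
# random residue after it with prob rate/2. Conserved positions never
# deleted; truth coordinates are only valid at indel_rate = 0.
apply_indels <- function(seq, rate, exempt = integer()) {
  ch <- seq_chars(seq)
  out <- character(0)
  for (i in seq_along(ch)) {
    u <- runif(1)
    if (u < rate / 2 && !(i %in% exempt)) next         # deletion
    out <- c(out, ch[i])
    if (u >= rate / 2 && u < rate) out <- c(out, sample(AA_ALPHABET20, 1))
  }
  paste(out, collapse = "")
}

#' Reverse-translate a protein into a stop-free coding sequence
#'
#' Random synonymous codons under the standard genetic code; appends a stop
#' codon. Used to embed synthetic transposase ORFs in planted elements.
#'
#' @param protein character or AAString.
#' @return a character coding sequence of length `3 * (nchar(protein) + 1)`.
#' @export
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  aas <- seq_chars(protein)
  stopifnot(all(aas %in% names(by_aa)))
  codons <- vapply(aas, function(a) sample(by_aa[[a]], 1), character(1))
  paste0(paste(codons, collapse = ""), sample(by_aa[["*"]], 1))
}
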