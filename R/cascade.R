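# Iterative profile-based homolog expansion ("cascade" search).
#
# Each round runs a substitution-matrix search from the current query,
# builds a position-specific profile from the retained hits, re-searches
# with the profile, then picks the most distantly related unused hit (on a
# BLOSUM62 average-distance tree) as the next query. Hits failing the
# E-value or query-coverage filter are never retained.

encode_aa <- function(x) {
  ch <- seq_chars(x)
  m <- match(ch, AA_ALPHABET20)
  m[is.na(m)] <- 0L
  as.integer(m)
}

#' Build a position-specific profile from a query and its retained hits
#'
#' Hits are star-aligned to the query (pairwise overlap alignments,
#' BLOSUM62); residues falling on query columns are counted with
#' Henikoff position-based sequence weighting, blended with background
#' frequencies by a pseudocount, and converted to half-bit log-odds
#' scores. Columns are query positions, so profile coordinates equal
#' query coordinates. This is a deliberately simple stand-in for full
#' iterative PSSM construction: no compositional adjustment.
#'
#' @param query query sequence (character or AAString).
#' @param hit_seqs [Biostrings::AAStringSet] of retained hits.
#' @param pseudocount pseudocount weight blending background frequencies.
#' @param gap_open,gap_extend gap costs for the star alignments.
#' @return an `aa_profile`: list with `pssm` (20 x L half-bit log-odds,
#'   rows in the package amino-acid order), `length`, `n_sequences`.
#' @export
build_profile <- function(query, hit_seqs, pseudocount = 1,
                          gap_open = 11, gap_extend = 1) {
  query <- as.character(query)
  L <- nchar(query)
  sm <- blosum62()
  hit_seqs <- as_aa_set(hit_seqs)
  # residue-by-column matrix, row 1 = query
  rows <- list(seq_chars(query))
  for (k in seq_along(hit_seqs)) {
    hs <- as.character(hit_seqs[[k]])
    if (identical(hs, query)) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(hs), Biostrings::AAString(query),
      type = "overlap", substitutionMatrix = sm,
      gapOpening = gap_open, gapExtension = gap_extend)
    pg <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    sg <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    row <- rep("-", L)
    qpos <- 0L
    for (i in seq_along(sg)) {
      if (sg[i] != "-") {
        qpos <- qpos + 1L
        row[qpos] <- pg[i]
      }
    }
    rows[[length(rows) + 1]] <- row
  }
  amat <- do.call(rbind, rows)

  # Henikoff position-based weights
  nseq <- nrow(amat)
  w <- numeric(nseq)
  for (j in seq_len(L)) {
    col <- amat[, j]
    res <- col[col != "-"]
    if (length(res) == 0) next
    r <- length(unique(res))
    cnt <- table(res)
    contrib <- ifelse(col == "-", 0, 1 / (r * as.numeric(cnt[col])))
    w <- w + contrib
  }
  if (sum(w) == 0) w <- rep(1, nseq)
  w <- w / sum(w)

  bg <- rep(1 / 20, 20)
  pssm <- matrix(0, nrow = 20, ncol = L,
                 dimnames = list(AA_ALPHABET20, NULL))
  for (j in seq_len(L)) {
    col <- amat[, j]
    keep <- col != "-" & col %in% AA_ALPHABET20
    f <- rep(0, 20)
    if (any(keep)) {
      wk <- w[keep] / sum(w[keep])
      f <- vapply(AA_ALPHABET20, function(a) sum(wk[col[keep] == a]),
                  numeric(1))
    }
    p <- (f + pseudocount * bg) / (1 + pseudocount)
    pssm[, j] <- 2 * log2(p / bg)
  }
  structure(list(pssm = pssm, length = L, n_sequences = nseq),
            class = "aa_profile")
}

# Gumbel calibration of profile-score E-values on shuffled decoys
# (method-of-moments fit; cheap stand-in for island statistics).
calibrate_profile <- function(profile, database, n_decoys = 30,
                              gap_open = 11, gap_extend = 1, seed = 1) {
  set.seed(derive_seed(seed, "decoys"))
  db <- as_aa_set(database)
  pick <- sample(length(db), n_decoys, replace = TRUE)
  scores <- vapply(pick, function(i) {
    ch <- sample(seq_chars(as.character(db[[i]])))
    .pssm_sw(profile$pssm, encode_aa(paste(ch, collapse = "")),
             gap_open, gap_extend)$score
  }, numeric(1))
  s <- sd(scores)
  if (!is.finite(s) || s < 1e-9) s <- 1
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772 / lambda
  list(lambda = lambda, mu = mu)
}

#' Search a protein database with a query sequence or profile
#'
#' First-round searches score with BLOSUM62 Smith-Waterman local
#' alignments and Karlin-Altschul E-values; profile searches score with
#' the position-specific log-odds matrix (E-values from a Gumbel fit on
#' shuffled decoys). Hits with `e_value > e_max` or query coverage below
#' `cov_min` are filtered out.
#'
#' @param query an AAString/character sequence, or an `aa_profile` from
#'   [build_profile()].
#' @param database a named [Biostrings::AAStringSet].
#' @param e_max E-value cutoff (retain `e_value <= e_max`).
#' @param cov_min minimum aligned fraction of the query/profile.
#' @param gap_open,gap_extend gap costs.
#' @param lambda,K Karlin-Altschul constants for sequence queries.
#' @param seed seed for decoy shuffling (profile queries).
#' @return data.frame: `id`, `e_value`, `coverage`, `score`, all passing
#'   both filters.
#' @export
profile_search <- function(query, database, e_max = 0.005, cov_min = 0.6,
                           gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, seed = 1) {
  db <- as_aa_set(database)
  if (length(db) == 0) stop("empty database")
  ntotal <- sum(Biostrings::width(db))

  if (is(query, "aa_profile")) {
    cal <- calibrate_profile(query, db, gap_open = gap_open,
                             gap_extend = gap_extend, seed = seed)
    res <- lapply(seq_along(db), function(i) {
      r <- .pssm_sw(query$pssm, encode_aa(as.character(db[[i]])),
                    gap_open, gap_extend)
      data.frame(id = names(db)[i],
                 e_value = length(db) * exp(-cal$lambda * (r$score - cal$mu)),
                 coverage = (r$profile_end - r$profile_start + 1) / query$length,
                 score = r$score, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
  } else {
    qs <- Biostrings::AAString(as.character(query))
    sm <- blosum62()
    pa <- Biostrings::pairwiseAlignment(db, qs, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = gap_open,
                                        gapExtension = gap_extend)
    s <- Biostrings::score(pa)
    sr <- Biostrings::subject(pa)
    cov <- (Biostrings::end(sr) - Biostrings::start(sr) + 1) / length(qs)
    out <- data.frame(id = names(db),
                      e_value = karlin_evalue(s, length(qs), ntotal,
                                              lambda, K),
                      coverage = pmin(cov, 1), score = s,
                      stringsAsFactors = FALSE)
  }
  out <- out[out$e_value <= e_max & out$coverage >= cov_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Choose the next cascade query: most distant unused hit on a UPGMA tree
#'
#' Pairwise BLOSUM62 similarity scores of the retained hits are converted
#' to distances (`1 - S(a,b) / min(S(a,a), S(b,b))`), an average-distance
#' (UPGMA) tree is built, and the unused leaf with maximal tree
#' (cophenetic) distance from the current query is returned; ties break to
#' the lexicographically smallest label.
#'
#' @param hit_seqs named [Biostrings::AAStringSet] of retained hits
#'   (including the current query).
#' @param current_query_id label of the current query within `hit_seqs`.
#' @param used_ids labels already used as queries.
#' @return the chosen label, or `NULL` when every hit has been used
#'   (cascade exhaustion).
#' @export
select_next_query <- function(hit_seqs, current_query_id, used_ids) {
  hit_seqs <- as_aa_set(hit_seqs)
  ids <- names(hit_seqs)
  unused <- setdiff(ids, used_ids)
  if (length(unused) == 0) return(NULL)
  if (length(unused) == 1 && length(ids) <= 2) return(unused)
  if (!(current_query_id %in% ids)) stop("current query not among hits")

  sm <- blosum62()
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  self <- vapply(seq_len(n), function(i) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      hit_seqs[[i]], hit_seqs[[i]], type = "global",
      substitutionMatrix = sm, gapOpening = 11, gapExtension = 1))
  }, numeric(1))
  for (i in seq_len(n - 1)) {
    pa <- Biostrings::pairwiseAlignment(hit_seqs[(i + 1):n], hit_seqs[[i]],
                                        type = "global",
                                        substitutionMatrix = sm,
                                        gapOpening = 11, gapExtension = 1)
    S[i, (i + 1):n] <- S[(i + 1):n, i] <- Biostrings::score(pa)
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) D[i, j] <- max(0, 1 - S[i, j] / min(self[i], self[j]))
    }
  }
  hc <- hclust(as.dist(D), method = "average")
  cd <- as.matrix(cophenetic(hc))
  d <- cd[current_query_id, unused]
  cand <- sort(names(d)[d == max(d)])
  cand[1]
}

#' Run the cascade homolog search
#'
#' Iterates [profile_search()] (one substitution-matrix pass plus one
#' profile pass per query) and [select_next_query()] until `max_rounds`
#' queries have been used or no unused hit remains. The cumulative hit set
#' is monotone nondecreasing across rounds and every hit satisfied both
#' filters at its admitting round.
#'
#' @param seed_query id of a database sequence, or a (named) sequence.
#' @param database named [Biostrings::AAStringSet].
#' @param max_rounds maximum number of query rounds (default 7).
#' @param e_max,cov_min retention filters (see [profile_search()]).
#' @param seed integer seed (decoy shuffling).
#' @return list with `hits` (data.frame `id`, `round`, `e_value`,
#'   `coverage`, `query`: the round and filters at first admission),
#'   `queries` (the query labels in order) and `exhausted` (logical).
#' @export
run_cascade <- function(seed_query, database, max_rounds = 7,
                        e_max = 0.005, cov_min = 0.6, seed = 1) {
  db <- as_aa_set(database)
  empty <- data.frame(id = character(0), round = integer(0),
                      e_value = numeric(0), coverage = numeric(0),
                      query = character(0), stringsAsFactors = FALSE)
  if (max_rounds < 1) {
    return(list(hits = empty, queries = character(0), exhausted = FALSE))
  }
  if (is.character(seed_query) && length(seed_query) == 1 &&
      seed_query %in% names(db)) {
    query_id <- seed_query
    query_seq <- as.character(db[[seed_query]])
  } else {
    query_id <- if (!is.null(names(seed_query))) names(seed_query)[1] else "seed_query"
    query_seq <- as.character(seed_query)
  }

  hits <- empty
  used <- character(0)
  exhausted <- FALSE
  for (round in seq_len(max_rounds)) {
    used <- c(used, query_id)
    h1 <- profile_search(query_seq, db, e_max = e_max, cov_min = cov_min,
                         seed = derive_seed(seed, round))
    admit <- function(h) {
      new <- h[!(h$id %in% hits$id), , drop = FALSE]
      if (nrow(new) > 0) {
        hits <<- rbind(hits, data.frame(id = new$id, round = round,
                                        e_value = new$e_value,
                                        coverage = new$coverage,
                                        query = query_id,
                                        stringsAsFactors = FALSE))
      }
    }
    admit(h1)
    if (nrow(hits) > 0) {
      prof <- build_profile(query_seq, db[intersect(names(db), hits$id)])
      h2 <- profile_search(prof, db, e_max = e_max, cov_min = cov_min,
                           seed = derive_seed(seed, round * 101))
      admit(h2)
    }
    if (round == max_rounds) break
    pool <- db[intersect(names(db), hits$id)]
    if (length(pool) == 0) { exhausted <- TRUE; break }
    nxt <- select_next_query(pool, if (query_id %in% names(pool)) query_id
                                   else names(pool)[1], used)
    if (is.null(nxt)) { exhausted <- TRUE; break }
    query_id <- nxt
    query_seq <- as.character(db[[nxt]])
  }
  list(hits = hits, queries = used, exhausted = exhausted)
}
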