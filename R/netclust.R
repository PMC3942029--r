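# All-against-all protein similarity network and Markov clustering.
#
# Pairwise similarities are Smith-Waterman local alignments scored with
# BLOSUM62; E-values use the Karlin-Altschul form E = K*m*n*exp(-lambda*S)
# with published gapped-BLOSUM62 constants (lambda = 0.267, K = 0.041).
# Edges below the E-value threshold are weighted -log10(E) and clustered
# with an in-package Markov Cluster (MCL) implementation.

#' Karlin-Altschul E-value for a local alignment score
#'
#' @param score raw alignment score `S`.
#' @param m,n lengths (residues) of the two sequences (or query length and
#'   database size).
#' @param lambda,K Karlin-Altschul parameters; defaults are the published
#'   gapped BLOSUM62 values (gap open 11, extend 1).
#' @return the expectation value, monotone decreasing in `score`.
#' @export
karlin_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * score)
}

#' All-against-all local-alignment similarity of a protein set
#'
#' Smith-Waterman local alignment for every unordered pair (the
#' substitution matrix is symmetric, so the better-of-both-directions rule
#' reduces to one alignment per pair). Empty sequences are skipped with a
#' warning.
#'
#' @param proteins a named [Biostrings::AAStringSet] (or named character
#'   vector).
#' @param matrix substitution matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul constants for [karlin_evalue()].
#' @return a data.frame of pair hits: `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `raw_score`, `bit_score`,
#'   `e_value`, `query_coverage` (aligned fraction of the query).
#' @export
all_vs_all_similarity <- function(proteins, matrix = "BLOSUM62",
                                  gap_open = 11, gap_extend = 1,
                                  lambda = 0.267, K = 0.041) {
  proteins <- as_aa_set(proteins)
  if (length(proteins) < 2) stop("need at least two sequences")
  empty <- Biostrings::width(proteins) == 0
  if (any(empty)) {
    warning("skipping empty sequences: ",
            paste(names(proteins)[empty], collapse = ", "))
    proteins <- proteins[!empty]
  }
  sm <- resolve_submatrix(matrix)
  ids <- names(proteins)
  n <- length(proteins)
  out <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    subj <- proteins[[i]]
    pats <- proteins[(i + 1):n]
    pa <- Biostrings::pairwiseAlignment(pats, subj, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = gap_open,
                                        gapExtension = gap_extend)
    s <- Biostrings::score(pa)
    alen <- Biostrings::nchar(pa)
    qw <- length(subj)
    sr <- Biostrings::subject(pa)
    cov <- (Biostrings::end(sr) - Biostrings::start(sr) + 1) / qw
    ev <- karlin_evalue(s, qw, Biostrings::width(pats), lambda, K)
    out[[i]] <- data.frame(
      query_id = ids[i], subject_id = ids[(i + 1):n],
      percent_identity = Biostrings::pid(pa),
      alignment_length = alen, raw_score = s,
      bit_score = (lambda * s - log(K)) / log(2),
      e_value = ev, query_coverage = pmin(cov, 1),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read a 12-column tab-separated local-alignment hit table
#'
#' The standard tabular pairwise-search format (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score). Query coverage is computed when
#' query lengths are supplied.
#'
#' @param path file path.
#' @param query_lengths optional named integer vector of query lengths.
#' @return a pair-hit data.frame compatible with [build_network()].
#' @export
read_hit_table <- function(path, query_lengths = NULL) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("query_id", "subject_id", "percent_identity",
                                 "alignment_length", "mismatches", "gap_opens",
                                 "q_start", "q_end", "s_start", "s_end",
                                 "e_value", "bit_score"))
  cov <- rep(NA_real_, nrow(df))
  if (!is.null(query_lengths)) {
    cov <- (abs(df$q_end - df$q_start) + 1) / query_lengths[df$query_id]
  }
  df$query_coverage <- unname(cov)
  df$raw_score <- df$bit_score
  df
}

#' Build a homolog similarity network from pair hits
#'
#' Keeps edges with `e_value < e_threshold` (strict), drops self-hits,
#' collapses reciprocal duplicates to one undirected edge carrying the
#' maximum weight, and weights edges `-log10(max(e_value, e_floor))`.
#'
#' @param hits pair-hit data.frame ([all_vs_all_similarity()] or
#'   [read_hit_table()]).
#' @param e_threshold retain similarities with E-value strictly below this
#'   (default `1e-4`).
#' @param e_floor floor applied to E-values before taking logs, so that
#'   `E = 0` maps to a finite weight.
#' @param nodes optional character vector of all node ids (include
#'   proteins with no retained edge as isolated nodes).
#' @return a `homolog_network`: list with `graph` (an [igraph] graph with
#'   `weight` edge attribute), `e_threshold`, `e_floor` and `clusters`
#'   (`NULL` until [mcl_cluster()] is run).
#' @export
build_network <- function(hits, e_threshold = 1e-4, e_floor = 1e-200,
                          nodes = NULL) {
  keep <- hits$e_value < e_threshold & hits$query_id != hits$subject_id
  h <- hits[keep, , drop = FALSE]
  w <- -log10(pmax(h$e_value, e_floor))
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  key <- paste(a, b, sep = "\r")
  best <- tapply(w, key, max)
  if (is.null(nodes)) {
    nodes <- sort(unique(c(hits$query_id, hits$subject_id)))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(best) > 0) {
    ab <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(ab)), weight = as.numeric(best))
  }
  structure(list(graph = g, e_threshold = e_threshold, e_floor = e_floor,
                 clusters = NULL),
            class = "homolog_network")
}

#' @export
print.homolog_network <- function(x, ...) {
  cat("homolog_network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges (E <", x$e_threshold, ")\n")
  if (!is.null(x$clusters)) {
    cat("  clusters:", length(unique(x$clusters)), "\n")
  }
  invisible(x)
}

# Core MCL matrix iteration: expansion (matrix squaring) alternating with
# inflation (entrywise power + column renormalization) and pruning.
# Exposed internally for property tests.
mcl_iterate <- function(M, inflation, pruning_threshold, max_iter, epsilon) {
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < pruning_threshold] <- 0    # pruning
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")        # column renormalization
    if (max(abs(M2 - M)) < epsilon) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  list(M = M, converged = converged, iterations = it)
}

#' Markov clustering (MCL) of a homolog network
#'
#' From-scratch MCL: a column-stochastic transition matrix with self-loops
#' (weight = maximum incident edge weight) is alternately expanded (matrix
#' squaring) and inflated (entrywise power `inflation`, column
#' renormalization, entries below `pruning_threshold` zeroed) until the
#' matrix changes by less than `epsilon` or `max_iter` is reached. Clusters
#' are read from attractor rows of the limit matrix; a node attracted to
#' two clusters is assigned to the one whose attractor label sorts first.
#'
#' @param network a `homolog_network` (or an [igraph] graph with `weight`).
#' @param inflation inflation factor (default 1.2, suited to delineating
#'   IS/transposase families).
#' @param pruning_threshold entries below this are zeroed after each
#'   inflation (cost bound; 0 disables).
#' @param max_iter,epsilon iteration cap and convergence tolerance on the
#'   maximum absolute matrix change.
#' @return the `homolog_network` with `clusters` filled in: a named
#'   character vector mapping node to cluster label, with attributes
#'   `converged` and `iterations`. Passing a bare graph returns just the
#'   membership vector.
#' @export
mcl_cluster <- function(network, inflation = 1.2, pruning_threshold = 1e-5,
                        max_iter = 100, epsilon = 1e-6) {
  g <- if (is(network, "homolog_network")) network$graph else network
  n <- igraph::vcount(g)
  if (n == 0) stop("empty network")
  ids <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g) > 0) "weight" else NULL,
                                   sparse = FALSE)
  if (igraph::ecount(g) == 0) A <- matrix(0, n, n, dimnames = list(ids, ids))
  # self-loops: max incident weight (1 for isolated nodes)
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")

  res <- mcl_iterate(M, inflation, pruning_threshold, max_iter, epsilon)
  M <- res$M

  eps <- 1e-6
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0) attractors <- seq_len(n)
  member_sets <- lapply(attractors, function(a) which(M[a, ] > eps))
  # merge attractor systems that share members
  cluster_of <- rep(NA_integer_, n)
  cluster_attr <- character(0)
  for (k in order(ids[attractors])) {
    a <- attractors[k]
    mem <- member_sets[[k]]
    existing <- unique(stats::na.omit(cluster_of[mem]))
    if (length(existing) == 0) {
      cid <- length(cluster_attr) + 1L
      cluster_attr[cid] <- ids[a]
      cluster_of[mem] <- cid
    } else {
      # overlap: keep earlier (lexicographically smaller attractor) for
      # already-assigned nodes; new nodes join this attractor's cluster
      cid <- min(existing)
      cluster_of[mem[is.na(cluster_of[mem])]] <- cid
    }
  }
  un <- which(is.na(cluster_of))
  for (i in un) {
    cid <- length(cluster_attr) + 1L
    cluster_attr[cid] <- ids[i]
    cluster_of[i] <- cid
  }
  membership <- setNames(cluster_attr[cluster_of], ids)
  attr(membership, "converged") <- res$converged
  attr(membership, "iterations") <- res$iterations
  if (!res$converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current partition")
  }
  if (is(network, "homolog_network")) {
    network$clusters <- membership
    network
  } else {
    membership
  }
}

#' Export a homolog network as edge-list TSV, GraphML and cluster TSV
#'
#' @param network a `homolog_network`.
#' @param prefix output path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>.graphml` and, when clustered, `<prefix>_clusters.tsv`.
#' @return invisibly, the paths written.
#' @export
export_network <- function(network, prefix) {
  g <- network$graph
  el <- igraph::as_edgelist(g)
  w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else numeric(0)
  edges <- data.frame(node_a = el[, 1], node_b = el[, 2],
                      weight = round(w, 6), stringsAsFactors = FALSE)
  paths <- c(edges = paste0(prefix, "_edges.tsv"),
             graphml = paste0(prefix, ".graphml"))
  write.table(edges, paths["edges"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(network$clusters)) {
    igraph::V(g)$cluster <- unname(network$clusters[igraph::V(g)$name])
    paths["clusters"] <- paste0(prefix, "_clusters.tsv")
    write.table(data.frame(node = names(network$clusters),
                           cluster = unname(network$clusters)),
                paths["clusters"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  invisible(paths)
}

#' Read an exported edge-list TSV back into a homolog network
#'
#' @param path edge-list TSV written by [export_network()].
#' @param nodes optional full node set.
#' @return a `homolog_network`.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(df$node_a, df$node_b)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(df) > 0) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(df[, 1:2]))),
                           weight = df$weight)
  }
  structure(list(graph = g, e_threshold = NA_real_, e_floor = NA_real_,
                 clusters = NULL),
            class = "homolog_network")
}
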