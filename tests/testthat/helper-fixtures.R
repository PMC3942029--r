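# Shared fixture builders for the test suite. Everything is generated in
# code at test time; seeds are fixed so assertions are deterministic.

five_family_set <- function(seed = 11, n_members = 6, rate = 0.18) {
  specs <- lapply(1:5, function(i) {
    family_spec(sprintf("fam%d", i), n_members = n_members,
                substitution_rate = rate)
  })
  generate_protein_families(specs, seed = seed)
}

# per-position identity of two equal-length ungapped sequences
seq_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

# partition comparison up to label renaming
same_partition <- function(x, y) {
  stopifnot(identical(sort(names(x)), sort(names(y))))
  y <- y[names(x)]
  gx <- split(names(x), unname(x))
  gy <- split(names(y), unname(y))
  setequal(lapply(gx, sort), lapply(gy, sort))
}

adjusted_rand <- function(x, y) {
  mclust::adjustedRandIndex(x, y)
}

# run the independent numpy MCL reference on a homolog_network
mcl_reference <- function(network, inflation = 1.2, pruning = 1e-5,
                          max_iter = 100, eps = 1e-6) {
  g <- network$graph
  td <- withr::local_tempdir(.local_envir = parent.frame())
  edges <- file.path(td, "edges.tsv")
  nodesf <- file.path(td, "nodes.txt")
  outf <- file.path(td, "clusters.tsv")
  el <- igraph::as_edgelist(g)
  w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else numeric(0)
  write.table(data.frame(a = el[, 1], b = el[, 2], w = w), edges,
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(igraph::V(g)$name, nodesf)
  script <- test_path("mcl_oracle.py")
  status <- system2("python", c(script, edges, nodesf, inflation, pruning,
                                max_iter, eps, outf))
  stopifnot(status == 0)
  df <- read.table(outf, sep = "\t", stringsAsFactors = FALSE)
  setNames(df[[2]], df[[1]])
}

# random weighted graph with a planted 2-block partition
planted_two_block <- function(seed, n = 20, p_in = 0.7, p_out = 0.08) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  half <- n / 2
  block <- rep(1:2, each = half)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (block[i] == block[j]) p_in else p_out
      if (runif(1) < p) {
        edges[[length(edges) + 1]] <- data.frame(
          query_id = ids[i], subject_id = ids[j],
          e_value = 10^(-runif(1, 5, 30)), stringsAsFactors = FALSE)
      }
    }
  }
  hits <- do.call(rbind, edges)
  list(network = build_network(hits, nodes = ids),
       truth = setNames(block, ids))
}
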