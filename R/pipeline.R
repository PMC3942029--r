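# Pipeline orchestration: validated configuration, stage graph with a
# manifest, and named synthetic fixture scenarios.

config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "mulekit_run",
    stages = c("synth", "net", "cluster", "bounds", "sitespec", "consmotif"),
    e_max = 0.005,            # cascade retention E-value
    cov_min = 0.6,            # cascade retention query coverage
    edge_e_threshold = 1e-4,  # similarity-network edge threshold
    e_floor = 1e-200,
    inflation = 1.2,          # MCL inflation factor
    max_rounds = 7L,          # cascade rounds
    flank = 400L,             # boundary-calling flank
    junction_flank = 300L,    # insertion-site flank
    horizon = 30L,            # promoter-enrichment horizon
    promoter_score_min = 14,
    spacer_min = 15L, spacer_max = 19L,
    ir_min = 18L, ir_max = 39L,
    dr_lengths = c(8L, 9L),
    window_catalytic = 15L,   # conservation window (catalytic-domain view)
    window_signature = 10L,   # conservation window (differential view)
    max_gap_frac = 0.6,
    n_families = 5L, family_members = 6L, substitution_rate = 0.18,
    n_insertions = 12L, genome_length = 60000L
  )
}

#' Build a validated pipeline configuration
#'
#' All thresholds default to the values used throughout the package
#' (retention E <= 0.005 and coverage >= 60%, network edges at E < 1e-4,
#' MCL inflation 1.2, 400/300 bp flanks, 30 bp promoter horizon, 15/10 aa
#' conservation windows, 60% gap-column filter, 15-19 bp spacers, 18-39 bp
#' IRs, 8-9 bp DRs). Unknown keys are rejected; every threshold is checked
#' against its documented domain.
#'
#' @param ... overrides of the defaults (see Details in the vignette).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    stopifnot(e_max > 0, cov_min >= 0, cov_min <= 1,
              edge_e_threshold > 0, inflation > 1,
              max_rounds >= 0, flank > 0, junction_flank > 0,
              horizon > 0, spacer_min >= 15, spacer_max <= 19,
              spacer_min <= spacer_max,
              ir_min >= 18, ir_max <= 39, ir_min <= ir_max,
              all(dr_lengths %in% c(8L, 9L)),
              max_gap_frac >= 0, max_gap_frac <= 1)
  })
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with config keys.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the analysis pipeline over synthetic or supplied inputs
#'
#' Executes the requested stages in dependency order (`synth` -> `net` ->
#' `cluster`; `synth` -> `bounds` -> `sitespec`; `synth` -> `consmotif`),
#' writing every stage output under `config$out_dir` and a manifest
#' (`manifest.yaml`) listing each file with its MD5 checksum alongside the
#' config snapshot. Reruns with the same config and inputs are
#' byte-identical for the deterministic stages. A stage whose upstream
#' output is missing fails with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(is(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  need <- function(stage, parent, obj) {
    if (is.null(obj)) {
      stop("stage '", stage, "' requires output of stage '", parent, "'")
    }
    obj
  }
  files <- character(0)
  emit <- function(path) files <<- c(files, path)
  state <- list()

  if ("synth" %in% stages) {
    specs <- lapply(seq_len(config$n_families), function(i) {
      family_spec(sprintf("fam%d", i), n_members = config$family_members,
                  substitution_rate = config$substitution_rate)
    })
    fam <- generate_protein_families(specs, seed = derive_seed(config$seed, "synth"))
    te <- local({
      set.seed(derive_seed(config$seed, "te"))
      random_te("TE1", family_id = "fam1",
                transposase = as.character(fam$proteins[[1]]))
    })
    planted <- plant_insertions(config$genome_length, te,
                                site_model("promoter_offset"),
                                n_insertions = config$n_insertions,
                                seed = derive_seed(config$seed, "genome"))
    state$fam <- fam; state$te <- te; state$planted <- planted
    p <- file.path(config$out_dir, "proteins.fasta")
    Biostrings::writeXStringSet(fam$proteins, p); emit(p)
    p <- file.path(config$out_dir, "genome.fasta")
    Biostrings::writeXStringSet(planted$genome, p); emit(p)
    p <- file.path(config$out_dir, "truth.gff3")
    write_truth(planted$truth, p,
                file.path(config$out_dir, "truth.tsv"))
    emit(p); emit(file.path(config$out_dir, "truth.tsv"))
  }

  if ("net" %in% stages) {
    fam <- need("net", "synth", state$fam)
    hits <- all_vs_all_similarity(fam$proteins)
    net <- build_network(hits, e_threshold = config$edge_e_threshold,
                         e_floor = config$e_floor,
                         nodes = names(fam$proteins))
    state$net <- net
    p <- file.path(config$out_dir, "hits.tsv")
    write.table(hits, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
  }

  if ("cluster" %in% stages) {
    net <- need("cluster", "net", state$net)
    net <- mcl_cluster(net, inflation = config$inflation)
    state$net <- net
    paths <- export_network(net, file.path(config$out_dir, "network"))
    for (p in paths) emit(p)
  }

  if ("bounds" %in% stages) {
    planted <- need("bounds", "synth", state$planted)
    te <- state$te
    first <- planted$truth[1, ]
    ann <- annotate_te(planted$genome,
                       first$start + te$cds_start - 1L,
                       first$start + te$cds_end - 1L,
                       flank = config$flank, te_id = te$te_id,
                       family_id = te$family_id)
    state$annotations <- ann
    p <- file.path(config$out_dir, "te_annotations.tsv")
    write.table(ann, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    if (nrow(ann) > 0) {
      p <- file.path(config$out_dir, "te_annotations.gff3")
      write_gff3(ann[, c("genome_id", "start", "end", "strand", "te_id",
                         "copy_id", "dr_length", "frameshift")], p)
      emit(p)
    }
  }

  if ("sitespec" %in% stages) {
    ann <- need("sitespec", "bounds", state$annotations)
    planted <- state$planted
    flanks <- extract_junction_flanks(ann, planted$genome,
                                      flank = config$junction_flank)
    jh <- scan_junction_flanks(flanks,
                               spacer_range = c(config$spacer_min, config$spacer_max),
                               score_min = config$promoter_score_min)
    prof <- positional_enrichment(jh, horizon = config$horizon,
                                  n_junctions = nrow(flanks))
    state$junction_profile <- prof
    p <- file.path(config$out_dir, "junction_profile.tsv")
    write.table(prof$profile, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
  }

  if ("consmotif" %in% stages) {
    fam <- need("consmotif", "synth", state$fam)
    tr <- fam$truth
    fam1 <- fam$proteins[tr$protein_id[tr$family_id == tr$family_id[1]]]
    aln <- as_alignment(setNames(as.character(fam1), names(fam1)))
    prof <- windowed_conservation(aln, window = config$window_catalytic)
    calls <- anchor_triad(aln, rownames(aln)[1],
                          unlist(tr[1, c("d1", "d2", "e")]))
    p <- file.path(config$out_dir, "conservation_profile.tsv")
    write.table(data.frame(column = seq_along(prof), score = prof), p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
    p <- file.path(config$out_dir, "triad_calls.tsv")
    write.table(calls, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
  }

  manifest <- list(config = unclass(config),
                   files = lapply(unname(files), function(f) {
                     list(path = f, md5 = unname(tools::md5sum(f)))
                   }))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Write a named synthetic fixture scenario
#'
#' Available profiles: `families5` (five-family protein FASTA + truth),
#' `promoter_bias` (genome with promoter-targeted insertions + GFF truth),
#' `ish6_motif` (AT-rich-motif-targeted insertions), `frameshift`
#' (multi-copy element with a split transposase), `chain_homology`
#' (protein database with a transitive-homology chain A-B-C for cascade
#' sensitivity tests).
#'
#' @param profile_name one of the profiles above.
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, a list of the objects written (profile-dependent).
#' @export
make_fixtures <- function(profile_name, seed, dir = ".") {
  profiles <- c("families5", "promoter_bias", "ish6_motif", "frameshift",
                "chain_homology")
  if (!(profile_name %in% profiles)) {
    stop("unknown profile '", profile_name, "'; available: ",
         paste(profiles, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(profile_name,
    families5 = {
      specs <- lapply(1:5, function(i) {
        family_spec(sprintf("fam%d", i), n_members = 6,
                    substitution_rate = 0.18)
      })
      fam <- generate_protein_families(specs, seed = seed)
      Biostrings::writeXStringSet(fam$proteins,
                                  file.path(dir, "families5.fasta"))
      write.table(fam$truth, file.path(dir, "families5_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      fam
    },
    promoter_bias = {
      set.seed(derive_seed(seed, "fixture"))
      te <- random_te("TEp", family_id = "fam1", tpase_aa_length = 300)
      planted <- plant_insertions(120000, te, site_model("promoter_offset"),
                                  n_insertions = 30, seed = seed)
      Biostrings::writeXStringSet(planted$genome,
                                  file.path(dir, "promoter_bias.fasta"))
      write_truth(planted$truth, file.path(dir, "promoter_bias.gff3"),
                  file.path(dir, "promoter_bias_truth.tsv"))
      c(planted, list(te = te))
    },
    ish6_motif = {
      set.seed(derive_seed(seed, "fixture"))
      te <- random_te("TEh", family_id = "fam2", dr_length = 8,
                      tpase_aa_length = 300)
      planted <- plant_insertions(120000, te, site_model("at_rich_motif"),
                                  n_insertions = 30, seed = seed)
      Biostrings::writeXStringSet(planted$genome,
                                  file.path(dir, "ish6_motif.fasta"))
      write_truth(planted$truth, file.path(dir, "ish6_motif.gff3"),
                  file.path(dir, "ish6_motif_truth.tsv"))
      c(planted, list(te = te))
    },
    frameshift = {
      set.seed(derive_seed(seed, "fixture"))
      te <- random_te("TEf", family_id = "fam4", frameshift_split = TRUE,
                      tpase_aa_length = 320)
      planted <- plant_insertions(80000, te, site_model("uniform"),
                                  n_insertions = 6, seed = seed)
      Biostrings::writeXStringSet(planted$genome,
                                  file.path(dir, "frameshift.fasta"))
      write_truth(planted$truth, file.path(dir, "frameshift.gff3"),
                  file.path(dir, "frameshift_truth.tsv"))
      c(planted, list(te = te))
    },
    chain_homology = {
      db <- chain_homology_db(seed)
      Biostrings::writeXStringSet(db$proteins,
                                  file.path(dir, "chain_homology.fasta"))
      write.table(db$truth, file.path(dir, "chain_homology_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      db
    })
  invisible(out)
}

#' Transitive-homology chain database (families A - B - C)
#'
#' Families A and C are both derived from family B's ancestor by heavy
#' independent divergence, so A and B (and B and C) are detectably
#' similar while A and C are not: recovering C from an A seed requires
#' iterating through B. Used to quantify cascade sensitivity.
#'
#' @param seed integer seed.
#' @param n_members members per family.
#' @param length protein length (aa).
#' @param bridge_rate per-site divergence between B's ancestor and the A/C
#'   ancestors.
#' @param within_rate per-site divergence within each family.
#' @return list with `proteins` (AAStringSet) and `truth` (data.frame
#'   `protein_id`, `family_id`).
#' @export
chain_homology_db <- function(seed, n_members = 6, length = 250,
                              bridge_rate = 0.62, within_rate = 0.08) {
  set.seed(derive_seed(seed, "chain"))
  anc_b <- random_aa(length)
  anc_a <- mutate_protein(anc_b, bridge_rate)
  anc_c <- mutate_protein(anc_b, bridge_rate)
  seqs <- character(0)
  truth <- list()
  for (fam in c("A", "B", "C")) {
    anc <- switch(fam, A = anc_a, B = anc_b, C = anc_c)
    for (m in seq_len(n_members)) {
      id <- sprintf("%s_%02d", fam, m)
      seqs[id] <- mutate_protein(anc, within_rate)
      truth[[id]] <- data.frame(protein_id = id, family_id = fam,
                                stringsAsFactors = FALSE)
    }
  }
  list(proteins = Biostrings::AAStringSet(seqs),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
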