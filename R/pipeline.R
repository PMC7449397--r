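## End-to-end pipeline: CG-null translation -> global one-hot PCA ->
## per-family MDS + K-means cluster retrieval -> cross-family projections ->
## per-cluster CG-null/CG-restored consensus pairs -> NJ tree over cluster
## consensuses. Driven by a config list (or YAML file); every random stage
## receives an explicit seed and the config is echoed into the run
## directory, so a run is reproducible from config + seed alone. Run
## directories are immutable: an existing directory is refused.

#' Default pipeline configuration
#'
#' @return Named list of defaults; see [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    simulate = NULL,          # sim_params() arguments, or NULL
    families = NULL,          # named list of codon FASTA paths, or NULL
    frame = 0L,
    junction_mask = "both",
    mask_per = "column",
    threshold = 0.5,
    min_cg = 2L,
    scale = "count",
    pca_k = 3L,
    mds_m = 2L,
    k = "auto",               # integer, or "auto" for silhouette selection
    k_range = 2:8,
    restarts = 25L,
    seed = 1L,
    project_onto = NULL,      # family name whose space others are projected on
    out_dir = NULL
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- default_pipeline_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  cfg
}

#' Run the full sequence-space pipeline
#'
#' Executes, in order: input loading (codon FASTA per family, or a fresh
#' simulation), CG-null translation, global one-hot PCA over all families,
#' per-family metric MDS with K-means cluster retrieval (K fixed or chosen
#' by silhouette), optional projection of every family onto one family's
#' space, per-cluster CG-null/CG-restored consensus pairs, and a
#' neighbor-joining tree over all cluster CG-null consensuses. All outputs
#' (coordinates, cluster tables, consensus FASTA, Newick tree, config echo
#' and log) are written into a fresh run directory.
#'
#' @param config Config list or YAML path; see [default_pipeline_config()].
#'   Exactly one of `simulate` (arguments for [sim_params()]) or `families`
#'   (named list of aligned codon FASTA paths) must be given.
#' @return Invisibly, a list with `run_dir`, `pca`, per-family results
#'   (`space`, `assignment`, `consensus`), projections and `tree`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  if (dir.exists(cfg$out_dir))
    stop("run directory '", cfg$out_dir,
         "' already exists; runs are immutable, choose a fresh directory")
  if (is.null(cfg$simulate) == is.null(cfg$families))
    stop("exactly one of 'simulate' or 'families' must be configured")
  dir.create(cfg$out_dir, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "log.txt")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                                "\n", sep = "", file = logf, append = TRUE)
  log_line("ccspace ", as.character(utils::packageVersion("ccspace")),
           " pipeline; seed ", cfg$seed)
  cfg_echo <- cfg; cfg_echo$k_range <- as.integer(cfg$k_range)
  yaml::write_yaml(cfg_echo, file.path(cfg$out_dir, "config.yaml"))

  stage <- "load"
  result <- list(run_dir = cfg$out_dir)
  tryCatch({
    if (!is.null(cfg$simulate)) {
      p <- do.call(sim_params, c(cfg$simulate,
                                 if (is.null(cfg$simulate$seed))
                                   list(seed = cfg$seed)))
      sim <- simulate_family_series(p)
      fam_alns <- lapply(sim$families, `[[`, "codon_aln")
      result$sim <- sim
      log_line("simulated ", length(fam_alns), " families")
    } else {
      fam_alns <- lapply(cfg$families, read_alignment, alphabet = "dna")
      if (is.null(names(fam_alns)))
        names(fam_alns) <- paste0("F", seq_along(fam_alns))
      log_line("loaded ", length(fam_alns), " family alignments")
    }
    fam_num <- function(fn) {
      n <- suppressWarnings(as.integer(gsub("\\D", "", fn)))
      if (is.na(n)) match(fn, names(fam_alns)) else n
    }

    stage <- "cgnull"
    peps <- lapply(fam_alns, cg_null_translate_alignment, frame = cfg$frame,
                   junction_mask = cfg$junction_mask, per = cfg$mask_per)
    for (fn in names(peps))
      write_alignment(peps[[fn]],
                      file.path(cfg$out_dir, paste0(fn, "_cgnull.faa")))

    stage <- "pca"
    all_pep <- do.call(rbind, unname(peps))
    fam_of <- rep(names(peps), vapply(peps, nrow, integer(1)))
    names(fam_of) <- rownames(all_pep)
    pca <- fit_pca(one_hot_encode(all_pep), k = cfg$pca_k)
    write_coordinates(pca$scores,
                      file.path(cfg$out_dir, "pca_coords.tsv"),
                      labels = fam_of)
    result$pca <- pca
    log_line("global PCA on ", nrow(all_pep), " sequences")

    stage <- "mmds"
    fams <- list()
    for (fn in names(peps)) {
      dm <- pairwise_difference(peps[[fn]], scale = cfg$scale)
      space <- classical_mds(dm, m = cfg$mds_m)
      if (identical(cfg$k, "auto")) {
        K <- select_k(space, k_range = cfg$k_range, seed = cfg$seed,
                      restarts = cfg$restarts)
        scores <- attr(K, "scores")
      } else {
        K <- as.integer(cfg$k); scores <- NULL
      }
      asg <- kmeans_cluster(space, K, seed = cfg$seed,
                            restarts = cfg$restarts,
                            family = fam_num(fn),
                            selection_scores = scores)
      write_cluster_table(asg,
                          file.path(cfg$out_dir, paste0(fn, "_clusters.tsv")))
      write_coordinates(space$coordinates,
                        file.path(cfg$out_dir, paste0(fn, "_mds_coords.tsv")),
                        labels = stats::setNames(
                          asg$tags[asg$labels], names(asg$labels)))
      write_mds_space(space,
                      file.path(cfg$out_dir, paste0(fn, "_space.json")))
      fams[[fn]] <- list(diff = dm, space = space, assignment = asg)
      log_line(fn, ": ", nrow(peps[[fn]]), " sequences, K = ", asg$K)
    }
    result$families <- fams

    stage <- "project"
    if (!is.null(cfg$project_onto)) {
      target <- cfg$project_onto
      if (!target %in% names(fams)) stop("project_onto family not found")
      proj <- list()
      for (fn in setdiff(names(fams), target)) {
        dn <- cross_difference(peps[[fn]], peps[[target]],
                               scale = cfg$scale)
        proj[[fn]] <- project_supplementary(fams[[target]]$space, dn)
        write_coordinates(proj[[fn]],
                          file.path(cfg$out_dir,
                                    paste0(fn, "_on_", target, ".tsv")))
      }
      result$projections <- proj
      log_line("projected ", length(proj), " families onto ", target)
    }

    stage <- "consensus"
    cons_o <- character(0); cons_rt <- character(0)
    for (fn in names(fams)) {
      asg <- fams[[fn]]$assignment
      for (cl in seq_len(asg$K)) {
        ids <- names(asg$labels)[asg$labels == cl]
        pair <- consensus_pair(peps[[fn]][ids, , drop = FALSE],
                               fam_alns[[fn]][ids, , drop = FALSE],
                               threshold = cfg$threshold,
                               cluster = cl, family = fam_num(fn),
                               min_cg = cfg$min_cg)
        cons_o[render_name(pair$o$name)] <- pair$o$seq
        cons_rt[render_name(pair$rt$name)] <- pair$rt$seq
      }
    }
    write_alignment(cons_o, file.path(cfg$out_dir, "cluster_consensus_o.faa"))
    write_alignment(cons_rt, file.path(cfg$out_dir, "cluster_consensus_rt.faa"))
    result$consensus <- list(o = cons_o, rt = cons_rt)
    log_line(length(cons_o), " cluster consensus pairs")

    stage <- "tree"
    if (length(cons_o) >= 3L) {
      dmc <- pairwise_difference(cons_o, scale = cfg$scale,
                                 min_overlap = 1L)
      tree <- nj_tree(dmc)
      write_newick(tree, file.path(cfg$out_dir, "cluster_consensus_nj.nwk"))
      result$tree <- tree
      log_line("NJ tree over ", length(cons_o), " consensuses")
    } else {
      log_line("fewer than 3 consensuses; tree stage skipped")
    }
    log_line("done")
  }, error = function(e) {
    log_line("FAILED at stage '", stage, "': ", conditionMessage(e))
    writeLines(paste0("incomplete run; failed at stage: ", stage),
               file.path(cfg$out_dir, "INCOMPLETE"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
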