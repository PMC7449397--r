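## Forward simulator of L1 family succession with post-insertion CpG
## hypermutation.
##
## Model: an active master coding sequence drifts by replacement codon
## substitutions (weak purifying filter: no stops) through a series of
## family steps, oldest family first. Each family spawns several coexisting
## lineage founders separated by replacement substitutions concentrated in
## the coiled coil region; optionally a fraction of lineages is carried
## unchanged into the next family (persistence). Each founder emits dead
## genomic copies that then decay neutrally for their age: planted CpG
## dinucleotides mutate through the deamination channel only, at
## cpg_rate_multiplier times the background per-site rate, to TG (C>T) or
## CA (G>A on the complementary strand) with equal probability, so that a
## planted CpG survives as CG with probability
## exp(-neutral_rate * cpg_rate_multiplier * age). All other sites mutate
## uniformly at the background rate. No indels are introduced, so copies
## are aligned by construction.

SENSE_CODONS <- NULL  # initialized on load

.onLoad <- function(libname, pkgname) {
  gc_tab <- Biostrings::GENETIC_CODE
  utils::assignInMyNamespace("SENSE_CODONS", names(gc_tab)[gc_tab != "*"])
}

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

random_sense_codons <- function(n) sample(SENSE_CODONS, n, replace = TRUE)

replacement_codon <- function(codon) {
  aa <- codon_aa(codon)
  pool <- SENSE_CODONS[Biostrings::GENETIC_CODE[SENSE_CODONS] != aa]
  sample(pool, 1L)
}

#' Simulation parameters
#'
#' Validated parameter set for [simulate_family_series()]. Defaults describe
#' a desk-scale L1-like study system: a 101-codon coiled-coil-sized protein,
#' three successive families, three coexisting lineages of 50 copies each
#' (150 copies per family), founders separated by about 14 replacement
#' substitutions, and a 10-fold CpG decay acceleration.
#'
#' @param n_families Number of successive families (oldest first).
#' @param lineages_per_family Coexisting lineages ("clusters") per family.
#' @param copies_per_lineage Dead genomic copies emitted per lineage.
#' @param protein_length Protein length in codons.
#' @param cc_region `c(start, end)` codon interval where lineage divergence
#'   is concentrated.
#' @param master_sub_rate Replacement substitutions per codon per family
#'   step on the active master lineage.
#' @param lineage_divergence Approximate pairwise replacement-substitution
#'   distance between coexisting lineage founders (each founder receives
#'   half as private substitutions at disjoint positions).
#' @param lineage_persistence Fraction of lineages carried unchanged into
#'   the next family.
#' @param cpg_rate_multiplier Fold acceleration of CpG decay over the
#'   background rate (`>= 1`).
#' @param neutral_rate Background per-site substitution probability rate
#'   per age unit of a dead copy.
#' @param decay_time_scale Age units per family step; family `f` of `n` has
#'   age `decay_time_scale * (n - f + 1)` (older families decay longer).
#' @param seed Mandatory RNG seed.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_families = 3L, lineages_per_family = 3L,
                       copies_per_lineage = 50L, protein_length = 101L,
                       cc_region = c(1L, protein_length),
                       master_sub_rate = 0.02, lineage_divergence = 14L,
                       lineage_persistence = 0, cpg_rate_multiplier = 10,
                       neutral_rate = 0.008, decay_time_scale = 1,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  p <- list(n_families = as.integer(n_families),
            lineages_per_family = as.integer(lineages_per_family),
            copies_per_lineage = as.integer(copies_per_lineage),
            protein_length = as.integer(protein_length),
            cc_region = as.integer(cc_region),
            master_sub_rate = master_sub_rate,
            lineage_divergence = as.integer(lineage_divergence),
            lineage_persistence = lineage_persistence,
            cpg_rate_multiplier = cpg_rate_multiplier,
            neutral_rate = neutral_rate,
            decay_time_scale = decay_time_scale,
            seed = as.integer(seed))
  with(p, {
    if (n_families < 1L || lineages_per_family < 1L || copies_per_lineage < 1L)
      stop("counts must be positive")
    if (protein_length < 2L) stop("protein_length must be >= 2 codons")
    if (length(cc_region) != 2L || cc_region[1L] < 1L ||
        cc_region[2L] > protein_length || cc_region[1L] > cc_region[2L])
      stop("cc_region must be an interval within the protein")
    if (master_sub_rate < 0 || neutral_rate < 0 || decay_time_scale < 0 ||
        lineage_persistence < 0 || lineage_persistence > 1)
      stop("rates must be >= 0 (persistence in [0, 1])")
    if (cpg_rate_multiplier < 1) stop("cpg_rate_multiplier must be >= 1")
  })
  structure(p, class = "sim_params")
}

cpg_sites_of <- function(nt) {
  which(nt[-length(nt)] == "C" & nt[-1L] == "G")
}

decay_copy <- function(founder_nt, age, params) {
  nt <- founder_nt
  cpg <- cpg_sites_of(nt)
  cpg_p <- 1 - exp(-params$neutral_rate * params$cpg_rate_multiplier * age)
  bg_p <- 1 - exp(-params$neutral_rate * age)
  if (length(cpg)) {
    hit <- cpg[stats::runif(length(cpg)) < cpg_p]
    for (i in hit) {
      if (stats::runif(1) < 0.5) nt[i] <- "T" else nt[i + 1L] <- "A"
    }
  }
  protected <- unique(c(cpg, cpg + 1L))
  bg_idx <- setdiff(seq_along(nt), protected)
  hit <- bg_idx[stats::runif(length(bg_idx)) < bg_p]
  for (i in hit) nt[i] <- sample(setdiff(c("A", "C", "G", "T"), nt[i]), 1L)
  nt
}

#' Simulate a series of L1-like families with CpG hypermutation
#'
#' See [sim_params()] for the model. Output alignments contain no indels,
#' so they are aligned by construction, and the returned truth object maps
#' every copy to its founder and lineage.
#'
#' @param params A [sim_params()] object.
#' @return Object of class `ccs_sim`: list with
#'   * `params`;
#'   * `families`: named list (`F1`, `F2`, ...), each with `codon_aln`
#'     (nucleotide character matrix, one row per copy), `age`, `family`;
#'   * `truth`: list with `founders` (per family, per lineage: `nt`,
#'     `peptide`, `origin` — the global id of the founding lineage),
#'     `labels` (data.frame `id`, `family`, `lineage`, `origin`, `age`)
#'     and `cpg_sites` (per family, per lineage: planted CpG start
#'     positions in the founder).
#' @export
simulate_family_series <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(params$seed)

  L <- params$protein_length
  master <- random_sense_codons(L)
  families <- list()
  founders_all <- list()
  cpg_all <- list()
  labels <- list()
  prev_founders <- NULL

  n_persist <- if (params$n_families > 1L)
    floor(params$lineage_persistence * params$lineages_per_family) else 0L
  private_subs <- ceiling(params$lineage_divergence / 2)
  cc_codons <- seq.int(params$cc_region[1L], params$cc_region[2L])

  for (f in seq_len(params$n_families)) {
    if (f > 1L) {
      k <- stats::rpois(1L, params$master_sub_rate * L)
      for (pos in sample.int(L, min(k, L)))
        master[pos] <- replacement_codon(master[pos])
    }
    age <- params$decay_time_scale * (params$n_families - f + 1L)
    founders <- vector("list", params$lineages_per_family)
    # persistent lineages carried unchanged from the previous family
    np <- if (f > 1L && !is.null(prev_founders))
      min(n_persist, length(prev_founders)) else 0L
    if (np > 0L)
      for (l in seq_len(np)) founders[[l]] <- prev_founders[[l]]
    # fresh lineages: private substitutions at disjoint cc positions
    fresh <- if (np < params$lineages_per_family)
      seq.int(np + 1L, params$lineages_per_family) else integer(0)
    need <- length(fresh) * private_subs
    pool <- if (need <= length(cc_codons)) sample(cc_codons, need)
            else sample(cc_codons, need, replace = TRUE)
    for (k in seq_along(fresh)) {
      l <- fresh[k]
      cod <- master
      pos <- pool[seq.int((k - 1L) * private_subs + 1L, k * private_subs)]
      for (pp in unique(pos)) cod[pp] <- replacement_codon(cod[pp])
      founders[[l]] <- list(codons = cod,
                            origin = sprintf("F%d_L%d", f, l))
    }
    names(founders) <- paste0("L", seq_along(founders))

    copies <- character(0); ids <- character(0); lin <- integer(0)
    fam_cpg <- list()
    for (l in seq_along(founders)) {
      founder_nt <- strsplit(paste0(founders[[l]]$codons, collapse = ""),
                             "")[[1]]
      fam_cpg[[names(founders)[l]]] <- cpg_sites_of(founder_nt)
      for (ci in seq_len(params$copies_per_lineage)) {
        nt <- decay_copy(founder_nt, age, params)
        ids <- c(ids, sprintf("F%d_L%d_c%d", f, l, ci))
        copies <- c(copies, paste0(nt, collapse = ""))
        lin <- c(lin, l)
      }
    }
    aln <- as_alignment_matrix(stats::setNames(copies, ids))
    families[[paste0("F", f)]] <- list(codon_aln = aln, age = age,
                                       family = f)
    founders_all[[paste0("F", f)]] <- lapply(founders, function(fd)
      list(nt = paste0(fd$codons, collapse = ""),
           peptide = translate_codons(paste0(fd$codons, collapse = "")),
           origin = fd$origin))
    cpg_all[[paste0("F", f)]] <- fam_cpg
    labels[[f]] <- data.frame(
      id = ids, family = f, lineage = lin,
      origin = vapply(lin, function(l) founders[[l]]$origin, character(1)),
      age = age, stringsAsFactors = FALSE)
    prev_founders <- founders
  }

  structure(list(params = params, families = families,
                 truth = list(founders = founders_all,
                              labels = do.call(rbind, labels),
                              cpg_sites = cpg_all)),
            class = "ccs_sim")
}

#' @export
print.ccs_sim <- function(x, ...) {
  p <- x$params
  cat("<ccs_sim> ", p$n_families, " families x ", p$lineages_per_family,
      " lineages x ", p$copies_per_lineage, " copies; L = ",
      p$protein_length, " codons; seed ", p$seed, "\n", sep = "")
  invisible(x)
}

#' Score a cluster assignment against simulation truth
#'
#' Adjusted Rand index of the assignment labels against the planted lineage
#' labels of one simulated family; optionally, per-consensus recovery
#' identity against the planted founder peptides.
#'
#' @param assignment A `cluster_assignment` covering the copies of one
#'   family.
#' @param sim A `ccs_sim`.
#' @param family Family index.
#' @param consensuses Optional character vector of consensus peptide
#'   strings; for each, the best identity (over positions where both carry
#'   standard residues) against any planted founder peptide of the family
#'   is reported.
#' @return List with `ari` and (when requested) `founder_identity`.
#' @export
truth_metrics <- function(assignment, sim, family = 1L, consensuses = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(sim, "ccs_sim"))
  lab <- sim$truth$labels
  lab <- lab[lab$family == family, ]
  ids <- names(assignment$labels)
  if (!setequal(ids, lab$id))
    stop("assignment ids do not match the copies of family ", family)
  planted <- lab$lineage[match(ids, lab$id)]
  ari <- mclust::adjustedRandIndex(assignment$labels, planted)
  out <- list(ari = ari)
  if (!is.null(consensuses)) {
    founders <- vapply(sim$truth$founders[[paste0("F", family)]],
                       `[[`, character(1), "peptide")
    out$founder_identity <- vapply(consensuses, function(cs) {
      cv <- seq_chars(cs)
      max(vapply(founders, function(fp) {
        fv <- seq_chars(fp)
        ok <- cv %in% AA20 & fv %in% AA20
        if (!any(ok)) return(0)
        sum(cv[ok] == fv[ok]) / sum(ok)
      }, numeric(1)))
    }, numeric(1))
  }
  out
}

#' Write simulated families to a directory
#'
#' Emits one aligned FASTA per family, a truth TSV and a parameter echo
#' (YAML).
#'
#' @param sim A `ccs_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "ccs_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fn in names(sim$families))
    write_alignment(sim$families[[fn]]$codon_aln,
                    file.path(dir, paste0(fn, "_codon.fasta")))
  utils::write.table(sim$truth$labels, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(sim$params), file.path(dir, "params.yaml"))
  invisible(dir)
}
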