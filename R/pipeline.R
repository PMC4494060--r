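## End-to-end pipeline: wires the stages together on real or simulated
## inputs, with a resolved config, per-stage outputs and a checksummed run
## manifest.

#' Default species tree of the bundled simulation scenario
#'
#' A fixed 13-taxon rooted tree with branch lengths: a 10-strain species
#' complex of four microclusters (A-D) of 2-3 closely related strains, a
#' sister species (LSF), and two more distant outgroups, mirroring the scale
#' and geometry of a small symbiont clade nested among free-living relatives.
#' Internal nodes are labeled so branches can be addressed by name; the
#' `ingroup` stem (the species complex's ancestral branch) is the natural
#' focal branch for genome-reduction scenarios and is deliberately not
#' adjacent to the root, so losses on it are identifiable.
#'
#' @return a rooted `phylo`.
#' @export
kunkeei_like_tree <- function() {
  txt <- paste0(
    "(((((A1:0.05,(A2:0.04,A3:0.04)A23:0.02)A:0.08,",
    "(B1:0.05,B2:0.05)B:0.08)AB:0.06,",
    "((C1:0.05,C2:0.05)C:0.08,",
    "(D1:0.05,(D2:0.04,D3:0.04)D23:0.02)D:0.08)CD:0.06)ingroup:0.30,",
    "LSF:0.40)lks:0.10,(OUT1:0.25,OUT2:0.25)outg:0.15)root;")
  ape::read.tree(text = txt)
}

#' Default run configuration for the bundled simulation scenario
#'
#' A fully resolved configuration for [run_pipeline()] on synthetic data:
#' a 1.5 Mb circular genome with planted skew, 1,300 categorized genes, gene
#' content evolved on the 13-taxon tree with a loss-heavy ingroup stem, 790
#' gene trees from a topology mixture, and a small set of clonal and
#' recombinant alignments. All stage seeds are derived from `seed`.
#'
#' @param seed master seed; sub-seeds are small offsets of it.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 42L) {
  seed <- as.integer(seed) %% 100000L
  list(
    seed = seed,
    genome = list(length = 1500000L, ori = 0L, ter = 750000L,
                  skew_amp = 0.08, seed = seed + 1L),
    skew = list(window = 10000L, step = 1000L),
    genes = list(
      n_genes = 1300L,
      categories = data.frame(
        category = c("amino_acid_metabolism", "transport", "translation",
                     "replication", "other"),
        bias = c("ori_proximal", "ori_proximal", "ter_proximal",
                 "ter_proximal", "uniform"),
        weight = c(0.15, 0.10, 0.15, 0.10, 0.50),
        stringsAsFactors = FALSE),
      seed = seed + 2L),
    bias = list(min_group = 5L),
    flux = list(root_families = 500L, gain_rate = 0.05, loss_rate = 0.3,
                dup_rate = 0.05, focal_branch = "ingroup",
                focal_multiplier = 3, seed = seed + 3L,
                costs = cost_scheme()),
    trees = list(n_trees = 790L, threshold = 95, rare_fraction = 0.01,
                 support_mean = 97, support_sd = 4,
                 alt_weights = c(0.15, 0.10), seed = seed + 4L),
    recomb = list(n_clonal = 6L, n_recombinant = 2L, n_sites = 600L,
                  subst_rate = 0.8, window = 25L, n_permutations = 200L,
                  alpha = 0.01, seed = seed + 5L),
    growth = list(doubling = 55, t_max = 600, interval = 30,
                  noise_sd = 0.02, seed = seed + 6L),
    rvalue = list(speed = 1000)
  )
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_run_config()].
#'
#' @param path YAML file.
#' @param seed master seed for the defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path, seed = 42L) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_lists(default_run_config(seed), user)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes)
  else if (is.data.frame(x)) as.list(x)
  else x
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on the simulated default
#' scenario: `simulate` (genome, genes, ortholog matrix, gene trees,
#' alignments, growth curve), `skew` (GC-skew profile, ori/ter call, R
#' value), `bias` (distance table and positional-bias tests), `flux`
#' (ancestral gene content and per-branch flux), `trees` (sister-pair tally
#' and microcluster monophyly), `recomb` (Phi screen). Writes per-stage
#' outputs under `out_dir` plus a manifest with the resolved config and an
#' md5 checksum of every output file.
#'
#' @param config configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run; dependencies of later
#'   stages are satisfied by always running `simulate` first.
#' @return the manifest (invisibly), also written to `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir,
                         stages = c("simulate", "skew", "bias", "flux",
                                    "trees", "recomb")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }
  tree <- kunkeei_like_tree()

  ## -- simulate (always: later stages consume its objects) ------------------
  genome <- simulate_genome(config$genome$length, config$genome$ori,
                            config$genome$ter, config$genome$skew_amp,
                            config$genome$seed)
  genes <- simulate_gene_positions(config$genes$n_genes, config$genes$categories,
                                   genome, config$genes$seed)
  mat <- simulate_gene_content_evolution(
    tree, config$flux$root_families, config$flux$gain_rate,
    config$flux$loss_rate, config$flux$dup_rate,
    focal_branch = config$flux$focal_branch,
    focal_multiplier = config$flux$focal_multiplier,
    seed = config$flux$seed)
  ## alternative gene-tree topologies: the two other resolutions of the
  ## A-microcluster triplet, obtained by relabeling the species tree
  swap_tips <- function(tr, a, b) {
    i <- match(a, tr$tip.label); j <- match(b, tr$tip.label)
    tr$tip.label[c(i, j)] <- c(b, a)
    tr
  }
  alts <- list(
    list(tree = swap_tips(tree, "A1", "A2"),
         weight = config$trees$alt_weights[1]),
    list(tree = swap_tips(tree, "A1", "A3"),
         weight = config$trees$alt_weights[2]))
  genetrees <- simulate_gene_trees(tree, config$trees$n_trees, alts,
                                   support_mean = config$trees$support_mean,
                                   support_sd = config$trees$support_sd,
                                   seed = config$trees$seed)
  ingroup4 <- ape::keep.tip(tree, c("A1", "B1", "C1", "D1"))
  alt4 <- ape::read.tree(
    text = "(((A1:0.12,C1:0.12):0.05,(B1:0.12,D1:0.12):0.05):0.3,OUT2:0.0);")
  alt4 <- ape::drop.tip(alt4, "OUT2")
  rc <- config$recomb
  alns <- c(
    lapply(seq_len(rc$n_clonal), function(i)
      simulate_alignment(list(list(tree = ingroup4, n_sites = rc$n_sites)),
                         rc$subst_rate, seed = rc$seed + i)),
    lapply(seq_len(rc$n_recombinant), function(i)
      simulate_alignment(list(list(tree = ingroup4,
                                   n_sites = rc$n_sites %/% 2L),
                              list(tree = alt4,
                                   n_sites = rc$n_sites - rc$n_sites %/% 2L)),
                         rc$subst_rate, seed = rc$seed + 100L + i)))
  names(alns) <- c(sprintf("clonal%02d", seq_len(rc$n_clonal)),
                   sprintf("recomb%02d", seq_len(rc$n_recombinant)))
  growth <- simulate_growth_curve(config$growth$doubling,
                                  config$growth$t_max,
                                  config$growth$interval,
                                  config$growth$noise_sd,
                                  seed = config$growth$seed)
  if ("simulate" %in% stages) {
    write_genome(genome, emit(file.path(out_dir, "genome.fasta")))
    write_gene_table(genes, emit(file.path(out_dir, "genes.tsv")))
    write_ortholog_matrix(mat, emit(file.path(out_dir, "orthologs.tsv")))
    write_trees(tree, emit(file.path(out_dir, "species.nwk")))
    write_trees(genetrees, emit(file.path(out_dir, "genetrees.nwk")))
    for (nm in names(alns))
      write_alignment(alns[[nm]],
                      emit(file.path(out_dir, paste0("aln_", nm, ".fasta"))))
    write.table(growth, emit(file.path(out_dir, "growth.csv")), sep = ",",
                quote = FALSE, row.names = FALSE)
    .write_json(list(scenario = "kunkeei_like", seed = config$seed,
                     genome = attr(genome, "truth"),
                     flux = list(true_losses = as.list(
                       attr(mat, "truth")$true_losses)),
                     trees = list(weights = attr(genetrees,
                                                 "truth")$weights)),
                emit(file.path(out_dir, "truth.json")))
  }

  results <- list()
  if ("skew" %in% stages) {
    prof <- gc_skew_profile(genome, config$skew$window, config$skew$step)
    ot <- detect_ori_ter(prof)
    gfit <- estimate_doubling_time(growth$time_min, growth$od)
    rv <- replication_ratio_R(genome$length, config$rvalue$speed,
                              gfit$doubling_time)
    write.table(data.frame(center = prof$centers, skew = prof$skew,
                           cumulative = prof$cumulative),
                emit(file.path(out_dir, "skew.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$skew <- list(ori = ot$ori, ter = ot$ter,
                         uncertainty_bp = ot$uncertainty_bp,
                         doubling_time_min = gfit$doubling_time,
                         R = rv$R_2dp)
    .write_json(results$skew, emit(file.path(out_dir, "oriter.json")))
  }
  if ("bias" %in% stages) {
    dt <- build_distance_table(genes, genome)
    kw <- kruskal_wallis_bias(dt, config$bias$min_group)
    pw <- pairwise_mannwhitney(dt, config$bias$min_group)
    write.table(dt, emit(file.path(out_dir, "distances.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$bias <- list(H = kw$H, df = kw$df, p_global = kw$p_global,
                         pairwise = pw[c("cat_i", "cat_j", "U", "p_raw",
                                         "p_adjusted")])
    .write_json(results$bias, emit(file.path(out_dir, "bias.json")))
  }
  if ("flux" %in% stages) {
    recon <- sankoff_reconstruct(mat, tree, config$flux$costs)
    fs <- flux_summary(recon, focal_branch = config$flux$focal_branch)
    write.table(fs, emit(file.path(out_dir, "flux_branches.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(recon$events, emit(file.path(out_dir, "flux_events.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    anno <- recon$tree
    ntip <- length(anno$tip.label)
    anno$node.label <- recon$families_per_node[(ntip + 1):(ntip + anno$Nnode)]
    ape::write.tree(anno, emit(file.path(out_dir, "flux_annotated.nwk")))
    results$flux <- list(total_cost = recon$total_cost,
                         mode = recon$mode,
                         fold_vs_background = attr(fs, "fold_vs_background"))
  }
  if ("trees" %in% stages) {
    tly <- tally_sister_support(genetrees, config$trees$threshold,
                                config$trees$rare_fraction)
    mono <- monophyly_support(genetrees,
                              groups = list(A = c("A1", "A2", "A3"),
                                            B = c("B1", "B2"),
                                            C = c("C1", "C2"),
                                            D = c("D1", "D2", "D3")),
                              threshold = config$trees$threshold)
    write.table(tly$counts, emit(file.path(out_dir, "sister_tally.tsv")),
                sep = "\t", quote = FALSE)
    results$trees <- list(n_trees = tly$n_trees,
                          n_monophyly_support = mono$n_support)
    .write_json(results$trees, emit(file.path(out_dir, "trees.json")))
  }
  if ("recomb" %in% stages) {
    phis <- lapply(seq_along(alns), function(i)
      phi_test(alns[[i]], rc$window, rc$n_permutations,
               seed = rc$seed + 200L + i))
    names(phis) <- names(alns)
    scr <- recombination_screen(phis, alpha = rc$alpha)
    write.table(scr$verdicts, emit(file.path(out_dir, "recomb.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$recomb <- list(n_tested = scr$n_tested,
                           n_positive = scr$n_positive,
                           fraction_percent = scr$fraction_percent)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("archflux")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages,
    config = strip_classes(config),
    results = results,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  .write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
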