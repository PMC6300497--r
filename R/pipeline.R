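## Pipeline orchestration: read (or simulate) -> Bruvo distances per locus
## subset -> MLGs -> histogram/threshold -> clonal lineages -> diversity
## table -> PCoA + NJ on MLG representatives -> parentage (majority and
## pooled passes) -> cytotype table. Every stage's output is written to
## the bundle directory together with a manifest recording parameters and
## RNG seeds; a stage failure aborts with the stage named, retaining the
## outputs already written.

#' Default pipeline configuration
#'
#' @param seed RNG seed used for simulation and rarefaction.
#' @return A nested list understood by [run_pipeline()]. Fields:
#'   `simulate` (use the synthetic generator; otherwise `genotype_csv`,
#'   `panel` and optionally `fcm_csv` must point at input files),
#'   `sim_config`, `bruvo_model`, `core_loci`/`full_loci` (locus subsets:
#'   analyses spanning diploids and polyploids use the core subset,
#'   polyploid-only analyses the full panel), `bin_width`,
#'   `smooth_window`, `threshold_override`, `rarefaction` (`n`, `reps`),
#'   `ploidy` (`diploid_ref_2c`, `base_x`, `tolerance`), `parentage`
#'   (`targets`, `candidates`, `pool_source`, `variable_loci`), `seed`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    simulate = TRUE,
    sim_config = default_sim_config(seed),
    genotype_csv = NULL, panel = NULL, fcm_csv = NULL,
    bruvo_model = "combined",
    core_loci = NULL,          # NULL = sim_config$core_loci or full panel
    bin_width = 0.01,
    smooth_window = 3L,
    threshold_override = NULL,
    rarefaction = list(n = NULL, reps = 1000L),
    ploidy = list(diploid_ref_2c = NULL, base_x = 17L, tolerance = 0.25),
    parentage = list(targets = NULL, candidates = NULL,
                     pool_source = "all_samples",
                     variable_loci = character(0)),
    seed = as.integer(seed)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override [default_pipeline_config()].
#'
#' @param path YAML file.
#' @return Pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_pipeline_config(seed = if (!is.null(y$seed)) y$seed else 1L)
  for (nm in setdiff(names(y), "seed")) cfg[[nm]] <- y[[nm]]
  cfg
}

#' Run the full analysis pipeline
#'
#' @param config list from [default_pipeline_config()] /
#'   [read_pipeline_config()].
#' @param out_dir output directory for the report bundle (created if
#'   needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`gs`, `dm_core`, `dm_full`, `mlg`, `histogram`, `lineages`,
#'   `diversity_core`, `diversity_full`, `pcoa`, `tree`, `parentage`,
#'   `cytotypes`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "pipeline_out") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, bruvo_model = config$bruvo_model,
                   stages = list())
  res <- list()
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message("[", name, "] ...")
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      completed = TRUE, at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    out
  }

  res$gs <- stage("read", {
    if (isTRUE(config$simulate)) {
      sim <- simulate_study(config$sim_config, seed = config$seed)
      res$sim <- sim
      write_genotype_table(sim$gs, file.path(out_dir, "genotypes.csv"))
      utils::write.csv(sim$fcm, file.path(out_dir, "fcm.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        sim$truth$samples, file.path(out_dir, "truth_samples.json"))
      sim$gs
    } else {
      if (is.null(config$genotype_csv) || !file.exists(config$genotype_csv))
        stop("genotype_csv not found: ", config$genotype_csv)
      read_genotype_table(config$genotype_csv, config$panel)
    }
  })

  core <- config$core_loci
  if (is.null(core) && isTRUE(config$simulate))
    core <- config$sim_config$core_loci
  if (is.null(core)) core <- res$gs$panel$locus
  full <- res$gs$panel$locus
  polyploid_ids <- sample_ids(res$gs)[res$gs$meta$ploidy > 2 &
                                        !is.na(res$gs$meta$ploidy)]

  res$dm_core <- stage("distances_core", {
    dm <- bruvo_distance_matrix(res$gs, model = config$bruvo_model,
                                loci = core)
    write_distance_matrix(dm, file.path(out_dir, "distances_core.csv"))
    dm
  })
  res$dm_full <- stage("distances_full", {
    gp <- gs_subset(res$gs, samples = polyploid_ids)
    dm <- bruvo_distance_matrix(gp, model = config$bruvo_model,
                                loci = full)
    write_distance_matrix(dm, file.path(out_dir, "distances_full.csv"))
    dm
  })

  res$mlg <- stage("mlgs", assign_mlgs(res$dm_core))

  res$histogram <- stage("histogram", {
    h <- suppressWarnings(
      distance_histogram(res$dm_full, bin_width = config$bin_width,
                         smooth_window = config$smooth_window))
    utils::write.csv(
      data.frame(bin_low = utils::head(h$bin_edges, -1),
                 bin_high = utils::tail(h$bin_edges, -1),
                 count = h$counts),
      file.path(out_dir, "histogram.csv"), row.names = FALSE)
    h
  })

  threshold <- if (!is.null(config$threshold_override)) {
    message("using threshold override ", config$threshold_override)
    config$threshold_override
  } else res$histogram$detected_threshold
  manifest$threshold <- threshold
  manifest$threshold_source <- if (!is.null(config$threshold_override))
    "override" else "histogram_valley"

  res$lineages <- stage("lineages", {
    if (is.na(threshold))
      stop("no threshold detected and no override supplied")
    assign_clonal_lineages(res$dm_full, threshold)
  })

  stage("partitions_out", {
    ids <- names(res$mlg$group_of)
    utils::write.csv(
      data.frame(sample_id = ids, mlg_id = unname(res$mlg$group_of),
                 lineage_id = unname(
                   res$lineages$group_of[ids])),
      file.path(out_dir, "partitions.csv"), row.names = FALSE)
  })

  res$diversity_core <- stage("diversity_core", {
    d <- diversity_table(res$gs, res$mlg, loci = core)
    utils::write.csv(d, file.path(out_dir, "diversity_core.csv"),
                     row.names = FALSE)
    d
  })
  res$diversity_full <- stage("diversity_full", {
    gp <- gs_subset(res$gs, samples = polyploid_ids)
    mlg_full <- assign_mlgs(res$dm_full)
    d <- diversity_table(gp, mlg_full, res$lineages, loci = full)
    utils::write.csv(d, file.path(out_dir, "diversity_full.csv"),
                     row.names = FALSE)
    d
  })

  stage("rarefaction", {
    counts <- table(res$gs$meta$taxon)
    n <- config$rarefaction$n
    if (is.null(n)) n <- min(counts)
    big <- names(counts)[counts > n]
    if (length(big)) {
      rr <- vapply(big, function(tx)
        rarefied_richness(res$gs, tx, n = n,
                          reps = config$rarefaction$reps,
                          seed = config$seed, loci = core), numeric(1))
      utils::write.csv(
        data.frame(taxon = big, n = n, rarefied_A = rr),
        file.path(out_dir, "rarefaction.csv"), row.names = FALSE)
    }
  })

  reps <- res$mlg$representatives
  res$pcoa <- stage("pcoa", {
    dmr <- res$dm_core[reps, reps]
    p <- pcoa(dmr)
    utils::write.csv(
      data.frame(mlg = rownames(p$coordinates), p$coordinates),
      file.path(out_dir, "coords.csv"), row.names = FALSE)
    utils::write.csv(
      data.frame(axis = seq_along(p$percent_variance),
                 percent_variance = p$percent_variance),
      file.path(out_dir, "scree.csv"), row.names = FALSE)
    p
  })
  res$tree <- stage("nj_tree", {
    dmr <- res$dm_core[reps, reps]
    tr <- neighbor_joining(dmr)
    write_newick(tr, file.path(out_dir, "tree.nwk"))
    tr
  })

  res$parentage <- stage("parentage", {
    pc <- config$parentage
    taxa <- unique(res$gs$meta$taxon)
    apomict <- taxa[vapply(taxa, function(tx)
      all(res$gs$meta$ploidy[res$gs$meta$taxon == tx] > 2, na.rm = TRUE),
      logical(1))]
    targets <- if (is.null(pc$targets)) apomict else pc$targets
    tab <- do.call(rbind, lapply(targets, function(tg) {
      cand <- if (is.null(pc$candidates)) setdiff(taxa, tg) else
        setdiff(pc$candidates, tg)
      suppressWarnings(suppressMessages(
        rank_parent_pairs(res$gs, tg, cand, loci = core,
                          pool_source = pc$pool_source,
                          variable_loci = pc$variable_loci)))
    }))
    utils::write.csv(tab, file.path(out_dir, "parentage.csv"),
                     row.names = FALSE)
    tab
  })

  res$cytotypes <- stage("cytotypes", {
    fcm <- if (isTRUE(config$simulate)) res$sim$fcm
           else if (!is.null(config$fcm_csv)) read_fcm_table(config$fcm_csv)
           else NULL
    if (is.null(fcm)) NULL else {
      if (is.null(fcm$relative_2c))
        fcm$relative_2c <- relative_2c(fcm$sample_peak, fcm$standard_peak,
                                       fcm$standard_2c)
      ref <- config$ploidy$diploid_ref_2c
      if (is.null(ref)) {
        dip <- sample_ids(res$gs)[res$gs$meta$ploidy == 2 &
                                    !is.na(res$gs$meta$ploidy)]
        ref <- mean(fcm$relative_2c[fcm$sample_id %in% dip])
      }
      manifest$diploid_ref_2c <- ref
      ct <- cytotype_table(fcm, diploid_ref_2c = ref,
                           base_x = config$ploidy$base_x,
                           tolerance = config$ploidy$tolerance)
      utils::write.csv(ct, file.path(out_dir, "cytotypes.csv"),
                       row.names = FALSE)
      ct
    }
  })

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
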