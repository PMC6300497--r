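## Seeded synthetic-data generator emulating the statistical structure of
## a mixed-ploidy Sorbus-like species complex: two sexual outcrossing
## diploids with unique MLGs per individual, a reticulum of apomictic
## polyploid taxa each dominated (>80%) by one MLG plus rare
## stepwise-mutation variants, high allele sharing across taxa through
## shared hybrid ancestry, genome-specific loci that amplify only from one
## ancestral genome, and flow-cytometry peak summaries drawn around
## planted 2C values. Every sample carries ground-truth labels (founder
## clone, lineage, mutation count; true parent pair and gamete sizes for
## hybrids) for recovery tests.

# draw one allele set of `k` i.i.d. alleles (distinct set returned)
.draw_alleles <- function(freq, k, replace = TRUE) {
  size <- if (replace) k else min(k, length(freq$support))
  idx <- sample.int(length(freq$support), size, replace = replace,
                    prob = freq$prob)
  sort(unique(as.integer(freq$support[idx])))
}

#' Default simulation configuration
#'
#' Thirteen microsatellite loci (two genome-specific, three that fail to
#' amplify in the sexual diploids, ten 'core' loci scored in every taxon)
#' with truncated-geometric allele frequencies over 8-24 repeat-count
#' states per locus. Nine taxon entries: two sexual diploids (13 and 33
#' samples), two founder apomictic tetraploids, and five hybrid apomicts
#' including a triploid formed from a reduced diploid egg and a reduced
#' tetraploid pollen grain, two tetraploids formed over that triploid
#' bridge, and a two-sample second clone sharing its taxon label with
#' another entry (so the labelled taxon carries two true lineages).
#' Planted relative 2C values are 1.63 pg (diploid), 2.33 pg (triploid)
#' and 3.10/3.22 pg (tetraploids).
#'
#' @param seed default RNG seed recorded in the config (used by
#'   [simulate_study()] unless overridden).
#' @return A `sim_config` list: `panel`, `core_loci`, `freqs`, `taxa`,
#'   `mutation_rate`, `n_steps`, `fcm`, `seed`.
#' @export
default_sim_config <- function(seed = 1L) {
  loci <- c("GSA", "GSB", paste0("L", sprintf("%02d", 1:11)))
  tags <- c("genomeA", "genomeB", rep("none", 11))
  panel <- locus_panel(loci, repeat_len = 2L, genome_tag = tags)
  # loci that fail to amplify in the sexual diploids (polyploid-only panel)
  dip_fail <- c("L09", "L10", "L11")
  core <- setdiff(loci, dip_fail)
  supp_size <- c(24L, 24L, 8L, 10L, 12L, 14L, 16L, 18L, 20L, 22L, 24L,
                 9L, 15L)
  base <- c(10L, 30L, 12L, 18L, 24L, 8L, 15L, 21L, 27L, 11L, 19L, 25L,
            14L)
  ratio <- c(0.9, 0.9, rep(0.8, 11))
  freqs <- lapply(seq_along(loci), function(i) {
    support <- seq.int(base[i], length.out = supp_size[i])
    p <- ratio[i]^(seq_along(support) - 1L)
    list(support = support, prob = p / sum(p))
  })
  names(freqs) <- loci
  taxon <- function(name, breeding, ploidy, n, genomes, origin = "founder",
                    planted_2c, n_variants = 0L, label = name)
    list(name = name, label = label, breeding = breeding,
         ploidy = as.integer(ploidy), n = as.integer(n),
         genomes = genomes, origin = origin, planted_2c = planted_2c,
         n_variants = as.integer(n_variants))
  hyb <- function(parents, gametes) list(parents = parents,
                                         gametes = as.integer(gametes))
  taxa <- list(
    taxon("sexA", "sexual", 2, 13, "A", planted_2c = 1.63),
    taxon("sexT", "sexual", 2, 33, "B", planted_2c = 1.63),
    taxon("apoR", "apomictic", 4, 13, "A", planted_2c = 3.10,
          n_variants = 2),
    taxon("apoP", "apomictic", 4, 17, "A", planted_2c = 3.10,
          n_variants = 3),
    taxon("apoV", "apomictic", 4, 22, "A",
          origin = hyb(c("apoR", "sexA"), c(2, 2)), planted_2c = 3.10,
          n_variants = 4),
    taxon("apoM", "apomictic", 4, 29, "A",
          origin = hyb(c("apoV", "apoR"), c(2, 2)), planted_2c = 3.10,
          n_variants = 5),
    taxon("apoS", "apomictic", 3, 27, c("A", "B"),
          origin = hyb(c("sexT", "apoR"), c(1, 2)), planted_2c = 2.33,
          n_variants = 4),
    taxon("apoA", "apomictic", 4, 19, c("A", "B"),
          origin = hyb(c("apoS", "sexT"), c(3, 1)), planted_2c = 3.22,
          n_variants = 0),
    taxon("apoD", "apomictic", 4, 32, c("A", "B"),
          origin = hyb(c("apoS", "sexT"), c(3, 1)), planted_2c = 3.22,
          n_variants = 1),
    taxon("apoV2", "apomictic", 4, 2, "A",
          origin = hyb(c("apoV", "apoM"), c(2, 2)), planted_2c = 3.10,
          n_variants = 0, label = "apoV")
  )
  cfg <- list(panel = panel, core_loci = core, freqs = freqs, taxa = taxa,
              mutation_rate = 0.15, n_steps = 1L,
              fcm = list(standard_2c = 1, standard_peak = 200,
                         rel_noise_sd = 0.005, cv_mean = 2.54,
                         cv_sd = 0.39),
              seed = as.integer(seed))
  class(cfg) <- c("sim_config", "list")
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg$panel, "locus_panel"))
  for (loc in cfg$panel$locus) {
    f <- cfg$freqs[[loc]]
    if (is.null(f)) stop("no allele frequencies for locus ", loc)
    if (length(f$support) != length(f$prob))
      stop("support/prob length mismatch at locus ", loc)
    if (abs(sum(f$prob) - 1) > 1e-8)
      stop("allele frequencies at locus ", loc, " do not sum to 1")
    if (any(f$support <= 0)) stop("allele repeat counts must be positive")
  }
  seen <- character(0)
  for (tx in cfg$taxa) {
    if (tx$name %in% seen) stop("duplicate taxon entry name ", tx$name)
    if (!tx$breeding %in% c("sexual", "apomictic"))
      stop("breeding must be sexual or apomictic")
    if (!tx$ploidy %in% 2:4) stop("ploidy must be 2, 3 or 4")
    if (tx$n_variants > floor(0.19 * tx$n))
      stop("taxon ", tx$name, ": variants would break >80% MLG dominance")
    if (is.list(tx$origin)) {
      if (!all(tx$origin$parents %in% seen))
        stop("taxon ", tx$name,
             ": parents must be defined earlier in the taxa list")
      if (sum(tx$origin$gametes) != tx$ploidy)
        stop("taxon ", tx$name, ": gamete sizes must sum to the ploidy")
      pl <- vapply(cfg$taxa, function(t2) t2$ploidy, integer(1))
      names(pl) <- vapply(cfg$taxa, `[[`, character(1), "name")
      for (k in 1:2) {
        p <- pl[[tx$origin$parents[k]]]
        g <- tx$origin$gametes[k]
        if (!g %in% unique(c(p %/% 2L, (p + 1L) %/% 2L, p)))
          stop("taxon ", tx$name, ": gamete size ", g,
               " inconsistent with parent ploidy ", p,
               " (reduced = ploidy/2 rounded, unreduced = ploidy)")
      }
    }
    seen <- c(seen, tx$name)
  }
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Accepts the subset of [default_sim_config()] fields present in the file
#' and fills the rest from the defaults.
#'
#' @param path YAML file.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_sim_config(seed = if (!is.null(y$seed)) y$seed else 1L)
  for (nm in intersect(names(y), c("mutation_rate", "n_steps")))
    cfg[[nm]] <- y[[nm]]
  .validate_sim_config(cfg)
  cfg
}

# which panel loci amplify in a taxon entry
.amplifying_loci <- function(cfg, tx) {
  loci <- cfg$panel$locus
  keep <- rep(TRUE, length(loci))
  keep[cfg$panel$genome_tag == "genomeA" & !"A" %in% tx$genomes] <- FALSE
  keep[cfg$panel$genome_tag == "genomeB" & !"B" %in% tx$genomes] <- FALSE
  if (tx$breeding == "sexual")
    keep[loci %in% setdiff(loci, cfg$core_loci)] <- FALSE
  loci[keep]
}

#' Simulate a sexual outcrossing population
#'
#' Each individual independently draws `ploidy` alleles per locus from the
#' locus allele frequencies; the distinct set is recorded (copy number
#' unresolved, as in real fragment data). With many alleles per locus the
#' number of MLGs equals the sample size with high probability.
#'
#' @param freqs named list per locus: `support` (repeat counts), `prob`.
#' @param n number of individuals.
#' @param ploidy gametic multiplicity per locus (default 2).
#' @param seed optional RNG seed; omit to draw from the current stream.
#' @return List of `n` per-locus allele lists.
#' @export
simulate_sexual_population <- function(freqs, n, ploidy = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    g <- lapply(freqs, .draw_alleles, k = ploidy)
    names(g) <- names(freqs)
    g
  })
}

#' Combine two parental gametes into a hybrid founder genotype
#'
#' Per locus, each gamete samples `gamete_a` / `gamete_b` alleles without
#' replacement from the parent's distinct allele set (fewer when the
#' parent holds fewer distinct alleles; none when the locus is missing in
#' that parent). The child's allele set is the union, so at mutation rate
#' zero every child allele is contained in the parental pools and the true
#' parent pair scores zero mismatches by construction.
#'
#' @param parent_a,parent_b named per-locus allele lists.
#' @param gamete_a,gamete_b gamete sizes (alleles carried per locus);
#'   `ploidy/2` rounded for reduced gametes, the full ploidy for unreduced
#'   ones. The child's ploidy is their sum.
#' @param seed optional RNG seed.
#' @return List: `alleles` (child per-locus sets), `gametes` (the sampled
#'   per-locus contributions of each parent).
#' @export
make_hybrid_founder <- function(parent_a, parent_b, gamete_a, gamete_b,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (gamete_a < 0L || gamete_b < 0L || gamete_a + gamete_b < 2L)
    stop("inconsistent gamete sizes")
  loci <- union(names(parent_a), names(parent_b))
  ga <- gb <- child <- stats::setNames(vector("list", length(loci)), loci)
  for (loc in loci) {
    pa <- parent_a[[loc]]; pb <- parent_b[[loc]]
    ga[[loc]] <- if (length(pa))
      sort(pa[sample.int(length(pa), min(gamete_a, length(pa)))])
    else integer(0)
    gb[[loc]] <- if (length(pb))
      sort(pb[sample.int(length(pb), min(gamete_b, length(pb)))])
    else integer(0)
    child[[loc]] <- sort(unique(c(ga[[loc]], gb[[loc]])))
  }
  list(alleles = child, gametes = list(a = ga, b = gb))
}

#' Propagate an apomictic clone with stepwise mutation
#'
#' Each of `n` offspring copies the founder genotype, then for each of
#' `n_steps` propagation steps and each locus independently mutates with
#' probability `mutation_rate`: one allele moves one repeat unit up or
#' down with equal probability (the stepwise mutation model). A mutation
#' landing on a repeat count already present simply merges with it —
#' homoplasy is emergent, not prevented.
#'
#' @param founder named per-locus allele list.
#' @param n number of offspring.
#' @param mutation_rate per-locus per-step mutation probability in
#'   `[0, 1]`.
#' @param n_steps propagation steps per offspring.
#' @param seed optional RNG seed.
#' @return List: `alleles` (list of `n` genotypes), `mutation_counts`
#'   (integer vector).
#' @export
propagate_apomictic_clone <- function(founder, n, mutation_rate,
                                      n_steps = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  out <- vector("list", n)
  counts <- integer(n)
  for (i in seq_len(n)) {
    g <- founder
    for (s in seq_len(n_steps)) {
      for (loc in names(g)) {
        a <- g[[loc]]
        if (!length(a)) next
        if (stats::runif(1) < mutation_rate) {
          k <- if (length(a) == 1L) 1L else sample(length(a), 1L)
          step <- if (a[k] <= 1L) 1L else sample(c(-1L, 1L), 1L)
          a[k] <- a[k] + step
          g[[loc]] <- sort(unique(a))
          counts[i] <- counts[i] + 1L
        }
      }
    }
    out[[i]] <- g
  }
  list(alleles = out, mutation_counts = counts)
}

# pick a crossing individual from a sexual population that is informative
# at the genome-tagged loci: heterozygous there, and disjoint from the
# co-gamete's alleles where `avoid` is supplied; falls back to the first
# individual otherwise
.informative_parent <- function(pop, tagged_loci, avoid = list()) {
  score <- function(g) {
    for (loc in tagged_loci) {
      a <- g[[loc]]
      if (!length(a)) next
      if (length(a) < 2L) return(FALSE)
      if (length(intersect(a, avoid[[loc]]))) return(FALSE)
    }
    TRUE
  }
  ord <- sample(length(pop))
  for (i in ord) if (score(pop[[i]])) return(pop[[i]])
  pop[[ord[1]]]
}

#' Simulate a full mixed-ploidy study data set
#'
#' Runs the taxon entries of a [default_sim_config()]-style configuration
#' in order: sexual populations are drawn individual by individual; hybrid
#' founders combine gametes from earlier entries (the gamete of an
#' apomictic parent is drawn from its founder MLG; the gamete of a sexual
#' parent from an individual chosen to be informative at the
#' genome-diagnostic loci, so the planted genome contribution is
#' countable); clones are then propagated with the configured number of
#' mutant variants per taxon, keeping the majority MLG above 80%
#' dominance. Flow-cytometry peak summaries are drawn around each taxon's
#' planted 2C value.
#'
#' @param config a `sim_config` list.
#' @param seed RNG seed (default `config$seed`).
#' @return List: `gs` (a [genotype_set()]), `fcm` (peak-summary data
#'   frame), `truth` (per-sample `samples` data frame and per-hybrid
#'   `hybrids` list), `config`, `seed`.
#' @export
simulate_study <- function(config = default_sim_config(), seed = NULL) {
  .validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  panel <- config$panel
  tagged <- panel$locus[panel$genome_tag != "none"]
  meta_rows <- list()
  alleles <- list()
  truth_rows <- list()
  hybrids <- list()
  founders <- list()      # founder allele list per entry name
  sex_pops <- list()      # sexual population allele lists per entry name
  lineage_counter <- 0L

  for (tx in config$taxa) {
    amp <- .amplifying_loci(config, tx)
    mask <- function(g) {
      g[setdiff(panel$locus, amp)] <- replicate(
        length(setdiff(panel$locus, amp)), integer(0), simplify = FALSE)
      g[panel$locus]
    }
    ids <- sprintf("%s_%02d", tx$name, seq_len(tx$n))
    if (tx$breeding == "sexual") {
      pop <- simulate_sexual_population(config$freqs[amp], tx$n, tx$ploidy)
      pop <- lapply(pop, mask)
      sex_pops[[tx$name]] <- pop
      for (i in seq_len(tx$n)) {
        lineage_counter <- lineage_counter + 1L
        alleles[[ids[i]]] <- pop[[i]]
        truth_rows[[ids[i]]] <- data.frame(
          sample_id = ids[i], taxon = tx$label, founder = ids[i],
          lineage = lineage_counter, mutation_count = 0L,
          stringsAsFactors = FALSE)
      }
    } else {
      if (identical(tx$origin, "founder")) {
        founder <- stats::setNames(lapply(amp, function(loc) {
          f <- config$freqs[[loc]]
          .draw_alleles(f, tx$ploidy, replace = !loc %in% tagged)
        }), amp)
        founder <- mask(founder)
        gam <- NULL
      } else {
        pa_name <- tx$origin$parents[1]; pb_name <- tx$origin$parents[2]
        get_parent <- function(nm, avoid) {
          if (!is.null(founders[[nm]])) founders[[nm]]
          else .informative_parent(sex_pops[[nm]], tagged, avoid)
        }
        parent_a <- get_parent(pa_name, avoid = list())
        avoid_b <- parent_a[tagged]
        parent_b <- get_parent(pb_name, avoid = avoid_b)
        hy <- make_hybrid_founder(parent_a, parent_b,
                                  tx$origin$gametes[1],
                                  tx$origin$gametes[2])
        founder <- mask(hy$alleles)
        gam <- hy$gametes
      }
      founders[[tx$name]] <- founder
      lineage_counter <- lineage_counter + 1L
      n_var <- tx$n_variants
      n_true <- tx$n - n_var
      clones <- c(replicate(n_true, founder, simplify = FALSE),
                  if (n_var > 0)
                    propagate_apomictic_clone(founder, n_var,
                                              config$mutation_rate,
                                              config$n_steps)$alleles)
      for (i in seq_len(tx$n)) {
        g <- clones[[i]]
        alleles[[ids[i]]] <- g
        nmut <- sum(vapply(panel$locus, function(l)
          !identical(g[[l]], founder[[l]]), logical(1)))
        truth_rows[[ids[i]]] <- data.frame(
          sample_id = ids[i], taxon = tx$label, founder = tx$name,
          lineage = lineage_counter, mutation_count = nmut,
          stringsAsFactors = FALSE)
      }
      if (is.list(tx$origin)) {
        contrib <- c(
          genomeA = length(unlist(
            lapply(panel$locus[panel$genome_tag == "genomeA"],
                   function(l) founder[[l]]))),
          genomeB = length(unlist(
            lapply(panel$locus[panel$genome_tag == "genomeB"],
                   function(l) founder[[l]]))))
        hybrids[[tx$name]] <- list(
          name = tx$name, label = tx$label, parents = tx$origin$parents,
          gametes = tx$origin$gametes,
          planted_genome_counts = contrib,
          planted_ratio = paste0(contrib[["genomeA"]], ":",
                                 contrib[["genomeB"]]))
      }
    }
    meta_rows[[tx$name]] <- data.frame(
      sample_id = ids, taxon = tx$label, site = "sim",
      ploidy = tx$ploidy, stringsAsFactors = FALSE)
  }

  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  gs <- genotype_set(panel, meta, alleles)
  truth <- do.call(rbind, truth_rows[meta$sample_id])
  rownames(truth) <- NULL

  planted_2c <- stats::setNames(
    unlist(lapply(config$taxa, function(tx) rep(tx$planted_2c, tx$n))),
    meta$sample_id)
  fc <- config$fcm
  fcm <- data.frame(
    sample_id = meta$sample_id,
    sample_peak = fc$standard_peak * (planted_2c / fc$standard_2c) *
      (1 + stats::rnorm(nrow(meta), 0, fc$rel_noise_sd)),
    standard_peak = fc$standard_peak,
    standard_2c = fc$standard_2c,
    cv_percent = abs(stats::rnorm(nrow(meta), fc$cv_mean, fc$cv_sd)),
    planted_2c = unname(planted_2c),
    stringsAsFactors = FALSE)

  list(gs = gs, fcm = fcm,
       truth = list(samples = truth, hybrids = hybrids),
       config = config, seed = seed)
}
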