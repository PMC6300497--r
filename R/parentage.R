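## Exhaustive parental-pair allele-mismatch scoring for inferring hybrid
## origins, and genome-specific inheritance ratios. A putative parent pair
## is scored by the number of the target's alleles absent from the union
## of the pair's allele pools; zero mismatches marks a potential hybrid
## match. Pools come either from a taxon's majority MLG (apomicts, whose
## founding genotype is assumed extant) or from all sampled alleles
## (sexual outcrossers, whose founding genotype is presumed extinct).

#' Majority multilocus genotype of a taxon
#'
#' The modal MLG across a taxon's samples, with a dominance check: in an
#' obligate apomict the majority genotype is expected to cover more than
#' 80% of individuals, with rare stepwise-mutation variants in the
#' minority. Falling short of the check raises a warning but still returns
#' the modal MLG; modal ties are broken in favour of the profile carried
#' by the lexicographically smallest sample id (and flagged).
#'
#' @param gs a `genotype_set`.
#' @param taxon taxon name (must have at least one sample).
#' @param dominance_check minimum modal-MLG share expected (default 0.8).
#' @return A `majority_genotype`: `taxon`, `alleles` (named list per
#'   locus), `dominance` (modal share), `n`, `representative` sample id,
#'   `tie` flag.
#' @export
majority_genotype <- function(gs, taxon, dominance_check = 0.8) {
  sub <- gs_subset(gs, taxa = taxon)
  ids <- sample_ids(sub)
  profs <- vapply(sub$alleles, function(g)
    paste(vapply(g, paste, character(1), collapse = ","), collapse = ";"),
    character(1))
  tab <- table(profs)
  top <- max(tab)
  modal <- names(tab)[tab == top]
  tie <- length(modal) > 1L
  if (tie) {
    # profile of the lexicographically smallest sample id among tied MLGs
    cand <- ids[profs %in% modal]
    pick_id <- min(cand)
    modal <- profs[[pick_id]]
    warning("modal MLG tie in taxon ", taxon,
            "; picking the profile of sample ", pick_id)
  }
  rep_id <- min(ids[profs == modal[[1]]])
  dominance <- top / length(ids)
  if (dominance <= dominance_check)
    warning("majority MLG of taxon ", taxon, " covers only ",
            sprintf("%.0f%%", 100 * dominance),
            " of samples (expected > ",
            sprintf("%.0f%%", 100 * dominance_check), ")")
  structure(list(taxon = taxon,
                 alleles = sub$alleles[[rep_id]],
                 dominance = dominance,
                 n = length(ids),
                 representative = rep_id,
                 tie = tie),
            class = "majority_genotype")
}

#' Per-locus allele pool of a candidate parent taxon
#'
#' @param gs a `genotype_set`.
#' @param taxon taxon name.
#' @param source `"all_samples"` pools every allele observed in the taxon
#'   (sexual outcrossers); `"majority_mlg"` uses only the majority MLG
#'   (apomicts); `"majority_plus_minority"` augments the majority MLG with
#'   all minority-variant alleles (the 'next best match' pass — in content
#'   equal to `"all_samples"`, kept as an explicit pipeline stage).
#' @param variable_loci loci so mutation-prone that all observed variants
#'   enter the pool even under `"majority_mlg"`.
#' @return An `allele_pool`: `taxon`, `source`, `alleles` (named list of
#'   sorted integer vectors per locus; empty = locus not scored).
#' @export
allele_pool <- function(gs, taxon,
                        source = c("all_samples", "majority_mlg",
                                   "majority_plus_minority"),
                        variable_loci = character(0)) {
  source <- match.arg(source)
  sub <- gs_subset(gs, taxa = taxon)
  all_obs <- lapply(sub$panel$locus, function(loc)
    sort(unique(unlist(lapply(sub$alleles, `[[`, loc)))))
  names(all_obs) <- sub$panel$locus
  pool <- switch(source,
    all_samples = ,
    majority_plus_minority = all_obs,
    majority_mlg = {
      mg <- suppressWarnings(majority_genotype(gs, taxon))
      p <- mg$alleles
      for (loc in intersect(variable_loci, names(p)))
        p[[loc]] <- all_obs[[loc]]
      p
    })
  structure(list(taxon = taxon, source = source, alleles = pool),
            class = "allele_pool")
}

.target_alleles <- function(target) {
  if (inherits(target, "majority_genotype")) target$alleles
  else if (is.list(target)) target
  else stop("target must be a majority_genotype or a named allele list")
}

#' Allele-mismatch score of one putative parent pair
#'
#' Counts, over the given loci, the target's alleles absent from the union
#' of the two parental pools. Counting is per allele: a locus with two
#' uncovered alleles contributes 2. A score of zero means every target
#' allele is covered — a potential hybrid match. A locus scored in the
#' target but absent from both pools contributes all its target alleles
#' (with a message).
#'
#' @param target a [majority_genotype()] or named per-locus allele list.
#' @param pool_a,pool_b [allele_pool()] objects (order irrelevant).
#' @param loci loci to score; default: all loci scored in the target.
#' @return Integer mismatch count with a per-locus breakdown in
#'   `attr(, "by_locus")`.
#' @export
pair_mismatch_score <- function(target, pool_a, pool_b, loci = NULL) {
  ta <- .target_alleles(target)
  if (is.null(loci))
    loci <- names(ta)[vapply(ta, length, integer(1)) > 0L]
  by_locus <- vapply(loci, function(loc) {
    alle <- ta[[loc]]
    if (is.null(alle) || length(alle) == 0L) return(0L)
    pa <- pool_a$alleles[[loc]]
    pb <- pool_b$alleles[[loc]]
    if ((is.null(pa) || length(pa) == 0L) &&
        (is.null(pb) || length(pb) == 0L)) {
      message("locus ", loc, " absent from both pools (",
              pool_a$taxon, ", ", pool_b$taxon,
              "): all ", length(alle), " target alleles count as missing")
      return(length(alle))
    }
    length(setdiff(alle, union(pa, pb)))
  }, integer(1))
  structure(sum(by_locus), by_locus = by_locus)
}

#' Rank all candidate parent pairs for a target taxon
#'
#' Scores every unordered pair of candidate taxa with
#' [pair_mismatch_score()] against the target's majority MLG and returns
#' them sorted by ascending mismatch count (all best-score ties reported).
#'
#' @param gs a `genotype_set`.
#' @param target_taxon taxon whose origin is sought.
#' @param candidates character vector of candidate parent taxa (`>= 2`
#'   unless `include_self`).
#' @param loci loci to score; default: all loci scored in the target's
#'   majority MLG.
#' @param pool_source single source for all candidates, or a named
#'   character vector per candidate (see [allele_pool()]); typically
#'   `"all_samples"` for sexual taxa and `"majority_mlg"` for apomicts.
#' @param variable_loci passed to [allele_pool()].
#' @param include_self also score each candidate paired with itself
#'   (selfing pair); off by default.
#' @return A `parentage_table` data frame: `target`, `parent_a`,
#'   `parent_b`, `mismatches`, sorted ascending.
#' @export
rank_parent_pairs <- function(gs, target_taxon, candidates, loci = NULL,
                              pool_source = "all_samples",
                              variable_loci = character(0),
                              include_self = FALSE) {
  candidates <- unique(candidates)
  if (length(candidates) < 2L && !include_self)
    stop("need at least two candidate taxa")
  src <- if (length(pool_source) == 1L && is.null(names(pool_source)))
    stats::setNames(rep(pool_source, length(candidates)), candidates)
  else {
    missing <- setdiff(candidates, names(pool_source))
    if (length(missing))
      stop("pool_source missing for: ", paste(missing, collapse = ", "))
    pool_source[candidates]
  }
  pools <- lapply(candidates, function(tx)
    allele_pool(gs, tx, source = src[[tx]], variable_loci = variable_loci))
  names(pools) <- candidates
  target <- suppressWarnings(majority_genotype(gs, target_taxon))
  pairs <- if (length(candidates) >= 2L)
    utils::combn(candidates, 2L, simplify = FALSE) else list()
  if (include_self)
    pairs <- c(pairs, lapply(candidates, function(tx) c(tx, tx)))
  rows <- lapply(pairs, function(pr) {
    sc <- pair_mismatch_score(target, pools[[pr[1]]], pools[[pr[2]]],
                              loci = loci)
    data.frame(target = target_taxon, parent_a = pr[1], parent_b = pr[2],
               mismatches = as.integer(sc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mismatches, out$parent_a, out$parent_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("parentage_table", "data.frame")
  out
}

#' Genome-specific allele contributions of a genotype
#'
#' Counts the observed alleles at each genome-tagged locus of the panel
#' and summarises the contribution of each ancestral genome as a ratio
#' string (e.g. `"2:1"` for a triploid with two alleles at the genomeA
#' locus and one at the genomeB locus). A tagged locus missing from the
#' genotype counts 0 and is flagged — in a genome-specific marker,
#' non-amplification is itself informative (the genome is absent).
#'
#' @param target a [majority_genotype()] or named per-locus allele list.
#' @param panel a [locus_panel()] declaring at least one tagged locus.
#' @return A list: `per_locus` data frame (`locus`, `genome_tag`,
#'   `n_alleles`, `missing`), `counts` (named totals for genomeA/genomeB),
#'   `ratio` (`"A:B"` string).
#' @export
genome_specific_contribution <- function(target, panel) {
  ta <- .target_alleles(target)
  tagged <- panel[panel$genome_tag != "none", , drop = FALSE]
  if (!nrow(tagged)) stop("panel declares no genome-tagged locus")
  per <- do.call(rbind, lapply(seq_len(nrow(tagged)), function(i) {
    loc <- tagged$locus[i]
    alle <- ta[[loc]]
    n <- if (is.null(alle)) 0L else length(alle)
    data.frame(locus = loc, genome_tag = tagged$genome_tag[i],
               n_alleles = n, missing = n == 0L, stringsAsFactors = FALSE)
  }))
  counts <- c(genomeA = sum(per$n_alleles[per$genome_tag == "genomeA"]),
              genomeB = sum(per$n_alleles[per$genome_tag == "genomeB"]))
  list(per_locus = per, counts = counts,
       ratio = paste0(counts[["genomeA"]], ":", counts[["genomeB"]]))
}
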