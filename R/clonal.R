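## MLG assignment, clonal-lineage clustering, the mutation/recombination
## distance threshold detected from the pairwise-distance histogram, and
## genotypic diversity statistics.

# connected components of the graph linking samples with d <= threshold
# (single linkage: clone-mate chains are transitive)
.components <- function(dm, threshold) {
  n <- nrow(dm)
  grp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (grp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    grp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(dm[v, ] <= threshold & grp == 0L)
      grp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  grp
}

.make_partition <- function(dm, threshold) {
  ids <- rownames(dm)
  grp <- .components(dm, threshold)
  # stable renumbering by first appearance, representative = lexicographically
  # smallest sample id in each group (deterministic tie-break)
  grp <- match(grp, unique(grp))
  sizes <- tabulate(grp)
  reps <- vapply(seq_along(sizes), function(g)
    min(ids[grp == g]), character(1))
  structure(list(group_of = stats::setNames(grp, ids),
                 sizes = sizes,
                 representatives = reps,
                 threshold = threshold),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  cat("clone_partition:", length(x$group_of), "samples in",
      length(x$sizes), "groups (threshold", format(x$threshold), ")\n")
  invisible(x)
}

#' Assign multilocus genotypes (MLGs)
#'
#' Groups samples whose pairwise distance is exactly zero — every pair with
#' a non-zero genetic distance is treated as distinct MLGs. Returns a
#' partition with one representative per MLG (the lexicographically
#' smallest sample id), which downstream ordination and tree building use
#' to avoid weighting axes by clone size.
#'
#' @param dm symmetric distance matrix with sample ids as dimnames.
#' @return A `clone_partition`: `group_of` (named group index per sample),
#'   `sizes`, `representatives`, `threshold`.
#' @export
assign_mlgs <- function(dm) {
  dm <- .validate_distance_matrix(dm)
  .make_partition(dm, 0)
}

#' Assign clonal lineages below a distance threshold
#'
#' Single-linkage connected components under `d <= threshold`. Genotypes
#' within a lineage differ at most by somatic mutation (small stepwise
#' distances); distinct lineages imply separate sexual origins. A zero
#' threshold reduces to [assign_mlgs()].
#'
#' @param dm symmetric distance matrix with sample ids as dimnames.
#' @param threshold non-negative distance threshold, typically the valley
#'   detected by [distance_histogram()].
#' @return A `clone_partition`.
#' @export
assign_clonal_lineages <- function(dm, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop("threshold must be a single non-negative number")
  dm <- .validate_distance_matrix(dm)
  .make_partition(dm, threshold)
}

#' Pairwise-distance histogram and mutation/recombination threshold
#'
#' Tallies all ordered pairwise comparisons including self-comparisons
#' (`n^2` cells for an `n`-sample matrix, matching the bookkeeping used
#' when such histograms are published) and locates the 'valley' between
#' the first peak near zero (identical or nearly identical genotypes:
#' clone-mates differing by somatic mutation or scoring error) and the
#' next peak (distinct but related genotypes from separate sexual events).
#' The detected threshold is the centre of the minimum-count bin strictly
#' between the modal bin nearest zero and the next local maximum; on a
#' plateau of equally minimal bins the middle bin of the first such run is
#' used. A unimodal distribution yields `NA` with a warning, in which case
#' a manual threshold must be supplied downstream.
#'
#' @param x symmetric distance matrix (all `n^2` cells are tallied) or a
#'   plain numeric vector of distances.
#' @param bin_width histogram bin width (default 0.01).
#' @param smooth_window odd integer; width of the moving-average window
#'   applied to bin counts before peak/valley search (1 = no smoothing).
#' @return A `distance_histogram`: `bin_edges`, `counts` (raw),
#'   `smoothed`, `n_pairs` (`sum(counts)`), `detected_threshold`.
#' @export
distance_histogram <- function(x, bin_width = 0.01, smooth_window = 3L) {
  if (is.matrix(x)) {
    x <- .validate_distance_matrix(x)
    vals <- as.vector(x)
  } else {
    vals <- as.numeric(x)
  }
  if (!length(vals)) stop("no distances to tally")
  if (bin_width <= 0) stop("bin_width must be positive")
  top <- max(1, max(vals))
  edges <- seq(0, top + bin_width, by = bin_width)
  counts <- as.integer(table(cut(vals, breaks = edges, right = FALSE,
                                 include.lowest = TRUE)))
  sm <- .moving_average(counts, smooth_window)
  thr <- .valley_threshold(sm, edges)
  if (is.na(thr))
    warning("distance distribution looks unimodal; no threshold detected ",
            "- supply one manually")
  structure(list(bin_edges = edges, counts = counts, smoothed = sm,
                 n_pairs = sum(counts), bin_width = bin_width,
                 detected_threshold = thr),
            class = "distance_histogram")
}

.moving_average <- function(counts, window) {
  window <- as.integer(window)
  if (window <= 1L) return(as.numeric(counts))
  if (window %% 2L == 0L) stop("smooth_window must be odd")
  h <- (window - 1L) %/% 2L
  n <- length(counts)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(counts[lo:hi])
  }, numeric(1))
}

# first peak = modal bin nearest zero; second peak = highest bin after a
# strict dip; valley = minimal bin(s) strictly between them
.valley_threshold <- function(cs, edges) {
  n <- length(cs)
  p1 <- which.max(cs)              # ties resolve to the bin nearest zero
  if (p1 >= n - 1L) return(NA_real_)
  p2 <- NA_integer_
  best <- -Inf
  for (j in (p1 + 2L):n) {
    dip <- min(cs[(p1 + 1L):(j - 1L)])
    if (cs[j] > dip && cs[j] > best) {
      best <- cs[j]
      p2 <- j
    }
  }
  if (is.na(p2)) return(NA_real_)
  between <- (p1 + 1L):(p2 - 1L)
  m <- min(cs[between])
  run <- between[cs[between] == m]
  # first contiguous run of minimal bins, take its middle bin
  brk <- which(diff(run) > 1L)
  if (length(brk)) run <- run[seq_len(brk[1])]
  mid <- run[ceiling(length(run) / 2)]
  (edges[mid] + edges[mid + 1L]) / 2
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat("distance_histogram:", x$n_pairs, "pairs tallied in",
      length(x$counts), "bins; detected threshold:",
      ifelse(is.na(x$detected_threshold), "none",
             format(x$detected_threshold)), "\n")
  invisible(x)
}

#' Simpson's complement (1 - lambda) of genotypic diversity
#'
#' The probability that two individuals drawn at random carry distinct
#' MLGs: 0 for a monoclonal stand, 1 when every individual is unique. The
#' default unbiased (without-replacement) estimator is
#' `lambda = sum n_i (n_i - 1) / (N (N - 1))`; the biased plug-in
#' `sum (n_i / N)^2` is available for cross-checks.
#'
#' @param sizes integer vector of group sizes (e.g. `clone_partition$sizes`
#'   restricted to one taxon).
#' @param unbiased use the without-replacement estimator (default `TRUE`).
#' @return `1 - lambda` in `[0, 1]`.
#' @examples
#' simpson_complement(19)        # 0: a single clone
#' simpson_complement(rep(1, 13))  # 1: all distinct
#' simpson_complement(c(31, 1))  # 0.0625
#' @export
simpson_complement <- function(sizes, unbiased = TRUE) {
  sizes <- as.numeric(sizes)
  sizes <- sizes[sizes > 0]
  N <- sum(sizes)
  if (N < 2) stop("need at least two individuals")
  lambda <- if (unbiased)
    sum(sizes * (sizes - 1)) / (N * (N - 1))
  else
    sum((sizes / N)^2)
  1 - lambda
}

#' Total allelic richness
#'
#' Count of distinct alleles summed over the locus panel (or a subset),
#' optionally restricted to one taxon.
#'
#' @param gs a `genotype_set`.
#' @param taxon optional taxon name.
#' @param loci optional locus subset.
#' @return Integer allele count.
#' @export
allele_richness <- function(gs, taxon = NULL, loci = NULL) {
  if (!is.null(taxon)) gs <- gs_subset(gs, taxa = taxon)
  use_loci <- if (is.null(loci)) gs$panel$locus else loci
  sum(vapply(use_loci, function(loc) {
    length(unique(unlist(lapply(gs$alleles, `[[`, loc))))
  }, integer(1)))
}

#' Rarefied allelic richness
#'
#' Mean distinct-allele count over repeated random subsamples (without
#' replacement) of `n` individuals, to compare richness fairly across taxa
#' of unequal sample size.
#'
#' @param gs a `genotype_set`.
#' @param taxon taxon to subsample.
#' @param n subsample size (`<=` the taxon's sample count).
#' @param reps number of replicates (default 1000).
#' @param seed mandatory RNG seed for reproducibility.
#' @param loci optional locus subset.
#' @return Mean allele count over replicates.
#' @export
rarefied_richness <- function(gs, taxon, n, reps = 1000L, seed, loci = NULL) {
  if (missing(seed)) stop("seed is required for rarefaction")
  sub <- gs_subset(gs, taxa = taxon)
  ids <- sample_ids(sub)
  if (n > length(ids))
    stop("subsample size ", n, " exceeds taxon sample count ", length(ids))
  if (reps < 1L) stop("reps must be >= 1")
  set.seed(seed)
  mean(vapply(seq_len(reps), function(r) {
    pick <- sample(ids, n)
    allele_richness(gs_subset(sub, samples = pick), loci = loci)
  }, numeric(1)))
}

#' Per-taxon genotypic diversity table
#'
#' One row per taxon: sample count `N`, allelic richness `A`, number of
#' MLGs `Ng`, Simpson's complement `one_minus_lambda`, and number of clonal
#' lineages `Nc` (from the thresholded partition). Taxa with a single
#' sample get `NA` diversity (the estimator needs `N >= 2`).
#'
#' @param gs a `genotype_set`.
#' @param mlg_partition [assign_mlgs()] result on the same samples.
#' @param lineage_partition optional [assign_clonal_lineages()] result;
#'   `Nc` is `NA` where absent.
#' @param loci optional locus subset for allelic richness.
#' @param unbiased passed to [simpson_complement()].
#' @return Data frame, one row per taxon in order of first appearance.
#' @export
diversity_table <- function(gs, mlg_partition, lineage_partition = NULL,
                            loci = NULL, unbiased = TRUE) {
  ids <- sample_ids(gs)
  if (!all(ids %in% names(mlg_partition$group_of)))
    stop("mlg_partition does not cover all samples in gs")
  taxa <- unique(gs$meta$taxon)
  rows <- lapply(taxa, function(tx) {
    tids <- ids[gs$meta$taxon == tx]
    mlg <- mlg_partition$group_of[tids]
    sizes <- as.integer(table(mlg))
    oml <- if (length(tids) >= 2) simpson_complement(sizes, unbiased)
           else NA_real_
    nc <- if (!is.null(lineage_partition))
      length(unique(lineage_partition$group_of[tids])) else NA_integer_
    data.frame(taxon = tx, N = length(tids),
               A = allele_richness(gs, taxon = tx, loci = loci),
               Ng = length(sizes), one_minus_lambda = oml, Nc = nc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
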