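test_that("MLG assignment groups exactly the zero-distance pairs", {
  dm <- dm_from_upper(c("a", "b", "c"), c(0, 0.3, 0.4))
  p <- assign_mlgs(dm)
  expect_identical(length(p$sizes), 2L)
  expect_identical(p$group_of[["a"]], p$group_of[["b"]])
  expect_false(p$group_of[["a"]] == p$group_of[["c"]])
  expect_identical(sort(p$representatives), c("a", "c"))
})

test_that("sexual outcrossers resolve to one MLG per individual", {
  set.seed(21)
  sim <- simulate_study(default_sim_config(21))
  gs <- gs_subset(sim$gs, taxa = "sexA")
  dm <- bruvo_distance_matrix(gs, loci = sim$config$core_loci)
  p <- assign_mlgs(dm)
  expect_identical(length(p$sizes), nrow(gs$meta))
})

test_that("lineage clustering is single linkage under the threshold", {
  dm <- dm_from_upper(c("A", "B", "C"), c(0.02, 0.5, 0.5))
  p <- assign_clonal_lineages(dm, 0.09)
  expect_identical(length(p$sizes), 2L)
  expect_identical(p$group_of[["A"]], p$group_of[["B"]])
  # threshold zero on distinct genotypes: all singletons
  dm2 <- dm_from_upper(c("A", "B", "C"), c(0.1, 0.2, 0.3))
  expect_identical(length(assign_clonal_lineages(dm2, 0)$sizes), 3L)
  expect_error(assign_clonal_lineages(dm2, -0.1), "non-negative")
})

test_that("partitions coarsen monotonically as the threshold rises", {
  set.seed(22)
  n <- 25
  m <- matrix(runif(n * n, 0, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  expect_identical(assign_clonal_lineages(m, 0)$group_of,
                   assign_mlgs(m)$group_of)
  prev <- Inf
  for (t in c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
    k <- length(assign_clonal_lineages(m, t)$sizes)
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("Simpson's complement matches closed forms and a pair count", {
  expect_identical(simpson_complement(19), 0)
  expect_identical(simpson_complement(rep(1, 13)), 1)
  expect_equal(simpson_complement(c(31, 1)), 0.0625)
  expect_equal(round(simpson_complement(c(31, 1)), 2), 0.06)
  expect_error(simpson_complement(1), "two individuals")
  # brute force: share of unordered pairs drawn from distinct groups
  set.seed(23)
  for (rep in 1:20) {
    sizes <- sample(1:8, sample(2:6, 1), replace = TRUE)
    labels <- rep(seq_along(sizes), sizes)
    pairs <- utils::combn(labels, 2)
    brute <- mean(pairs[1, ] != pairs[2, ])
    expect_equal(simpson_complement(sizes), brute)
  }
  # biased plug-in estimator
  expect_equal(simpson_complement(c(3, 1), unbiased = FALSE),
               1 - (9 + 1) / 16)
})

test_that("histogram valley sits between the clone peak and the next mode", {
  h <- distance_histogram(c(0, 0, 0.01, 0.01, 0.2, 0.22, 0.25),
                          bin_width = 0.05)
  expect_identical(h$n_pairs, 7L)
  expect_gt(h$detected_threshold, 0.05)
  expect_lt(h$detected_threshold, 0.2)
  # all-zero distances: unimodal, no valley
  expect_warning(h0 <- distance_histogram(rep(0, 10), bin_width = 0.05),
                 "unimodal")
  expect_true(is.na(h0$detected_threshold))
  # matrix input tallies all ordered comparisons including self
  dm <- dm_from_upper(c("a", "b", "c"), c(0, 0.3, 0.4))
  expect_identical(suppressWarnings(distance_histogram(dm))$n_pairs, 9L)
})

test_that("allelic richness and rarefaction behave as sampling theory says", {
  set.seed(24)
  sim <- simulate_study(default_sim_config(24))
  core <- sim$config$core_loci
  A <- allele_richness(sim$gs, taxon = "sexT", loci = core)
  n_t <- sum(sim$gs$meta$taxon == "sexT")
  # full-sample rarefaction returns A exactly, for any seed
  expect_identical(rarefied_richness(sim$gs, "sexT", n = n_t, reps = 3,
                                     seed = 1, loci = core), as.numeric(A))
  expect_identical(rarefied_richness(sim$gs, "sexT", n = n_t, reps = 3,
                                     seed = 99, loci = core), as.numeric(A))
  # rarefied richness is below A and rises with subsample size
  r <- vapply(c(5, 13, 25), function(n)
    rarefied_richness(sim$gs, "sexT", n = n, reps = 50, seed = 7,
                      loci = core), numeric(1))
  expect_true(all(r <= A))
  expect_true(all(diff(r) > 0))
  expect_error(rarefied_richness(sim$gs, "sexT", n = n_t + 1, reps = 2,
                                 seed = 1), "exceeds")
  # duplicating a genotype adds no alleles
  g <- sim$gs$alleles[[1]]
  twin <- make_gs(list(g, g), panel = sim$gs$panel, ploidy = 4L)
  expect_identical(allele_richness(twin),
                   allele_richness(gs_subset(twin, samples = "s01")))
})

test_that("the diversity table reports N, A, Ng, 1-lambda and Nc per taxon", {
  prof1 <- list(L1 = c(10L, 11L), L2 = c(20L, 21L), L3 = c(5L, 9L))
  prof2 <- list(L1 = c(14L, 15L), L2 = c(24L, 25L), L3 = c(6L, 7L))
  profiles <- c(replicate(6, prof1, simplify = FALSE),
                replicate(2, prof2, simplify = FALSE))
  gs <- make_gs(profiles, taxon = c(rep("mono", 6), rep("duo", 2)),
                ploidy = 2L)
  dm <- bruvo_distance_matrix(gs)
  mlg <- assign_mlgs(dm)
  lin <- assign_clonal_lineages(dm, 0.09)
  d <- diversity_table(gs, mlg, lin)
  mono <- d[d$taxon == "mono", ]
  expect_identical(mono$Ng, 1L)
  expect_identical(mono$one_minus_lambda, 0)
  expect_identical(mono$Nc, 1L)
  # a taxon whose two MLGs are far apart carries two lineages
  duo <- d[d$taxon == "duo", ]
  expect_identical(duo$Ng, 1L)
  # synthetic two-origin taxon: merge both entries under one label
  gs2 <- make_gs(c(replicate(3, prof1, simplify = FALSE),
                   replicate(2, prof2, simplify = FALSE)),
                 taxon = "vex_like", ploidy = 2L)
  dm2 <- bruvo_distance_matrix(gs2)
  d2 <- diversity_table(gs2, assign_mlgs(dm2),
                        assign_clonal_lineages(dm2, 0.09))
  expect_identical(d2$Nc, 2L)
  expect_identical(d2$Ng, 2L)
})
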