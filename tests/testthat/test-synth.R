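test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_study(default_sim_config(5))
  b <- simulate_study(default_sim_config(5))
  expect_identical(a$gs$alleles, b$gs$alleles)
  expect_identical(a$fcm, b$fcm)
  expect_identical(a$truth$samples, b$truth$samples)
  c <- simulate_study(default_sim_config(6))
  expect_false(identical(a$gs$alleles, c$gs$alleles))
})

test_that("sexual populations draw ploidy alleles per locus independently", {
  freqs <- list(mono = list(support = 12L, prob = 1),
                poly = list(support = 10:25,
                            prob = rep(1 / 16, 16)))
  pop <- simulate_sexual_population(freqs, 10, ploidy = 2, seed = 8)
  # a single-allele locus is monomorphic across all individuals
  expect_true(all(vapply(pop, function(g) identical(g$mono, 12L),
                         logical(1))))
  expect_true(all(vapply(pop, function(g)
    length(g$poly) <= 2 && all(g$poly %in% 10:25), logical(1))))
  # seeded reruns are bit-identical
  expect_identical(pop, simulate_sexual_population(freqs, 10, 2, seed = 8))
  # 13 individuals over >= 10 polymorphic loci: all MLGs distinct
  cfg <- default_sim_config(1)
  for (seed in 1:5) {
    pop2 <- simulate_sexual_population(cfg$freqs[cfg$core_loci], 13,
                                       ploidy = 2, seed = seed)
    keys <- vapply(pop2, function(g)
      paste(vapply(g, paste, character(1), collapse = ","), collapse = ";"),
      character(1))
    expect_identical(length(unique(keys)), 13L)
  }
})

test_that("hybrid founders inherit only parental alleles", {
  set.seed(9)
  freqs <- lapply(1:5, function(i)
    list(support = 10:29, prob = rep(0.05, 20)))
  names(freqs) <- paste0("L", 1:5)
  pa <- simulate_sexual_population(freqs, 1, ploidy = 2)[[1]]
  pb <- simulate_sexual_population(freqs, 1, ploidy = 4)[[1]]
  hy <- make_hybrid_founder(pa, pb, 1, 2)   # triploid-bridge cross
  for (loc in names(freqs)) {
    expect_lte(length(hy$alleles[[loc]]), 3L)
    expect_true(all(hy$alleles[[loc]] %in% c(pa[[loc]], pb[[loc]])))
  }
  # identical homozygous parents reproduce themselves exactly
  homo <- lapply(freqs, function(f) 15L)
  hy2 <- make_hybrid_founder(homo, homo, 2, 2)
  expect_identical(hy2$alleles, lapply(homo, identity))
  expect_error(make_hybrid_founder(pa, pb, 0, 1), "gamete")
})

test_that("clonal propagation mutates stepwise at the configured rate", {
  founder <- list(L1 = c(10L, 12L), L2 = c(20L, 21L, 25L), L3 = 8L)
  still <- propagate_apomictic_clone(founder, 5, 0, seed = 10)
  expect_true(all(vapply(still$alleles, identical, logical(1), founder)))
  expect_identical(still$mutation_counts, rep(0L, 5))
  moved <- propagate_apomictic_clone(founder, 40, 0.5, n_steps = 2,
                                     seed = 10)
  expect_identical(moved$alleles,
                   propagate_apomictic_clone(founder, 40, 0.5, 2,
                                             seed = 10)$alleles)
  expect_gt(sum(moved$mutation_counts), 0)
  # mutated repeat counts stay positive and within one step per event
  for (g in moved$alleles) {
    for (loc in names(g)) {
      expect_true(all(g[[loc]] > 0))
      expect_lte(length(g[[loc]]), length(founder[[loc]]) + 0L)
    }
  }
  expect_error(propagate_apomictic_clone(founder, 2, 1.5), "mutation_rate")
})

test_that("the default study emulates the planted clonal structure", {
  sim <- simulate_study(default_sim_config(12))
  gs <- sim$gs
  cfg <- sim$config
  # every apomictic taxon entry is dominated (>80%) by its founder MLG
  for (tx in cfg$taxa) {
    if (tx$breeding != "apomictic") next
    ids <- grep(paste0("^", tx$name, "_"), sample_ids(gs), value = TRUE)
    keys <- vapply(gs$alleles[ids], function(g)
      paste(vapply(g, paste, character(1), collapse = ","), collapse = ";"),
      character(1))
    expect_gt(max(table(keys)) / length(ids), 0.8)
  }
  # genome-tagged loci amplify per subgenus: hybrids of both genomes show
  # alleles at both, pure-subgenus taxa at exactly one
  for (tx in cfg$taxa) {
    ids <- grep(paste0("^", tx$name, "_"), sample_ids(gs), value = TRUE)
    nA <- vapply(gs$alleles[ids], function(g) length(g$GSA), integer(1))
    nB <- vapply(gs$alleles[ids], function(g) length(g$GSB), integer(1))
    if (setequal(tx$genomes, c("A", "B"))) {
      expect_true(all(nA > 0 & nB > 0))
    } else if (identical(tx$genomes, "A")) {
      expect_true(all(nA > 0) && all(nB == 0))
    } else {
      expect_true(all(nB > 0) && all(nA == 0))
    }
  }
  # truth labels stay consistent with the emitted genotypes
  tr <- sim$truth$samples
  expect_identical(tr$sample_id, sample_ids(gs))
  expect_identical(tr$taxon, gs$meta$taxon)
  unmut <- tr$sample_id[tr$mutation_count == 0 & tr$founder == "apoS"]
  keys <- vapply(gs$alleles[unmut], function(g)
    paste(vapply(g, paste, character(1), collapse = ","), collapse = ";"),
    character(1))
  expect_identical(length(unique(keys)), 1L)
  # a hybrid's planted parent pair is recorded and conserved
  hy <- sim$truth$hybrids$apoS
  expect_identical(hy$parents, c("sexT", "apoR"))
  expect_identical(hy$planted_ratio, "2:1")
})

test_that("configuration invariants are enforced", {
  cfg <- default_sim_config(1)
  bad <- cfg
  bad$freqs$L01$prob <- bad$freqs$L01$prob * 2
  expect_error(simulate_study(bad), "sum to 1")
  bad2 <- cfg
  bad2$taxa[[5]]$origin$gametes <- c(3L, 2L)  # would exceed the ploidy
  expect_error(simulate_study(bad2), "gamete")
  bad3 <- cfg
  bad3$taxa[[5]]$n_variants <- 20L
  expect_error(simulate_study(bad3), "dominance")
})
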