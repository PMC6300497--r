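test_that("the majority genotype carries the dominance check and tie rule", {
  prof1 <- list(L1 = c(10L, 11L), L2 = c(20L, 21L))
  prof2 <- list(L1 = c(10L, 12L), L2 = c(20L, 21L))
  gs <- make_gs(c(replicate(9, prof1, simplify = FALSE), list(prof2)),
                taxon = "apo", ploidy = 2L, panel = toy_panel(2))
  mg <- majority_genotype(gs, "apo")
  expect_equal(mg$dominance, 0.9)
  expect_identical(mg$alleles$L1, c(10L, 11L))
  expect_false(mg$tie)
  # 50/50 split: warning plus deterministic pick (lowest sample id wins)
  gs2 <- make_gs(c(replicate(2, prof1, simplify = FALSE),
                   replicate(2, prof2, simplify = FALSE)),
                 taxon = "apo", ploidy = 2L, panel = toy_panel(2))
  expect_warning(expect_warning(mg2 <- majority_genotype(gs2, "apo"),
                                "tie"), "covers only")
  expect_identical(mg2$representative, "s01")
  expect_identical(mg2$alleles$L1, c(10L, 11L))
  expect_error(suppressWarnings(majority_genotype(gs, "nope")))
})

test_that("allele pools honour their source and the variable-locus rule", {
  prof1 <- list(L1 = c(10L, 11L), L2 = c(20L, 21L))
  prof2 <- list(L1 = c(10L, 15L), L2 = c(20L, 21L))
  gs <- make_gs(c(replicate(9, prof1, simplify = FALSE), list(prof2)),
                taxon = "apo", ploidy = 2L, panel = toy_panel(2))
  expect_identical(allele_pool(gs, "apo", "majority_mlg")$alleles$L1,
                   c(10L, 11L))
  expect_identical(allele_pool(gs, "apo", "all_samples")$alleles$L1,
                   c(10L, 11L, 15L))
  # a hypervariable locus contributes every observed variant to the pool
  expect_identical(
    allele_pool(gs, "apo", "majority_mlg", variable_loci = "L1")$alleles$L1,
    c(10L, 11L, 15L))
})

test_that("mismatch scoring counts uncovered target alleles per allele", {
  mk_pool <- function(taxon, alle) structure(
    list(taxon = taxon, source = "all_samples", alleles = alle),
    class = "allele_pool")
  pa <- mk_pool("A", list(L1 = 75L))
  pb <- mk_pool("B", list(L1 = 77L))
  target <- list(L1 = c(75L, 77L))
  expect_identical(as.integer(pair_mismatch_score(target, pa, pb)), 0L)
  target2 <- list(L1 = c(75L, 77L, 80L))
  expect_identical(as.integer(pair_mismatch_score(target2, pa, pb)), 1L)
  # order of the pair never matters
  expect_identical(as.integer(pair_mismatch_score(target2, pb, pa)), 1L)
  # a locus absent from both pools counts all its target alleles
  target3 <- list(L1 = c(75L, 77L), L2 = c(30L, 31L))
  expect_message(s3 <- pair_mismatch_score(target3, pa, pb), "L2")
  expect_identical(as.integer(s3), 2L)
})

test_that("pool enlargement never raises the score; zero iff covered", {
  set.seed(41)
  mk_pool <- function(alle) structure(
    list(taxon = "p", source = "all_samples", alleles = alle),
    class = "allele_pool")
  for (rep in 1:50) {
    target <- list(L1 = random_multiset(), L2 = random_multiset())
    pa <- mk_pool(list(L1 = random_multiset(), L2 = random_multiset()))
    pb <- mk_pool(list(L1 = random_multiset(), L2 = random_multiset()))
    s <- as.integer(pair_mismatch_score(target, pa, pb))
    # brute-force coverage check
    covered <- all(vapply(names(target), function(l)
      all(target[[l]] %in% c(pa$alleles[[l]], pb$alleles[[l]])),
      logical(1)))
    expect_identical(s == 0L, covered)
    # enlarge one pool
    pa2 <- mk_pool(lapply(pa$alleles, function(a) sort(unique(c(a, 5:9)))))
    expect_lte(as.integer(pair_mismatch_score(target, pa2, pb)), s)
  }
})

test_that("the true parent pair of a planted hybrid ranks first at zero", {
  set.seed(42)
  freqs <- lapply(1:4, function(i)
    list(support = (10 * i):(10 * i + 14), prob = rep(1 / 15, 15)))
  names(freqs) <- paste0("L", 1:4)
  panel <- locus_panel(names(freqs))
  popA <- simulate_sexual_population(freqs, 6, ploidy = 2)
  popB <- simulate_sexual_population(freqs, 6, ploidy = 4)
  child <- make_hybrid_founder(popA[[1]], popB[[1]], 1, 2)
  profiles <- c(popA, popB, replicate(3, child$alleles, simplify = FALSE))
  gs <- make_gs(profiles,
                taxon = c(rep("sexP", 6), rep("apoQ", 6), rep("hyb", 3)),
                ploidy = c(rep(2, 6), rep(4, 6), rep(3, 3)), panel = panel)
  tab <- suppressWarnings(
    rank_parent_pairs(gs, "hyb", c("sexP", "apoQ"),
                      pool_source = "all_samples"))
  expect_s3_class(tab, "parentage_table")
  expect_identical(tab$mismatches[1], 0L)
  expect_setequal(unlist(tab[1, c("parent_a", "parent_b")]),
                  c("sexP", "apoQ"))
  # selfing pairs only when asked for
  tab2 <- suppressWarnings(
    rank_parent_pairs(gs, "hyb", c("sexP", "apoQ"), include_self = TRUE))
  expect_identical(nrow(tab2), 3L)
  expect_true(any(tab2$parent_a == tab2$parent_b))
})

test_that("genome-specific loci count each ancestral genome's alleles", {
  panel <- locus_panel(c("GSA", "GSB", "L1"),
                       genome_tag = c("genomeA", "genomeB", "none"))
  # triploid hybrid: two alleles from genome A, one from genome B
  tri <- list(GSA = c(30L, 33L), GSB = 52L, L1 = c(10L, 11L, 12L))
  out <- genome_specific_contribution(tri, panel)
  expect_identical(out$ratio, "2:1")
  # tetraploid with an even contribution
  tet <- list(GSA = c(30L, 33L), GSB = c(52L, 55L), L1 = c(10L, 11L))
  expect_identical(genome_specific_contribution(tet, panel)$ratio, "2:2")
  # pure-subgenus tetraploid: four alleles at one tag, none at the other
  pure <- list(GSA = c(30L, 31L, 33L, 36L), GSB = integer(0),
               L1 = c(10L, 11L))
  out3 <- genome_specific_contribution(pure, panel)
  expect_identical(out3$ratio, "4:0")
  expect_true(out3$per_locus$missing[out3$per_locus$locus == "GSB"])
  expect_error(genome_specific_contribution(tri, locus_panel("L1")),
               "genome-tagged")
})
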