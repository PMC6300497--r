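# small in-code fixtures shared across test files

toy_panel <- function(n = 3L, repeat_len = 2L) {
  locus_panel(paste0("L", seq_len(n)), repeat_len = repeat_len)
}

# build a genotype_set from a list of per-locus allele lists; one taxon
# unless `taxon` is a vector
make_gs <- function(profiles, taxon = "tx", ploidy = 2L, panel = NULL,
                    ids = NULL) {
  n <- length(profiles)
  if (is.null(panel))
    panel <- toy_panel(length(profiles[[1]]))
  profiles <- lapply(profiles, function(g) {
    if (is.null(names(g))) names(g) <- panel$locus[seq_along(g)]
    g
  })
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  names(profiles) <- ids
  meta <- data.frame(sample_id = ids,
                     taxon = rep_len(taxon, n),
                     site = "here",
                     ploidy = rep_len(ploidy, n),
                     stringsAsFactors = FALSE)
  genotype_set(panel, meta, profiles)
}

# n identical copies of one profile
clone_gs <- function(profile, n, taxon = "tx", ploidy = 2L, ...) {
  make_gs(replicate(n, profile, simplify = FALSE), taxon = taxon,
          ploidy = ploidy, ...)
}

# a small symmetric distance matrix from the upper triangle
dm_from_upper <- function(ids, upper) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- upper
  m + t(m)
}

# random single-locus allele multiset (distinct repeat counts)
random_multiset <- function(max_size = 4L, support = 5:30) {
  k <- sample.int(max_size, 1L)
  sort(sample(support, k))
}

tmpfile <- function(ext = ".csv") tempfile(fileext = ext)
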