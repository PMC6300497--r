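## Bruvo stepwise-mutation distance for microsatellite genotypes of equal
## or unequal ploidy. All arithmetic is on allele repeat counts. The
## single-allele kernel is d(a, b) = 1 - 2^(-|a - b|); a locus distance is
## the minimum over allele matchings of the mean kernel value; unequal
## allele-set sizes are reconciled by the genome-loss model (virtual
## alleles at distance 1), the genome-addition model (the smaller genotype
## re-donates copies of its own alleles, chosen to minimise the result),
## or their arithmetic mean ("combined").

# permutations of 1..n, rows = permutations; sizes here never exceed 4
.perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- if (n == 1L) matrix(1L, 1, 1) else {
      sub <- Recall(n - 1L)
      do.call(rbind, lapply(seq_len(n), function(k) {
        cbind(k, sub + (sub >= k))
      }))
    }
    cache[[key]] <<- p
    p
  }
})

#' Bruvo distance between two alleles
#'
#' The stepwise-mutation kernel `1 - 2^(-|a - b|)` on repeat counts: 0 for
#' identical alleles, 0.5 for a single-repeat step, asymptotic to 1 as the
#' repeat difference grows.
#'
#' @param a,b positive integer repeat counts (vectorised).
#' @return Numeric distance(s) in `[0, 1)`.
#' @examples
#' bruvo_pair_distance(10, 11)  # 0.5
#' bruvo_pair_distance(10, 13)  # 0.875
#' @export
bruvo_pair_distance <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("repeat counts must be positive")
  1 - 2^(-abs(a - b))
}

# minimum-cost injective assignment of rows into columns of cost matrix D
# (nrow <= ncol). method "enumerate": exhaustive subsets x permutations;
# method "dp": bitmask dynamic programme over column subsets (fast path,
# must agree with the enumeration).
.assignment_min <- function(D, method = c("enumerate", "dp")) {
  method <- match.arg(method)
  m <- nrow(D); n <- ncol(D)
  stopifnot(m <= n)
  if (m == 0L) return(0)
  if (method == "enumerate") {
    P <- .perms(m)
    best <- Inf
    colsets <- if (m == n) list(seq_len(n)) else
      utils::combn(n, m, simplify = FALSE)
    ri <- seq_len(m)
    for (cs in colsets) {
      Dsub <- D[, cs, drop = FALSE]
      for (r in seq_len(nrow(P))) {
        s <- sum(Dsub[cbind(ri, P[r, ])])
        if (s < best) best <- s
      }
    }
    best
  } else {
    nmask <- bitwShiftL(1L, n)
    dp <- rep(Inf, nmask)
    dp[1L] <- 0
    for (i in seq_len(m)) {
      ndp <- rep(Inf, nmask)
      for (mask in 0:(nmask - 1L)) {
        if (!is.finite(dp[mask + 1L])) next
        for (j in seq_len(n)) {
          bit <- bitwShiftL(1L, j - 1L)
          if (bitwAnd(mask, bit) == 0L) {
            v <- dp[mask + 1L] + D[i, j]
            if (v < ndp[bitwOr(mask, bit) + 1L])
              ndp[bitwOr(mask, bit) + 1L] <- v
          }
        }
      }
      dp <- ndp
    }
    min(dp)
  }
}

# all multisets (as sorted vectors) of size k drawn from values
.multisets <- function(values, k) {
  values <- sort(unique(values))
  if (k == 0L) return(list(integer(0)))
  if (k == 1L) return(lapply(values, as.integer))
  grid <- as.matrix(do.call(expand.grid, rep(list(values), k)))
  sets <- unique(t(apply(grid, 1, sort)))
  lapply(seq_len(nrow(sets)), function(i) as.integer(sets[i, ]))
}

#' Bruvo distance between two single-locus allele multisets
#'
#' Equal-size genotypes are compared by the minimum over all perfect allele
#' matchings of the mean [bruvo_pair_distance()]. For unequal sizes the
#' `"loss"` model pads the smaller genotype with virtual alleles at
#' distance 1 from every real allele, the `"addition"` model pads it with
#' copies of its own alleles chosen to minimise the distance, and
#' `"combined"` (the default) averages the two — appropriate when the
#' direction of the ploidy change is unknown.
#'
#' @param a,b integer vectors of distinct allele repeat counts (non-empty).
#' @param model inter-ploidy model: `"combined"`, `"loss"` or `"addition"`.
#' @param method matching solver: `"enumerate"` (exhaustive, the reference)
#'   or `"dp"` (bitmask assignment solver; identical results).
#' @return Distance in `[0, 1]`.
#' @examples
#' bruvo_locus_distance(c(10, 12), c(10, 13))          # 0.25
#' bruvo_locus_distance(c(10, 11), c(10, 11, 13), "loss")      # 1/3
#' bruvo_locus_distance(c(10, 11), c(10, 11, 13), "addition")  # 0.25
#' @export
bruvo_locus_distance <- function(a, b,
                                 model = c("combined", "loss", "addition"),
                                 method = c("enumerate", "dp")) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (length(a) == 0L || length(b) == 0L)
    stop("empty allele multiset: locus is missing, exclude it upstream")
  if (any(a <= 0) || any(b <= 0)) stop("repeat counts must be positive")
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  m <- length(a); n <- length(b)
  D <- outer(a, b, bruvo_pair_distance)
  if (m == n)
    return(.assignment_min(D, method) / n)
  if (model %in% c("loss", "combined"))
    d_loss <- (.assignment_min(D, method) + (n - m)) / n
  if (model %in% c("addition", "combined")) {
    d_add <- Inf
    for (pad in .multisets(a, n - m)) {
      aa <- c(a, pad)
      Dp <- outer(aa, b, bruvo_pair_distance)
      v <- .assignment_min(Dp, method) / n
      if (v < d_add) d_add <- v
    }
  }
  switch(model,
         loss = d_loss,
         addition = d_add,
         combined = (d_loss + d_add) / 2)
}

#' Bruvo distance between two multilocus genotypes
#'
#' Unweighted mean of [bruvo_locus_distance()] over the loci scored
#' (non-missing) in both genotypes; loci missing in either are excluded.
#'
#' @param ga,gb named lists over loci of integer allele-repeat vectors
#'   (as stored in a `genotype_set`).
#' @param model,method passed to [bruvo_locus_distance()].
#' @param loci optional character vector restricting the comparison.
#' @return Distance in `[0, 1]`.
#' @export
bruvo_genotype_distance <- function(ga, gb,
                                    model = c("combined", "loss", "addition"),
                                    method = c("enumerate", "dp"),
                                    loci = NULL) {
  model <- match.arg(model)
  method <- match.arg(method)
  shared <- intersect(names(ga), names(gb))
  if (!is.null(loci)) shared <- intersect(shared, loci)
  shared <- shared[vapply(shared, function(l)
    length(ga[[l]]) > 0L && length(gb[[l]]) > 0L, logical(1))]
  if (!length(shared))
    stop("no locus scored in both genotypes")
  mean(vapply(shared, function(l)
    bruvo_locus_distance(ga[[l]], gb[[l]], model, method), numeric(1)))
}

#' Pairwise Bruvo distance matrix for a genotype set
#'
#' Computes the symmetric matrix of [bruvo_genotype_distance()] values over
#' all sample pairs. Per locus, distances are evaluated once per unique
#' pair of single-locus allele profiles and then expanded — in clonal data
#' sets most individuals repeat a handful of profiles, which makes the
#' matrix cheap even for hundreds of samples.
#'
#' @param gs a `genotype_set`.
#' @param model,method passed to [bruvo_locus_distance()].
#' @param loci optional locus subset (e.g. the core panel amplifying in
#'   every taxon).
#' @return Symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
bruvo_distance_matrix <- function(gs,
                                  model = c("combined", "loss", "addition"),
                                  method = c("enumerate", "dp"),
                                  loci = NULL) {
  model <- match.arg(model)
  method <- match.arg(method)
  ids <- sample_ids(gs)
  n <- length(ids)
  if (n < 2L) stop("need at least two genotypes")
  use_loci <- if (is.null(loci)) gs$panel$locus else {
    if (!all(loci %in% gs$panel$locus))
      stop("unknown loci: ", paste(setdiff(loci, gs$panel$locus),
                                   collapse = ", "))
    loci
  }
  dsum <- matrix(0, n, n)
  dcnt <- matrix(0L, n, n)
  for (loc in use_loci) {
    profs <- vapply(gs$alleles, function(g)
      paste(g[[loc]], collapse = ","), character(1))
    scored <- profs != ""
    if (!any(scored)) next
    uniq <- unique(profs[scored])
    code <- match(profs, uniq)            # NA where missing
    U <- length(uniq)
    alle <- lapply(strsplit(uniq, ",", fixed = TRUE), as.integer)
    du <- matrix(0, U, U)
    if (U > 1L) {
      for (i in 1:(U - 1L)) for (j in (i + 1L):U) {
        du[i, j] <- du[j, i] <-
          bruvo_locus_distance(alle[[i]], alle[[j]], model, method)
      }
    }
    ok <- !is.na(code)
    dl <- matrix(NA_real_, n, n)
    dl[ok, ok] <- du[code[ok], code[ok]]
    has <- !is.na(dl)
    dsum[has] <- dsum[has] + dl[has]
    dcnt <- dcnt + has
  }
  if (any(dcnt[upper.tri(dcnt)] == 0L)) {
    bad <- which(dcnt == 0L & upper.tri(dcnt), arr.ind = TRUE)[1, ]
    stop("no shared scored locus between samples ",
         ids[bad[1]], " and ", ids[bad[2]])
  }
  dm <- dsum / dcnt
  diag(dm) <- 0
  dimnames(dm) <- list(ids, ids)
  dm
}
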