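#' Define a microsatellite locus panel
#'
#' A locus panel records, for every marker, the length of its repeat motif
#' (used to convert fragment sizes in base pairs to repeat counts, the unit
#' on which the stepwise-mutation distance is defined), an optional constant
#' flanking-sequence offset, and a genome-specificity tag. Genome-specific
#' loci amplify only from one ancestral genome and are used to count each
#' parent's genomic contribution in putative hybrids (see
#' [genome_specific_contribution()]).
#'
#' @param locus character vector of unique locus names.
#' @param repeat_len integer vector (recycled), repeat motif length in bp,
#'   `>= 1`.
#' @param genome_tag character vector (recycled), one of `"none"`,
#'   `"genomeA"`, `"genomeB"`.
#' @param offset numeric vector (recycled), constant flanking length in bp
#'   subtracted before dividing by `repeat_len`.
#' @return A `locus_panel` data frame with columns `locus`, `repeat_len`,
#'   `genome_tag`, `offset`.
#' @examples
#' locus_panel(c("MSS5", "CH01F09"), repeat_len = 2,
#'             genome_tag = c("none", "genomeA"))
#' @export
locus_panel <- function(locus, repeat_len = 2L, genome_tag = "none",
                        offset = 0) {
  locus <- as.character(locus)
  if (anyDuplicated(locus))
    stop("locus names must be unique within a panel")
  n <- length(locus)
  repeat_len <- rep_len(as.integer(repeat_len), n)
  genome_tag <- rep_len(as.character(genome_tag), n)
  offset <- rep_len(as.numeric(offset), n)
  if (any(is.na(repeat_len)) || any(repeat_len < 1L))
    stop("repeat_len must be an integer >= 1")
  bad <- !genome_tag %in% c("none", "genomeA", "genomeB")
  if (any(bad))
    stop("genome_tag must be one of 'none', 'genomeA', 'genomeB'")
  out <- data.frame(locus = locus, repeat_len = repeat_len,
                    genome_tag = genome_tag, offset = offset,
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_panel", "data.frame")
  out
}

#' Assemble a genotype set
#'
#' The central container: a locus panel plus, per sample, taxon/site/ploidy
#' metadata and a per-locus multiset of *distinct* observed alleles in
#' repeat units. Allele copy number is deliberately unresolved (partial
#' heterozygotes in polyploids cannot be dosed from fragment data alone),
#' so a tetraploid scored `{110, 114}` simply records two distinct alleles.
#' An empty allele vector encodes a missing (non-amplifying) locus.
#'
#' @param panel a [locus_panel()].
#' @param meta data frame with columns `sample_id`, `taxon`, `site`,
#'   `ploidy` (integer 2/3/4, `NA` = unknown).
#' @param alleles named list (one element per sample, names =
#'   `meta$sample_id`); each element a named list over loci of integer
#'   vectors of allele repeat counts (possibly empty = missing).
#' @return A `genotype_set` object.
#' @export
genotype_set <- function(panel, meta, alleles) {
  stopifnot(inherits(panel, "locus_panel"))
  req <- c("sample_id", "taxon", "site", "ploidy")
  if (!all(req %in% names(meta)))
    stop("meta must have columns sample_id, taxon, site, ploidy")
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("sample ids must be unique")
  if (!setequal(names(alleles), meta$sample_id))
    stop("alleles list must be named by the sample ids in meta")
  alleles <- alleles[meta$sample_id]
  for (sid in meta$sample_id) {
    g <- alleles[[sid]]
    unknown <- setdiff(names(g), panel$locus)
    if (length(unknown))
      stop("sample ", sid, " references loci not in the panel: ",
           paste(unknown, collapse = ", "))
    pl <- meta$ploidy[meta$sample_id == sid]
    for (loc in names(g)) {
      a <- g[[loc]]
      if (length(a) == 0L) next
      if (any(a <= 0))
        stop("sample ", sid, " locus ", loc, ": allele values must be > 0")
      if (anyDuplicated(a))
        g[[loc]] <- sort(unique(as.integer(a)))
      else
        g[[loc]] <- sort(as.integer(a))
      if (!is.na(pl) && length(g[[loc]]) > pl)
        stop("sample ", sid, " locus ", loc, ": ",
             length(g[[loc]]), " distinct alleles exceed declared ploidy ",
             pl)
    }
    # ensure every panel locus has an entry (possibly empty)
    missing_loci <- setdiff(panel$locus, names(g))
    if (length(missing_loci))
      g[missing_loci] <- replicate(length(missing_loci), integer(0),
                                   simplify = FALSE)
    alleles[[sid]] <- g[panel$locus]
  }
  structure(list(panel = panel, meta = meta, alleles = alleles),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", nrow(x$meta), "samples,",
      nrow(x$panel), "loci,",
      length(unique(x$meta$taxon)), "taxa\n")
  invisible(x)
}

#' Sample ids of a genotype set
#' @param gs a `genotype_set`.
#' @return Character vector of sample ids, in storage order.
#' @export
sample_ids <- function(gs) gs$meta$sample_id

#' Subset a genotype set
#'
#' @param gs a `genotype_set`.
#' @param samples,taxa,loci optional character vectors; `NULL` keeps all.
#' @return A `genotype_set` restricted to the requested samples/loci.
#' @export
gs_subset <- function(gs, samples = NULL, taxa = NULL, loci = NULL) {
  keep <- gs$meta$sample_id
  if (!is.null(taxa)) keep <- keep[gs$meta$taxon %in% taxa]
  if (!is.null(samples)) keep <- intersect(keep, samples)
  if (!length(keep)) stop("subset selects no samples")
  panel <- gs$panel
  if (!is.null(loci)) {
    if (!all(loci %in% panel$locus))
      stop("unknown loci: ", paste(setdiff(loci, panel$locus), collapse = ", "))
    panel <- panel[panel$locus %in% loci, , drop = FALSE]
    class(panel) <- c("locus_panel", "data.frame")
  }
  meta <- gs$meta[gs$meta$sample_id %in% keep, , drop = FALSE]
  rownames(meta) <- NULL
  alleles <- lapply(gs$alleles[meta$sample_id],
                    function(g) g[panel$locus])
  genotype_set(panel, meta, alleles)
}

## ---- allele unit conversion -------------------------------------------

#' Convert fragment sizes (bp) to repeat counts
#'
#' Integer division after removing the constant flanking offset:
#' `(bp - offset) %/% repeat_len`. The conversion is monotone and, given
#' `repeat_len` and `offset`, invertible on exact repeat multiples.
#'
#' @param bp numeric vector of fragment sizes.
#' @param repeat_len repeat motif length in bp.
#' @param offset constant flanking length in bp.
#' @return Integer vector of repeat counts.
#' @export
bp_to_repeats <- function(bp, repeat_len, offset = 0) {
  as.integer((bp - offset) %/% repeat_len)
}

#' @rdname bp_to_repeats
#' @param repeats integer vector of repeat counts.
#' @export
repeats_to_bp <- function(repeats, repeat_len, offset = 0) {
  repeats * repeat_len + offset
}

## ---- genotype table IO ------------------------------------------------

#' Read a delimited genotype table
#'
#' One row per sample with columns `sample_id`, `taxon`, `site`, `ploidy`
#' followed by one column per locus holding 1..ploidy allele calls joined
#' by `/` (e.g. `"150/154"`). Allele calls may be fragment sizes in bp
#' (converted to repeat units via the panel's `repeat_len`/`offset`) or
#' already in repeat units.
#'
#' @param path file path to a delimited text file with a header row.
#' @param panel a [locus_panel()]; every locus column in the file must be
#'   declared in the panel.
#' @param units `"bp"` (convert via panel) or `"repeats"` (use as-is).
#' @param missing sentinel strings encoding a missing locus
#'   (default `"0"` and the empty string).
#' @param sep field separator.
#' @return A [genotype_set()].
#' @export
read_genotype_table <- function(path, panel, units = c("bp", "repeats"),
                                missing = c("0", ""), sep = ",") {
  units <- match.arg(units)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  req <- c("sample_id", "taxon", "site", "ploidy")
  if (!all(req %in% names(raw)))
    stop("genotype table must have columns ", paste(req, collapse = ", "))
  locus_cols <- setdiff(names(raw), req)
  unknown <- setdiff(locus_cols, panel$locus)
  if (length(unknown))
    stop("unknown loci in table: ", paste(unknown, collapse = ", "))
  meta <- data.frame(sample_id = raw$sample_id, taxon = raw$taxon,
                     site = raw$site,
                     ploidy = suppressWarnings(as.integer(raw$ploidy)),
                     stringsAsFactors = FALSE)
  alleles <- vector("list", nrow(raw))
  names(alleles) <- meta$sample_id
  for (i in seq_len(nrow(raw))) {
    g <- list()
    for (loc in locus_cols) {
      cell <- trimws(raw[[loc]][i])
      if (is.na(cell) || cell %in% missing) {
        g[[loc]] <- integer(0)
        next
      }
      vals <- as.numeric(strsplit(cell, "/", fixed = TRUE)[[1]])
      if (anyNA(vals))
        stop("sample ", meta$sample_id[i], " locus ", loc,
             ": unparseable allele call '", cell, "'")
      if (units == "bp") {
        j <- match(loc, panel$locus)
        vals <- bp_to_repeats(vals, panel$repeat_len[j], panel$offset[j])
      }
      g[[loc]] <- sort(unique(as.integer(vals)))
    }
    alleles[[i]] <- g
  }
  genotype_set(panel, meta, alleles)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; allele calls are `/`-joined, missing
#' loci written as the first `missing` sentinel.
#'
#' @param gs a `genotype_set`.
#' @param path output file path.
#' @param units `"repeats"` (default) or `"bp"` (convert via panel).
#' @param missing sentinel written for missing loci.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gs, path, units = c("repeats", "bp"),
                                 missing = "0", sep = ",") {
  units <- match.arg(units)
  panel <- gs$panel
  cols <- lapply(seq_len(nrow(panel)), function(j) {
    loc <- panel$locus[j]
    vapply(gs$alleles, function(g) {
      a <- g[[loc]]
      if (length(a) == 0L) return(missing)
      if (units == "bp")
        a <- repeats_to_bp(a, panel$repeat_len[j], panel$offset[j])
      paste(a, collapse = "/")
    }, character(1))
  })
  names(cols) <- panel$locus
  out <- cbind(gs$meta, as.data.frame(cols, check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- distance matrix IO -----------------------------------------------

# general non-negative symmetric dissimilarity (no unit upper bound):
# ordination and tree building accept any dissimilarity scale
.validate_dissimilarity <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("distance matrix must carry sample ids as dimnames")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column ids differ")
  if (any(m < -tol)) stop("distances must be non-negative")
  if (max(abs(m - t(m))) > tol) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > tol))
    stop("distance matrix diagonal must be zero")
  m[m < 0] <- 0
  diag(m) <- 0
  m[] <- (m + t(m)) / 2
  m
}

.validate_distance_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("distance matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("distance matrix must carry sample ids as dimnames")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column ids differ")
  if (any(m < -tol) || any(m > 1 + tol))
    stop("distance values must lie in [0, 1]")
  if (max(abs(m - t(m))) > tol)
    stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > tol))
    stop("distance matrix diagonal must be zero")
  m[m < 0] <- 0
  m[m > 1] <- 1
  diag(m) <- 0
  m[] <- (m + t(m)) / 2
  m
}

#' Write / read a square distance matrix as CSV
#'
#' The CSV has sample ids in the header and first column. Reading validates
#' symmetry, zero diagonal and the `[0, 1]` range; the round-trip is
#' lossless to the configured number of decimals.
#'
#' @param dm symmetric numeric matrix in `[0, 1]` with zero diagonal and
#'   sample ids as dimnames.
#' @param path file path.
#' @param digits decimals written.
#' @return `write_distance_matrix()` returns `path` invisibly;
#'   `read_distance_matrix()` returns the validated matrix.
#' @export
write_distance_matrix <- function(dm, path, digits = 10) {
  dm <- .validate_distance_matrix(dm)
  out <- data.frame(sample_id = rownames(dm),
                    round(dm, digits), check.names = FALSE)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = ",",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  .validate_distance_matrix(m)
}
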