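## Ordination (principal coordinate analysis) and neighbor-joining trees
## from a genetic distance matrix. Both run on MLG representatives rather
## than all samples, so that large clones do not dominate axes or branch
## placement.

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: Gower double-centering of `-d^2/2` followed by
#' an eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative eigenvalues — expected
#' when the distance is not Euclidean-embeddable, as Bruvo distances need
#' not be — are reported but not corrected.
#'
#' @param dm symmetric distance matrix with ids as dimnames (`n >= 3`).
#' @param k number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return A `pcoa_result`: `coordinates` (ids x axes), `eigenvalues`
#'   (all, descending), `percent_variance` (share of the positive
#'   eigenvalue total, per retained axis).
#' @export
pcoa <- function(dm, k = NULL) {
  dm <- .validate_dissimilarity(dm)
  n <- nrow(dm)
  if (n < 3L) stop("PCoA needs at least 3 points")
  D2 <- dm^2
  rm_ <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(D2))
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-9
  pos <- which(vals > tol)
  if (!length(pos)) stop("no positive eigenvalues; degenerate input")
  keep <- if (is.null(k)) pos else pos[seq_len(min(k, length(pos)))]
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(vals[keep]), nrow = length(keep))
  dimnames(coords) <- list(rownames(dm),
                           paste0("Axis", seq_along(keep)))
  pct <- 100 * vals[keep] / sum(vals[pos])
  structure(list(coordinates = coords, eigenvalues = vals,
                 percent_variance = pct),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "axes; axis 1-2 variance:",
      paste0(sprintf("%.1f%%", utils::head(x$percent_variance, 2)),
             collapse = ", "), "\n")
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q-criterion. Ties in Q are broken
#' deterministically in favour of the lowest index pair. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' edge, preserving path lengths; on additive matrices the input distances
#' are recovered exactly. The result is unrooted (trifurcating root).
#'
#' @param dm symmetric distance matrix with ids as dimnames (`n >= 3`).
#' @return An [ape] `phylo` tree with the input ids as tip labels.
#' @export
neighbor_joining <- function(dm) {
  dm <- .validate_dissimilarity(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labs <- rownames(dm)
  frag <- labs                      # newick fragment per active node
  D <- dm
  fmt <- function(x) sprintf("%.17g", max(x, 0))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest index pair among minima: scan i < j in row-major order
    qmin <- min(Q)
    pick <- NULL
    for (i in 1:(m - 1L)) {
      j <- which(Q[i, (i + 1L):m] == qmin)
      if (length(j)) { pick <- c(i, i + j[1]); break }
    }
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",",
                      frag[j], ":", fmt(lj), ")")
    others <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D2 <- rbind(cbind(D[others, others, drop = FALSE], dnew),
                c(dnew, 0))
    frag <- c(frag[others], newfrag)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(b1), ",", frag[2], ":", fmt(b2),
                ",", frag[3], ":", fmt(b3), ");")
  ape::read.tree(text = nwk)
}

#' Write a tree in newick format
#'
#' @param tree an `ape` `phylo` object.
#' @param path output file path.
#' @param digits decimals kept on branch lengths (default 6).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, digits)
  ape::write.tree(tree, file = path)
  invisible(path)
}
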