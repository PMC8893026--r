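#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d_{ij} = \sum_k |y_{ik} - y_{jk}| / \sum_k (y_{ik} + y_{jk})} on
#' per-sample relative abundances, computed via \code{vegan::vegdist}.
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @return symmetric samples x samples matrix in [0, 1].
#' @export
brayCurtis <- function(table) {
  m <- .counts(table)
  rel <- .rel_abund(m)
  as.matrix(vegan::vegdist(rel, method = "bray"))
}

#' Weighted UniFrac dissimilarity matrix
#'
#' For each branch \eqn{b} of the rooted phylogeny with length \eqn{\ell_b},
#' let \eqn{A_b} and \eqn{B_b} be the fraction of each sample's reads
#' descending from the branch. The raw weighted UniFrac distance is
#' \eqn{\sum_b \ell_b |A_b - B_b|}; the normalized variant (default) divides
#' by \eqn{\sum_b \ell_b (A_b + B_b)} so distances lie in [0, 1] and
#' "similarity = 1 - distance" is well defined.
#'
#' @param table [OtuExperiment-class] (tree taken from the object unless
#'   given) or samples x OTUs matrix.
#' @param tree rooted \code{ape::phylo}; every OTU with a nonzero count must
#'   be one of its tips.
#' @param normalized logical; divide by the branch-weighted total mass.
#' @return symmetric samples x samples matrix.
#' @export
weightedUnifrac <- function(table, tree = NULL, normalized = TRUE) {
  if (is.null(tree) && methods::is(table, "OtuExperiment"))
    tree <- otuTree(table)
  if (is.null(tree)) stop("a rooted tree is required for weighted UniFrac")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0) ||
      any(!is.finite(tree$edge.length)))
    stop("validation error: branch lengths must be finite and >= 0")
  m <- .counts(table)
  used <- colnames(m)[colSums(m) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing))
    stop("OTUs absent from tree tips: ", paste(missing, collapse = ", "))
  P <- .branch_proportions(m, tree)       # edges x samples
  len <- tree$edge.length
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(len * abs(P[, i] - P[, j]))
    d[i, j] <- d[j, i] <- if (normalized) {
      den <- sum(len * (P[, i] + P[, j]))
      if (den == 0) 0 else num / den
    } else num
  }
  d
}

# Fraction of each sample's reads descending from each edge, by postorder
# accumulation of tip masses up the tree. Returns an edges x samples matrix.
.branch_proportions <- function(m, tree) {
  rel <- .rel_abund(m)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  mass <- matrix(0, nnode, nrow(m))       # node mass per sample
  idx <- match(colnames(m), tree$tip.label)
  present <- !is.na(idx)
  mass[idx[present], ] <- t(rel[, present, drop = FALSE])
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge)))
    mass[edge[k, 1], ] <- mass[edge[k, 1], ] + mass[edge[k, 2], ]
  # edge b subtends the clade of its child node; order follows tree$edge
  P <- mass[tree$edge[, 2], , drop = FALSE]
  colnames(P) <- rownames(m)
  P
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centered matrix
#' \eqn{-\frac{1}{2} C D^{(2)} C}. Axes are ordered by eigenvalue; negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are retained with their magnitudes recorded and, for use by
#' dispersion analysis, their eigenvectors scaled by
#' \eqn{\sqrt{|\lambda|}} kept as "imaginary" coordinates.
#'
#' @param dm distance matrix ('dist', or labelled square matrix).
#' @return list of class \code{"PcoaResult"}: \code{eigenvalues} (all,
#'   descending), \code{points} (samples x positive axes, scaled by
#'   \eqn{\sqrt\lambda}), \code{imaginary_points},
#'   \code{prop_explained} (per positive axis, of the positive inertia),
#'   \code{negative_inertia}.
#' @export
pcoaOrdination <- function(dm) {
  d <- .dist_matrix(dm)
  n <- nrow(d)
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- e$values
  tol <- 1e-9 * max(abs(lam), 1e-300)
  pos <- which(lam > tol)
  neg <- which(lam < -tol)
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam[pos]), length(pos))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("Axis", seq_along(pos))
  ipts <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-lam[neg]), length(neg))
  rownames(ipts) <- rownames(d)
  structure(list(
    eigenvalues = lam,
    points = pts,
    imaginary_points = ipts,
    prop_explained = lam[pos] / sum(lam[pos]),
    negative_inertia = sum(-lam[neg])), class = "PcoaResult")
}
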