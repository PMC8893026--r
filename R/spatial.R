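#' Great-circle distance matrix between samples
#'
#' Haversine distances in kilometres (IUGG mean Earth radius 6371.0088 km)
#' from the latitude/longitude columns of a metadata table. Space is treated
#' as horizontal only; sampling depth is an environmental covariate, not a
#' spatial coordinate.
#'
#' @param metadata \code{data.frame} with \code{latitude} and
#'   \code{longitude} columns (decimal degrees) and sample ids as row names,
#'   or an [OtuExperiment-class].
#' @return symmetric samples x samples matrix (km).
#' @export
haversineMatrix <- function(metadata) {
  if (methods::is(metadata, "OtuExperiment")) metadata <- sampleData(metadata)
  if (!all(c("latitude", "longitude") %in% names(metadata)))
    stop("metadata needs latitude and longitude columns")
  bad <- !stats::complete.cases(metadata[, c("latitude", "longitude")])
  if (any(bad))
    stop("missing coordinates for: ",
         paste(rownames(metadata)[bad], collapse = ", "))
  xy <- cbind(metadata$longitude, metadata$latitude)
  d <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
  dimnames(d) <- list(rownames(metadata), rownames(metadata))
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries; the p-value permutes
#' the row/column order of the second matrix.
#'
#' @param dm1,dm2 distance matrices with matching ids.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with \code{r}, \code{p}, \code{n_permutations}.
#' @export
mantelTest <- function(dm1, dm2, n_perm = 999, seed = NULL) {
  al <- .align_dms(dm1, dm2)
  n <- nrow(al$d1)
  if (n < 3) stop("need >= 3 samples")
  x <- .lower(al$d1)
  if (stats::sd(x) == 0 || stats::sd(.lower(al$d2)) == 0)
    stop("undefined correlation: constant distance matrix")
  r_obs <- stats::cor(x, .lower(al$d2))
  r_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    stats::cor(x, .lower(al$d2[idx, idx]))
  }, 0))
  list(r = r_obs, p = .perm_p(r_obs, r_perm), n_permutations = n_perm)
}

#' PCNM spatial eigenfunctions
#'
#' Principal coordinates of neighbour matrices: the geographic distance
#' matrix is truncated at threshold \eqn{t} (the longest edge of its minimum
#' spanning tree, the smallest t keeping the neighbour graph connected);
#' distances above \eqn{t} are replaced by \code{replacement * t} (4t by
#' default, the canonical construction); PCoA of the truncated matrix yields
#' the spatial eigenfunctions. Only positive-eigenvalue axes are retained,
#' as unit-norm, mean-zero vectors.
#'
#' @param geo geographic distance matrix (km).
#' @param truncation optional threshold t (km); default = longest MST edge.
#' @param replacement multiplier for distances beyond t (default 4).
#' @return list of class \code{"PcnmBasis"}: \code{vectors} (samples x axes,
#'   orthonormal columns), \code{eigenvalues}, \code{threshold}.
#' @export
pcnmBasis <- function(geo, truncation = NULL, replacement = 4) {
  d <- .dist_matrix(geo, "geo")
  n <- nrow(d)
  if (n < 3) stop("need >= 3 samples")
  if (max(d) == 0) stop("degenerate geometry: all points coincident")
  t0 <- if (is.null(truncation))
    max(vegan::spantree(stats::as.dist(d))$dist) else truncation
  dstar <- d
  dstar[dstar > t0] <- replacement * t0
  diag(dstar) <- 0
  pc <- pcoaOrdination(dstar)
  lam <- pc$eigenvalues
  lam_pos <- lam[lam > 1e-9 * max(abs(lam))]  # same retention rule as pcoa
  # unit-norm eigenvectors: undo the sqrt(lambda) scaling of the PCoA points
  V <- sweep(pc$points[, seq_along(lam_pos), drop = FALSE], 2,
             sqrt(lam_pos), "/")
  rownames(V) <- rownames(d)
  colnames(V) <- paste0("PCNM", seq_len(ncol(V)))
  structure(list(vectors = V, eigenvalues = lam_pos, threshold = t0),
            class = "PcnmBasis")
}
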