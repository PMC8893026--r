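#' @importFrom withr with_seed
NULL

# Run expr under a temporary RNG state when seed is non-NULL; otherwise use
# the session RNG. All stochastic entry points funnel through this so no
# call mutates global RNG state when a seed is given.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Coerce the accepted table representations to a samples x OTUs integer-ish
# numeric matrix with dimnames.
.counts <- function(x) {
  if (methods::is(x, "OtuExperiment")) return(otuCounts(x))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected an OtuExperiment or a numeric samples x OTUs matrix")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("OTU", seq_len(ncol(x)))
  if (any(!is.finite(x)) || any(x < 0))
    stop("counts must be finite and non-negative")
  x
}

.check_integer_counts <- function(m) {
  if (any(abs(m - round(m)) > 1e-8))
    stop("counts must be integral")
  invisible(TRUE)
}

# Per-sample relative abundances (rows sum to 1); errors on empty samples.
.rel_abund <- function(m) {
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("undefined for empty samples: ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  m / tot
}

# Validate/normalize a square symmetric distance matrix with ids.
.dist_matrix <- function(d, arg = "d") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop(arg, " must be a square distance matrix or 'dist' object")
  if (max(abs(d - t(d))) > 1e-8) stop(arg, " must be symmetric")
  if (any(!is.finite(d))) stop(arg, " must be finite")
  if (any(diag(d) != 0)) stop(arg, " must have a zero diagonal")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  d
}

# Align two labelled square matrices on shared ids, preserving dm1 order.
.align_dms <- function(d1, d2) {
  d1 <- .dist_matrix(d1, "dm1"); d2 <- .dist_matrix(d2, "dm2")
  ids <- rownames(d1)
  if (!setequal(ids, rownames(d2))) stop("distance matrices have different ids")
  list(d1 = d1, d2 = d2[ids, ids, drop = FALSE])
}

.lower <- function(m) m[lower.tri(m)]

# Permutation p-value with the +1 correction.
.perm_p <- function(stat_obs, stat_perm) {
  (sum(stat_perm >= stat_obs - 1e-12) + 1) / (length(stat_perm) + 1)
}

.groups_factor <- function(groups, n, ids = NULL) {
  if (!is.null(ids) && !is.null(names(groups))) groups <- groups[ids]
  g <- factor(groups)
  if (length(g) != n) stop("groups length does not match number of samples")
  if (anyNA(g)) stop("groups contain missing values")
  droplevels(g)
}
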