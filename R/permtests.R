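# Within-group sum of squared distances for a label assignment, from the
# squared-distance matrix: SS_within = sum_g (1/n_g) sum_{i<j in g} d^2_ij.
.ss_within <- function(d2, g) {
  lv <- levels(g)
  s <- 0
  for (l in lv) {
    idx <- which(g == l)
    if (length(idx) > 1)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-way PERMANOVA operating directly on a distance matrix.
#' \eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' pseudo-F \eqn{= \frac{SS_{among}/(a-1)}{SS_{within}/(N-a)}}. The p-value
#' permutes whole-sample group labels:
#' \eqn{p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(n_{perm} + 1)}.
#'
#' @param dm distance matrix ('dist' or labelled square matrix).
#' @param groups grouping factor (named by sample id, or in matrix order).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list of class \code{"PermanovaResult"}: \code{pseudo_F}, \code{p},
#'   \code{n_permutations}, \code{ss_among}, \code{ss_within},
#'   \code{ss_total}, \code{df_among}, \code{df_within}, \code{n}.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  d <- .dist_matrix(dm)
  n <- nrow(d)
  g <- .groups_factor(groups, n, rownames(d))
  a <- nlevels(g)
  if (a < 2) stop("need >= 2 groups")
  if (n_perm < 1) stop("n_perm must be >= 1")
  d2 <- d^2
  ss_total <- sum(d2) / (2 * n)
  ss_within <- .ss_within(d2, g)
  ss_among <- ss_total - ss_within
  f_obs <- (ss_among / (a - 1)) / (ss_within / (n - a))
  f_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(k) {
    gp <- g[sample.int(n)]
    ssw <- .ss_within(d2, gp)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }, 0))
  structure(list(pseudo_F = f_obs, p = .perm_p(f_obs, f_perm),
                 n_permutations = n_perm, ss_among = ss_among,
                 ss_within = ss_within, ss_total = ss_total,
                 df_among = a - 1, df_within = n - a, n = n),
            class = "PermanovaResult")
}

#' Pairwise PERMANOVA
#'
#' Runs [permanova()] on every pair of group levels. P-values are reported
#' unadjusted (a Bonferroni column is appended for reference).
#'
#' @inheritParams permanova
#' @return \code{data.frame}: one row per pair with \code{pseudo_F}, \code{p},
#'   \code{p_bonferroni}, \code{n}.
#' @export
pairwisePermanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  d <- .dist_matrix(dm)
  g <- .groups_factor(groups, nrow(d), rownames(d))
  pairs <- utils::combn(levels(g), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    keep <- g %in% pairs[, k]
    r <- permanova(d[keep, keep, drop = FALSE], droplevels(g[keep]),
                   n_perm = n_perm,
                   seed = if (is.null(seed)) NULL else seed + k)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               pseudo_F = r$pseudo_F, p = r$p, n = r$n)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Samples are embedded by PCoA keeping negative-eigenvalue axes as
#' imaginary coordinates; the distance of sample i to its group center is
#' \eqn{z_i = \sqrt{\max(0, \sum_{real}(y_{ik}-c_k)^2 -
#' \sum_{imag}(y_{ik}-c_k)^2)}}. A one-way ANOVA F is computed on z and its
#' p-value obtained by permuting z across groups.
#'
#' @inheritParams permanova
#' @param center \code{"centroid"} (coordinate mean, default) or
#'   \code{"median"} (coordinate-wise spatial median approximation).
#' @return list of class \code{"PermdispResult"}: \code{F}, \code{p},
#'   \code{distances} (named z), \code{df}.
#' @export
permdisp <- function(dm, groups, n_perm = 999, seed = NULL,
                     center = c("centroid", "median")) {
  center <- match.arg(center)
  d <- .dist_matrix(dm)
  n <- nrow(d)
  g <- .groups_factor(groups, n, rownames(d))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 samples")
  pc <- pcoaOrdination(d)
  Yr <- pc$points
  Yi <- pc$imaginary_points
  cen <- function(M) if (ncol(M) == 0) M[0, , drop = FALSE] else M
  z <- numeric(n)
  for (l in levels(g)) {
    idx <- which(g == l)
    cr <- if (center == "centroid") colMeans(Yr[idx, , drop = FALSE])
          else apply(Yr[idx, , drop = FALSE], 2, stats::median)
    dr2 <- rowSums(sweep(Yr[idx, , drop = FALSE], 2, cr)^2)
    di2 <- 0
    if (ncol(Yi) > 0) {
      ci <- if (center == "centroid") colMeans(Yi[idx, , drop = FALSE])
            else apply(Yi[idx, , drop = FALSE], 2, stats::median)
      di2 <- rowSums(sweep(Yi[idx, , drop = FALSE], 2, ci)^2)
    }
    z[idx] <- sqrt(pmax(0, dr2 - di2))
  }
  names(z) <- rownames(d)
  f_of <- function(zz, gg) {
    gm <- tapply(zz, gg, mean)
    ssb <- sum(table(gg) * (gm - mean(zz))^2)
    ssw <- sum((zz - gm[gg])^2)
    (ssb / (nlevels(gg) - 1)) / (ssw / (length(zz) - nlevels(gg)))
  }
  f_obs <- f_of(z, g)
  f_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(k)
    f_of(z[sample.int(n)], g), 0))
  structure(list(F = f_obs, p = .perm_p(f_obs, f_perm), distances = z,
                 df = c(nlevels(g) - 1, n - nlevels(g)),
                 n_permutations = n_perm),
            class = "PermdispResult")
}

#' ANOSIM: analysis of similarities
#'
#' \eqn{R = (\bar r_B - \bar r_W)/(M/2)} where \eqn{\bar r_B} and
#' \eqn{\bar r_W} are the mean ranks (average ties) of between- and
#' within-group distances and \eqn{M = N(N-1)/2}; permutation p-value over
#' group-label permutations.
#'
#' @inheritParams permanova
#' @return list with \code{R}, \code{p}, \code{n_permutations}.
#' @export
anosimTest <- function(dm, groups, n_perm = 999, seed = NULL) {
  d <- .dist_matrix(dm)
  n <- nrow(d)
  g <- .groups_factor(groups, n, rownames(d))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  lt <- lower.tri(d)
  r <- rank(d[lt])
  M <- n * (n - 1) / 2
  r_of <- function(gg) {
    same <- outer(gg, gg, "==")[lt]
    (mean(r[!same]) - mean(r[same])) / (M / 2)
  }
  r_obs <- r_of(g)
  r_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(k)
    r_of(g[sample.int(n)]), 0))
  list(R = r_obs, p = .perm_p(r_obs, r_perm), n_permutations = n_perm)
}

#' SIMPER: per-taxon contributions to between-group dissimilarity
#'
#' For every admissible between-group sample pair, the contribution of taxon
#' k is \eqn{100\,|y_{ik} - y_{jk}| / \sum_k (y_{ik} + y_{jk})} on relative
#' abundances; contributions are averaged over pairs, so they sum exactly to
#' the average Bray-Curtis dissimilarity (in percent). In two-way mode the
#' admissible pairs are restricted to matching levels of a crossed factor
#' (e.g. comparing regions within each depth stratum).
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @param groups primary grouping factor.
#' @param crossed_factor optional secondary factor whose levels must match
#'   within a compared pair (two-way SIMPER); NULL for one-way.
#' @return list of class \code{"SimperResult"}, one element per group pair,
#'   each with \code{contributions} (data.frame sorted by contribution:
#'   taxon, average percent contribution, cumulative percent) and
#'   \code{overall_dissimilarity} (percent).
#' @export
simperAnalysis <- function(table, groups, crossed_factor = NULL) {
  m <- .counts(table)
  rel <- .rel_abund(m)
  g <- .groups_factor(groups, nrow(m), rownames(m))
  cf <- if (is.null(crossed_factor)) NULL
        else .groups_factor(crossed_factor, nrow(m), rownames(m))
  pairs <- utils::combn(levels(g), 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    i1 <- which(g == pairs[1, k]); i2 <- which(g == pairs[2, k])
    contrib <- matrix(0, 0, ncol(m))
    for (i in i1) for (j in i2) {
      if (!is.null(cf) && cf[i] != cf[j]) next
      contrib <- rbind(contrib,
                       100 * abs(rel[i, ] - rel[j, ]) / sum(rel[i, ] + rel[j, ]))
    }
    nm <- paste(pairs[, k], collapse = " vs ")
    if (nrow(contrib) == 0) {
      warning("no admissible sample pairs for ", nm, "; skipped")
      next
    }
    avg <- colMeans(contrib)
    ord <- order(avg, decreasing = TRUE)
    df <- data.frame(taxon = colnames(m)[ord], contribution = avg[ord],
                     cumulative = cumsum(avg[ord]))
    out[[nm]] <- list(contributions = df,
                      overall_dissimilarity = sum(avg))
  }
  structure(out, class = "SimperResult")
}

#' Distance-decay regression of community similarity
#'
#' Ordinary least squares of community similarity (1 - dissimilarity) on
#' geographic distance over all ordered off-diagonal pairs (both (i,j) and
#' (j,i); \eqn{n_{points} = N(N-1)}), reporting the regression F with
#' degrees of freedom (1, \eqn{n_{points} - 2}). The ordered-pair convention
#' double-counts each pair; it is retained because it matches the degrees of
#' freedom printed in classic distance-decay reports (the pseudo-replication
#' caveat applies to the p-value).
#'
#' @param dm community dissimilarity matrix.
#' @param geo geographic distance matrix (same ids; e.g. from
#'   [haversineMatrix()]).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{F}, \code{df} (length 2), \code{p}, \code{n_points}.
#' @export
distanceDecay <- function(dm, geo) {
  al <- .align_dms(dm, geo)
  n <- nrow(al$d1)
  if (n < 3) stop("need >= 3 samples")
  off <- row(al$d1) != col(al$d1)
  sim <- 1 - al$d1[off]
  gd <- al$d2[off]
  npts <- n * (n - 1)
  fit <- stats::lm(sim ~ gd)
  sm <- suppressWarnings(summary(fit))  # degenerate fits handled below
  fstat <- if (stats::sd(sim) == 0 || stats::sd(gd) == 0) 0
           else unname(sm$fstatistic[1])
  r2 <- if (stats::sd(sim) == 0) 0 else sm$r.squared
  p <- if (fstat == 0) 1 else stats::pf(fstat, 1, npts - 2, lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, F = fstat, df = c(1, npts - 2), p = p,
       n_points = npts)
}
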