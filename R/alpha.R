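#' Observed OTU richness
#'
#' @param counts non-negative count vector for one sample.
#' @return number of taxa with count > 0.
#' @export
observedOtus <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  s <- sum(counts > 0)
  if (s == 0) warning("all-zero sample: S = 0")
  s
}

#' Shannon diversity index
#'
#' \eqn{H' = -\sum p_i \log_b p_i} over taxa with positive counts, where
#' \eqn{p_i} is the within-sample relative abundance. The default base 2
#' reports H' in bits.
#'
#' @param counts non-negative count vector.
#' @param base logarithm base (2 = bits, exp(1) = nats).
#' @return Shannon index.
#' @export
shannonIndex <- function(counts, base = 2) {
  if (sum(counts) == 0) stop("undefined metric: empty sample")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p, base = base))
}

#' Heip's evenness
#'
#' \eqn{E = (e^{H} - 1)/(S - 1)} with the Shannon index \eqn{H} in
#' natural-log units; 1 for a perfectly even community.
#'
#' @param counts non-negative count vector with at least 2 taxa present.
#' @return evenness in (0, 1].
#' @seealso [heipFromShannon()] to compute E from a published (H', S) pair.
#' @export
heipEvenness <- function(counts) {
  s <- sum(counts > 0)
  if (s < 2) stop("undefined metric: Heip's evenness needs S >= 2")
  heipFromShannon(shannonIndex(counts, base = 2), s, base = 2)
}

#' Heip's evenness from a Shannon index and richness
#'
#' Converts a Shannon index reported in any logarithm base to natural-log
#' units and applies \eqn{E = (e^{H} - 1)/(S - 1)}. Useful for checking
#' published diversity tables where only (H', S) pairs are printed.
#'
#' @param shannon Shannon index value.
#' @param s observed richness (>= 2).
#' @param base the logarithm base \code{shannon} was computed in.
#' @return evenness value.
#' @examples
#' heipFromShannon(8.13, 2150, base = 2)  # ~0.13
#' @export
heipFromShannon <- function(shannon, s, base = 2) {
  if (any(s < 2)) stop("s must be >= 2")
  h_nats <- shannon * log(base)
  (exp(h_nats) - 1) / (s - 1)
}

#' Chao1 richness estimator
#'
#' Classic estimator \eqn{S + F_1^2/(2 F_2)} when the doubleton count
#' \eqn{F_2 > 0}; the bias-corrected form \eqn{S + F_1 (F_1 - 1)/2} when
#' \eqn{F_2 = 0} (\eqn{F_1} = singletons).
#'
#' @param counts non-negative integer count vector.
#' @param bias_corrected always use the bias-corrected form
#'   \eqn{S + F_1 (F_1-1) / (2 (F_2 + 1))}; default FALSE (classic form with
#'   the \eqn{F_2 = 0} fallback).
#' @return estimated richness (>= observed S).
#' @export
chao1 <- function(counts, bias_corrected = FALSE) {
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("validation error: Chao1 needs integer counts")
  s <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) return(s + f1 * (f1 - 1) / (2 * (f2 + 1)))
  if (f2 > 0) s + f1^2 / (2 * f2) else s + f1 * (f1 - 1) / 2
}

#' Per-sample alpha-diversity table
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @param shannon_base logarithm base for the Shannon index (default 2).
#' @param chao1_bias_corrected see [chao1()].
#' @return \code{data.frame} with columns \code{sample_id},
#'   \code{observed_otus}, \code{shannon}, \code{chao1},
#'   \code{heip_evenness}.
#' @export
alphaDiversity <- function(table, shannon_base = 2,
                           chao1_bias_corrected = FALSE) {
  m <- .counts(table)
  data.frame(
    sample_id = rownames(m),
    observed_otus = apply(m, 1, function(v) sum(v > 0)),
    shannon = apply(m, 1, shannonIndex, base = shannon_base),
    chao1 = apply(m, 1, chao1, bias_corrected = chao1_bias_corrected),
    heip_evenness = apply(m, 1, heipEvenness),
    row.names = rownames(m))
}

#' Kruskal-Wallis test on an alpha-diversity metric
#'
#' Rank-based H with tie correction (chi-square approximation), as used for
#' comparing diversity metrics between depth strata or among regions.
#'
#' @param values numeric vector (one value per sample).
#' @param groups grouping factor.
#' @return list with \code{H}, \code{df}, \code{p}.
#' @export
kruskalWallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  g <- .groups_factor(groups, length(values))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values with a t-approximation
#' p-value; incomplete pairs are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list with \code{rho}, \code{p}, \code{n} (complete pairs used).
#' @export
spearmanCor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Least-squares regression of a squared diversity metric on covariates
#'
#' The metric is square-transformed (for normality of residuals) and fitted
#' by ordinary least squares on the covariate matrix; complete cases only.
#'
#' @param values per-sample metric values.
#' @param covariates \code{data.frame} or matrix of environmental covariates
#'   (rows aligned with \code{values}).
#' @return list with \code{coefficients} (coefficient table: estimate, se,
#'   t, p), \code{r_squared}, \code{n} and the underlying \code{lm} fit.
#' @export
diversityRegression <- function(values, covariates) {
  X <- as.data.frame(covariates)
  ok <- if (ncol(X)) stats::complete.cases(values, X) else !is.na(values)
  df <- if (ncol(X)) data.frame(.y2 = values[ok]^2, X[ok, , drop = FALSE])
        else data.frame(.y2 = values[ok]^2)
  if (nrow(df) < ncol(X) + 2) stop("too few complete cases for the design")
  fit <- stats::lm(.y2 ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinearity error: aliased columns ", paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  list(coefficients = as.data.frame(sm$coefficients),
       r_squared = sm$r.squared, n = nrow(df), fit = fit)
}
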