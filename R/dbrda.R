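# Residualize the columns of M on the column space of B (which includes the
# intercept); returns the residual matrix.
.resid_on <- function(M, B) {
  qrB <- qr(B)
  M - qr.fitted(qrB, M)
}

.as_predictor_matrix <- function(X, ids) {
  if (is.null(X)) return(NULL)
  X <- as.data.frame(X)
  if (!is.null(ids)) {
    if (!is.null(rownames(X)) && all(ids %in% rownames(X)))
      X <- X[ids, , drop = FALSE]
    else if (nrow(X) != length(ids))
      stop("predictor rows do not match the distance matrix ids")
  }
  op <- options(na.action = "na.pass"); on.exit(options(op))
  M <- stats::model.matrix(~ . - 1, data = X)
  rownames(M) <- rownames(X)
  M
}

.standardize <- function(M) {
  M <- scale(M)
  M[, attr(M, "scaled:scale") == 0] <- 0  # constant columns carry no signal
  M
}

#' Distance-based redundancy analysis (optionally partial)
#'
#' The community distance matrix is embedded by PCoA (positive-eigenvalue
#' axes only; any negative inertia is recorded and dropped), the coordinate
#' matrix Y and the standardized predictors X are residualized on the
#' conditioning table Z (plus intercept), and Y is regressed on X by least
#' squares. Constrained inertia is the sum of squared fitted values;
#' \eqn{R^2} = constrained / total (total after conditioning); pseudo-F
#' \eqn{= (constrained/m)/(residual/(n - m - q - 1))} with m and q the ranks
#' of X and Z after conditioning. Significance is assessed by permuting rows
#' of the residualized response (reduced-model permutation). The adjusted
#' \eqn{R^2} uses the Ezekiel correction with conditioned degrees of
#' freedom: \eqn{1 - (1 - R^2)(n - 1 - q)/(n - 1 - q - m)}.
#'
#' @param dm community distance matrix.
#' @param X predictor table (data.frame or matrix keyed by sample id).
#' @param Z optional conditioning table (partialled out).
#' @param n_perm permutations for the pseudo-F test (0 skips the test).
#' @param seed integer seed.
#' @return list of class \code{"DbRdaResult"}: \code{constrained_inertia},
#'   \code{residual_inertia}, \code{total_inertia}, \code{r_squared},
#'   \code{adj_r_squared}, \code{pseudo_F}, \code{p}, \code{m}, \code{q},
#'   \code{n}, \code{negative_inertia}.
#' @export
dbRda <- function(dm, X, Z = NULL, n_perm = 999, seed = NULL) {
  d <- .dist_matrix(dm)
  ids <- rownames(d)
  Xm <- .as_predictor_matrix(X, ids)
  Zm <- .as_predictor_matrix(Z, ids)
  ok <- stats::complete.cases(if (is.null(Zm)) Xm else cbind(Xm, Zm))
  if (!all(ok)) {
    d <- d[ok, ok, drop = FALSE]
    Xm <- Xm[ok, , drop = FALSE]
    if (!is.null(Zm)) Zm <- Zm[ok, , drop = FALSE]
  }
  Xm <- .standardize(Xm)
  if (!is.null(Zm)) Zm <- .standardize(Zm)
  n <- nrow(d)
  B <- cbind(rep(1, n), Zm)
  q <- qr(B)$rank - 1
  pc <- pcoaOrdination(d)
  Y <- pc$points
  Yr <- .resid_on(Y, B)
  Xr <- .resid_on(Xm, B)
  # drop predictors absorbed by the conditioning set before rank detection
  Xr <- Xr[, sqrt(colSums(Xr^2)) > 1e-8 * sqrt(n), drop = FALSE]
  qrX <- qr(Xr)
  m <- qrX$rank
  if (n < m + q + 2) stop("too few samples for the requested model")
  if (m < ncol(Xm))
    warning("collinear predictors after conditioning; rank reduced to ", m)
  total <- sum(Yr^2)
  fstat <- function(Yperm) {
    fit <- qr.fitted(qrX, Yperm)
    con <- sum(fit^2)
    (con / m) / ((sum(Yperm^2) - con) / (n - m - q - 1))
  }
  if (m == 0) {
    con <- 0; r2 <- 0; f_obs <- 0; p <- 1
  } else {
    con <- sum(qr.fitted(qrX, Yr)^2)
    r2 <- con / total
    f_obs <- (con / m) / ((total - con) / (n - m - q - 1))
    p <- NA_real_
    if (n_perm > 0) {
      f_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(k)
        fstat(Yr[sample.int(n), , drop = FALSE]), 0))
      p <- .perm_p(f_obs, f_perm)
    }
  }
  adj <- if (m == 0) 0 else 1 - (1 - r2) * (n - 1 - q) / (n - 1 - q - m)
  structure(list(constrained_inertia = con, residual_inertia = total - con,
                 total_inertia = total, r_squared = r2, adj_r_squared = adj,
                 pseudo_F = f_obs, p = p, m = m, q = q, n = n,
                 negative_inertia = pc$negative_inertia,
                 n_permutations = n_perm),
            class = "DbRdaResult")
}

#' Forward selection of predictors by adjusted R-squared
#'
#' Greedy forward selection with a double stopping rule: at each step the
#' candidate giving the largest adjusted-\eqn{R^2} gain is considered and
#' added only if its marginal permutation p-value (conditioned on Z and the
#' already-selected predictors) is \eqn{\le} \code{alpha}; selection then
#' stops once the cumulative adjusted \eqn{R^2} reaches the global
#' (all-candidate) adjusted \eqn{R^2}, which guards against accumulating
#' spurious predictors. May return an empty selection.
#'
#' @param dm community distance matrix.
#' @param candidates predictor table; columns are selected individually.
#' @param Z optional conditioning table.
#' @param alpha significance threshold for the marginal test.
#' @param n_perm permutations per marginal test.
#' @param seed integer seed.
#' @return list with \code{selected} (ordered names), \code{adj_r_squared}
#'   (per-step cumulative values), \code{global_adj_r_squared} and
#'   \code{steps} (data.frame log).
#' @export
forwardSelect <- function(dm, candidates, Z = NULL, alpha = 0.05,
                          n_perm = 999, seed = NULL) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1) stop("need >= 1 candidate")
  global <- dbRda(dm, candidates, Z, n_perm = 0)$adj_r_squared
  selected <- character()
  steps <- data.frame()
  adj_path <- numeric()
  k <- 0L
  repeat {
    remaining <- setdiff(colnames(candidates), selected)
    if (!length(remaining)) break
    adj_try <- vapply(remaining, function(v)
      dbRda(dm, candidates[, c(selected, v), drop = FALSE], Z,
            n_perm = 0)$adj_r_squared, 0)
    best <- remaining[which.max(adj_try)]
    best_adj <- max(adj_try)
    k <- k + 1L
    Zcur <- candidates[, selected, drop = FALSE]
    if (!is.null(Z)) Zcur <- cbind(as.data.frame(Z), Zcur)
    if (ncol(Zcur) == 0) Zcur <- NULL
    marg <- dbRda(dm, candidates[, best, drop = FALSE], Zcur,
                  n_perm = n_perm,
                  seed = if (is.null(seed)) NULL else seed + k)
    steps <- rbind(steps, data.frame(variable = best, adj_r_squared = best_adj,
                                     marginal_F = marg$pseudo_F,
                                     marginal_p = marg$p))
    if (is.na(marg$p) || marg$p > alpha) break
    selected <- c(selected, best)
    adj_path <- c(adj_path, best_adj)
    # overfitting guard applied after admitting a significant variable: once
    # the cumulative adjusted R2 reaches the global model's, stop adding
    if (best_adj > global + 1e-12) break
  }
  list(selected = selected, adj_r_squared = adj_path,
       global_adj_r_squared = global, steps = steps)
}

#' Variation partitioning between environmental and spatial predictors
#'
#' Fits three unconditioned db-RDA models (E, S, and E+S) and decomposes the
#' adjusted \eqn{R^2} values into pure environmental (a), shared (b), pure
#' spatial (c) and residual (d) fractions:
#' \eqn{a = adjR^2(ES) - adjR^2(S)}, \eqn{c = adjR^2(ES) - adjR^2(E)},
#' \eqn{b = adjR^2(E) + adjR^2(S) - adjR^2(ES)}, \eqn{d = 1 - adjR^2(ES)}.
#' When collinearity between an environmental driver and space makes the
#' shared fraction negative, proportional apportioning redistributes the
#' combined explained variance over the pure fractions in proportion to
#' their raw values (see [proportionalApportion()]).
#'
#' @param dm community distance matrix.
#' @param E environmental predictor table.
#' @param S spatial predictor table (e.g. [pcnmBasis()] vectors).
#' @param n_perm permutations for the three model tests.
#' @param seed integer seed.
#' @return list of class \code{"VariationPartition"}: raw fractions
#'   \code{a}, \code{b}, \code{c}, \code{d}; \code{apportioned} flag and
#'   corrected \code{a_prime}, \code{b_prime}, \code{c_prime}; the three
#'   \code{fits}.
#' @export
variationPartition <- function(dm, E, S, n_perm = 199, seed = NULL) {
  fit_e <- dbRda(dm, E, n_perm = n_perm, seed = seed)
  fit_s <- dbRda(dm, S, n_perm = n_perm,
                 seed = if (is.null(seed)) NULL else seed + 1)
  ES <- cbind(as.data.frame(E), as.data.frame(S))
  names(ES) <- make.unique(names(ES))
  fit_es <- dbRda(dm, ES, n_perm = n_perm,
                  seed = if (is.null(seed)) NULL else seed + 2)
  ae <- fit_e$adj_r_squared; as_ <- fit_s$adj_r_squared
  aes <- fit_es$adj_r_squared
  a <- aes - as_; c_ <- aes - ae; b <- ae + as_ - aes; d <- 1 - aes
  apportioned <- b < 0
  if (apportioned && (a + c_) > 0) {
    ap <- proportionalApportion(a, c_, aes)
    a_p <- ap$a_prime; c_p <- ap$c_prime; b_p <- 0
  } else {
    a_p <- a; c_p <- c_; b_p <- b
  }
  structure(list(a = a, b = b, c = c_, d = d,
                 apportioned = apportioned,
                 a_prime = a_p, b_prime = b_p, c_prime = c_p,
                 adj_r_squared = c(E = ae, S = as_, ES = aes),
                 fits = list(E = fit_e, S = fit_s, ES = fit_es)),
            class = "VariationPartition")
}

#' Proportional apportioning of a negative shared fraction
#'
#' When the shared fraction b of a variation partition is negative, the
#' combined explained variance is reallocated to the pure fractions in
#' proportion to their raw values: \eqn{a' = R^2_{ES} \cdot a/(a + c)},
#' \eqn{c' = R^2_{ES} \cdot c/(a + c)}, \eqn{b' = 0}. Preserves the a:c
#' ratio and restores \eqn{a' + c' = R^2_{ES}}.
#'
#' @param a,c raw pure environmental and pure spatial fractions (a + c > 0).
#' @param combined adjusted \eqn{R^2} of the combined model (>= 0).
#' @return list with \code{a_prime}, \code{c_prime}, \code{b_prime} (= 0).
#' @examples
#' proportionalApportion(0.22, 0.14, 0.28)  # ~0.171 and ~0.109
#' @export
proportionalApportion <- function(a, c, combined) {
  if (a + c <= 0) stop("undefined apportionment: a + c must be > 0")
  if (combined < 0) stop("combined adjusted R-squared must be >= 0")
  list(a_prime = combined * a / (a + c),
       c_prime = combined * c / (a + c),
       b_prime = 0)
}
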