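#' Per-taxon mean relative abundance and occurrence frequency
#'
#' The inputs of the Sloan neutral model fit: for each taxon, the mean over
#' samples of its within-sample relative abundance (\eqn{p_i}) and the
#' fraction of samples in which it was detected (\eqn{F_{obs,i}}), together
#' with the community size N (mean sample total, rounded). Assumes an
#' evenly rarefied table; a warning names the spread if totals differ by
#' more than 1\%.
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @return list with \code{freq} (data.frame: taxon, p, f_obs; taxa absent
#'   everywhere excluded) and \code{N}.
#' @export
frequencyAbundance <- function(table) {
  m <- .counts(table)
  if (nrow(m) < 2) stop("need >= 2 samples")
  tot <- rowSums(m)
  if (diff(range(tot)) > 0.01 * mean(tot))
    warning("sample totals are uneven (range ", min(tot), "-", max(tot),
            "); rarefy first")
  rel <- .rel_abund(m)
  p <- colMeans(rel)
  f <- colMeans(m > 0)
  keep <- p > 0
  list(freq = data.frame(taxon = colnames(m)[keep], p = p[keep],
                         f_obs = f[keep], row.names = NULL),
       N = round(mean(tot)))
}

#' Sloan model predicted occurrence frequency
#'
#' Under the neutral model a taxon with metacommunity relative abundance p
#' has local relative abundance distributed Beta(\eqn{Nmp}, \eqn{Nm(1-p)});
#' its predicted detection frequency above the detection limit d is
#' \eqn{F_{pred} = 1 - I_d(Nmp,\ Nm(1-p))} with \eqn{I} the regularized
#' incomplete beta function.
#'
#' @param p metacommunity relative abundance(s), in (0, 1).
#' @param m immigration probability, in (0, 1].
#' @param N reads per community (>= 1).
#' @param d detection limit as a relative abundance, in (0, 1);
#'   conventionally 1/N.
#' @return predicted frequency(ies) in [0, 1].
#' @export
predictFrequency <- function(p, m, N, d = 1 / N) {
  if (any(p <= 0) || any(p >= 1)) stop("p must lie in (0, 1)")
  if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
  if (N < 1) stop("N must be >= 1")
  if (d <= 0 || d >= 1) stop("d must lie in (0, 1)")
  stats::pbeta(d, N * m * p, N * m * (1 - p), lower.tail = FALSE)
}

#' Fit the Sloan neutral community model
#'
#' Least-squares fit of the immigration probability m: minimizes
#' \eqn{\sum_i (F_{obs,i} - F_{pred,i}(m))^2} over \eqn{m \in (10^{-6}, 1]}
#' by bounded scalar minimization (tolerance 1e-8).
#' \eqn{R^2 = 1 - SSE/\sum_i(F_{obs,i} - \bar F_{obs})^2} (can be negative
#' for a poor fit). The 95\% prediction envelope uses Wilson score intervals
#' for a binomial proportion at the predicted frequency with n = number of
#' samples; each taxon is classified below / within / above the envelope.
#'
#' @param freq_data data.frame with columns \code{p} and \code{f_obs} (and
#'   optionally \code{taxon}), as produced by [frequencyAbundance()], or the
#'   list returned by that function.
#' @param N reads per community (taken from \code{freq_data} if it is the
#'   [frequencyAbundance()] result).
#' @param d detection limit; default 1/N.
#' @param n_samples number of samples behind the observed frequencies (for
#'   the Wilson envelope); default inferred from the frequency resolution.
#' @return list of class \code{"NcmFit"}: \code{m}, \code{Nm}, \code{N},
#'   \code{d}, \code{r_squared}, \code{sse}, \code{taxa} (per-taxon
#'   data.frame: p, f_obs, f_pred, lower, upper, class) and counts
#'   \code{n_below}, \code{n_within}, \code{n_above}.
#' @export
fitNcm <- function(freq_data, N = NULL, d = NULL, n_samples = NULL) {
  if (is.list(freq_data) && !is.data.frame(freq_data) &&
      !is.null(freq_data$freq)) {
    if (is.null(N)) N <- freq_data$N
    freq_data <- freq_data$freq
  }
  if (is.null(N)) stop("N is required")
  fd <- freq_data[freq_data$p > 0 & freq_data$p < 1, , drop = FALSE]
  if (nrow(fd) < 10) stop("need >= 10 taxa with 0 < p < 1")
  if (is.null(d)) d <- 1 / N
  sst <- sum((fd$f_obs - mean(fd$f_obs))^2)
  if (sst == 0) stop("undefined R-squared: observed frequencies are constant")
  sse_of <- function(m)
    sum((fd$f_obs - predictFrequency(fd$p, m, N, d))^2)
  opt <- stats::optimize(sse_of, interval = c(1e-6, 1), tol = 1e-8)
  m_hat <- opt$minimum
  f_pred <- predictFrequency(fd$p, m_hat, N, d)
  if (is.null(n_samples)) {
    # frequencies are multiples of 1/n_samples; recover n from the grid
    fr <- fd$f_obs[fd$f_obs > 0 & fd$f_obs < 1]
    n_samples <- if (length(fr)) round(1 / min(diff(sort(unique(c(0, fr, 1))))))
                 else 20
  }
  wil <- .wilson(f_pred, n_samples)
  cls <- ifelse(fd$f_obs < wil$lower, "below",
                ifelse(fd$f_obs > wil$upper, "above", "within"))
  taxa <- data.frame(taxon = if ("taxon" %in% names(fd)) fd$taxon else
                       seq_len(nrow(fd)),
                     p = fd$p, f_obs = fd$f_obs, f_pred = f_pred,
                     lower = wil$lower, upper = wil$upper, class = cls,
                     row.names = NULL)
  structure(list(m = m_hat, Nm = m_hat * N, N = N, d = d,
                 r_squared = 1 - opt$objective / sst, sse = opt$objective,
                 n_samples = n_samples, taxa = taxa,
                 n_below = sum(cls == "below"),
                 n_within = sum(cls == "within"),
                 n_above = sum(cls == "above")),
            class = "NcmFit")
}

# Wilson score interval for a proportion phat with n trials (95%).
.wilson <- function(phat, n, z = stats::qnorm(0.975)) {
  den <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / den
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  list(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Fit the neutral model per depth stratum
#'
#' Subsets samples by the \code{depth_category} metadata column and fits the
#' Sloan model on each requested stratum; \code{"all"} pools every sample.
#'
#' @param table [OtuExperiment-class] or samples x OTUs matrix.
#' @param metadata metadata with a \code{depth_category} column (taken from
#'   the OtuExperiment when omitted).
#' @param strata character vector from \code{c("all", "surface", "DCM")}.
#' @param d detection limit passed to [fitNcm()].
#' @return named list of \code{NcmFit} objects.
#' @export
ncmByStratum <- function(table, metadata = NULL,
                         strata = c("all", "surface", "DCM"), d = NULL) {
  m <- .counts(table)
  if (is.null(metadata) && methods::is(table, "OtuExperiment"))
    metadata <- sampleData(table)
  out <- list()
  for (s in strata) {
    keep <- if (s == "all") rep(TRUE, nrow(m)) else {
      if (is.null(metadata$depth_category))
        stop("metadata needs a depth_category column")
      metadata[rownames(m), "depth_category"] == s
    }
    sub <- m[keep, , drop = FALSE]
    out[[s]] <- fitNcm(frequencyAbundance(sub), n_samples = nrow(sub))
  }
  out
}
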