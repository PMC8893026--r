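#' @export
print.NcmFit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.4g  (Nm = %.4g, N = %d, detection limit %.3g)\n",
              x$m, x$Nm, x$N, x$d))
  cat(sprintf("  R-squared = %.3f over %d taxa (%d below / %d within / %d above the 95%% envelope)\n",
              x$r_squared, nrow(x$taxa), x$n_below, x$n_within, x$n_above))
  invisible(x)
}

#' @export
print.PermanovaResult <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f (df %d, %d), p = %.4g [%d permutations]\n",
              x$pseudo_F, x$df_among, x$df_within, x$p, x$n_permutations))
  invisible(x)
}

#' @export
print.PermdispResult <- function(x, ...) {
  cat(sprintf("PERMDISP: F = %.3f (df %d, %d), p = %.4g\n",
              x$F, x$df[1], x$df[2], x$p))
  invisible(x)
}

#' @export
print.VariationPartition <- function(x, ...) {
  cat("Variation partitioning (adjusted R-squared units)\n")
  cat(sprintf("  raw: a (pure env) = %.3f, b (shared) = %.3f, c (pure space) = %.3f, d (residual) = %.3f\n",
              x$a, x$b, x$c, x$d))
  if (x$apportioned)
    cat(sprintf("  negative shared fraction -> proportional apportioning: a' = %.3f, c' = %.3f\n",
                x$a_prime, x$c_prime))
  invisible(x)
}

#' @export
print.DbRdaResult <- function(x, ...) {
  cat(sprintf("db-RDA: R2 = %.3f (adj %.3f), pseudo-F = %.3f (m = %d, q = %d, n = %d), p = %s\n",
              x$r_squared, x$adj_r_squared, x$pseudo_F, x$m, x$q, x$n,
              format(x$p)))
  invisible(x)
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("seabiome pipeline report (", x$schema, ")\n", sep = "")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
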