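# Fixture builders and independent oracles shared across the suite.

random_table <- function(n_samples = 5, n_otus = 8, lambda = 20, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus)
    m[m < 0] <- 0
    # guarantee non-empty samples
    empty <- rowSums(m) == 0
    m[empty, 1] <- 1
    dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                        sprintf("OTU%03d", seq_len(n_otus)))
    m
  })
}

random_tree <- function(tips, seed = 1) {
  withr::with_seed(seed,
    ape::rtree(length(tips), rooted = TRUE, tip.label = tips,
               br = function(n) stats::rexp(n, 1)))
}

# Independent weighted-UniFrac oracle: per-branch accumulation through
# phangorn::Descendants tip sets (a different traversal than the package's
# postorder mass propagation).
brute_unifrac <- function(m, tree, normalized = TRUE) {
  rel <- m / rowSums(m)
  n <- nrow(m)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], "tips")
  P <- vapply(seq_len(nrow(tree$edge)), function(b) {
    tips <- intersect(tree$tip.label[desc[[b]]], colnames(m))
    if (length(tips)) rowSums(rel[, tips, drop = FALSE]) else numeric(n)
  }, numeric(n))
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(tree$edge.length * abs(P[i, ] - P[j, ]))
    den <- sum(tree$edge.length * (P[i, ] + P[j, ]))
    d[i, j] <- d[j, i] <- if (normalized) num / den else num
  }
  d
}

# Euclidean distance matrix from a coordinate matrix, with sample ids.
euclid_dm <- function(Y) {
  d <- as.matrix(stats::dist(Y))
  dimnames(d) <- list(rownames(Y), rownames(Y))
  d
}
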