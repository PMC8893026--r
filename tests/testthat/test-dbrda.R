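test_that("db-RDA on Euclidean distances equals classical RDA", {
  for (s in 1:3) {
    Y <- withr::with_seed(s, matrix(stats::rnorm(60), 15, 4))
    rownames(Y) <- paste0("p", 1:15)
    X <- withr::with_seed(s + 50, data.frame(
      x1 = stats::rnorm(15), x2 = stats::rnorm(15), x3 = stats::rnorm(15),
      row.names = rownames(Y)))
    mine <- dbRda(euclid_dm(Y), X, n_perm = 0)
    veg <- vegan::rda(Y ~ x1 + x2 + x3, data = X)
    adj <- vegan::RsquareAdj(veg)
    expect_equal(mine$r_squared, adj$r.squared, tolerance = 1e-9)
    expect_equal(mine$adj_r_squared, adj$adj.r.squared, tolerance = 1e-9)
    aov <- stats::anova(veg, permutations = 9)
    expect_equal(mine$pseudo_F, aov$F[1], tolerance = 1e-9)
  }
})

test_that("db-RDA inertia decomposition, self-prediction and conditioning", {
  Y <- withr::with_seed(7, matrix(stats::rnorm(48), 12, 4))
  rownames(Y) <- paste0("p", 1:12)
  dm <- euclid_dm(Y)

  res <- dbRda(dm, data.frame(a = Y[, 1], row.names = rownames(Y)),
               n_perm = 199, seed = 1)
  expect_equal(res$constrained_inertia + res$residual_inertia,
               res$total_inertia, tolerance = 1e-9)
  # X = first coordinate axis: R2 matches the multivariate regression oracle
  cY <- scale(Y, scale = FALSE)
  fitted <- stats::fitted(stats::lm(cY ~ Y[, 1]))
  expect_equal(res$r_squared,
               sum(scale(fitted, scale = FALSE)^2) / sum(cY^2),
               tolerance = 1e-9)
  expect_equal(res$p, 1 / 200)

  # conditioning on X itself leaves nothing: rank collapses to zero
  expect_warning(
    res0 <- dbRda(dm, data.frame(a = Y[, 1], row.names = rownames(Y)),
                  Z = data.frame(z = Y[, 1], row.names = rownames(Y)),
                  n_perm = 0),
    "collinear")
  expect_equal(res0$r_squared, 0)

  # partial model: conditioned df enter the Ezekiel adjustment
  Z <- data.frame(z = Y[, 2], row.names = rownames(Y))
  resp <- dbRda(dm, data.frame(a = Y[, 1], row.names = rownames(Y)), Z = Z,
                n_perm = 0)
  expect_equal(resp$q, 1)
  n <- 12; m <- 1; q <- 1
  expect_equal(resp$adj_r_squared,
               1 - (1 - resp$r_squared) * (n - 1 - q) / (n - 1 - q - m),
               tolerance = 1e-12)
})

test_that("forward selection recovers true drivers and stops on noise", {
  # single pure-noise candidate: empty selection
  Y <- withr::with_seed(11, matrix(stats::rnorm(64), 16, 4))
  rownames(Y) <- paste0("p", 1:16)
  noise <- withr::with_seed(12, data.frame(u = stats::rnorm(16),
                                           row.names = rownames(Y)))
  fs0 <- forwardSelect(euclid_dm(Y), noise, n_perm = 199, seed = 3)
  expect_length(fs0$selected, 0)

  # response driven by exactly 2 of 6 candidates
  hits <- 0
  for (s in 1:8) {
    X <- withr::with_seed(s + 200, as.data.frame(
      matrix(stats::rnorm(16 * 6), 16, 6,
             dimnames = list(paste0("p", 1:16), paste0("v", 1:6)))))
    Yr <- withr::with_seed(s + 300,
      cbind(2 * X$v2 + stats::rnorm(16, sd = 0.1),
            2 * X$v5 + stats::rnorm(16, sd = 0.1)))
    rownames(Yr) <- rownames(X)
    fs <- forwardSelect(euclid_dm(Yr), X, n_perm = 199, seed = s)
    if (setequal(fs$selected[1:2], c("v2", "v5"))) hits <- hits + 1
  }
  expect_gte(hits, 7)

  # identical candidates: exactly one survives
  dup <- data.frame(a = Y[, 1], b = Y[, 1], c = Y[, 1],
                    row.names = rownames(Y))
  fsd <- suppressWarnings(forwardSelect(euclid_dm(Y), dup, n_perm = 199,
                                        seed = 4))
  expect_length(fsd$selected, 1)
})

test_that("variation partitioning fractions close and apportion correctly", {
  # raw fractions always satisfy a + b + c + d = 1 (adjusted-R2 units)
  Y <- withr::with_seed(21, matrix(stats::rnorm(56), 14, 4))
  rownames(Y) <- paste0("p", 1:14)
  E <- withr::with_seed(22, data.frame(e1 = stats::rnorm(14), e2 = stats::rnorm(14),
                                       row.names = rownames(Y)))
  S <- withr::with_seed(23, data.frame(s1 = stats::rnorm(14),
                                       row.names = rownames(Y)))
  vp <- variationPartition(euclid_dm(Y), E, S, n_perm = 0)
  expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-9)
  # fractions are pure arithmetic on the three adjusted R2 values
  expect_equal(vp$a, vp$adj_r_squared["ES"] - vp$adj_r_squared["S"],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(vp$b, vp$adj_r_squared["E"] + vp$adj_r_squared["S"] -
                 vp$adj_r_squared["ES"], ignore_attr = TRUE, tolerance = 1e-12)
  if (vp$apportioned) {
    expect_equal(vp$b_prime, 0)
    expect_equal(vp$a_prime + vp$c_prime, unname(vp$adj_r_squared["ES"]),
                 tolerance = 1e-9)
    expect_equal(vp$a_prime / vp$c_prime, vp$a / vp$c, tolerance = 1e-9)
  }

  # duplicated tables: all signal is shared
  vpd <- suppressWarnings(variationPartition(euclid_dm(Y), E, E, n_perm = 0))
  expect_equal(vpd$a, 0, tolerance = 1e-9)
  expect_equal(vpd$c, 0, tolerance = 1e-9)
  expect_equal(vpd$b, unname(vpd$adj_r_squared["E"]), tolerance = 1e-9)

  # space orthogonal to both E and the response: c and b near zero
  Yo <- withr::with_seed(24, matrix(stats::rnorm(400 * 2), 400, 2))
  rownames(Yo) <- paste0("p", seq_len(400))
  Eo <- data.frame(e = Yo[, 1] + withr::with_seed(25, stats::rnorm(400, sd = 0.2)),
                   row.names = rownames(Yo))
  So <- withr::with_seed(26, data.frame(s = stats::rnorm(400),
                                        row.names = rownames(Yo)))
  vpo <- variationPartition(euclid_dm(Yo), Eo, So, n_perm = 0)
  expect_lt(abs(vpo$c), 0.02)
  expect_lt(abs(vpo$b), 0.02)
  expect_gt(vpo$a, 0.2)
})

test_that("proportional apportioning preserves the a:c ratio", {
  ap <- proportionalApportion(0.22, 0.14, 0.28)
  expect_equal(ap$a_prime, 0.28 * 0.22 / 0.36)
  expect_equal(ap$c_prime, 0.28 * 0.14 / 0.36)
  expect_equal(round(ap$a_prime, 2), 0.17)
  expect_equal(round(ap$c_prime, 2), 0.11)

  sym <- proportionalApportion(0.1, 0.1, 0.3)
  expect_equal(sym$a_prime, 0.15)
  expect_equal(sym$c_prime, 0.15)

  z <- proportionalApportion(0.2, 0, 0.25)
  expect_equal(z$a_prime, 0.25)
  expect_equal(z$c_prime, 0)

  expect_error(proportionalApportion(-0.1, 0.1, 0.2), "a \\+ c")
})
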