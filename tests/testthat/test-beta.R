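test_that("Bray-Curtis distances match hand arithmetic and bounds", {
  m <- rbind(a = c(6, 4), b = c(2, 8))
  colnames(m) <- c("o1", "o2")
  d <- brayCurtis(m)
  expect_equal(d["a", "b"], 0.4)                 # |.6-.2|+|.4-.8| over 2
  expect_equal(d["a", "a"], 0)
  disj <- rbind(a = c(5, 0), b = c(0, 9)); colnames(disj) <- c("o1", "o2")
  expect_equal(brayCurtis(disj)["a", "b"], 1)
  expect_error(brayCurtis(rbind(a = c(1, 1), b = c(0, 0))), "empty")
})

test_that("weighted UniFrac equals the independent per-branch oracle", {
  # two-tip star tree, unit branches, opposite tips
  star <- ape::read.tree(text = "(t1:1,t2:1);")
  m <- rbind(s1 = c(10, 0), s2 = c(0, 10))
  colnames(m) <- c("t1", "t2")
  expect_equal(weightedUnifrac(m, star)["s1", "s2"], 1)
  expect_equal(weightedUnifrac(m, star, normalized = FALSE)["s1", "s2"], 2)
  expect_equal(weightedUnifrac(rbind(a = m[1, ], b = m[1, ]), star)["a", "b"], 0)

  for (s in 1:12) {
    tips <- sprintf("OTU%03d", 1:8)
    tr <- random_tree(tips, seed = s)
    m <- random_table(5, 8, seed = s + 100)
    expect_lt(max(abs(weightedUnifrac(m, tr) - brute_unifrac(m, tr))), 1e-12)
    expect_lt(max(abs(weightedUnifrac(m, tr, normalized = FALSE) -
                        brute_unifrac(m, tr, normalized = FALSE))), 1e-12)
    d <- weightedUnifrac(m, tr)
    expect_true(all(d >= 0 & d <= 1))
  }

  tr <- random_tree(sprintf("OTU%03d", 1:8), seed = 1)
  bad <- random_table(3, 9, seed = 1)   # OTU009 not a tip
  expect_error(weightedUnifrac(bad, tr), "OTU009")
  tr$edge.length[1] <- -1
  expect_error(weightedUnifrac(random_table(3, 8, seed = 1), tr),
               "branch length")
})

test_that("PCoA reproduces geometry and preserves negative eigenvalues", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  pc <- pcoaOrdination(d3)
  lam <- pc$eigenvalues[pc$eigenvalues > 1e-9]
  expect_length(lam, 2)
  expect_equal(lam[1], lam[2], tolerance = 1e-9)

  # Euclidean distances from known 2-D points are reconstructed
  Y <- withr::with_seed(4, matrix(stats::rnorm(20), 10, 2))
  rownames(Y) <- paste0("p", 1:10)
  pc2 <- pcoaOrdination(euclid_dm(Y))
  expect_lt(max(abs(euclid_dm(pc2$points) - euclid_dm(Y))), 1e-9)
  expect_equal(sum(pc2$prop_explained), 1, tolerance = 1e-12)

  # Bray-Curtis typically yields negative inertia, which is kept and flagged
  db <- brayCurtis(random_table(8, 12, lambda = 4, seed = 9))
  pcb <- pcoaOrdination(db)
  expect_gt(pcb$negative_inertia, 0)
  expect_equal(ncol(pcb$imaginary_points),
               sum(pcb$eigenvalues < -1e-9 * max(abs(pcb$eigenvalues))))

  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA matches brute-force sums of squares and vegan", {
  # 4-sample hand evaluation
  d <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d["s1", "s2"] <- d["s2", "s1"] <- 1
  d["s3", "s4"] <- d["s4", "s3"] <- 2
  d["s1", "s3"] <- d["s3", "s1"] <- 5
  d["s1", "s4"] <- d["s4", "s1"] <- 6
  d["s2", "s3"] <- d["s3", "s2"] <- 7
  d["s2", "s4"] <- d["s4", "s2"] <- 4
  g <- c("A", "A", "B", "B")
  res <- permanova(d, g, n_perm = 99, seed = 1)
  ss_tot <- sum(d[lower.tri(d)]^2) / 4
  ss_w <- (1^2) / 2 + (2^2) / 2
  expect_equal(res$ss_total, ss_tot)
  expect_equal(res$ss_within, ss_w)
  expect_equal(res$pseudo_F, ((ss_tot - ss_w) / 1) / (ss_w / 2))
  expect_equal(res$ss_among + res$ss_within, res$ss_total, tolerance = 1e-9)

  # perfect separation: clone groups give zero within-group sum of squares
  # and the smallest attainable p (up to permutations that happen to
  # reproduce the clone partition exactly)
  dc <- matrix(3, 12, 12) - 3 * diag(12)
  dc[1:6, 1:6] <- 0; dc[7:12, 7:12] <- 0
  dimnames(dc) <- list(paste0("s", 1:12), paste0("s", 1:12))
  resc <- permanova(dc, rep(c("A", "B"), each = 6), n_perm = 199, seed = 2)
  expect_equal(resc$ss_within, 0)
  expect_equal(resc$p, 1 / 200)

  # agreement with vegan::adonis2 on random fixtures
  for (s in 1:5) {
    m <- random_table(9, 15, seed = s)
    db <- brayCurtis(m)
    gg <- rep(c("A", "B", "C"), each = 3)
    mine <- permanova(db, gg, n_perm = 9, seed = s)
    veg <- vegan::adonis2(stats::as.dist(db) ~ gg, permutations = 9)
    expect_equal(mine$pseudo_F, veg$F[1], tolerance = 1e-9)
  }

  expect_error(permanova(d, rep("A", 4)), ">= 2 groups")
})

test_that("pairwise PERMANOVA covers all pairs and reduces to the global test", {
  m <- random_table(10, 12, seed = 3)
  db <- brayCurtis(m)
  g2 <- rep(c("A", "B"), each = 5)
  pw <- pairwisePermanova(db, g2, n_perm = 99, seed = 5)
  expect_equal(nrow(pw), 1)
  expect_equal(pw$pseudo_F, permanova(db, g2, n_perm = 99)$pseudo_F)

  g3 <- c(rep("A", 3), rep("B", 3), rep("C", 4))
  pw3 <- pairwisePermanova(db, g3, n_perm = 49, seed = 5)
  expect_equal(nrow(pw3), 3)
  expect_true(all(pw3$p_bonferroni >= pw3$p))
})

test_that("PERMDISP distances equal betadisper's, including imaginary axes", {
  # Euclidean geometry: z is the plain distance to the group centroid
  Y <- withr::with_seed(6, matrix(stats::rnorm(24), 12, 2))
  rownames(Y) <- paste0("p", 1:12)
  g <- rep(c("A", "B"), each = 6)
  pd <- permdisp(euclid_dm(Y), g, n_perm = 99, seed = 1)
  zref <- numeric(12)
  for (l in c("A", "B")) {
    idx <- which(g == l)
    zref[idx] <- sqrt(rowSums(sweep(Y[idx, ], 2, colMeans(Y[idx, ]))^2))
  }
  expect_equal(unname(pd$distances), zref, tolerance = 1e-9)

  # non-Euclidean input: agreement with vegan::betadisper
  m <- random_table(10, 14, lambda = 4, seed = 8)
  db <- brayCurtis(m)
  g <- rep(c("A", "B"), each = 5)
  pd2 <- permdisp(db, g, n_perm = 99, seed = 2)
  bd <- vegan::betadisper(stats::as.dist(db), g, type = "centroid")
  expect_equal(unname(pd2$distances), unname(bd$distances), tolerance = 1e-8)
  expect_equal(pd2$F, unname(stats::anova(bd)$`F value`[1]), tolerance = 1e-8)

  # one tight vs one diffuse group
  Yt <- rbind(matrix(stats::rnorm(12, sd = 0.05), 6, 2),
              matrix(stats::rnorm(12, sd = 3), 6, 2))
  rownames(Yt) <- paste0("q", 1:12)
  pd3 <- permdisp(euclid_dm(Yt), rep(c("T", "D"), each = 6),
                  n_perm = 199, seed = 3)
  expect_gt(pd3$F, 5)
  expect_lt(pd3$p, 0.05)

  expect_error(permdisp(db, c("A", rep("B", 9)), n_perm = 9), ">= 2 samples")
})

test_that("ANOSIM R statistic matches rank arithmetic and vegan", {
  # perfect separation: all between-group ranks above within-group ranks
  dc <- matrix(5, 6, 6); diag(dc) <- 0
  dc[1:3, 1:3] <- 1; dc[4:6, 4:6] <- 1; diag(dc) <- 0
  dimnames(dc) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("A", "B"), each = 3)
  res <- anosimTest(dc, g, n_perm = 199, seed = 1)
  expect_equal(res$R, 1)

  for (s in 1:5) {
    db <- brayCurtis(random_table(9, 12, seed = s + 20))
    gg <- rep(c("A", "B", "C"), 3)
    mine <- anosimTest(db, gg, n_perm = 9, seed = s)
    veg <- vegan::anosim(stats::as.dist(db), gg, permutations = 9)
    expect_equal(mine$R, unname(veg$statistic), tolerance = 1e-9)
  }

  # random labels: R near zero in expectation over permutations
  db <- brayCurtis(random_table(12, 10, seed = 31))
  rs <- vapply(1:30, function(s) anosimTest(
    db, withr::with_seed(s, sample(rep(c("A", "B"), each = 6))),
    n_perm = 1, seed = s)$R, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("SIMPER contributions reconstruct mean Bray-Curtis dissimilarity", {
  m <- random_table(8, 10, seed = 12)
  g <- rep(c("A", "B"), each = 4)
  sp <- simperAnalysis(m, g)
  db <- brayCurtis(m)
  between <- db[1:4, 5:8]
  expect_equal(sp[["A vs B"]]$overall_dissimilarity, mean(between) * 100,
               tolerance = 1e-9)
  expect_true(all(sp[["A vs B"]]$contributions$contribution >= 0))
  expect_equal(max(sp[["A vs B"]]$contributions$cumulative),
               sp[["A vs B"]]$overall_dissimilarity, tolerance = 1e-9)

  # agreement with vegan::simper per-species averages (one-way)
  rel <- m / rowSums(m)
  vs <- withr::with_seed(1, vegan::simper(rel, g, permutations = 0))
  va <- vs$A_B$average[match(sp[["A vs B"]]$contributions$taxon,
                             vs$A_B$species)]
  expect_equal(sp[["A vs B"]]$contributions$contribution, unname(va) * 100,
               tolerance = 1e-9)

  # two-way mode restricts pairs to matching crossed levels: hand 2x2 case
  m2 <- rbind(a1 = c(10, 0), a2 = c(5, 5), b1 = c(0, 10), b2 = c(5, 5))
  colnames(m2) <- c("x", "y")
  g2 <- c("A", "A", "B", "B")
  depth <- c("s", "d", "s", "d")
  sp2 <- simperAnalysis(m2, g2, crossed_factor = depth)
  # admissible pairs: (a1,b1) with contribution (100,100)/2 and (a2,b2) = 0
  expect_equal(sp2[["A vs B"]]$overall_dissimilarity, 50)
  expect_equal(unname(sort(sp2[["A vs B"]]$contributions$contribution,
                           decreasing = TRUE)), c(25, 25))

  # single informative taxon carries all of the dissimilarity
  m3 <- rbind(u = c(10, 10), v = c(2, 10))
  colnames(m3) <- c("x", "y")
  sp3 <- simperAnalysis(m3, c("U", "V"))
  ctr <- sp3[["U vs V"]]$contributions
  expect_equal(ctr$contribution[1] / sum(ctr$contribution), 0.5, tolerance = 1e-9)
})

test_that("distance decay uses ordered pairs and degenerate inputs vanish", {
  m <- random_table(5, 10, seed = 14)
  db <- brayCurtis(m)
  geo <- euclid_dm(withr::with_seed(2, matrix(stats::rnorm(10), 5, 2)))
  dimnames(geo) <- dimnames(db)
  dd <- distanceDecay(db, geo)
  expect_equal(dd$n_points, 20)
  expect_equal(dd$df, c(1, 18))
  # oracle: plain lm on the expanded ordered pairs
  off <- row(db) != col(db)
  fit <- stats::lm((1 - db[off]) ~ geo[off])
  expect_equal(dd$slope, unname(stats::coef(fit)[2]), tolerance = 1e-12)
  expect_equal(dd$r_squared, summary(fit)$r.squared, tolerance = 1e-12)

  # constant similarity: slope and R2 collapse to zero
  dconst <- matrix(0.5, 5, 5); diag(dconst) <- 0
  dimnames(dconst) <- dimnames(db)
  ddc <- distanceDecay(dconst, geo)
  expect_equal(ddc$r_squared, 0)
  expect_error(distanceDecay(db[1:2, 1:2], geo[1:2, 1:2]), ">= 3")
})
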