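make_group_dm <- function(n_per = 3, gap = 1) {
  # two groups; within-distances ~ U(0, .2), between ~ U(.2, .2 + gap)
  n <- 2 * n_per
  lab <- rep(c("g1", "g2"), each = n_per)
  v <- matrix(0, n, n, dimnames = list(sprintf("S%d", 1:n), sprintf("S%d", 1:n)))
  for (i in 2:n) for (j in 1:(i - 1)) {
    v[i, j] <- v[j, i] <- if (lab[i] == lab[j]) runif(1, 0, 0.2)
    else runif(1, 0.2001, min(1, 0.2 + gap))
  }
  list(dm = dist_matrix(v, "bray_curtis"), labels = lab)
}

test_that("ANOSIM R is 1 under perfect separation and 0 for constant distances", {
  set.seed(5)
  g <- make_group_dm()
  res <- anosim_test(g$dm, g$labels, n_permutations = 99, seed = 1)
  expect_equal(res$R, 1.0)

  v <- matrix(0.5, 6, 6, dimnames = list(sprintf("S%d", 1:6), sprintf("S%d", 1:6)))
  diag(v) <- 0
  res0 <- anosim_test(dist_matrix(v, "bray_curtis"), rep(c("a", "b"), each = 3),
                      n_permutations = 99, seed = 1)
  expect_equal(res0$R, 0)
  expect_equal(res0$p, 1)
})

test_that("ANOSIM validates groups and is reproducible under a seed", {
  set.seed(2)
  g <- make_group_dm(gap = 0.1)
  expect_error(anosim_test(g$dm, c("a", "a", "a", "a", "a", "b")), "singleton")
  expect_error(anosim_test(g$dm, rep("a", 6)), "2 groups")
  r1 <- anosim_test(g$dm, g$labels, n_permutations = 199, seed = 42)
  r2 <- anosim_test(g$dm, g$labels, n_permutations = 199, seed = 42)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 200)  # add-one estimator floor
})

test_that("ANOSIM R agrees with vegan and is rank-invariant", {
  set.seed(9)
  tab <- random_table(8, 30, seed = 9)
  dm <- distance_matrix(tab, "bray_curtis")
  lab <- rep(c("x", "y"), each = 4)
  ours <- anosim_test(dm, lab, n_permutations = 99, seed = 1)
  ref <- vegan::anosim(stats::as.dist(dm$values), grouping = factor(lab),
                       permutations = 19)
  expect_equal(ours$R, unname(ref$statistic), tolerance = 1e-12)

  # invariance under a strictly monotone transform of the distances
  v2 <- sqrt(dm$values)
  ours2 <- anosim_test(dist_matrix(v2, "bray_curtis"), lab,
                       n_permutations = 99, seed = 1)
  expect_equal(ours2$R, ours$R, tolerance = 1e-12)
})

test_that("exact ANOSIM p matches brute-force enumeration for two groups of 3", {
  set.seed(77)
  g <- make_group_dm(gap = 0.05)
  res <- anosim_test(g$dm, g$labels, exact = TRUE)
  expect_equal(res$n_permutations, choose(6, 3))  # 20 distinct label sequences

  # independent oracle: choose the positions of group 1 via combn and
  # recompute the rank statistic from scratch
  v <- g$dm$values
  lt <- lower.tri(v)
  r <- rank(v[lt]); ii <- row(v)[lt]; jj <- col(v)[lt]
  m_half <- length(r) / 2
  combos <- combn(6, 3)
  r_all <- apply(combos, 2, function(idx) {
    lab <- rep("g2", 6); lab[idx] <- "g1"
    w <- lab[ii] == lab[jj]
    (mean(r[!w]) - mean(r[w])) / m_half
  })
  obs <- r_all[1]  # combn lists 1,2,3 (the true grouping) first
  p_exact <- mean(r_all >= obs - 1e-12)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("NMDS embeds planar geometry exactly and is deterministic", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1), 3, byrow = TRUE)
  v <- as.matrix(stats::dist(pts)) / 2  # scale into [0,1]
  dimnames(v) <- list(c("a", "b", "c"), c("a", "b", "c"))
  dm <- dist_matrix(v, "bray_curtis")
  fit <- nmds_embed(dm, dims = 2, seed = 3, n_starts = 5)
  expect_lt(fit$stress, 1e-6)
  expect_gt(fit$r2, 1 - 1e-6)

  fit2 <- nmds_embed(dm, dims = 2, seed = 3, n_starts = 5)
  expect_identical(fit$coordinates, fit2$coordinates)
  expect_error(nmds_embed(dm, dims = 3), "dims")
})

test_that("NMDS stress does not increase with embedding dimension", {
  set.seed(21)
  for (i in 1:3) {
    tab <- random_table(9, 40, seed = 100 + i)
    dm <- distance_matrix(tab, "bray_curtis")
    s1 <- nmds_embed(dm, dims = 1, seed = 1, n_starts = 8)$stress
    s2 <- nmds_embed(dm, dims = 2, seed = 1, n_starts = 8)$stress
    expect_lte(s2, s1 + 1e-8)
  }
})

test_that("cluster assignment covers the degenerate cases and planted systems", {
  set.seed(3)
  g <- make_group_dm(n_per = 4)
  expect_equal(unname(assign_clusters(g$dm, 1)), rep(1L, 8))
  expect_equal(sort(unname(assign_clusters(g$dm, 8))), 1:8)
  two <- assign_clusters(g$dm, 2)
  expect_equal(length(unique(two[1:4])), 1L)
  expect_equal(length(unique(two[5:8])), 1L)
  expect_false(two[1] == two[5])
  expect_error(assign_clusters(g$dm, 9), "1..n")

  # planted two-system synthetic data: k = 2 average-linkage clusters on
  # Bray-Curtis recover the system membership
  ds <- small_synth(seed = 4)
  dm <- distance_matrix(ds$table, "bray_curtis")
  cl <- assign_clusters(dm, 2)
  sys <- ds$metadata$category[match(names(cl), ds$metadata$sample_id)] == "WWTP-AD"
  expect_true(all(table(cl, sys) %in% c(0, table(sys))))
})

test_that("Kruskal-Wallis matches hand calculation and the tie-corrected oracle", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$H, 27 / 7, tolerance = 1e-12)
  expect_equal(res$df, 1)

  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)  # identical groups

  # tie-corrected oracle on tied data
  groups <- list(c(1, 2, 2, 5), c(2, 3, 3), c(5, 5, 1))
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h_raw <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  h <- h_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskal_wallis(groups)$H, h, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Wilcoxon signed rank drops zero differences and reports W", {
  # 5 pairs, all differences positive: W = 15 is maximal
  res <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(res$W, 15)
  expect_equal(res$n_used, 5)

  # symmetric +/- differences of equal magnitude: W = half the total rank sum
  res2 <- wilcoxon_signed_rank(c(5, 1, 6, 2), c(1, 5, 2, 6))
  expect_equal(res2$W, sum(1:4) / 2)

  res3 <- wilcoxon_signed_rank(c(1, 2, 5), c(1, 2, 3))  # zero diffs dropped
  expect_equal(res3$n_used, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("Spearman matrix handles monotone, missing and constant inputs", {
  params <- data.frame(up = 1:8, down = 8:1, flat = rep(2, 8))
  features <- data.frame(div = (1:8)^2)
  out <- spearman_matrix(params, features)
  expect_equal(out$rho[out$param == "up"], 1)
  expect_equal(out$rho[out$param == "down"], -1)
  expect_true(is.na(out$rho[out$param == "flat"]))
  expect_true(out$significant[out$param == "up"])

  # pairwise deletion with reported n
  params$up[c(2, 5)] <- NA
  out2 <- spearman_matrix(params, features)
  expect_equal(out2$n_used[out2$param == "up"], 6)

  # tied data: rho equals rank-then-Pearson oracle
  x <- c(1, 2, 2, 4, 7, 7, 7, 9)
  y <- c(3, 3, 5, 1, 8, 8, 2, 9)
  out3 <- spearman_matrix(data.frame(x = x), data.frame(y = y))
  expect_equal(out3$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
})
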