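# Distance-based group statistics (ANOSIM, NMDS ordination, agglomerative
# cluster assignment) and the univariate tests and correlations used to
# compare clusters and covariates (Kruskal-Wallis, Wilcoxon signed rank,
# Spearman).

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities exceed
#' within-group dissimilarities. All M = n(n-1)/2 distances are ranked with
#' mid-ranks for ties and R = (mean between-group rank - mean within-group
#' rank) / (M/2), so R = 1 when every between-group distance exceeds every
#' within-group distance and R = 0 when ranks are exchangeable (e.g. a
#' constant matrix). The p-value permutes whole-sample labels and uses the
#' add-one estimator (1 + #{R* >= R}) / (1 + n_permutations); with
#' \code{exact = TRUE} all distinct label assignments are enumerated instead
#' and p is the exact tail fraction.
#'
#' @param dm a \code{dist_matrix} (or square symmetric matrix).
#' @param labels per-sample group labels (>= 2 groups, each >= 2 samples).
#' @param n_permutations number of random permutations (ignored when exact).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all distinct label assignments (small n only).
#' @return list(R, p, n_permutations, seed, exact).
#' @export
anosim_test <- function(dm, labels, n_permutations = 999L, seed = 1L,
                        exact = FALSE) {
  v <- if (inherits(dm, "dist_matrix")) dm$values else as.matrix(dm)
  n <- nrow(v)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required", call. = FALSE)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2L], collapse = ", "),
         call. = FALSE)
  }
  lt <- lower.tri(v)
  ii <- row(v)[lt]
  jj <- col(v)[lt]
  r <- rank(v[lt])  # mid-ranks for ties
  m_half <- length(r) / 2
  stat <- function(lab) {
    w <- lab[ii] == lab[jj]
    (mean(r[!w]) - mean(r[w])) / m_half
  }
  r_obs <- stat(labels)
  if (exact) {
    perms <- multiset_permutations(labels)
    r_perm <- apply(perms, 1L, stat)
    p <- mean(r_perm >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    r_perm <- with_seed(seed, {
      replicate(n_permutations, stat(sample(labels)))
    })
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_permutations)
    n_used <- n_permutations
  }
  list(R = r_obs, p = p, n_permutations = n_used, seed = seed, exact = exact)
}

# All distinct permutations of a label multiset, one per row. Guarded by a
# hard cap since the count grows multinomially.
#' @noRd
multiset_permutations <- function(labels, cap = 200000L) {
  lev <- unique(labels)
  counts <- as.integer(table(factor(labels, levels = lev)))
  total <- exp(lgamma(length(labels) + 1) - sum(lgamma(counts + 1)))
  if (total > cap) {
    stop("too many distinct permutations (", format(round(total)),
         ") for exact enumeration", call. = FALSE)
  }
  n <- length(labels)
  out <- matrix(NA_character_, nrow = round(total), ncol = n)
  row_i <- 0L
  current <- character(n)
  recurse <- function(pos, remaining) {
    if (pos > n) {
      row_i <<- row_i + 1L
      out[row_i, ] <<- current
      return(invisible())
    }
    for (k in seq_along(lev)) {
      if (remaining[k] > 0L) {
        current[pos] <<- lev[k]
        remaining[k] <- remaining[k] - 1L
        recurse(pos + 1L, remaining)
        remaining[k] <- remaining[k] + 1L
      }
    }
  }
  recurse(1L, counts)
  out
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal's monotone-regression stress minimisation (via
#' \code{vegan::monoMDS}, stress-1) from multiple starts: the first start is
#' the classical metric scaling solution, the remaining are random
#' configurations; the lowest-stress configuration is returned. \code{r2} is
#' the squared Pearson correlation between the ordination distances and the
#' original dissimilarities (the "linear fit" of a Shepard diagram).
#'
#' @param dm a \code{dist_matrix}.
#' @param dims embedding dimension (>= 1, < number of samples).
#' @param seed RNG seed; the same seed reproduces the same configuration.
#' @param n_starts number of starting configurations.
#' @return list(coordinates, stress, r2, converged, seed).
#' @export
nmds_embed <- function(dm, dims = 2L, seed = 1L, n_starts = 10L) {
  stopifnot(inherits(dm, "dist_matrix"))
  n <- nrow(dm$values)
  if (dims < 1L || dims >= n) {
    stop("'dims' must satisfy 1 <= dims < n_samples", call. = FALSE)
  }
  d <- stats::as.dist(dm$values)
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(max(1L, n_starts))) {
      init <- if (s == 1L) {
        stats::cmdscale(d, k = dims)
      } else {
        matrix(stats::runif(n * dims, -1, 1), n, dims)
      }
      fit <- vegan::monoMDS(d, y = init, k = dims, model = "global")
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    coords <- best$points
    rownames(coords) <- rownames(dm$values)
    odist <- stats::dist(coords)
    r2 <- stats::cor(as.vector(odist), as.vector(d))^2
    list(coordinates = coords, stress = best$stress, r2 = r2,
         converged = best$iters < best$maxits, seed = seed)
  })
}

#' Agglomerative cluster assignment on a distance matrix
#'
#' Average- or complete-linkage hierarchical clustering cut at k groups; a
#' reproducible stand-in for visually delineated ordination clusters,
#' deterministic given the distance matrix.
#'
#' @param dm a \code{dist_matrix}.
#' @param k number of clusters (1 <= k <= n).
#' @param linkage "average" or "complete".
#' @return Named integer vector of cluster labels per sample.
#' @export
assign_clusters <- function(dm, k, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(dm, "dist_matrix"))
  n <- nrow(dm$values)
  if (k < 1L || k > n) stop("'k' must lie in 1..n", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dm$values), method = linkage)
  stats::cutree(hc, k = k)
}

#' Kruskal-Wallis rank sum test
#'
#' Mid-rank, tie-corrected H statistic with a chi-square p-value on
#' (number of groups - 1) degrees of freedom (via \code{stats::kruskal.test}).
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return list(H, df, p).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(x, g)
  list(H = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Wilcoxon signed rank test for paired samples
#'
#' Zero differences are dropped before ranking; W is the sum of
#' positive-difference ranks; the two-sided p-value uses the normal
#' approximation with optional continuity correction (via
#' \code{stats::wilcox.test}).
#'
#' @param x,y paired numeric vectors of equal length.
#' @param continuity apply the continuity correction (default TRUE).
#' @return list(W, n_used, p).
#' @export
wilcoxon_signed_rank <- function(x, y, continuity = TRUE) {
  if (length(x) != length(y)) stop("paired vectors differ in length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) stop("all differences are zero: no test possible", call. = FALSE)
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = FALSE, correct = continuity)
  )
  list(W = unname(ht$statistic), n_used = length(d), p = ht$p.value)
}

#' Spearman correlation matrix between covariates and community features
#'
#' For every covariate x feature pair, Spearman's rho (Pearson correlation of
#' mid-ranks) with a two-sided p-value; missing values are deleted pairwise
#' and the number of complete pairs reported. Constant vectors leave rho
#' undefined (NA, flagged). Benjamini-Hochberg adjustment across cells is
#' available but off by default (unadjusted p <= alpha is the reported
#' significance rule).
#'
#' @param params data.frame of per-sample covariates (same row order as
#'   \code{features}).
#' @param features data.frame of per-sample abundances or diversity values.
#' @param alpha significance level (default 0.05).
#' @param adjust "none" or "BH".
#' @return data.frame(param, feature, n_used, rho, p, significant).
#' @export
spearman_matrix <- function(params, features, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  params <- as.data.frame(params)
  features <- as.data.frame(features)
  if (nrow(params) != nrow(features)) {
    stop("'params' and 'features' must have the same rows", call. = FALSE)
  }
  grid <- expand.grid(param = names(params), feature = names(features),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- params[[grid$param[i]]]
    y <- features[[grid$feature[i]]]
    ok <- stats::complete.cases(x, y)
    n_used <- sum(ok)
    if (n_used < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(grid[i, ], n_used = n_used, rho = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ht <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
    )
    data.frame(grid[i, ], n_used = n_used, rho = unname(ht$estimate),
               p = ht$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p <= alpha
  rownames(out) <- NULL
  out
}
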