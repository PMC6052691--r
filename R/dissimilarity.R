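# Pairwise community dissimilarities (Bray-Curtis for structure, Jaccard for
# membership) and their use as temporal-stability measures within reactors or
# clusters.

#' Bray-Curtis dissimilarity between two samples
#'
#' sum(|x_i - y_i|) / sum(x_i + y_i); abundance-weighted, in [0, 1].
#'
#' @param x,y non-negative count or abundance vectors of equal length.
#' @return Dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("negative abundances", call. = FALSE)
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both samples empty: Bray-Curtis undefined", call. = FALSE)
  sum(abs(x - y)) / tot
}

#' Jaccard dissimilarity between two samples
#'
#' Presence/absence (detection = count >= 1) membership difference:
#' 1 - |intersection| / |union|. Invariant to positive rescaling of counts.
#'
#' @param x,y non-negative count vectors of equal length.
#' @return Dissimilarity in [0, 1].
#' @export
jaccard_dissimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("negative abundances", call. = FALSE)
  a <- x > 0
  b <- y > 0
  union <- sum(a | b)
  if (union == 0) stop("both samples empty: Jaccard undefined", call. = FALSE)
  1 - sum(a & b) / union
}

#' All-pairs distance matrix for a count table
#'
#' Pairwise Bray-Curtis or Jaccard dissimilarities over samples, computed with
#' \code{vegan::vegdist} (Jaccard on presence/absence, i.e. vegan's binary
#' Jaccard, which equals 1 - |intersection|/|union|).
#'
#' @param table a \code{count_table} with >= 2 samples.
#' @param metric "bray_curtis" or "jaccard".
#' @return A \code{dist_matrix}.
#' @export
distance_matrix <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  if (nrow(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[totals == 0], collapse = ", "), call. = FALSE)
  }
  d <- if (metric == "bray_curtis") {
    vegan::vegdist(m, method = "bray")
  } else {
    vegan::vegdist(m, method = "jaccard", binary = TRUE)
  }
  v <- as.matrix(d)
  diag(v) <- 0
  dist_matrix(v, metric = metric)
}

#' Temporal stability of communities within groups
#'
#' Summarises within-group dissimilarities as a stability measure: lower mean
#' dissimilarity means a more stable community. Groups are reactors (from
#' metadata) or externally supplied cluster labels; samples within a group are
#' ordered by timepoint. \code{scheme = "all_pairs"} uses every within-group
#' pair, \code{"consecutive"} only month-to-month pairs (t, t+1).
#'
#' @param table a \code{count_table}.
#' @param metadata metadata data.frame covering the table's samples.
#' @param metric "bray_curtis" or "jaccard".
#' @param scheme pair construction scheme.
#' @param group_by "reactor" or "cluster".
#' @param cluster_labels named per-sample labels, required when
#'   \code{group_by = "cluster"}.
#' @return data.frame(group, metric, scheme, n_samples, n_pairs, mean, sd,
#'   ci_lower, ci_upper); groups with a single sample are skipped with a
#'   warning.
#' @export
temporal_stability <- function(table, metadata,
                               metric = c("bray_curtis", "jaccard"),
                               scheme = c("all_pairs", "consecutive"),
                               group_by = c("reactor", "cluster"),
                               cluster_labels = NULL) {
  metric <- match.arg(metric)
  scheme <- match.arg(scheme)
  group_by <- match.arg(group_by)
  stopifnot(inherits(table, "count_table"))
  ids <- sample_ids(table)
  md <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(md$sample_id)) {
    stop("metadata missing for sample(s): ",
         paste(ids[is.na(md$sample_id)], collapse = ", "), call. = FALSE)
  }
  groups <- if (group_by == "reactor") {
    md$reactor
  } else {
    if (is.null(cluster_labels)) {
      stop("'cluster_labels' required when group_by = \"cluster\"", call. = FALSE)
    }
    as.character(cluster_labels[ids])
  }
  dm <- distance_matrix(table, metric)$values
  out <- lapply(unique(groups), function(g) {
    members <- ids[groups == g]
    if (length(members) < 2L) {
      warning("group '", g, "' has a single sample; skipped", call. = FALSE)
      return(NULL)
    }
    members <- members[order(md$timepoint[match(members, ids)])]
    vals <- if (scheme == "consecutive") {
      vapply(seq_len(length(members) - 1L),
             function(i) dm[members[i], members[i + 1L]], numeric(1))
    } else {
      dm[members, members][lower.tri(diag(length(members)))]
    }
    n <- length(vals)
    s <- if (n > 1L) stats::sd(vals) else NA_real_
    half <- if (n > 1L) stats::qt(0.975, n - 1L) * s / sqrt(n) else NA_real_
    data.frame(group = g, metric = metric, scheme = scheme,
               n_samples = length(members), n_pairs = n,
               mean = mean(vals), sd = s,
               ci_lower = mean(vals) - half, ci_upper = mean(vals) + half,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
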