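# Alpha-diversity surface: observed richness (sobs), inverse Simpson
# diversity, inverse-Simpson evenness, rarefaction curves and rank-abundance
# curves. All indices are meant to be computed on the depth-normalised
# (subsampled) table so they are comparable across samples.

check_counts <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
}

#' Observed richness (sobs)
#'
#' @param counts one sample's count vector.
#' @return Number of OTUs with count >= 1.
#' @export
richness_sobs <- function(counts) {
  check_counts(counts)
  sum(counts >= 1L)
}

#' Inverse Simpson diversity
#'
#' The reciprocal of the probability that two randomly drawn reads belong to
#' the same OTU. \code{mode = "mle"} uses plug-in proportions, 1 / sum(p_i^2);
#' \code{mode = "unbiased"} (default, the finite-sample estimator of the
#' mothur invsimpson calculator) uses N(N-1) / sum(n_i (n_i - 1)). The
#' unbiased form is undefined when every OTU is a singleton, in which case
#' \code{Inf} is returned with a warning (never a spurious finite value).
#'
#' @param counts one sample's count vector.
#' @param mode estimator variant.
#' @return Diversity value >= 1 (or Inf when undefined, see above).
#' @export
inverse_simpson <- function(counts, mode = c("unbiased", "mle")) {
  mode <- match.arg(mode)
  check_counts(counts)
  n <- sum(counts)
  if (mode == "mle") {
    if (n < 1) stop("need at least 1 read", call. = FALSE)
    p <- counts / n
    1 / sum(p^2)
  } else {
    if (n < 2) stop("unbiased estimator needs at least 2 reads", call. = FALSE)
    denom <- sum(counts * (counts - 1))
    if (denom == 0) {
      warning("all OTUs are singletons; unbiased inverse Simpson undefined",
              call. = FALSE)
      return(Inf)
    }
    n * (n - 1) / denom
  }
}

#' Inverse-Simpson evenness
#'
#' The mothur invsimpsoneven coefficient: inverse Simpson (plug-in form)
#' divided by observed richness. Ranges over (0, 1]; equals 1 iff reads are
#' spread uniformly over the present OTUs. The plug-in (mle) diversity is used
#' here because the ratio of the finite-sample estimator to richness can
#' exceed 1, breaking the documented 0-1 scale.
#'
#' @param counts one sample's count vector.
#' @return Evenness in (0, 1].
#' @export
evenness_invsimpson <- function(counts) {
  check_counts(counts)
  s <- richness_sobs(counts)
  if (s == 0) stop("empty sample: evenness undefined", call. = FALSE)
  inverse_simpson(counts, mode = "mle") / s
}

#' Rarefaction curve for one sample
#'
#' Expected richness at a series of subsampling depths. The analytic form is
#' the hypergeometric expectation E[S_d] = sum_j (1 - choose(N - n_j, d) /
#' choose(N, d)); the resampling form averages observed richness over repeated
#' without-replacement draws. At d = N both recover the observed richness.
#'
#' @param counts one sample's count vector.
#' @param depths integer depths, each <= sum(counts).
#' @param method "analytic" or "resample".
#' @param reps resampling repetitions (resample method).
#' @param seed RNG seed (resample method).
#' @return data.frame(depth, expected_richness[, sd]).
#' @export
rarefaction_curve <- function(counts, depths, method = c("analytic", "resample"),
                              reps = 100L, seed = 1L) {
  method <- match.arg(method)
  check_counts(counts)
  n_total <- sum(counts)
  if (any(depths < 1) || any(depths != round(depths))) {
    stop("depths must be positive integers", call. = FALSE)
  }
  if (any(depths > n_total)) {
    stop("depth exceeds sample total ", n_total, call. = FALSE)
  }
  nz <- counts[counts > 0]
  if (method == "analytic") {
    es <- vapply(depths, function(d) {
      # log-space hypergeometric absence probabilities for numerical stability
      sum(1 - exp(lchoose(n_total - nz, d) - lchoose(n_total, d)))
    }, numeric(1))
    data.frame(depth = as.integer(depths), expected_richness = es)
  } else {
    sims <- with_seed(seed, {
      vapply(depths, function(d) {
        draws <- replicate(reps, sum(rmvhyper(nz, d) > 0L))
        c(mean(draws), stats::sd(draws))
      }, numeric(2))
    })
    data.frame(depth = as.integer(depths), expected_richness = sims[1L, ],
               sd = sims[2L, ])
  }
}

#' Rank-abundance curves
#'
#' Per-sample relative abundances of present OTUs sorted in descending order,
#' ties broken by OTU id so the ranking is deterministic.
#'
#' @param table a \code{count_table} with positive sample totals.
#' @return data.frame(sample_id, rank, otu_id, relative_abundance), present
#'   OTUs only.
#' @export
rank_abundance <- function(table) {
  rel <- to_relative(table)
  out <- lapply(rownames(rel), function(s) {
    v <- rel[s, ]
    v <- v[v > 0]
    ord <- order(-v, names(v))
    data.frame(sample_id = s, rank = seq_along(ord), otu_id = names(v)[ord],
               relative_abundance = unname(v[ord]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-sample diversity table
#'
#' sobs, inverse Simpson (unbiased), inverse-Simpson evenness and reads used,
#' one row per sample.
#'
#' @param table a \code{count_table} (normally the subsampled table).
#' @return data.frame(sample_id, depth, sobs, invsimpson, evenness).
#' @export
diversity_table <- function(table) {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  data.frame(
    sample_id = rownames(m),
    depth = as.integer(rowSums(m)),
    sobs = apply(m, 1L, richness_sobs),
    invsimpson = apply(m, 1L, inverse_simpson),
    evenness = apply(m, 1L, evenness_invsimpson),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
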