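# Bring raw count tables to the analysis state: singleton-filtered,
# subsampled to a fixed per-sample depth, and convertible to relative
# abundances.

#' Remove OTUs below a total-count threshold
#'
#' OTUs whose summed count across all samples is below \code{min_total} are
#' dropped; with the default of 2 this removes global singletons, keeping only
#' OTUs represented by more than one read. The sample set is unchanged.
#'
#' @param table a \code{count_table}.
#' @param min_total minimum total count (>= 1) for an OTU to be kept.
#' @return A filtered \code{count_table}.
#' @export
filter_low_count_otus <- function(table, min_total = 2L) {
  stopifnot(inherits(table, "count_table"))
  stop_if_not_scalar_number(min_total, "min_total")
  if (min_total < 1) stop("'min_total' must be >= 1", call. = FALSE)
  keep <- colSums(table$counts) >= min_total
  count_table(table$counts[, keep, drop = FALSE],
              domain = table$domain, label = table$label)
}

#' Subsample every sample to a fixed depth
#'
#' Rarefaction in the sense of mothur's \code{normalize.shared}: each sample
#' is drawn without replacement from its own reads (multivariate
#' hypergeometric), so subsampled counts never exceed the originals and each
#' retained sample sums exactly to \code{depth}. Samples whose total is below
#' \code{depth} are dropped with a warning when \code{drop_below_depth} is
#' set. Each sample uses its own RNG substream derived as \code{seed +
#' sample index}, so removing one sample never changes another sample's draw.
#'
#' @param table a \code{count_table}.
#' @param depth target reads per sample (> 0).
#' @param seed integer seed; the same seed reproduces the same table.
#' @param drop_below_depth drop samples with fewer than \code{depth} reads
#'   (TRUE, default) instead of erroring.
#' @return A subsampled \code{count_table}; attribute \code{"dropped_samples"}
#'   lists any samples removed for insufficient depth.
#' @export
subsample <- function(table, depth, seed = 1L, drop_below_depth = TRUE) {
  stopifnot(inherits(table, "count_table"))
  stop_if_not_scalar_number(depth, "depth")
  if (depth <= 0) stop("'depth' must be > 0", call. = FALSE)
  depth <- as.integer(depth)
  totals <- rowSums(table$counts)
  low <- totals < depth
  if (all(low)) stop("all samples are below depth ", depth, call. = FALSE)
  if (any(low)) {
    if (!drop_below_depth) {
      stop("samples below depth ", depth, ": ",
           paste(sample_ids(table)[low], collapse = ", "), call. = FALSE)
    }
    warning(sum(low), " sample(s) below depth ", depth, " dropped: ",
            paste(sample_ids(table)[low], collapse = ", "), call. = FALSE)
  }
  m <- table$counts
  out <- matrix(0L, nrow = sum(!low), ncol = ncol(m),
                dimnames = list(rownames(m)[!low], colnames(m)))
  # draw in canonical OTU-id order so the result is equivariant under
  # reordering of the table's columns
  ord <- order(colnames(m))
  keep_idx <- which(!low)
  for (k in seq_along(keep_idx)) {
    i <- keep_idx[k]
    if (totals[i] == depth) {
      out[k, ] <- m[i, ]  # exhaustive draw: counts unchanged
    } else {
      out[k, ord] <- with_seed(seed + i, rmvhyper(m[i, ord], depth))
    }
  }
  res <- count_table(out, domain = table$domain, label = table$label)
  attr(res, "dropped_samples") <- rownames(m)[low]
  res
}

# Multivariate hypergeometric draw: k reads without replacement from an urn
# with counts n. Sequential conditional univariate hypergeometrics.
#' @noRd
rmvhyper <- function(n, k) {
  out <- integer(length(n))
  remaining <- sum(n)
  todo <- k
  for (j in which(n > 0L)) {
    if (todo == 0L) break
    x <- stats::rhyper(1L, n[j], remaining - n[j], todo)
    out[j] <- x
    todo <- todo - x
    remaining <- remaining - n[j]
  }
  out
}

#' Convert counts to relative abundances
#'
#' @param table a \code{count_table} (all sample totals > 0).
#' @return Numeric matrix of proportions, same dimnames as the counts; each
#'   row sums to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "count_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(sample_ids(table)[totals == 0], collapse = ", "), call. = FALSE)
  }
  sweep(table$counts, 1L, totals, "/")
}
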