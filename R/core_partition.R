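# Occurrence-based core/transient partitioning of OTUs: the central procedure
# of the pipeline. Within a sample scope, an OTU occurring in more than
# core_min_occurrence of samples is core; one present in fewer than
# transient_max_occurrence (but at least once) is transient; everything else
# detected in the scope is intermediate. OTUs never detected in the scope are
# excluded from the partition universe.

#' Per-OTU occurrence fractions within a sample scope
#'
#' Occurrence = (number of scope samples where the OTU reaches
#' \code{detection_min_count} reads) / |scope|.
#'
#' @param table a \code{count_table}.
#' @param scope character vector of sample ids (default: all samples).
#' @param detection_min_count minimum reads for an OTU to count as present.
#' @return Named numeric vector over all table OTUs, values in [0, 1].
#' @export
occurrence_fractions <- function(table, scope = NULL, detection_min_count = 1L) {
  stopifnot(inherits(table, "count_table"))
  scope <- scope %||% sample_ids(table)
  if (length(scope) == 0L) stop("empty scope", call. = FALSE)
  unknown <- setdiff(scope, sample_ids(table))
  if (length(unknown)) {
    stop("scope samples not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  m <- table$counts[scope, , drop = FALSE]
  colSums(m >= detection_min_count) / length(scope)
}

#' Partition OTUs into core / intermediate / transient
#'
#' Threshold semantics follow a strict reading of "over 80\%" and "less than
#' 20\%": core iff occurrence > \code{core_min_occurrence}, transient iff
#' 0 < occurrence < \code{transient_max_occurrence}; occurrences exactly on a
#' boundary are intermediate. OTUs with zero occurrence in the scope are not
#' part of the partition universe.
#'
#' @param table a \code{count_table}.
#' @param scope sample ids defining the occurrence denominator (default: all).
#' @param core_min_occurrence core threshold (exclusive), default 0.80.
#' @param transient_max_occurrence transient threshold (exclusive), default 0.20.
#' @param detection_min_count minimum reads for presence, default 1.
#' @return An object of class \code{otu_partition}: list(scope, occurrence
#'   (detected OTUs only), assignment (factor core/intermediate/transient),
#'   thresholds, universe (all table OTUs)).
#' @export
partition_otus <- function(table, scope = NULL,
                           core_min_occurrence = 0.80,
                           transient_max_occurrence = 0.20,
                           detection_min_count = 1L) {
  if (!(transient_max_occurrence >= 0 && transient_max_occurrence < core_min_occurrence &&
        core_min_occurrence <= 1)) {
    stop("need 0 <= transient_max_occurrence < core_min_occurrence <= 1",
         call. = FALSE)
  }
  scope <- scope %||% sample_ids(table)
  occ <- occurrence_fractions(table, scope, detection_min_count)
  detected <- occ[occ > 0]
  assignment <- factor(
    ifelse(detected > core_min_occurrence, "core",
           ifelse(detected < transient_max_occurrence, "transient", "intermediate")),
    levels = c("core", "intermediate", "transient")
  )
  names(assignment) <- names(detected)
  structure(list(
    scope = scope,
    occurrence = detected,
    assignment = assignment,
    thresholds = list(core_min_occurrence = core_min_occurrence,
                      transient_max_occurrence = transient_max_occurrence,
                      detection_min_count = detection_min_count),
    universe = otu_ids(table)
  ), class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  tab <- table(x$assignment)
  cat(sprintf(
    "otu_partition over %d samples: %d core, %d intermediate, %d transient (of %d detected; thresholds >%.2f / <%.2f)\n",
    length(x$scope), tab[["core"]], tab[["intermediate"]], tab[["transient"]],
    length(x$occurrence), x$thresholds$core_min_occurrence,
    x$thresholds$transient_max_occurrence))
  invisible(x)
}

#' OTU ids carrying a given partition label
#'
#' @param partition an \code{otu_partition}.
#' @param label "core", "intermediate" or "transient".
#' @return Character vector of OTU ids.
#' @export
partition_members <- function(partition, label = c("core", "intermediate", "transient")) {
  label <- match.arg(label)
  names(partition$assignment)[partition$assignment == label]
}

#' Restrict a count table to an OTU set
#'
#' Counts and the sample set are untouched; only columns are selected. An
#' empty OTU set is allowed (degenerate zero-column table) and flagged with a
#' warning.
#'
#' @param table a \code{count_table}.
#' @param otu_set character vector of OTU ids, subset of the table's OTUs.
#' @return A \code{count_table} over \code{otu_set}.
#' @export
subset_table <- function(table, otu_set) {
  stopifnot(inherits(table, "count_table"))
  unknown <- setdiff(otu_set, otu_ids(table))
  if (length(unknown)) {
    stop("unknown OTU id(s): ", paste(utils::head(unknown, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (length(otu_set) == 0L) warning("empty OTU set: zero-column table", call. = FALSE)
  count_table(table$counts[, otu_set, drop = FALSE],
              domain = table$domain, label = table$label)
}

#' Read-abundance share of an OTU set
#'
#' Per sample, the fraction of reads carried by \code{otu_set}, plus the mean
#' and standard deviation over the scope samples.
#'
#' @param table a \code{count_table} with positive sample totals in scope.
#' @param otu_set character vector of OTU ids.
#' @param scope sample ids (default: all samples).
#' @return list(per_sample named vector, mean, sd, n).
#' @export
abundance_share <- function(table, otu_set, scope = NULL) {
  stopifnot(inherits(table, "count_table"))
  scope <- scope %||% sample_ids(table)
  unknown <- setdiff(otu_set, otu_ids(table))
  if (length(unknown)) {
    stop("unknown OTU id(s): ", paste(utils::head(unknown, 5L), collapse = ", "),
         call. = FALSE)
  }
  m <- table$counts[scope, , drop = FALSE]
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ", paste(scope[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  share <- if (length(otu_set) == 0L) {
    stats::setNames(rep(0, length(scope)), scope)
  } else {
    rowSums(m[, otu_set, drop = FALSE]) / totals
  }
  list(per_sample = share, mean = mean(share),
       sd = if (length(share) > 1L) stats::sd(share) else NA_real_,
       n = length(share))
}

#' Mean relative abundance over samples where an OTU is present
#'
#' The average abundance of the occurrence-abundance plots: for each OTU, the
#' mean of its relative abundances over only the samples where it has at
#' least one read. OTUs absent from every sample get NA (undefined), never 0.
#'
#' @param table a \code{count_table} with positive sample totals.
#' @param scope sample ids (default: all samples).
#' @return Named numeric vector over all table OTUs.
#' @export
mean_nonzero_abundance <- function(table, scope = NULL) {
  stopifnot(inherits(table, "count_table"))
  scope <- scope %||% sample_ids(table)
  sub <- count_table(table$counts[scope, , drop = FALSE],
                     domain = table$domain, label = table$label)
  rel <- to_relative(sub)
  present <- sub$counts >= 1L
  n_present <- colSums(present)
  means <- colSums(rel * present) / n_present
  means[n_present == 0] <- NA_real_
  means
}

#' Occurrence-abundance summary of a partition
#'
#' One row per OTU detected in the partition scope: occurrence fraction,
#' number of scope samples where present, mean non-zero relative abundance and
#' partition assignment. The attached \code{"occurrence_histogram"} attribute
#' gives, for each possible number of samples 1..|scope|, the percentage of
#' detected OTUs occurring in exactly that many samples (sums to 100).
#'
#' @param table a \code{count_table}.
#' @param partition an \code{otu_partition} built on this table.
#' @return data.frame(otu_id, occurrence, n_samples_present,
#'   mean_nonzero_abundance, assignment) with attribute
#'   \code{occurrence_histogram}.
#' @export
occurrence_abundance_summary <- function(table, partition) {
  stopifnot(inherits(table, "count_table"), inherits(partition, "otu_partition"))
  scope <- partition$scope
  unknown <- setdiff(scope, sample_ids(table))
  if (length(unknown)) {
    stop("partition scope not covered by table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  otus <- names(partition$occurrence)
  mna <- mean_nonzero_abundance(table, scope)[otus]
  n_present <- round(partition$occurrence * length(scope))
  out <- data.frame(
    otu_id = otus,
    occurrence = unname(partition$occurrence),
    n_samples_present = as.integer(n_present),
    mean_nonzero_abundance = unname(mna),
    assignment = as.character(partition$assignment[otus]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  bins <- seq_len(length(scope))
  hist <- 100 * tabulate(out$n_samples_present, nbins = length(scope)) / nrow(out)
  attr(out, "occurrence_histogram") <- data.frame(n_samples = bins,
                                                  percent_of_otus = hist)
  out
}

#' Overlap between two core sets
#'
#' Compares the core OTU sets of two partitions built from the same OTU
#' universe (e.g. the general AD-core versus a WWTP-only core).
#'
#' @param a,b \code{otu_partition} objects over the same table OTUs.
#' @return list(shared_core (ids), n_a, n_b, n_shared, n_union, jaccard).
#' @export
core_overlap <- function(a, b) {
  stopifnot(inherits(a, "otu_partition"), inherits(b, "otu_partition"))
  if (!setequal(a$universe, b$universe)) {
    stop("partitions built from different OTU universes", call. = FALSE)
  }
  ca <- partition_members(a, "core")
  cb <- partition_members(b, "core")
  shared <- intersect(ca, cb)
  un <- union(ca, cb)
  list(shared_core = shared, n_a = length(ca), n_b = length(cb),
       n_shared = length(shared), n_union = length(un),
       jaccard = if (length(un)) length(shared) / length(un) else NA_real_)
}
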