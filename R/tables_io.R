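# Reading, validating and writing the file formats the pipeline touches:
# mothur "shared" count tables, plain TSV count tables, SILVA-style taxonomy,
# sample metadata CSV and PHYLIP distance matrices.

AD_CATEGORIES <- c("farm", "bio-waste", "MSW", "WWTP-AD")
REACTOR_ROLES <- c("Fd", "Pd", "St")
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct an OTU count table
#'
#' The count table is the universal currency of the pipeline: a samples x OTUs
#' matrix of non-negative integer read counts, tagged with the amplicon domain
#' (bacteria or archaea) and a free-text label (e.g. the OTU-definition cutoff
#' "0.03").
#'
#' @param counts integer matrix, one row per sample, one column per OTU;
#'   rownames are sample ids, colnames are OTU ids.
#' @param domain "bacteria" or "archaea".
#' @param label free-text label carried through outputs.
#' @return An object of class \code{count_table}.
#' @export
count_table <- function(counts, domain = c("bacteria", "archaea"), label = "0.03") {
  domain <- match.arg(domain)
  if (!is.matrix(counts)) stop("'counts' must be a matrix", call. = FALSE)
  # R normalises empty dimnames to NULL, so only require ids on non-empty axes
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    stop("'counts' must carry sample ids as rownames and OTU ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate OTU id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, domain = domain, label = label),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs (%s, label %s), %s total reads\n",
              nrow(x$counts), ncol(x$counts), x$domain, x$label,
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

sample_ids <- function(table) rownames(table$counts)
otu_ids <- function(table) colnames(table$counts)

#' Read an OTU count table
#'
#' Supports the mothur shared dialect (tab-delimited; header row; first three
#' columns \code{label}, \code{Group}, \code{numOtus}, then one column per
#' OTU) and a plain TSV layout whose first column is the sample id.
#'
#' @param path file path.
#' @param format "shared" or "tsv".
#' @param domain amplicon domain tag attached to the result.
#' @return A \code{count_table}.
#' @export
read_count_table <- function(path, format = c("shared", "tsv"),
                             domain = c("bacteria", "archaea")) {
  format <- match.arg(format)
  domain <- match.arg(domain)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no data rows in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]

  if (format == "shared") {
    if (length(header) < 4L ||
        !identical(tolower(header[1:3]), c("label", "group", "numotus"))) {
      stop("not a shared file: header must start with label, Group, numOtus",
           call. = FALSE)
    }
    otus <- header[-(1:3)]
    n_otu <- length(otus)
    rows <- fields[-1L]
    if (any(lengths(rows) != n_otu + 3L)) {
      bad <- which(lengths(rows) != n_otu + 3L)[1L]
      stop(sprintf("parse error at line %d: expected %d fields, found %d",
                   bad + 1L, n_otu + 3L, length(rows[[bad]])), call. = FALSE)
    }
    declared <- vapply(rows, function(r) r[3L], character(1))
    if (any(suppressWarnings(as.integer(declared)) != n_otu)) {
      bad <- which(suppressWarnings(as.integer(declared)) != n_otu)[1L]
      stop(sprintf(
        "parse error at line %d: numOtus=%s inconsistent with %d OTU columns",
        bad + 1L, declared[bad], n_otu), call. = FALSE)
    }
    samples <- vapply(rows, function(r) r[2L], character(1))
    label <- rows[[1L]][1L]
    raw <- vapply(rows, function(r) r[-(1:3)], character(n_otu))
    counts <- t(matrix(suppressWarnings(as.numeric(raw)), nrow = n_otu))
  } else {
    otus <- header[-1L]
    n_otu <- length(otus)
    rows <- fields[-1L]
    if (any(lengths(rows) != n_otu + 1L)) {
      bad <- which(lengths(rows) != n_otu + 1L)[1L]
      stop(sprintf("parse error at line %d: expected %d fields, found %d",
                   bad + 1L, n_otu + 1L, length(rows[[bad]])), call. = FALSE)
    }
    samples <- vapply(rows, function(r) r[1L], character(1))
    label <- "0.03"
    raw <- vapply(rows, function(r) r[-1L], character(n_otu))
    counts <- t(matrix(suppressWarnings(as.numeric(raw)), nrow = n_otu))
  }

  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    bad <- which(apply(is.na(counts) | counts < 0 | counts != round(counts), 1L, any))[1L]
    stop(sprintf("validation error at line %d: non-integer or negative count",
                 bad + 1L), call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("validation error: duplicate sample ID ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(counts) <- list(samples, otus)
  count_table(counts, domain = domain, label = label)
}

#' Write an OTU count table
#'
#' @param table a \code{count_table}.
#' @param path output path.
#' @param format "shared" or "tsv".
#' @export
write_count_table <- function(table, path, format = c("shared", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  if (format == "shared") {
    header <- c("label", "Group", "numOtus", colnames(m))
    body <- cbind(table$label, rownames(m), ncol(m),
                  matrix(as.character(m), nrow = nrow(m)))
  } else {
    header <- c("sample_id", colnames(m))
    body <- cbind(rownames(m), matrix(as.character(m), nrow = nrow(m)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a SILVA-style taxonomy table
#'
#' Expects a TSV with columns \code{otu_id} and a semicolon-delimited lineage,
#' each rank optionally carrying a bootstrap confidence, e.g.
#' \code{"Bacteria(100);Firmicutes(99);"}. Missing trailing ranks are allowed.
#'
#' @param path file path.
#' @return data.frame with otu_id, one column per rank (domain..genus) and one
#'   \code{<rank>_conf} confidence column per rank.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("otu_id", "lineage"),
                           colClasses = "character", quote = "")
  if (anyDuplicated(raw$otu_id)) {
    stop("duplicate otu_id in taxonomy: ",
         paste(unique(raw$otu_id[duplicated(raw$otu_id)]), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(otu_id = raw$otu_id, stringsAsFactors = FALSE)
  for (r in TAXONOMY_RANKS) {
    out[[r]] <- NA_character_
    out[[paste0(r, "_conf")]] <- NA_real_
  }
  for (i in seq_len(nrow(raw))) {
    parts <- strsplit(raw$lineage[i], ";", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    if (length(parts) > length(TAXONOMY_RANKS)) {
      stop("lineage with more than ", length(TAXONOMY_RANKS), " ranks for ",
           raw$otu_id[i], call. = FALSE)
    }
    for (j in seq_along(parts)) {
      m <- regmatches(parts[j], regexec("^([^()]+)(?:\\(([0-9.]+)\\))?$", parts[j]))[[1L]]
      if (length(m) == 0L) stop("malformed lineage entry: ", parts[j], call. = FALSE)
      out[[TAXONOMY_RANKS[j]]][i] <- m[2L]
      if (nzchar(m[3L])) {
        conf <- as.numeric(m[3L])
        if (is.na(conf) || conf < 0 || conf > 100) {
          stop("confidence outside [0,100] for ", raw$otu_id[i], call. = FALSE)
        }
        out[[paste0(TAXONOMY_RANKS[j], "_conf")]][i] <- conf
      }
    }
  }
  out
}

#' Read sample metadata
#'
#' CSV with required columns \code{sample_id, reactor, unit, category,
#' timepoint}; optional \code{reactor_role} and physicochemical covariates
#' (pH, temperature, TIC, NH4N, TS, VS, total_VFA). Category values are
#' matched case-insensitively against farm, bio-waste, MSW, WWTP-AD and
#' normalised to the canonical spelling. Missing covariates stay \code{NA}.
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "reactor", "unit", "category", "timepoint")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols)) {
    stop("metadata missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(tolower(md$category), tolower(AD_CATEGORIES))
  if (anyNA(idx)) {
    stop("unknown category value(s): ",
         paste(unique(md$category[is.na(idx)]), collapse = ", "),
         "; allowed: ", paste(AD_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  md$category <- AD_CATEGORIES[idx]
  if ("reactor_role" %in% names(md)) {
    bad <- !is.na(md$reactor_role) & !(md$reactor_role %in% REACTOR_ROLES)
    if (any(bad)) {
      stop("unknown reactor_role value(s): ",
           paste(unique(md$reactor_role[bad]), collapse = ", "),
           "; allowed: ", paste(REACTOR_ROLES, collapse = ", "), call. = FALSE)
    }
  }
  md$timepoint <- as.integer(md$timepoint)
  md
}

#' Write sample metadata
#' @param metadata data.frame as returned by \code{\link{read_metadata}}.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a distance matrix object
#'
#' @param values symmetric numeric matrix in [0,1] with zero diagonal and
#'   sample ids as dimnames.
#' @param metric "bray_curtis" or "jaccard".
#' @return An object of class \code{dist_matrix}.
#' @export
dist_matrix <- function(values, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("'values' must be a square matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) stop("'values' must carry sample ids", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-9) {
    stop("asymmetric distance matrix", call. = FALSE)
  }
  if (any(abs(diag(values)) > 1e-12)) stop("nonzero diagonal", call. = FALSE)
  if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop("distances must lie in [0,1]", call. = FALSE)
  }
  colnames(values) <- rownames(values)
  structure(list(values = values, metric = metric), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d samples, metric %s\n", nrow(x$values), x$metric))
  invisible(x)
}

#' Write a distance matrix
#'
#' @param dm a \code{dist_matrix}.
#' @param path output path.
#' @param format "phylip_square" (leading n line, full matrix),
#'   "phylip_lower" (lower triangle) or "tsv" (header + row names).
#' @export
write_distance_matrix <- function(dm, path,
                                  format = c("phylip_square", "phylip_lower", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(dm, "dist_matrix"))
  v <- dm$values
  ids <- rownames(v)
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "phylip_square") {
    writeLines(as.character(nrow(v)), con)
    for (i in seq_len(nrow(v))) {
      writeLines(paste(c(ids[i], fmt(v[i, ])), collapse = "\t"), con)
    }
  } else if (format == "phylip_lower") {
    writeLines(as.character(nrow(v)), con)
    for (i in seq_len(nrow(v))) {
      writeLines(paste(c(ids[i], if (i > 1L) fmt(v[i, seq_len(i - 1L)])),
                       collapse = "\t"), con)
    }
  } else {
    writeLines(paste(c("sample_id", ids), collapse = "\t"), con)
    for (i in seq_len(nrow(v))) {
      writeLines(paste(c(ids[i], fmt(v[i, ])), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a distance matrix written by \code{\link{write_distance_matrix}}
#'
#' @param path file path.
#' @param format file dialect.
#' @param metric metric label to attach.
#' @return A \code{dist_matrix}.
#' @export
read_distance_matrix <- function(path,
                                 format = c("phylip_square", "phylip_lower", "tsv"),
                                 metric = c("bray_curtis", "jaccard")) {
  format <- match.arg(format)
  metric <- match.arg(metric)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    ids <- fields[[1L]][-1L]
    rows <- fields[-1L]
    v <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(ids))))
    rownames(v) <- vapply(rows, function(r) r[1L], character(1))
  } else {
    n <- as.integer(fields[[1L]][1L])
    rows <- fields[-1L]
    if (length(rows) != n) stop("expected ", n, " rows, found ", length(rows), call. = FALSE)
    ids <- vapply(rows, function(r) r[1L], character(1))
    v <- matrix(0, n, n, dimnames = list(ids, ids))
    if (format == "phylip_square") {
      for (i in seq_len(n)) v[i, ] <- as.numeric(rows[[i]][-1L])
    } else {
      for (i in seq_len(n)) {
        if (i > 1L) {
          vals <- as.numeric(rows[[i]][-1L])
          v[i, seq_len(i - 1L)] <- vals
          v[seq_len(i - 1L), i] <- vals
        }
      }
    }
  }
  colnames(v) <- rownames(v)
  dist_matrix(v, metric = metric)
}

#' Cross-check a count table against its metadata
#'
#' Report-only validation: lists samples with no metadata row, metadata rows
#' with no sample, and zero-total samples. \code{ok} is TRUE iff all three
#' lists are empty.
#'
#' @param table a \code{count_table}.
#' @param metadata metadata data.frame.
#' @return list(ok, samples_missing_metadata, metadata_without_samples,
#'   zero_total_samples).
#' @export
validate_dataset <- function(table, metadata) {
  stopifnot(inherits(table, "count_table"))
  ids <- sample_ids(table)
  totals <- rowSums(table$counts)
  report <- list(
    samples_missing_metadata = setdiff(ids, metadata$sample_id),
    metadata_without_samples = setdiff(metadata$sample_id, ids),
    zero_total_samples = ids[totals == 0]
  )
  report$ok <- all(lengths(report[1:3]) == 0L)
  report
}
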