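# End-to-end orchestration: normalize -> diversity -> distances -> partition
# -> stability -> group statistics, from a single config, with a JSON manifest
# recording seed, config hash and per-stage record counts. Bacterial and
# archaeal tables are processed as independent runs with their own depths.

#' Build a pipeline configuration
#'
#' Exactly one input source must be set: file paths (count table + metadata)
#' or a \code{\link{synthetic_spec}}.
#'
#' @param count_table_path path to a shared/TSV count table (file input).
#' @param count_format "shared" or "tsv".
#' @param metadata_path path to the metadata CSV (file input).
#' @param taxonomy_path optional taxonomy TSV (carried through, not required).
#' @param synth_spec a \code{synthetic_spec} (synthetic input).
#' @param domain amplicon domain of the run.
#' @param depth subsampling depth (bacteria 11,550 / archaea 2,070 are the
#'   conventional defaults).
#' @param min_total singleton filter threshold.
#' @param core_min_occurrence,transient_max_occurrence partition thresholds.
#' @param scopes character vector of partition scopes: "all",
#'   "category:<name>" or "unit:<name>".
#' @param n_permutations ANOSIM permutations.
#' @param seed seed for every stochastic stage.
#' @param out_dir output directory (created if missing).
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(count_table_path = NULL, count_format = "shared",
                            metadata_path = NULL, taxonomy_path = NULL,
                            synth_spec = NULL,
                            domain = c("bacteria", "archaea"),
                            depth = 11550L, min_total = 2L,
                            core_min_occurrence = 0.80,
                            transient_max_occurrence = 0.20,
                            scopes = c("all", "category:WWTP-AD"),
                            n_permutations = 999L, seed = 1L,
                            out_dir = tempfile("coremicro_run_")) {
  domain <- match.arg(domain)
  file_input <- !is.null(count_table_path) || !is.null(metadata_path)
  synth_input <- !is.null(synth_spec)
  if (file_input && synth_input) {
    stop("set either input paths or a synthetic spec, not both", call. = FALSE)
  }
  if (!file_input && !synth_input) {
    stop("no input: set count_table_path + metadata_path or synth_spec",
         call. = FALSE)
  }
  if (file_input && (is.null(count_table_path) || is.null(metadata_path))) {
    stop("file input needs both count_table_path and metadata_path", call. = FALSE)
  }
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  cfg <- as.list(environment())[c(
    "count_table_path", "count_format", "metadata_path", "taxonomy_path",
    "synth_spec", "domain", "depth", "min_total", "core_min_occurrence",
    "transient_max_occurrence", "scopes", "n_permutations", "seed", "out_dir")]
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order is fixed: load/generate, validate, singleton filter, subsample,
#' diversity, distance matrices (Bray-Curtis and Jaccard), partition per
#' scope, abundance shares, occurrence-abundance summaries, temporal
#' stability, ANOSIM by category. Each stage's outputs are written under
#' \code{config$out_dir}; the manifest (JSON) records package version, seed,
#' a hash of the config and per-stage record counts. Re-running with the same
#' config and seed reproduces byte-identical text outputs. Any stage error
#' aborts with the stage name; the manifest is still written and flagged
#' incomplete.
#'
#' @param config a \code{pipeline_config}.
#' @return The manifest, invisibly a list; also written as manifest.json.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "coremicro",
    version = as.character(utils::packageVersion("coremicro")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = list(),
    files = character(0),
    complete = FALSE
  )
  path_of <- function(f) file.path(config$out_dir, f)
  note <- function(stage, rows_in, rows_out) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = stage, rows_in = rows_in, rows_out = rows_out)
  }
  add_file <- function(f) manifest$files <<- c(manifest$files, f)
  write_manifest <- function() {
    jsonlite::write_json(manifest, path_of("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- "load"
  res <- tryCatch({
    # load / generate ------------------------------------------------------
    if (!is.null(config$synth_spec)) {
      ds <- generate_dataset(config$synth_spec)
      table <- ds$table
      metadata <- ds$metadata
    } else {
      table <- read_count_table(config$count_table_path,
                                format = config$count_format,
                                domain = config$domain)
      metadata <- read_metadata(config$metadata_path)
    }
    note("load", NA_integer_, nrow(table$counts))

    stage <- "validate"
    report <- validate_dataset(table, metadata)
    if (!report$ok) {
      stop("dataset validation failed: ",
           paste(names(report)[lengths(report) > 0 & names(report) != "ok"],
                 collapse = ", "))
    }
    note("validate", nrow(table$counts), nrow(table$counts))

    stage <- "filter"
    filtered <- filter_low_count_otus(table, config$min_total)
    note("filter", ncol(table$counts), ncol(filtered$counts))

    stage <- "subsample"
    sub <- subsample(filtered, depth = config$depth, seed = config$seed)
    write_count_table(sub, path_of("subsampled.shared"), "shared")
    add_file("subsampled.shared")
    note("subsample", nrow(filtered$counts), nrow(sub$counts))
    metadata <- metadata[metadata$sample_id %in% sample_ids(sub), ]

    stage <- "diversity"
    div <- diversity_table(sub)
    write_tsv(div, path_of("diversity.tsv"))
    add_file("diversity.tsv")
    note("diversity", nrow(sub$counts), nrow(div))

    stage <- "distance"
    dms <- list()
    for (metric in c("bray_curtis", "jaccard")) {
      dms[[metric]] <- distance_matrix(sub, metric)
      f <- sprintf("distance_%s.phylip", metric)
      write_distance_matrix(dms[[metric]], path_of(f), "phylip_square")
      add_file(f)
    }
    note("distance", nrow(sub$counts), 2L)

    stage <- "partition"
    scope_samples <- function(sc) {
      if (sc == "all") return(sample_ids(sub))
      kv <- strsplit(sc, ":", fixed = TRUE)[[1L]]
      if (length(kv) != 2L || !(kv[1L] %in% c("category", "unit"))) {
        stop("bad scope '", sc, "': use all, category:<name> or unit:<name>")
      }
      metadata$sample_id[metadata[[kv[1L]]] == kv[2L]]
    }
    partitions <- list()
    part_rows <- list()
    share_rows <- list()
    occab_rows <- list()
    for (sc in config$scopes) {
      samp <- scope_samples(sc)
      if (length(samp) == 0L) stop("scope '", sc, "' matches no samples")
      part <- partition_otus(sub, scope = samp,
                             core_min_occurrence = config$core_min_occurrence,
                             transient_max_occurrence = config$transient_max_occurrence)
      partitions[[sc]] <- part
      summ <- occurrence_abundance_summary(sub, part)
      part_rows[[sc]] <- data.frame(scope = sc,
                                    summ[c("otu_id", "occurrence", "assignment")],
                                    stringsAsFactors = FALSE)
      occab_rows[[sc]] <- data.frame(scope = sc, summ, stringsAsFactors = FALSE)
      for (lab in levels(part$assignment)) {
        sh <- abundance_share(sub, partition_members(part, lab), samp)
        share_rows[[paste(sc, lab)]] <- data.frame(
          scope = sc, assignment = lab, n_otus = sum(part$assignment == lab),
          mean_share = sh$mean, sd_share = sh$sd, n_samples = sh$n,
          stringsAsFactors = FALSE)
      }
    }
    write_tsv(do.call(rbind, part_rows), path_of("partition.tsv"))
    add_file("partition.tsv")
    write_tsv(do.call(rbind, share_rows), path_of("abundance_shares.tsv"))
    add_file("abundance_shares.tsv")
    write_tsv(do.call(rbind, occab_rows), path_of("occurrence_abundance.tsv"))
    add_file("occurrence_abundance.tsv")
    note("partition", ncol(sub$counts), length(partitions))

    stage <- "stability"
    stab <- do.call(rbind, lapply(c("bray_curtis", "jaccard"), function(metric) {
      do.call(rbind, lapply(c("all_pairs", "consecutive"), function(scheme) {
        temporal_stability(sub, metadata, metric = metric, scheme = scheme)
      }))
    }))
    write_tsv(stab, path_of("stability.tsv"))
    add_file("stability.tsv")
    note("stability", nrow(sub$counts), nrow(stab))

    stage <- "anosim"
    labels <- metadata$category[match(sample_ids(sub), metadata$sample_id)]
    an <- anosim_test(dms$bray_curtis, labels,
                      n_permutations = config$n_permutations, seed = config$seed)
    jsonlite::write_json(an, path_of("anosim.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    add_file("anosim.json")
    note("anosim", nrow(sub$counts), 1L)

    manifest$complete <- TRUE
    write_manifest()
    add_file("manifest.json")
    manifest
  }, error = function(e) {
    manifest$error <<- list(stage = stage, message = conditionMessage(e))
    write_manifest()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# Deterministic TSV writer used for all tabular pipeline outputs.
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
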