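# Small fixtures built in code, shared across test files.

toy_table <- function(counts = NULL, domain = "bacteria") {
  if (is.null(counts)) {
    counts <- matrix(c(5L, 0L, 3L,
                       2L, 8L, 0L),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("S1", "S2"), c("OTU_A", "OTU_B", "OTU_C")))
  }
  count_table(counts, domain = domain)
}

random_table <- function(n_samples, n_otus, max_count = 50, zero_prob = 0.3,
                         seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda = max_count / 4), n_samples, n_otus)
  m[runif(length(m)) < zero_prob] <- 0L
  # avoid all-zero samples
  for (i in seq_len(n_samples)) if (sum(m[i, ]) == 0) m[i, 1] <- 1L
  storage.mode(m) <- "integer"
  dimnames(m) <- list(sprintf("S%02d", seq_len(n_samples)),
                      sprintf("OTU_%03d", seq_len(n_otus)))
  count_table(m)
}

toy_metadata <- function(table) {
  ids <- rownames(table$counts)
  data.frame(sample_id = ids,
             reactor = rep("BF", length(ids)),
             unit = "U-1", category = "farm", reactor_role = "Fd",
             timepoint = seq_along(ids), stringsAsFactors = FALSE)
}

small_synth <- function(seed = 1, ...) {
  args <- list(n_reactors = 6L, n_timepoints = 12L, n_otus = 800L,
               depth = 2000L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  generate_dataset(do.call(synthetic_spec, args))
}
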