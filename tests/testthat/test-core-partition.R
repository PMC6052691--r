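test_that("occurrence fractions respect scope and detection threshold", {
  m <- matrix(0L, 12, 3, dimnames = list(sprintf("S%02d", 1:12), c("A", "B", "C")))
  m[, "A"] <- 5L          # in all 12
  m[1, "B"] <- 2L         # in 1 of 12
  m[, "C"] <- 1L          # 1 read everywhere
  tab <- count_table(m)
  occ <- occurrence_fractions(tab)
  expect_equal(unname(occ), c(1, 1 / 12, 1))
  occ2 <- occurrence_fractions(tab, detection_min_count = 2)
  expect_equal(unname(occ2["C"]), 0)
  occ_scope <- occurrence_fractions(tab, scope = c("S01", "S02"))
  expect_equal(unname(occ_scope["B"]), 0.5)
  expect_error(occurrence_fractions(tab, scope = character(0)), "empty scope")
  expect_error(occurrence_fractions(tab, scope = "GHOST"), "GHOST")
})

test_that("boundary occurrences are intermediate under strict thresholds", {
  # 10 samples: occurrence exactly 0.8 and exactly 0.2 must both be intermediate
  m <- matrix(0L, 10, 4, dimnames = list(sprintf("S%02d", 1:10),
                                         c("core", "at80", "at20", "trans")))
  m[, "core"] <- 1L
  m[1:8, "at80"] <- 1L
  m[1:2, "at20"] <- 1L
  m[1, "trans"] <- 1L
  part <- partition_otus(count_table(m))
  expect_equal(as.character(part$assignment[c("core", "at80", "at20", "trans")]),
               c("core", "intermediate", "intermediate", "transient"))
})

test_that("partition matches brute-force reclassification on a random table", {
  tab <- random_table(15, 50, zero_prob = 0.7, seed = 23)
  part <- partition_otus(tab, core_min_occurrence = 0.6,
                         transient_max_occurrence = 0.3)
  # independent oracle: explicit per-OTU loop over raw counts
  for (otu in colnames(tab$counts)) {
    occ <- sum(tab$counts[, otu] >= 1) / 15
    if (occ == 0) {
      expect_false(otu %in% names(part$assignment))
    } else {
      expected <- if (occ > 0.6) "core" else if (occ < 0.3) "transient" else "intermediate"
      expect_identical(as.character(part$assignment[otu]), expected)
      expect_equal(unname(part$occurrence[otu]), occ)
    }
  }
})

test_that("partition is complete, disjoint, and monotone in the core threshold", {
  tab <- random_table(20, 80, zero_prob = 0.8, seed = 11)
  part <- partition_otus(tab)
  sets <- split(names(part$assignment), part$assignment)
  expect_identical(sort(unlist(sets, use.names = FALSE)),
                   sort(names(part$occurrence)))
  expect_equal(sum(lengths(sets)), length(part$occurrence))  # disjoint union

  cores <- lapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(cm) {
    partition_members(partition_otus(tab, core_min_occurrence = cm), "core")
  })
  for (i in seq_len(length(cores) - 1)) {
    expect_true(all(cores[[i + 1]] %in% cores[[i]]))
  }
})

test_that("subset_table selects columns without touching counts", {
  tab <- toy_table()
  expect_identical(subset_table(tab, colnames(tab$counts))$counts, tab$counts)
  sub <- subset_table(tab, "OTU_B")
  expect_identical(sub$counts, tab$counts[, "OTU_B", drop = FALSE])
  expect_error(subset_table(tab, "NOPE"), "unknown OTU")
  expect_warning(empty <- subset_table(tab, character(0)), "empty OTU set")
  expect_identical(dim(empty$counts), c(2L, 0L))
})

test_that("abundance shares divide reads correctly and sum to 1 across partitions", {
  m <- matrix(c(70L, 20L, 10L), 1, dimnames = list("S1", c("A", "B", "C")))
  tab <- count_table(m)
  expect_equal(abundance_share(tab, "A")$per_sample[["S1"]], 0.70)
  expect_equal(abundance_share(tab, c("A", "B", "C"))$mean, 1.0)
  expect_equal(abundance_share(tab, character(0))$mean, 0.0)

  big <- random_table(10, 60, zero_prob = 0.6, seed = 40)
  part <- partition_otus(big)
  total <- Reduce(`+`, lapply(levels(part$assignment), function(lab) {
    abundance_share(big, partition_members(part, lab))$per_sample
  }))
  # detected OTUs carry every read, so the three shares sum to 1 per sample
  expect_true(all(abs(total - 1) < 1e-12))
})

test_that("mean non-zero abundance averages only over samples with the OTU", {
  m <- matrix(c(10L, 90L,
                 0L, 50L,
                30L, 70L), 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), c("A", "B")))
  tab <- count_table(m)
  mna <- mean_nonzero_abundance(tab)
  expect_equal(unname(mna["A"]), mean(c(0.1, 0.3)))  # S2 excluded
  expect_equal(unname(mna["B"]), mean(c(0.9, 1.0, 0.7)))

  m2 <- cbind(m, GONE = c(0L, 0L, 0L))
  expect_true(is.na(mean_nonzero_abundance(count_table(m2))["GONE"]))
})

test_that("occurrence-abundance summary matches independent recomputation", {
  tab <- random_table(8, 10, zero_prob = 0.5, seed = 3)
  part <- partition_otus(tab)
  summ <- occurrence_abundance_summary(tab, part)
  rel <- to_relative(tab)
  for (k in seq_len(nrow(summ))) {
    otu <- summ$otu_id[k]
    present <- tab$counts[, otu] >= 1
    expect_equal(summ$occurrence[k], mean(present))
    expect_equal(summ$n_samples_present[k], sum(present))
    expect_equal(summ$mean_nonzero_abundance[k], mean(rel[present, otu]))
  }
  hist <- attr(summ, "occurrence_histogram")
  expect_equal(sum(hist$percent_of_otus), 100, tolerance = 1e-9)
  expect_identical(hist$n_samples, 1:8)

  # degenerate: every OTU in every sample puts 100% in the last bin
  all_in <- count_table(matrix(1L, 4, 3, dimnames = list(sprintf("S%d", 1:4),
                                                         c("A", "B", "C"))))
  h <- attr(occurrence_abundance_summary(all_in, partition_otus(all_in)),
            "occurrence_histogram")
  expect_equal(h$percent_of_otus, c(0, 0, 0, 100))
})

test_that("core overlap compares core sets over a common universe", {
  tab <- random_table(12, 40, zero_prob = 0.6, seed = 8)
  part <- partition_otus(tab)
  self <- core_overlap(part, part)
  expect_equal(self$n_shared, length(partition_members(part, "core")))
  expect_equal(self$jaccard, ifelse(self$n_union > 0, 1, NA_real_))

  part2 <- partition_otus(tab, scope = rownames(tab$counts)[1:6])
  ov <- core_overlap(part, part2)
  expect_equal(ov$n_shared,
               length(intersect(partition_members(part, "core"),
                                partition_members(part2, "core"))))
  expect_equal(ov$n_shared, core_overlap(part2, part)$n_shared)  # symmetric

  other <- partition_otus(random_table(5, 10, seed = 1))
  expect_error(core_overlap(part, other), "universe")
})

test_that("system-specific cores with planted shared OTUs are recovered by overlap", {
  ds <- small_synth(seed = 13)
  md <- ds$metadata
  ad_scope <- md$sample_id[md$category != "WWTP-AD"]
  ww_scope <- md$sample_id[md$category == "WWTP-AD"]
  part_ad <- partition_otus(ds$table, scope = ad_scope)
  part_ww <- partition_otus(ds$table, scope = ww_scope)
  planted_shared <- with(ds$truth$otus, sum(label == "core" & system == "both"))
  ov <- core_overlap(part_ad, part_ww)
  expect_equal(ov$n_shared, planted_shared)
})
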