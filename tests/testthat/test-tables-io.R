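test_that("shared files parse to the exact counts and round-trip identically", {
  txt <- c("label\tGroup\tnumOtus\tOTU_A\tOTU_B\tOTU_C",
           "0.03\tS1\t3\t5\t0\t3",
           "0.03\tS2\t3\t2\t8\t0")
  f <- withr::local_tempfile(lines = txt, fileext = ".shared")
  tab <- read_count_table(f, "shared")
  expect_identical(tab$counts, toy_table()$counts)
  expect_identical(tab$label, "0.03")

  f2 <- withr::local_tempfile(fileext = ".shared")
  write_count_table(tab, f2, "shared")
  expect_identical(read_count_table(f2, "shared")$counts, tab$counts)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, f3, "tsv")
  expect_identical(read_count_table(f3, "tsv")$counts, tab$counts)
})

test_that("malformed shared rows are rejected with a line number", {
  bad_numotus <- c("label\tGroup\tnumOtus\tOTU_A\tOTU_B\tOTU_C",
                   "0.03\tS1\t3\t5\t0\t3",
                   "0.03\tS2\t4\t2\t8\t0")
  f <- withr::local_tempfile(lines = bad_numotus)
  expect_error(read_count_table(f, "shared"), "line 3.*numOtus")

  short_row <- c("label\tGroup\tnumOtus\tOTU_A\tOTU_B",
                 "0.03\tS1\t2\t5")
  f <- withr::local_tempfile(lines = short_row)
  expect_error(read_count_table(f, "shared"), "line 2")

  negative <- c("label\tGroup\tnumOtus\tOTU_A",
                "0.03\tS1\t1\t-2")
  f <- withr::local_tempfile(lines = negative)
  expect_error(read_count_table(f, "shared"), "negative")

  fractional <- c("label\tGroup\tnumOtus\tOTU_A",
                  "0.03\tS1\t1\t2.5")
  f <- withr::local_tempfile(lines = fractional)
  expect_error(read_count_table(f, "shared"), "non-integer")

  dup <- c("label\tGroup\tnumOtus\tOTU_A",
           "0.03\tS1\t1\t2", "0.03\tS1\t1\t3")
  f <- withr::local_tempfile(lines = dup)
  expect_error(read_count_table(f, "shared"), "duplicate sample")
})

test_that("taxonomy lineages parse rank by rank with confidences", {
  txt <- c("OTU_1\tBacteria(100);Firmicutes(99);",
           "OTU_2\tBacteria(100);Bacteroidetes(97);Bacteroidia(95);Bacteroidales(92);Porphyromonadaceae(80);Petrimonas(77);",
           "OTU_3\tArchaea")
  f <- withr::local_tempfile(lines = txt)
  tax <- read_taxonomy(f)
  expect_equal(tax$domain, c("Bacteria", "Bacteria", "Archaea"))
  expect_equal(tax$phylum[1], "Firmicutes")
  expect_equal(tax$phylum_conf[1], 99)
  expect_true(is.na(tax$class[1]))
  expect_equal(tax$genus[2], "Petrimonas")
  expect_equal(tax$genus_conf[2], 77)
  expect_true(is.na(tax$domain_conf[3]))

  f <- withr::local_tempfile(lines = c("OTU_1\tBacteria;", "OTU_1\tArchaea;"))
  expect_error(read_taxonomy(f), "duplicate otu_id")

  f <- withr::local_tempfile(lines = "OTU_1\tBacteria(120);")
  expect_error(read_taxonomy(f), "confidence")
})

test_that("metadata categories are normalised and validated", {
  txt <- c("sample_id,reactor,unit,category,timepoint,pH",
           "S01,BF,U-1,farm,1,7.9",
           "S02,P,U-8,wwtp-ad,1,7.1",
           "S03,MK,U-7,msw,2,")
  f <- withr::local_tempfile(lines = txt)
  md <- read_metadata(f)
  expect_equal(md$category, c("farm", "WWTP-AD", "MSW"))
  expect_true(is.na(md$pH[3]))  # missing covariate stays missing, not zero
  expect_identical(md$timepoint, c(1L, 1L, 2L))

  f <- withr::local_tempfile(lines = c(txt[1], "S01,BF,U-1,compost,1,7.9"))
  expect_error(read_metadata(f), "compost.*allowed.*WWTP-AD")

  f <- withr::local_tempfile(lines = c(txt[1], txt[2], txt[2]))
  expect_error(read_metadata(f), "duplicate sample_id")
})

test_that("distance matrices round-trip in all three dialects", {
  v <- matrix(c(0, .2, .7, .2, 0, .456789123456, .7, .456789123456, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dm <- dist_matrix(v, "bray_curtis")
  for (fmt in c("phylip_square", "phylip_lower", "tsv")) {
    f <- withr::local_tempfile()
    write_distance_matrix(dm, f, fmt)
    back <- read_distance_matrix(f, fmt)
    expect_lt(max(abs(back$values - v)), 1e-9)
    expect_identical(rownames(back$values), rownames(v))
  }
  f <- withr::local_tempfile()
  write_distance_matrix(dm, f, "phylip_square")
  expect_identical(readLines(f)[1], "3")

  asym <- v; asym[1, 2] <- 0.3
  expect_error(dist_matrix(asym, "bray_curtis"), "asymmetric")
})

test_that("dataset validation flags each injected defect", {
  tab <- toy_table()
  md <- toy_metadata(tab)
  expect_true(validate_dataset(tab, md)$ok)

  md_extra <- rbind(md, transform(md[1, ], sample_id = "GHOST"))
  rep <- validate_dataset(tab, md_extra)
  expect_false(rep$ok)
  expect_identical(rep$metadata_without_samples, "GHOST")

  rep <- validate_dataset(tab, md[1, ])
  expect_identical(rep$samples_missing_metadata, "S2")

  m <- tab$counts; m["S2", ] <- 0L
  rep <- validate_dataset(count_table(m), md)
  expect_identical(rep$zero_total_samples, "S2")
})
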