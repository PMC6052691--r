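# coremicro

Occurrence-based core/transient partitioning of OTU count tables from
longitudinal, multi-reactor amplicon surveys — the kind of dataset produced by
monitoring full-scale anaerobic digestion (AD) reactors monthly over a year —
together with the supporting analysis pipeline: depth normalisation,
alpha-diversity, community dissimilarity and temporal stability, and
distance-based group statistics.

## The scientific problem

Anaerobic digesters host thousands of mostly uncharacterised microbial taxa,
but only a fraction of them persist across reactors and time. A practical way
to find the taxa that plausibly drive the process is to partition OTUs by
**occurrence**: given a scope of `n` samples (e.g. all monthly samples from
the agricultural and bio-waste reactors), an OTU with occurrence fraction

```
occ_j = #{ samples in scope with count_ij >= 1 } / n
```

is assigned

- **core** if `occ_j > 0.80` (present in over 80% of samples),
- **transient** if `0 < occ_j < 0.20` (present in fewer than 20%),
- **intermediate** otherwise (boundary values included).

Abundance enters only afterwards: for each partition the pipeline reports the
per-sample read share `sum(counts[otu set]) / sample total` and, per OTU, the
mean relative abundance computed **only over the samples where the OTU is
present** (zero samples excluded). Because occurrence is detection-limited,
everything runs on tables subsampled without replacement to a fixed depth
(bacterial assays conventionally 11,550 reads/sample, archaeal 2,070), so the
smallest detectable relative abundance is `1/depth`.

Around this core procedure the package provides, in the form the field's
standard tools use:

- mothur `shared`-format and TSV count-table IO, SILVA-style taxonomy and
  metadata parsing, PHYLIP distance-matrix IO;
- `sobs` richness, inverse Simpson diversity (plug-in and finite-sample
  estimators), inverse-Simpson evenness, analytic (hypergeometric) and
  resampled rarefaction curves, rank-abundance curves;
- Bray–Curtis (structure) and Jaccard (membership) dissimilarities and
  within-reactor temporal-stability summaries;
- ANOSIM with seed-controlled permutations and exact enumeration for small
  designs, NMDS ordination, average-linkage cluster assignment,
  Kruskal–Wallis, Wilcoxon signed rank and Spearman correlation matrices;
- a Dirichlet-multinomial synthetic survey generator with planted
  core/intermediate/transient labels and two digestion systems with largely
  distinct cores, so the whole pipeline can be validated against known truth.

## Worked example

```r
library(coremicro)

# a year-long survey of 20 reactors (6,000 OTUs, depth 11,550)
ds <- generate_dataset(synthetic_spec(seed = 42))
ds$table
#> count_table: 240 samples x 6000 OTUs (bacteria, label synthetic), 2,772,000 total reads

md <- ds$metadata
ad <- md$sample_id[md$category != "WWTP-AD"]   # agricultural + bio-waste scope

part <- partition_otus(ds$table, scope = ad)
part
#> otu_partition over 204 samples: 83 core, 446 intermediate, 4943 transient
#> (of 5472 detected; thresholds >0.80 / <0.20)

core <- partition_members(part, "core")
share <- abundance_share(ds$table, core, scope = ad)
sprintf("AD-core share: %.1f%% +/- %.1f", 100 * share$mean, 100 * share$sd)
#> "AD-core share: 70.1% +/- 1.4"

head(diversity_table(ds$table), 3)
#>   sample_id depth sobs invsimpson  evenness
#> 1     B_T01 11550  372   76.66755 0.2047541
#> 2     B_T02 11550  392   82.55320 0.2091183
#> 3     B_T03 11550  404   74.03583 0.1821055

dm <- distance_matrix(ds$table, "bray_curtis")
system <- ifelse(md$category == "WWTP-AD", "WWTP", "AD")
anosim_test(dm, system[match(rownames(ds$table$counts), md$sample_id)],
            n_permutations = 999, seed = 1)[c("R", "p")]
#> $R
#> [1] 1
#> $p
#> [1] 0.001
```

Read: a small core (83 of ~5,500 detected OTUs) carries ~70% of the reads in
every sample while ~84% of OTUs are transient; the wastewater digesters
separate completely from the agricultural/bio-waste system (ANOSIM R = 1,
p = 0.001). `run_pipeline(pipeline_config(...))` executes the same stages
end-to-end and writes TSV/PHYLIP/JSON artifacts plus a reproducibility
manifest; `inst/scripts/coremicro-run.R` is a thin command-line wrapper.

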