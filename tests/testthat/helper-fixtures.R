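# Shared small simulation fixtures; memoised so several test files can
# reuse one generation pass.
.fixture_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 11L) {
  simulation_config(
    seed = seed,
    n_contigs = 2L,
    contig_length_bp = 40000L,
    mean_depth = 12,
    background_het_rate = 1e-4,
    fixed_diff_rate = 1e-3,
    planted_clusters = list(
      list(contig = "contig_1", start = 10001L, n = 35L),
      list(contig = "contig_2", start = 20001L, n = 32L)
    ),
    n_decoys = 10L,
    sex_exclusive_blocks = list(
      list(contig = "contig_1", start = 35001L, end = 35600L, zero_sex = "female"),
      list(contig = "contig_2", start = 5001L, end = 5400L, zero_sex = "male")
    ),
    n_genes = 4L,
    gene_length_bp = 900L,
    ortholog_mutations = list(c(syn = 4L, nonsyn = 0L), c(syn = 0L, nonsyn = 4L))
  )
}

small_cohort <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- small_sim_config()
    ref <- generate_reference(cfg)
    coh <- generate_cohort(cfg, ref)
    .fixture_cache$small <- list(cfg = cfg, ref = ref, coh = coh,
                                 dm = depth_matrix(coh$depth))
  }
  .fixture_cache$small
}

# Merged asymmetric stream (filtered males + unfiltered females) for the
# small cohort, plus the all-filtered merge.
small_merges <- function() {
  if (is.null(.fixture_cache$small_merges)) {
    fx <- small_cohort()
    manifest <- fx$coh$manifest
    males <- manifest[sex == "male", sample_id]
    females <- manifest[sex == "female", sample_id]
    filtered <- lapply(fx$coh$vcfs, filter_quality)
    .fixture_cache$small_merges <- list(
      males = males, females = females,
      all_filtered = merge_samples(filtered, manifest$sample_id),
      asym = merge_samples(c(filtered[males], fx$coh$vcfs[females]),
                           manifest$sample_id)
    )
  }
  .fixture_cache$small_merges
}

# Tiny hand-built depth matrix: one contig, explicit per-sample depths.
toy_depth_matrix <- function(depths_by_sample) {
  n <- length(depths_by_sample[[1L]])
  tabs <- lapply(depths_by_sample, function(d)
    data.table::data.table(contig = "c1", pos = seq_len(n), depth = as.integer(d)))
  depth_matrix(tabs)
}

# Minimal merged-sites table built from explicit per-sample genotypes.
toy_merged <- function(gt_by_sample, contig = "c1", pos = 100L,
                       ref = "A", alt = "T") {
  streams <- lapply(gt_by_sample, function(g) {
    if (is.na(g)) {
      data.table::data.table(contig = character(), pos = integer(),
                             ref = character(), alt = character(),
                             qual = numeric(), gt = character())
    } else {
      data.table::data.table(contig = contig, pos = pos, ref = ref, alt = alt,
                             qual = 60, gt = g)
    }
  })
  merge_samples(streams, names(gt_by_sample))
}
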