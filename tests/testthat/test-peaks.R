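segment_fixture <- function(counts, window = 10000L) {
  lens <- c(c1 = window * length(counts))
  sites <- data.table::rbindlist(lapply(seq_along(counts), function(w) {
    if (counts[w] == 0L) return(NULL)
    data.table::data.table(contig = "c1",
                           pos = (w - 1L) * window + seq_len(counts[w]))
  }))
  if (is.null(sites) || !nrow(sites))
    sites <- data.table::data.table(contig = character(), pos = integer())
  list(sites = sites, segments = per_segment_counts(sites, lens, window))
}

test_that("peak scanning honours threshold, comparator and summaries", {
  fxt <- segment_fixture(c(32L, 29L, 88L, 0L))
  scan <- scan_clusters(fxt$segments, threshold = 30L)
  expect_equal(nrow(scan$peaks), 2L)
  expect_equal(scan$peaks$count, c(32L, 88L))
  expect_equal(scan$n_nonempty_windows, 3L)
  expect_equal(scan$n_contigs_nonempty, 1L)
  # strictly-greater comparator, as in the "more than 25" style of report
  expect_equal(nrow(scan_clusters(fxt$segments, 29L, strict = TRUE)$peaks), 2L)
  expect_equal(nrow(scan_clusters(fxt$segments, 32L, strict = TRUE)$peaks), 1L)
  expect_error(scan_clusters(fxt$segments, 0L), "at least 1")

  empty <- segment_fixture(c(0L, 0L))
  expect_equal(nrow(scan_clusters(empty$segments, 30L)$peaks), 0L)
})

test_that("peak count is monotone non-increasing in the threshold", {
  fxt <- segment_fixture(c(5L, 30L, 31L, 40L, 12L, 88L))
  n_prev <- Inf
  for (thr in c(1L, 5L, 30L, 31L, 41L, 89L)) {
    n <- nrow(scan_clusters(fxt$segments, thr)$peaks)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("the peak table reports first/last variant positions per window", {
  lens <- c(c1 = 30000L)
  sites <- data.table::data.table(contig = "c1",
                                  pos = c(22222L, 25000L, 29999L, 15L))
  segs <- per_segment_counts(sites, lens)
  scan <- scan_clusters(segs, threshold = 3L)
  tab <- peak_table(scan, sites)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$first_variant_pos, 22222L)
  expect_equal(tab$last_variant_pos, 29999L)
  expect_equal(tab$n_variants, 3L)
  # single-variant window sits below the threshold and is absent
  expect_false(any(tab$window_index == 0L))
  # a peak whose window holds no sites is an input inconsistency
  fake <- data.table::data.table(contig = "c1", window_index = 1L,
                                 start = 10001L, end = 20000L, count = 3L)
  expect_error(peak_table(fake, sites[pos > 20000L]), "contains no sites")
  # peak spans always stay inside their window
  expect_true(all(tab$first_variant_pos > (tab$window_index) * 10000L &
                    tab$last_variant_pos <= (tab$window_index + 1L) * 10000L))
})

test_that("nearest-gene distances and tie-breaking follow the closest-gene rules", {
  genes <- data.table::data.table(
    contig = "c1", start = c(100L, 1100L), end = c(900L, 2000L),
    name = c("geneA", "geneB"), short_name = c("a", "b"))
  inside <- nearest_gene(data.table::data.table(contig = "c1", pos = 500L), genes)
  expect_equal(inside$distance, 0L)
  expect_true(inside$in_gene)
  expect_equal(inside$gene_name, "geneA")
  # 1-based position 900 is the last base of [100, 900); 901 is 1 bp away
  expect_equal(nearest_gene(data.table::data.table(contig = "c1", pos = 900L),
                            genes)$distance, 0L)
  expect_equal(nearest_gene(data.table::data.table(contig = "c1", pos = 901L),
                            genes)$distance, 1L)

  # closer-but-second gene loses only on a true tie
  genes0 <- data.table::data.table(
    contig = "c1", start = c(0L, 1099L), end = c(900L, 2000L),
    name = c("geneA", "geneB"), short_name = c("a", "b"))
  tie <- nearest_gene(data.table::data.table(contig = "c1", pos = 1000L), genes0)
  expect_equal(tie$distance, 100L)
  expect_equal(tie$gene_name, "geneA")   # first in coordinate order wins

  expect_error(nearest_gene(data.table::data.table(contig = "c1", pos = 1L),
                            genes[2:1]), "sort")
  nog <- nearest_gene(data.table::data.table(contig = "cX", pos = 5L), genes)
  expect_true(is.na(nog$gene_name))
  expect_false(nog$in_gene)
})

test_that("nearest-gene assignment matches the all-pairs oracle", {
  set.seed(21)
  genes <- data.table::rbindlist(lapply(c("c1", "c2"), function(ctg) {
    s <- sort(sample.int(50000L, 12L))
    data.table::data.table(contig = ctg, start = s, end = s + sample(50:900, 12L),
                           name = paste0(ctg, "_g", 1:12),
                           short_name = paste0(ctg, "_g", 1:12))
  }))
  data.table::setorder(genes, contig, start, end)
  queries <- data.table::data.table(
    contig = sample(c("c1", "c2", "c3"), 80L, replace = TRUE),
    pos = sample.int(55000L, 80L))
  got <- nearest_gene(queries, genes)
  want <- bf_nearest_gene(queries, genes)
  expect_equal(got$gene_name, want$name)
  expect_equal(got$distance, want$distance)
  expect_equal(got$in_gene, !is.na(want$distance) & want$distance == 0L)
})

test_that("distinct gene counting deduplicates shared nearest genes", {
  asg <- data.table::data.table(
    short_name = c(paste0("g", 1:13), "g13", "g14"),
    in_gene = rep(c(TRUE, FALSE), length.out = 15L))
  res <- distinct_gene_count(asg)
  expect_equal(res$n_assignments, 15L)
  expect_equal(res$n_distinct_genes, 14L)
  expect_equal(res$in_gene, asg$in_gene)
  none <- distinct_gene_count(asg[0])
  expect_equal(none$n_distinct_genes, 0L)
})

test_that("noise-free planted clusters are recovered end to end", {
  cfg <- simulation_config(seed = 17L, n_contigs = 2L, contig_length_bp = 50000L,
                           background_het_rate = 0, fixed_diff_rate = 0,
                           planted_clusters = list(
                             list(contig = "contig_1", start = 10001L, n = 34L),
                             list(contig = "contig_2", start = 30001L, n = 40L)),
                           n_decoys = 0L, sex_exclusive_blocks = list(),
                           n_genes = 5L, gene_length_bp = 1200L)
  ref <- generate_reference(cfg)
  coh <- generate_cohort(cfg, ref)
  dm <- depth_matrix(coh$depth)
  males <- coh$manifest[sex == "male", sample_id]
  females <- coh$manifest[sex == "female", sample_id]
  merged <- merge_samples(c(lapply(coh$vcfs[males], filter_quality),
                            coh$vcfs[females]), coh$manifest$sample_id)
  sites <- sex_associated_variants(merged, males, females, dm)
  segs <- per_segment_counts(sites, ref$contig_lengths)
  tab <- peak_table(scan_clusters(segs, 30L), sites)
  tr <- coh$truth
  expect_equal(tab[, .(contig, window_index)], tr$sex_windows,
               ignore_attr = TRUE)
  expected_bounds <- tr$sex_sites[, .(first = min(pos), last = max(pos)),
                                  by = .(contig, window_index)]
  expect_equal(tab$first_variant_pos, expected_bounds$first)
  expect_equal(tab$last_variant_pos, expected_bounds$last)
  expect_equal(tab$n_variants, c(34L, 40L))
  # each peak's nearest gene matches the brute-force assignment
  asg <- nearest_gene(tab[, .(contig, pos_start = first_variant_pos,
                              pos_end = last_variant_pos)], ref$genes)
  want <- bf_nearest_gene(tab[, .(contig, pos_start = first_variant_pos,
                                  pos_end = last_variant_pos)], ref$genes)
  expect_equal(asg$gene_name, want$name)
})
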