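test_that("the quality filter keeps strictly greater QUAL only", {
  rec <- data.table::data.table(contig = "c1", pos = 1:4, ref = "A", alt = "T",
                                qual = c(30, 30.01, 29.99, 100), gt = "1/1")
  kept <- filter_quality(rec)
  expect_equal(kept$qual, c(30.01, 100))
  expect_equal(nrow(filter_quality(rec[0])), 0L)
  # planted decoys are removed and planted-pass truth survives exactly
  fx <- small_cohort()
  tr <- fx$coh$truth
  for (s in fx$coh$manifest[sex == "male", sample_id]) {
    kept <- filter_quality(fx$coh$vcfs[[s]])
    expect_length(intersect(kept[, paste(contig, pos)],
                            tr$decoy_sites[, paste(contig, pos)]), 0L)
    expect_true(all(tr$sex_sites[, paste(contig, pos)] %in%
                      kept[, paste(contig, pos)]))
    expect_true(all(tr$fixed_sites[, paste(contig, pos)] %in%
                      kept[, paste(contig, pos)]))
  }
})

test_that("merging computes allele counts and missingness correctly", {
  ten <- setNames(rep("1/1", 10L), paste0("s", 1:10))
  m <- toy_merged(as.list(ten))
  expect_equal(nrow(m), 1L)
  expect_equal(m$AN, 20L)
  expect_equal(m$AC, 20L)
  expect_equal(m$AF, 1)

  nine <- as.list(ten); nine$s10 <- NA
  m9 <- toy_merged(nine)
  expect_equal(m9$AN, 18L)
  expect_equal(m9$AC, 18L)
  expect_equal(m9$AF, 1)
  expect_true(is.na(m9$gt_s10))

  het <- as.list(ten); het$s10 <- "0/1"
  mh <- toy_merged(het)
  expect_equal(mh$AC, 19L)
  expect_equal(mh$AN, 20L)
})

test_that("conflicting REF alleles at one position are excluded with a note", {
  a <- data.table::data.table(contig = "c1", pos = 5L, ref = "A", alt = "T",
                              qual = 50, gt = "1/1")
  b <- data.table::data.table(contig = "c1", pos = 5L, ref = "G", alt = "T",
                              qual = 50, gt = "1/1")
  expect_message(m <- merge_samples(list(s1 = a, s2 = b)), "conflicting REF")
  expect_equal(nrow(m), 0L)
})

test_that("inter-species fixed extraction requires 1/1 in every sample", {
  ten <- setNames(rep("1/1", 10L), paste0("s", 1:10))
  expect_equal(nrow(interspecies_fixed_variants(toy_merged(as.list(ten)))), 1L)
  het <- as.list(ten); het$s10 <- "0/1"
  expect_equal(nrow(interspecies_fixed_variants(toy_merged(het))), 0L)
  miss <- as.list(ten); miss$s10 <- NA
  expect_equal(nrow(interspecies_fixed_variants(toy_merged(miss),
                                                n_samples = 10L)), 0L)
  # synthetic cohort: recovered set equals the planted fixed truth
  mg <- small_merges()
  fx <- small_cohort()
  fixed <- interspecies_fixed_variants(mg$all_filtered)
  expect_setequal(fixed[, paste(contig, pos)],
                  fx$coh$truth$fixed_sites[, paste(contig, pos)])
})

test_that("sex-associated extraction applies all three rules", {
  gts <- c(setNames(rep("1/1", 5L), paste0("m", 1:5)),
           setNames(rep(NA_character_, 5L), paste0("f", 1:5)))
  males <- paste0("m", 1:5); females <- paste0("f", 1:5)
  dm_ok <- toy_depth_matrix(setNames(rep(list(rep(5L, 200L)), 10L),
                                     c(males, females)))
  m <- toy_merged(as.list(gts))
  expect_equal(nrow(sex_associated_variants(m, males, females, dm_ok)), 1L)

  # one female 1/1 (whatever its QUAL was) disqualifies
  bad <- as.list(gts); bad$f1 <- "1/1"
  expect_equal(nrow(sex_associated_variants(toy_merged(bad), males, females,
                                            dm_ok)), 0L)
  # heterozygous and reference females are fine
  mix <- as.list(gts); mix$f1 <- "0/1"; mix$f2 <- "0/0"
  expect_equal(nrow(sex_associated_variants(toy_merged(mix), males, females,
                                            dm_ok)), 1L)
  # depth gate is strict: one sample at exactly 2 kills the site
  depths <- setNames(rep(list(rep(5L, 200L)), 10L), c(males, females))
  depths$f3 <- rep(5L, 200L); depths$f3[100L] <- 2L
  dm_edge <- toy_depth_matrix(depths)
  expect_equal(nrow(sex_associated_variants(m, males, females, dm_edge)), 0L)
  depths$f3[100L] <- 3L
  expect_equal(nrow(sex_associated_variants(m, males, females,
                                            toy_depth_matrix(depths))), 1L)
  # a site missing from the depth matrix is a hard error
  dm_short <- toy_depth_matrix(setNames(rep(list(rep(5L, 50L)), 10L),
                                        c(males, females)))
  expect_error(sex_associated_variants(m, males, females, dm_short),
               "absent from depth matrix")
})

test_that("a female homozygous for another ALT allele disqualifies the position", {
  males <- paste0("m", 1:5); females <- paste0("f", 1:5)
  streams <- c(
    lapply(setNames(males, males), function(s)
      data.table::data.table(contig = "c1", pos = 100L, ref = "A", alt = "T",
                             qual = 60, gt = "1/1")),
    lapply(setNames(females, females), function(s)
      data.table::data.table(contig = "c1", pos = 100L, ref = "A", alt = "G",
                             qual = 10, gt = "1/1"))
  )
  m <- merge_samples(streams)
  dm <- toy_depth_matrix(setNames(rep(list(rep(9L, 200L)), 10L),
                                  c(males, females)))
  expect_equal(nrow(sex_associated_variants(m, males, females, dm)), 0L)
})

test_that("synthetic sex-associated recovery is exact and oracle-equivalent", {
  fx <- small_cohort()
  mg <- small_merges()
  got <- sex_associated_variants(mg$asym, mg$males, mg$females, fx$dm)
  expect_setequal(got[, paste(contig, pos)],
                  fx$coh$truth$sex_sites[, paste(contig, pos)])
  want <- bf_sex_associated(mg$asym, mg$males, mg$females, fx$dm)
  expect_equal(got[, .(contig, pos, ref, alt)], want[, .(contig, pos, ref, alt)])
  # fixed extraction agrees with its oracle too
  expect_equal(interspecies_fixed_variants(mg$all_filtered)[, .(contig, pos)],
               bf_fixed_variants(mg$all_filtered,
                                 fx$coh$manifest$sample_id)[, .(contig, pos)])
})

test_that("variant classification follows the allele-shape rules", {
  expect_equal(classify_variant("A", "G"), "snp")
  expect_equal(classify_variant("A", "AT"), "insertion")
  expect_equal(classify_variant("ACT", "A"), "deletion")
  expect_equal(classify_variant("AC", "GT"), "mnp_other")
  expect_error(classify_variant("A", "N"), "A/C/G/T")
  sites <- data.table::data.table(
    ref = c(rep("A", 90L), rep("A", 10L)),
    alt = c(rep("G", 90L), rep("AT", 10L))
  )
  pr <- variant_class_proportions(sites)
  expect_equal(unname(pr[["snp"]]), 90)
  expect_equal(unname(pr[["insertion"]]), 10)
  expect_equal(sum(pr), 100)
})

test_that("spacing statistics use within-contig consecutive distances only", {
  s <- data.table::data.table(contig = "c1", pos = c(100L, 200L, 350L))
  sp <- variant_spacing_stats(s)
  expect_equal(sp$distances$distance, c(100L, 150L))
  expect_equal(sp$mean_distance, 125)

  one_per <- data.table::data.table(contig = paste0("c", 1:5), pos = 10L)
  sp1 <- variant_spacing_stats(one_per)
  expect_equal(sp1$n_distances, 0L)
  expect_true(is.na(sp1$mean_distance))

  set.seed(9)
  rnd <- data.table::data.table(
    contig = sample(c("c1", "c2", "c3"), 60L, replace = TRUE),
    pos = sample.int(5000L, 60L)
  )
  want <- bf_spacing(rnd)
  got <- variant_spacing_stats(rnd)
  expect_equal(got$mean_distance, want$mean_distance)
  expect_equal(got$n_distances, want$n_distances)
  expect_true(all(got$distances$distance > 0L))
})

test_that("segment counts cover every implied window", {
  lens <- c(c1 = 25000L)
  s <- data.table::data.table(contig = "c1", pos = c(5L, 10005L, 10006L))
  sc <- per_segment_counts(s, lens)
  expect_equal(sc$windows$count, c(1L, 2L, 0L))
  expect_equal(sc$windows$end, c(10000L, 20000L, 25000L))
  expect_equal(sc$mean_incl_empty, 1)
  expect_equal(sc$mean_excl_empty, 1.5)

  empty <- per_segment_counts(s[0], lens)
  expect_true(all(empty$windows$count == 0L))
  expect_true(is.na(empty$mean_excl_empty))

  expect_error(per_segment_counts(
    data.table::data.table(contig = "c1", pos = 25001L), lens),
    "beyond contig length")

  fx <- small_cohort()
  tr <- fx$coh$truth
  sc2 <- per_segment_counts(tr$sex_sites, fx$ref$contig_lengths)
  expect_equal(sum(sc2$windows$count), nrow(tr$sex_sites))
  want <- bf_segment_counts(tr$sex_sites, fx$ref$contig_lengths)
  expect_equal(as.data.frame(sc2$windows), want, ignore_attr = TRUE)
})

test_that("raising thresholds never enlarges the extracted site sets", {
  fx <- small_cohort()
  mg <- small_merges()
  n_prev <- Inf
  for (mq in c(0, 30, 60, 90)) {
    filtered <- lapply(fx$coh$vcfs, filter_quality, min_qual = mq)
    merged <- merge_samples(filtered, fx$coh$manifest$sample_id)
    n <- nrow(interspecies_fixed_variants(merged))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (md in c(0L, 2L, 5L, 11L)) {
    n <- nrow(sex_associated_variants(mg$asym, mg$males, mg$females, fx$dm,
                                      min_depth_exclusive = md))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
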