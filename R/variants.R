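#' Quality-filter variant records
#'
#' Retains records with QUAL strictly greater than `min_qual` (a record
#' with QUAL exactly equal to the threshold is removed). Input order is
#' preserved.
#'
#' @param records `data.table` of variant records with a `qual` column.
#' @param min_qual Quality threshold (default 30).
#' @return Filtered `data.table`.
#' @export
filter_quality <- function(records, min_qual = 30) {
  records[qual > min_qual]
}

gt_alt_count <- function(gt) {
  data.table::fcase(
    is.na(gt), 0L,
    gt == "1/1", 2L,
    gt %in% c("0/1", "1/0"), 1L,
    gt == "0/0", 0L,
    default = NA_integer_
  )
}

#' Merge per-sample variant streams into multi-sample sites
#'
#' Sites are keyed by (contig, pos, ref, alt); a sample without a record at
#' a key gets a missing genotype. Allele counts follow the usual VCF
#' conventions: AC counts ALT alleles over called genotypes, AN counts
#' called alleles (2 per non-missing sample), AF = AC/AN. Positions where
#' samples disagree on the REF allele are excluded with a message.
#'
#' @param streams Named list (sample -> record `data.table` with columns
#'   contig, pos, ref, alt, qual, gt).
#' @param samples Sample order for the genotype columns (default: names of
#'   `streams`).
#' @return A `merged_sites` `data.table`: contig, pos, ref, alt, one
#'   `gt_<sample>` column per sample, AC, AN, AF; samples recorded in
#'   `attr(, "samples")`.
#' @export
merge_samples <- function(streams, samples = names(streams)) {
  stopifnot(is.list(streams), !is.null(names(streams)),
            all(samples %in% names(streams)))
  tagged <- data.table::rbindlist(lapply(samples, function(s) {
    x <- streams[[s]]
    if (!nrow(x)) return(NULL)
    cbind(x[, .(contig, pos, ref, alt, gt)], sample_id = s)
  }))
  if (is.null(tagged) || !nrow(tagged)) {
    out <- data.table::data.table(contig = character(), pos = integer(),
                                  ref = character(), alt = character())
    for (s in samples) out[, (paste0("gt_", s)) := character(0)]
    out[, `:=`(AC = integer(0), AN = integer(0), AF = numeric(0))]
    data.table::setattr(out, "samples", samples)
    return(out)
  }
  # reject positions with conflicting REF alleles across samples
  ref_conflict <- unique(tagged[, .(contig, pos, ref)])[
    , .(n_ref = .N), by = .(contig, pos)][n_ref > 1L]
  if (nrow(ref_conflict)) {
    message("merge_samples: excluded ", nrow(ref_conflict),
            " position(s) with conflicting REF alleles")
    tagged <- tagged[!ref_conflict, on = .(contig, pos)]
  }
  wide <- data.table::dcast(tagged, contig + pos + ref + alt ~ sample_id,
                            value.var = "gt")
  for (s in setdiff(samples, names(wide))) wide[, (s) := NA_character_]
  data.table::setnames(wide, samples, paste0("gt_", samples))
  data.table::setcolorder(wide, c("contig", "pos", "ref", "alt",
                                  paste0("gt_", samples)))
  gt_cols <- paste0("gt_", samples)
  acm <- as.matrix(wide[, lapply(.SD, gt_alt_count), .SDcols = gt_cols])
  called <- !is.na(as.matrix(wide[, ..gt_cols]))
  wide[, AC := as.integer(rowSums(acm, na.rm = TRUE))]
  wide[, AN := 2L * as.integer(rowSums(called))]
  wide[, AF := ifelse(AN > 0L, AC / AN, NA_real_)]
  data.table::setorder(wide, contig, pos, alt)
  data.table::setattr(wide, "samples", samples)
  wide[]
}

merged_gt_cols <- function(merged, samples = attr(merged, "samples")) {
  paste0("gt_", samples)
}

#' Inter-species fixed variants: homozygous ALT in every sample
#'
#' Returns the merged sites where all samples carry the 1/1 genotype, i.e.
#' AC = AN = 2 x n_samples and AF = 1. The AF test is done on the integer
#' identity AC == AN (with AN at its full value), never on floating-point
#' equality. A missing genotype disqualifies the site.
#'
#' @param merged `merged_sites` built from quality-filtered records of all
#'   samples.
#' @param n_samples Expected cohort size (default: all samples in `merged`).
#' @return Subset of `merged` rows.
#' @export
interspecies_fixed_variants <- function(merged,
                                        n_samples = length(attr(merged, "samples"))) {
  gt_cols <- merged_gt_cols(merged)
  if (length(gt_cols) < n_samples)
    stop("merged stream has fewer samples than n_samples")
  gm <- as.matrix(merged[, ..gt_cols])
  all11 <- rowSums(gm == "1/1", na.rm = TRUE) == n_samples &
    rowSums(!is.na(gm)) == n_samples
  merged[all11 & merged$AC == merged$AN & merged$AN == 2L * n_samples]
}

#' Sex-associated variants under the asymmetric male/female design
#'
#' A site is reported when (a) every male sample is homozygous ALT (1/1) in
#' the quality-filtered male records; (b) every female sample is 0/1, 0/0,
#' or has no record at the site in the deliberately unfiltered female
#' records (a recordless female counts as reference-homozygous because the
#' caller emits variant-only VCFs); and (c) read depth is strictly greater
#' than `min_depth_exclusive` in every sample at the position, so that
#' female reference calls are backed by coverage. A female 1/1 genotype at
#' the position -- at any ALT allele and any QUAL -- disqualifies it.
#'
#' @param merged `merged_sites` over all samples, built from
#'   quality-filtered male streams and unfiltered female streams.
#' @param males,females Sample names of each sex.
#' @param dm A `depth_matrix` covering every site (a site absent from the
#'   matrix is an error: the depth gate cannot be evaluated).
#' @param min_depth_exclusive Depth must exceed this value in all samples
#'   (default 2, i.e. depth >= 3).
#' @return Subset of `merged` rows that pass all three rules.
#' @export
sex_associated_variants <- function(merged, males, females, dm,
                                    min_depth_exclusive = 2L) {
  samples <- attr(merged, "samples")
  stopifnot(all(c(males, females) %in% samples))
  if (!nrow(merged)) return(merged)
  male_cols <- paste0("gt_", males)
  female_cols <- paste0("gt_", females)

  gm <- as.matrix(merged[, ..male_cols])
  cond_a <- rowSums(gm == "1/1", na.rm = TRUE) == length(males) &
    rowSums(!is.na(gm)) == length(males)

  gf <- as.matrix(merged[, ..female_cols])
  cond_b <- rowSums(is.na(gf) | gf == "0/1" | gf == "0/0") == length(females)

  # a female 1/1 at the same position under any ALT key disqualifies it
  any_f11 <- rowSums(gf == "1/1", na.rm = TRUE) > 0L
  bad_pos <- unique(merged[any_f11, .(contig, pos)])
  not_disq <- if (nrow(bad_pos)) {
    is.na(bad_pos[merged, on = .(contig, pos), which = TRUE])
  } else rep(TRUE, nrow(merged))

  cand <- merged[cond_a & cond_b & not_disq]
  if (!nrow(cand)) return(cand)

  check_samples_present(dm, c(males, females))
  idx <- dm[cand[, .(contig, pos)], on = .(contig, pos), which = TRUE]
  if (anyNA(idx)) {
    miss <- cand[is.na(idx)][1L]
    stop("site ", miss$contig, ":", miss$pos,
         " absent from depth matrix; depth gate cannot be evaluated")
  }
  depth_mat <- as.matrix(dm[idx, c(males, females), with = FALSE])
  gate <- rowSums(depth_mat > min_depth_exclusive) == ncol(depth_mat)
  cand[gate]
}

#' Classify a variant by its REF/ALT alleles
#'
#' SNP: both alleles single bases. Insertion: ALT longer than REF with a
#' shared first base; deletion: REF longer than ALT with a shared first
#' base. Everything else (including equal-length multi-base substitutions)
#' is `mnp_other`.
#'
#' @param ref,alt Character vectors of REF/ALT alleles (uppercase A/C/G/T).
#' @return Character vector of classes: snp, insertion, deletion, mnp_other.
#' @export
classify_variant <- function(ref, alt) {
  if (any(!grepl("^[ACGT]+$", c(ref, alt))))
    stop("alleles must be non-empty uppercase A/C/G/T strings")
  if (any(ref == alt)) stop("REF and ALT must differ")
  nr <- nchar(ref); na_ <- nchar(alt)
  shared_first <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  data.table::fcase(
    nr == 1L & na_ == 1L, "snp",
    na_ > nr & shared_first, "insertion",
    nr > na_ & shared_first, "deletion",
    default = "mnp_other"
  )
}

#' Class proportions over a site list
#'
#' @param sites `data.table` with ref/alt columns.
#' @return Named numeric vector of percentages (snp, insertion, deletion,
#'   mnp_other) summing to 100 (all-NA for an empty list).
#' @export
variant_class_proportions <- function(sites) {
  lv <- c("snp", "insertion", "deletion", "mnp_other")
  if (!nrow(sites)) return(setNames(rep(NA_real_, 4L), lv))
  cls <- factor(classify_variant(sites$ref, sites$alt), levels = lv)
  setNames(100 * as.numeric(table(cls)) / nrow(sites), lv)
}

#' Spacing between consecutive variants within contigs
#'
#' Distances are computed between consecutive variant positions on the same
#' contig only; contigs with fewer than two variants contribute none, and
#' no cross-contig distances are formed. Duplicate positions (multi-allelic
#' keys) are collapsed first.
#'
#' @param sites `data.table` with contig/pos columns.
#' @return List with `distances` (`data.table`: contig, distance),
#'   `mean_distance` (NA when no pair exists) and `n_distances`.
#' @export
variant_spacing_stats <- function(sites) {
  u <- unique(sites[, .(contig, pos)])
  data.table::setorder(u, contig, pos)
  d <- u[, if (.N >= 2L) .(distance = diff(pos)) else NULL, by = contig]
  if (is.null(d) || !nrow(d))
    return(list(distances = data.table::data.table(contig = character(),
                                                   distance = integer()),
                mean_distance = NA_real_, n_distances = 0L))
  list(distances = d[], mean_distance = mean(d$distance), n_distances = nrow(d))
}

#' Variant counts per fixed-width genome segment
#'
#' Segments (windows) are consecutive non-overlapping `window`-bp blocks
#' anchored at position 1 of every contig; the final partial window is
#' retained. Every implied window is counted, including empty ones; the
#' window index is `floor((pos - 1) / window)`. Every site row counts, so
#' multi-allelic keys at one position contribute one count each.
#'
#' @param sites `data.table` with contig/pos columns.
#' @param contig_lengths Named integer vector of contig lengths.
#' @param window Window width in bp (default 10000).
#' @return A `segment_counts` list: `windows` (`data.table`: contig,
#'   window_index, start, end, count), `window`, `n_sites`,
#'   `mean_incl_empty`, `mean_excl_empty` (NA when no window has a variant).
#' @export
per_segment_counts <- function(sites, contig_lengths, window = 10000L) {
  stopifnot(length(contig_lengths) >= 1L, !is.null(names(contig_lengths)))
  if (nrow(sites)) {
    unknown <- setdiff(unique(sites$contig), names(contig_lengths))
    if (length(unknown))
      stop("site on contig with unknown length: ", paste(unknown, collapse = ", "))
    over <- sites[pos > contig_lengths[contig]]
    if (nrow(over))
      stop("site beyond contig length: ", over$contig[1L], ":", over$pos[1L])
  }
  frame <- data.table::rbindlist(lapply(names(contig_lengths), function(ctg) {
    L <- contig_lengths[[ctg]]
    n_win <- as.integer(ceiling(L / window))
    wi <- seq_len(n_win) - 1L
    data.table::data.table(contig = ctg, window_index = wi,
                           start = wi * window + 1L,
                           end = pmin((wi + 1L) * window, L))
  }))
  if (nrow(sites)) {
    cnt <- sites[, .(contig, window_index = (pos - 1L) %/% as.integer(window))][
      , .(count = .N), by = .(contig, window_index)]
    frame <- cnt[frame, on = .(contig, window_index)]
    frame[is.na(count), count := 0L]
  } else frame[, count := 0L]
  data.table::setcolorder(frame, c("contig", "window_index", "start", "end", "count"))
  data.table::setorder(frame, contig, window_index)
  out <- list(
    windows = frame[],
    window = as.integer(window),
    n_sites = nrow(sites),
    mean_incl_empty = mean(frame$count),
    mean_excl_empty = if (any(frame$count > 0L)) mean(frame$count[frame$count > 0L])
    else NA_real_
  )
  class(out) <- "segment_counts"
  out
}
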