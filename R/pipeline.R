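#' Pipeline run configuration
#'
#' Bundles every threshold of the discovery pipeline in one auditable
#' place; stage functions receive them explicitly and hold no hidden
#' constants.
#'
#' @param sim A `sim_config` describing the synthetic cohort (see
#'   [simulation_config()]); its seed drives all randomness.
#' @param out_dir Output directory for all artifacts.
#' @param min_qual QUAL threshold for the strict quality filter
#'   (records kept when QUAL > min_qual; default 30).
#' @param min_depth_exclusive Per-sample depth gate for sex-associated
#'   sites (depth must exceed this; default 2).
#' @param exclusive_min_depth,exclusive_min_samples Sex-exclusive coverage
#'   rule: depth >= `exclusive_min_depth` in at least
#'   `exclusive_min_samples` samples of the covered sex (defaults 10 and 3).
#' @param window Segment width in bp (default 10000).
#' @param cluster_threshold Minimum variants for a peak (default 30).
#' @param ds_lo,ds_hi Inclusive dS plausibility bounds (defaults 0.01, 2).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = simulation_config(), out_dir = tempfile("svs_run_"),
                       min_qual = 30, min_depth_exclusive = 2L,
                       exclusive_min_depth = 10L, exclusive_min_samples = 3L,
                       window = 10000L, cluster_threshold = 30L,
                       ds_lo = 0.01, ds_hi = 2.0) {
  cfg <- list(sim = sim, out_dir = out_dir, min_qual = min_qual,
              min_depth_exclusive = as.integer(min_depth_exclusive),
              exclusive_min_depth = as.integer(exclusive_min_depth),
              exclusive_min_samples = as.integer(exclusive_min_samples),
              window = as.integer(window),
              cluster_threshold = as.integer(cluster_threshold),
              ds_lo = ds_lo, ds_hi = ds_hi)
  class(cfg) <- "run_config"
  cfg
}

# Hash of the scientific part of the configuration (output paths excluded,
# so reruns into different directories compare equal).
config_hash <- function(config) {
  core <- config[setdiff(names(config), "out_dir")]
  core$sim <- unclass(core$sim)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(core, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full discovery pipeline on a simulated cohort
#'
#' Stages, in order: simulate reference + cohort + ortholog pairs; re-read
#' every artifact from disk through the package parsers; per-sample and
#' per-sex coverage summaries; sex-exclusive coverage positions (both
#' directions); quality filtering and merging of variant calls;
#' inter-species fixed variants (all samples filtered); sex-associated
#' variants (filtered males + unfiltered females + depth gate); class
#' proportions, spacing and 10 kb segment statistics; peak calling, peak
#' table and nearest-gene assignment; NG86 dN/dS with the dS filter.
#' Rerunning with an identical configuration reproduces identical outputs.
#'
#' @param config A `run_config`.
#' @return A `run_report` list; also written as `report.json` under
#'   `config$out_dir` together with all intermediate TSV artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_dir <- file.path(config$out_dir, "sim")

  # --- stage 1: simulate ---
  reference <- generate_reference(config$sim, dir = sim_dir)
  cohort <- generate_cohort(config$sim, reference, dir = sim_dir)
  orth <- generate_ortholog_pairs(config$sim, dir = sim_dir)

  # --- stage 2: read back from disk ---
  contig_lengths <- read_contig_lengths(file.path(sim_dir, "reference.fa.fai"))
  genes <- read_genes_bed(file.path(sim_dir, "genes.bed"))
  manifest <- data.table::fread(file.path(sim_dir, "manifest.tsv"))
  males <- manifest[sex == "male", sample_id]
  females <- manifest[sex == "female", sample_id]
  dm <- read_depth_dir(file.path(sim_dir, "depth"), samples = manifest$sample_id)
  vcfs <- lapply(setNames(manifest$sample_id, manifest$sample_id), function(s)
    read_vcf(file.path(sim_dir, "vcf", paste0(s, ".vcf"))))

  # --- stage 3: coverage ---
  cov <- c(
    lapply(setNames(manifest$sample_id, manifest$sample_id), function(s)
      coverage_summary(dm, s)),
    list(males = coverage_summary(dm, males, group = "males"),
         females = coverage_summary(dm, females, group = "females"),
         all = coverage_summary(dm, manifest$sample_id, group = "all"))
  )
  cov_tab <- data.table::rbindlist(lapply(cov, function(x)
    data.table::data.table(group = x$group, n_positions = x$n_positions,
                           covered_fraction = x$covered_fraction,
                           mean_depth = x$mean_depth)))
  data.table::fwrite(cov_tab, file.path(config$out_dir, "coverage_summary.tsv"),
                     sep = "\t")

  # --- stage 4: sex-exclusive coverage ---
  excl_female_zero <- sex_exclusive_positions(
    dm, females, males, config$exclusive_min_depth, config$exclusive_min_samples)
  excl_male_zero <- sex_exclusive_positions(
    dm, males, females, config$exclusive_min_depth, config$exclusive_min_samples)
  data.table::fwrite(excl_female_zero$sites,
                     file.path(config$out_dir, "exclusive_female_zero.tsv"),
                     sep = "\t")
  data.table::fwrite(excl_male_zero$sites,
                     file.path(config$out_dir, "exclusive_male_zero.tsv"),
                     sep = "\t")

  # --- stage 5: variants ---
  filtered <- lapply(vcfs, filter_quality, min_qual = config$min_qual)
  merged_all_filtered <- merge_samples(filtered, manifest$sample_id)
  fixed <- interspecies_fixed_variants(merged_all_filtered)

  asym_streams <- c(filtered[males], vcfs[females])
  merged_asym <- merge_samples(asym_streams, manifest$sample_id)
  sex_sites <- sex_associated_variants(merged_asym, males, females, dm,
                                       config$min_depth_exclusive)
  data.table::fwrite(fixed[, .(contig, pos, ref, alt, AC, AN, AF)],
                     file.path(config$out_dir, "interspecies_fixed.tsv"),
                     sep = "\t")
  data.table::fwrite(sex_sites[, .(contig, pos, ref, alt, AC, AN, AF)],
                     file.path(config$out_dir, "sex_associated.tsv"), sep = "\t")

  # --- stage 6: statistics ---
  props_sex <- variant_class_proportions(sex_sites)
  props_fixed <- variant_class_proportions(fixed)
  spacing_sex <- variant_spacing_stats(sex_sites)
  spacing_fixed <- variant_spacing_stats(fixed)
  segments_sex <- per_segment_counts(sex_sites, contig_lengths, config$window)
  segments_fixed <- per_segment_counts(fixed, contig_lengths, config$window)
  data.table::fwrite(segments_sex$windows,
                     file.path(config$out_dir, "segments_sex.tsv"), sep = "\t")

  # --- stage 7: peaks and genes ---
  scan <- scan_clusters(segments_sex, config$cluster_threshold)
  ptab <- peak_table(scan, sex_sites)
  data.table::fwrite(ptab, file.path(config$out_dir, "peaks.tsv"), sep = "\t")
  gene_assign <- if (nrow(ptab)) {
    nearest_gene(ptab[, .(contig, pos_start = first_variant_pos,
                          pos_end = last_variant_pos)], genes)
  } else nearest_gene(data.table::data.table(contig = character(),
                                             pos = integer()), genes)
  data.table::fwrite(gene_assign, file.path(config$out_dir, "peak_genes.tsv"),
                     sep = "\t")
  genes_summary <- distinct_gene_count(gene_assign)

  # --- stage 8: dN/dS ---
  pair_ids <- orth$ortholog_truth$pair_id
  alignments <- lapply(pair_ids, function(pid) {
    codon_align(orth$proteins[[paste0(pid, "_a")]],
                orth$proteins[[paste0(pid, "_b")]],
                orth$cds[[paste0(pid, "_a")]],
                orth$cds[[paste0(pid, "_b")]], pair_id = pid)
  })
  dnds <- ng86_batch(alignments)
  dnds_kept <- suppressMessages(ds_filter(dnds, config$ds_lo, config$ds_hi))
  data.table::fwrite(dnds, file.path(config$out_dir, "dnds.tsv"), sep = "\t")

  report <- list(
    provenance = list(seed = config$sim$seed, config_hash = config_hash(config),
                      package_version = as.character(packageVersion("sexvarscan"))),
    coverage = cov_tab,
    sex_exclusive = list(
      female_zero = list(n_positions = nrow(excl_female_zero$sites),
                         n_contigs = excl_female_zero$n_contigs),
      male_zero = list(n_positions = nrow(excl_male_zero$sites),
                       n_contigs = excl_male_zero$n_contigs)
    ),
    variants = list(
      n_interspecies_fixed = nrow(fixed),
      n_sex_associated = nrow(sex_sites),
      class_proportions_sex = as.list(props_sex),
      class_proportions_fixed = as.list(props_fixed),
      mean_spacing_sex = spacing_sex$mean_distance,
      mean_spacing_fixed = spacing_fixed$mean_distance,
      segments_sex = list(mean_incl_empty = segments_sex$mean_incl_empty,
                          mean_excl_empty = segments_sex$mean_excl_empty),
      segments_fixed = list(mean_incl_empty = segments_fixed$mean_incl_empty,
                            mean_excl_empty = segments_fixed$mean_excl_empty)
    ),
    peaks = list(n_peaks = nrow(ptab),
                 n_nonempty_windows = scan$n_nonempty_windows,
                 n_contigs_nonempty = scan$n_contigs_nonempty,
                 table = ptab),
    genes = list(n_distinct_genes = genes_summary$n_distinct_genes,
                 n_assignments = genes_summary$n_assignments,
                 table = gene_assign),
    dnds = list(n_pairs = nrow(dnds), n_kept = attr(dnds_kept, "n_kept"),
                n_dropped = attr(dnds_kept, "n_dropped"),
                table = dnds)
  )
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", force = TRUE)
  report
}

#' @method print run_report
#' @export
print.run_report <- function(x, ...) {
  cat("sexvarscan run report\n",
      "  interspecies fixed sites: ", x$variants$n_interspecies_fixed, "\n",
      "  sex-associated sites:     ", x$variants$n_sex_associated, "\n",
      "  peaks (>= threshold):     ", x$peaks$n_peaks, "\n",
      "  distinct nearest genes:   ", x$genes$n_distinct_genes, "\n",
      "  dN/dS pairs kept by dS:   ", x$dnds$n_kept, "/", x$dnds$n_pairs, "\n",
      sep = "")
  invisible(x)
}

#' Validate an on-disk input bundle
#'
#' Checks, without running the pipeline: VCF sortedness per sample, depth
#' table density (dense -aa layout), gene BED sortedness, manifest sanity
#' (exactly two sex labels), and contig-name agreement between the VCFs,
#' depth tables and the reference index. Diagnostics are returned with a
#' `level` of `"fatal"` or `"warning"`.
#'
#' @param dir Directory holding `reference.fa.fai`, `genes.bed`,
#'   `manifest.tsv`, `depth/` and `vcf/` (the [run_pipeline()] simulation
#'   layout).
#' @return `data.table` of diagnostics (level, message); zero rows when the
#'   bundle is well formed.
#' @export
validate_inputs <- function(dir) {
  diags <- list()
  note <- function(level, msg)
    diags[[length(diags) + 1L]] <<- data.table::data.table(level = level,
                                                           message = msg)
  fai <- file.path(dir, "reference.fa.fai")
  contigs <- character(0)
  if (!file.exists(fai)) note("fatal", "missing reference index reference.fa.fai")
  else contigs <- names(read_contig_lengths(fai))

  man_path <- file.path(dir, "manifest.tsv")
  manifest <- NULL
  if (!file.exists(man_path)) note("fatal", "missing manifest.tsv")
  else {
    manifest <- data.table::fread(man_path)
    sexes <- unique(manifest$sex)
    if (length(sexes) != 2L)
      note("fatal", paste0("manifest must contain exactly two sex labels, found ",
                           length(sexes)))
  }

  bed <- file.path(dir, "genes.bed")
  if (!file.exists(bed)) note("warning", "missing genes.bed")
  else {
    genes <- read_genes_bed(bed)
    bad <- genes[, .(bad = is.unsorted(start)), by = contig][bad == TRUE]
    if (nrow(bad))
      note("fatal", paste0("genes.bed is not coordinate-sorted (contig ",
                           bad$contig[1L],
                           "); sort by contig then start and retry"))
    if (length(contigs) && !all(genes$contig %in% contigs))
      note("warning", "genes.bed names contigs absent from the reference index")
  }

  if (!is.null(manifest)) {
    for (s in manifest$sample_id) {
      dp <- file.path(dir, "depth", paste0(s, ".depth.tsv"))
      if (!file.exists(dp)) { note("fatal", paste0("missing depth table for ", s)); next }
      ok <- tryCatch({ parse_depth_table(dp); TRUE },
                     error = function(e) { note("fatal", conditionMessage(e)); FALSE })
      vp <- file.path(dir, "vcf", paste0(s, ".vcf"))
      if (!file.exists(vp)) { note("fatal", paste0("missing VCF for ", s)); next }
      body <- grep("^#", readLines(vp), invert = TRUE, value = TRUE)
      if (length(body)) {
        chrom <- sub("\t.*$", "", body)
        p <- as.integer(vapply(strsplit(body, "\t", fixed = TRUE), `[[`, "", 2L))
        if (!identical(order(chrom, p), seq_along(body)))
          note("fatal", paste0("VCF for ", s, " is not sorted by contig, position"))
        if (length(contigs) && !all(chrom %in% contigs))
          note("fatal", paste0("VCF for ", s,
                               " names contigs absent from the reference index"))
      }
    }
  }
  if (!length(diags))
    return(data.table::data.table(level = character(), message = character()))
  data.table::rbindlist(diags)
}
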