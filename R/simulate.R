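#' Configuration for a synthetic whole-genome cohort
#'
#' Describes a toy diploid-coded cohort of `n_male` + `n_female` samples on a
#' small random reference, with planted inter-species fixed variants,
#' clustered sex-associated variants, background heterozygous noise,
#' low-quality decoy records and sex-exclusive coverage blocks. All planted
#' coordinates are recorded in a truth set so downstream recovery can be
#' scored exactly.
#'
#' Genotypes are diploid-coded (0/0, 0/1, 1/1) even though sturgeons are
#' polyploid: this mirrors the diploid caller model the pipeline consumes.
#'
#' @param seed Integer seed; the whole bundle is byte-identical for a fixed
#'   seed and configuration.
#' @param n_contigs,contig_length_bp Reference shape. Each contig must hold
#'   at least three 10 kb windows.
#' @param n_male,n_female Cohort composition (default 5 + 5).
#' @param mean_depth Poisson mean of per-position read depth.
#' @param background_het_rate Per-bp probability that a position carries a
#'   0/1 noise variant in one random sample.
#' @param fixed_diff_rate Per-bp probability of a species-fixed site
#'   (1/1 in every sample).
#' @param planted_clusters List of `list(contig=, start=, n=)`: `n`
#'   sex-associated variants planted inside the 10 kb window starting at
#'   `start` (1-based; males 1/1 with passing QUAL, females 0/1 or absent).
#' @param low_qual_fraction Probability that a planted passing record is
#'   demoted to QUAL <= 30 (default 0: planted truth survives the quality
#'   filter exactly).
#' @param n_decoys Number of standalone decoy sites: 1/1 in all males but
#'   with QUAL <= 30, so the quality filter must remove them.
#' @param sex_exclusive_blocks List of `list(contig=, start=, end=, zero_sex=)`
#'   blocks with zero depth in every sample of `zero_sex` and depth >= 10 in
#'   at least three samples of the other sex.
#' @param n_genes,gene_length_bp Gene annotation shape: `n_genes`
#'   non-overlapping genes of `gene_length_bp` per contig.
#' @param indel_fraction Fraction of planted fixed/cluster variants emitted
#'   as 1 bp insertions or deletions rather than SNPs.
#' @param ortholog_mutations List of `c(syn, nonsyn)` pairs: one CDS/protein
#'   ortholog pair is generated per entry with that many synonymous-only and
#'   nonsynonymous-only codon point mutations.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_contigs = 2L,
                              contig_length_bp = 100000L,
                              n_male = 5L,
                              n_female = 5L,
                              mean_depth = 20,
                              background_het_rate = 1e-4,
                              fixed_diff_rate = 5e-4,
                              planted_clusters = list(
                                list(contig = "contig_1", start = 20001L, n = 40L),
                                list(contig = "contig_1", start = 70001L, n = 40L),
                                list(contig = "contig_2", start = 40001L, n = 40L)
                              ),
                              low_qual_fraction = 0,
                              n_decoys = 50L,
                              sex_exclusive_blocks = list(
                                list(contig = "contig_2", start = 90001L, end = 92000L,
                                     zero_sex = "female"),
                                list(contig = "contig_1", start = 95001L, end = 96500L,
                                     zero_sex = "male")
                              ),
                              n_genes = 8L,
                              gene_length_bp = 1500L,
                              indel_fraction = 0.1,
                              ortholog_mutations = list(
                                c(syn = 3L, nonsyn = 0L),
                                c(syn = 0L, nonsyn = 3L),
                                c(syn = 5L, nonsyn = 2L),
                                c(syn = 2L, nonsyn = 5L),
                                c(syn = 0L, nonsyn = 0L)
                              )) {
  cfg <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length_bp = as.integer(contig_length_bp),
    n_male = as.integer(n_male), n_female = as.integer(n_female),
    mean_depth = mean_depth, background_het_rate = background_het_rate,
    fixed_diff_rate = fixed_diff_rate, planted_clusters = planted_clusters,
    low_qual_fraction = low_qual_fraction, n_decoys = as.integer(n_decoys),
    sex_exclusive_blocks = sex_exclusive_blocks,
    n_genes = as.integer(n_genes), gene_length_bp = as.integer(gene_length_bp),
    indel_fraction = indel_fraction, ortholog_mutations = ortholog_mutations,
    window = 10000L
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @param config A `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$window
  if (config$contig_length_bp < 3L * w)
    stop("contig_length_bp must be at least three windows (", 3L * w, " bp)")
  if (config$n_male < 1L || config$n_female < 1L)
    stop("need at least one sample of each sex")
  contigs <- sim_contig_names(config)
  if (config$n_genes * config$gene_length_bp > config$contig_length_bp)
    stop("impossible gene packing: ", config$n_genes, " genes of ",
         config$gene_length_bp, " bp exceed the ", config$contig_length_bp,
         " bp contig")
  if (config$gene_length_bp %% 3L != 0L)
    stop("gene_length_bp must be divisible by 3 (codon-sized)")
  cl <- cluster_table(config)
  if (nrow(cl)) {
    if (!all(cl$contig %in% contigs))
      stop("planted cluster on unknown contig: ",
           paste(setdiff(cl$contig, contigs), collapse = ", "))
    if (any(cl$start < 1L | cl$start + w - 1L > config$contig_length_bp))
      stop("planted cluster window extends beyond its contig")
    if (any((cl$start - 1L) %% w != 0L))
      stop("planted cluster start must be the first position of a 10 kb window")
    if (any(cl$n > w))
      stop("planted cluster requests more variants than window capacity (", w, ")")
    if (any(duplicated(cl[, .(contig, start)])))
      stop("duplicate planted cluster windows")
  }
  bl <- block_table(config)
  if (nrow(bl)) {
    if (!all(bl$contig %in% contigs)) stop("sex-exclusive block on unknown contig")
    if (any(bl$start < 1L | bl$end > config$contig_length_bp | bl$start > bl$end))
      stop("sex-exclusive block outside contig or inverted")
    if (!all(bl$zero_sex %in% c("male", "female")))
      stop("zero_sex must be 'male' or 'female'")
    if (nrow(cl)) {
      ov <- bl[cl, on = .(contig), allow.cartesian = TRUE, nomatch = 0L][
        start <= i.start + w - 1L & end >= i.start]
      if (nrow(ov)) stop("sex-exclusive blocks must not overlap planted clusters")
    }
  }
  muts <- mutation_table(config)
  if (nrow(muts) && any(muts$syn < 0L | muts$nonsyn < 0L))
    stop("ortholog mutation counts must be non-negative")
  invisible(config)
}

sim_contig_names <- function(config) paste0("contig_", seq_len(config$n_contigs))

sim_sample_manifest <- function(config) {
  data.table::data.table(
    sample_id = c(paste0("male_", seq_len(config$n_male)),
                  paste0("female_", seq_len(config$n_female))),
    sex = c(rep("male", config$n_male), rep("female", config$n_female))
  )
}

cluster_table <- function(config) {
  if (!length(config$planted_clusters))
    return(data.table::data.table(contig = character(), start = integer(), n = integer()))
  data.table::rbindlist(lapply(config$planted_clusters, function(x)
    data.table::data.table(contig = as.character(x$contig),
                           start = as.integer(x$start), n = as.integer(x$n))))
}

block_table <- function(config) {
  if (!length(config$sex_exclusive_blocks))
    return(data.table::data.table(contig = character(), start = integer(),
                                  end = integer(), zero_sex = character()))
  data.table::rbindlist(lapply(config$sex_exclusive_blocks, function(x)
    data.table::data.table(contig = as.character(x$contig),
                           start = as.integer(x$start), end = as.integer(x$end),
                           zero_sex = as.character(x$zero_sex))))
}

mutation_table <- function(config) {
  if (!length(config$ortholog_mutations))
    return(data.table::data.table(pair_id = character(), syn = integer(),
                                  nonsyn = integer()))
  data.table::rbindlist(lapply(seq_along(config$ortholog_mutations), function(i) {
    m <- config$ortholog_mutations[[i]]
    data.table::data.table(pair_id = sprintf("pair_%02d", i),
                           syn = as.integer(m[["syn"]]),
                           nonsyn = as.integer(m[["nonsyn"]]))
  }))
}

#' Generate the toy reference genome and gene annotation
#'
#' Draws `n_contigs` uniform-random nucleotide sequences and places
#' `n_genes` non-overlapping genes of `gene_length_bp` per contig (one gene
#' per equal-width slot, at a random offset inside its slot). Deterministic
#' for a fixed seed.
#'
#' @param config A `sim_config`.
#' @param dir Optional output directory; when given, writes `reference.fa`,
#'   `reference.fa.fai` and `genes.bed`.
#' @return List with `sequences` (`DNAStringSet`), `genes` (BED-style
#'   `data.table`: contig, start, end, name, short_name) and
#'   `contig_lengths` (named integer vector).
#' @export
generate_reference <- function(config, dir = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  contigs <- sim_contig_names(config)
  L <- config$contig_length_bp
  seqs <- vapply(contigs, function(ctg)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1L))
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- contigs

  slot <- L %/% config$n_genes
  if (slot < config$gene_length_bp)
    stop("impossible gene packing: slot width ", slot, " bp < gene length")
  genes <- data.table::rbindlist(lapply(seq_along(contigs), function(ci) {
    offs <- sample.int(slot - config$gene_length_bp + 1L, config$n_genes,
                       replace = TRUE) - 1L
    start0 <- (seq_len(config$n_genes) - 1L) * slot + offs
    data.table::data.table(
      contig = contigs[ci],
      start = start0,
      end = start0 + config$gene_length_bp,
      name = sprintf("%s_gene_%02d", contigs[ci], seq_len(config$n_genes)),
      short_name = sprintf("g%d.%d", ci, seq_len(config$n_genes))
    )
  }))
  ref <- list(sequences = sequences, genes = genes,
              contig_lengths = setNames(rep(L, length(contigs)), contigs))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sequences, file.path(dir, "reference.fa"))
    write_fai(sequences, file.path(dir, "reference.fa"))
    write_genes_bed(genes, file.path(dir, "genes.bed"))
  }
  ref
}

# Sample n distinct positions from `candidates` (integer vector), error if
# not enough candidates remain.
sample_positions <- function(candidates, n, what) {
  if (length(candidates) < n)
    stop("cannot place ", n, " ", what, " variants: only ",
         length(candidates), " free positions")
  sort(candidates[sample.int(length(candidates), n)])
}

#' Generate the synthetic cohort: depth tables, per-sample VCFs and truth
#'
#' Plants, with pairwise-disjoint coordinates: species-fixed sites (1/1 in
#' every sample, passing QUAL), clustered sex-associated sites (males 1/1
#' passing QUAL; each female independently 0/1 or recordless), background
#' heterozygous noise (0/1 in one random sample), low-QUAL decoys (1/1 in
#' all males, QUAL <= 30, the first decoy pinned at exactly 30), and
#' sex-exclusive coverage blocks. Depths are Poisson around `mean_depth`,
#' clamped to >= 3 at planted fixed/sex sites so the depth gate never erases
#' planted truth, forced to 0 for the zero sex inside exclusive blocks and
#' to >= 10 in three samples of the covered sex there.
#'
#' @param config A `sim_config`.
#' @param reference Result of [generate_reference()] with the same config.
#' @param dir Optional output directory; writes `depth/<sample>.depth.tsv`,
#'   `vcf/<sample>.vcf`, `manifest.tsv` and `truth.tsv`.
#' @return List with `depth` (named list of per-sample depth tables),
#'   `vcfs` (named list of per-sample record tables), `manifest`
#'   (sample/sex table) and `truth` (see [write_truth_set()]).
#' @export
generate_cohort <- function(config, reference, dir = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  contigs <- sim_contig_names(config)
  L <- config$contig_length_bp
  manifest <- sim_sample_manifest(config)
  males <- manifest[sex == "male", sample_id]
  females <- manifest[sex == "female", sample_id]
  cl <- cluster_table(config)
  bl <- block_table(config)
  w <- config$window
  seq_chr <- as.character(reference$sequences)

  # --- plant coordinates, contig by contig, pairwise disjoint ---
  used <- lapply(setNames(contigs, contigs), function(x) integer(0))
  blocked <- lapply(setNames(contigs, contigs), function(ctg) {
    b <- bl[contig == ctg]
    if (!nrow(b)) integer(0) else unlist(Map(seq.int, b$start, b$end))
  })

  sex_sites <- data.table::rbindlist(lapply(seq_len(nrow(cl)), function(i) {
    ctg <- cl$contig[i]
    cand <- setdiff(seq.int(cl$start[i], cl$start[i] + w - 1L),
                    c(used[[ctg]], blocked[[ctg]]))
    p <- sample_positions(cand, cl$n[i], "cluster")
    used[[ctg]] <<- c(used[[ctg]], p)
    data.table::data.table(contig = ctg, pos = p,
                           window_index = (cl$start[i] - 1L) %/% w)
  }))
  if (is.null(sex_sites$pos))
    sex_sites <- data.table::data.table(contig = character(), pos = integer(),
                                        window_index = integer())

  fixed_sites <- data.table::rbindlist(lapply(contigs, function(ctg) {
    hits <- which(runif(L) < config$fixed_diff_rate)
    hits <- setdiff(hits, c(used[[ctg]], blocked[[ctg]]))
    used[[ctg]] <<- c(used[[ctg]], hits)
    data.table::data.table(contig = ctg, pos = as.integer(hits))
  }))

  # decoys spread across contigs proportionally
  decoy_sites <- data.table::data.table(contig = character(), pos = integer())
  if (config$n_decoys > 0L) {
    per_ctg <- tabulate(sample.int(length(contigs), config$n_decoys, replace = TRUE),
                        nbins = length(contigs))
    decoy_sites <- data.table::rbindlist(lapply(seq_along(contigs), function(ci) {
      ctg <- contigs[ci]
      if (per_ctg[ci] == 0L) return(NULL)
      cand <- setdiff(seq_len(L), c(used[[ctg]], blocked[[ctg]]))
      p <- sample_positions(cand, per_ctg[ci], "decoy")
      used[[ctg]] <<- c(used[[ctg]], p)
      data.table::data.table(contig = ctg, pos = p)
    }))
  }

  n_samples <- nrow(manifest)
  noise_sites <- data.table::rbindlist(lapply(contigs, function(ctg) {
    hits <- which(runif(L) < config$background_het_rate * n_samples)
    hits <- setdiff(hits, c(used[[ctg]], blocked[[ctg]]))
    used[[ctg]] <<- c(used[[ctg]], hits)
    if (!length(hits))
      return(data.table::data.table(contig = character(), pos = integer(),
                                    sample_id = character()))
    data.table::data.table(contig = ctg, pos = as.integer(hits),
                           sample_id = manifest$sample_id[
                             sample.int(n_samples, length(hits), replace = TRUE)])
  }))

  # --- alleles ---
  allele_for <- function(sites) {
    if (!nrow(sites)) return(sites[, `:=`(ref = character(0), alt = character(0))])
    refb <- substr_base(seq_chr, sites$contig, sites$pos)
    is_indel <- runif(nrow(sites)) < config$indel_fraction & sites$pos < L
    is_ins <- is_indel & runif(nrow(sites)) < 0.5
    is_del <- is_indel & !is_ins
    alt <- other_base(refb)
    ref <- refb
    # insertion: REF=base, ALT=base + extra; deletion: REF=base+next, ALT=base
    alt[is_ins] <- paste0(refb[is_ins], other_base(refb[is_ins]))
    nextb <- substr_base(seq_chr, sites$contig, pmin(sites$pos + 1L, L))
    ref[is_del] <- paste0(refb[is_del], nextb[is_del])
    alt[is_del] <- refb[is_del]
    sites$ref <- ref
    sites$alt <- alt
    sites
  }
  sex_sites <- allele_for(sex_sites)
  fixed_sites <- allele_for(fixed_sites)
  decoy_sites <- allele_for(decoy_sites)
  if (nrow(noise_sites)) {
    refb <- substr_base(seq_chr, noise_sites$contig, noise_sites$pos)
    noise_sites[, `:=`(ref = refb, alt = other_base(refb))]
  } else noise_sites[, `:=`(ref = character(0), alt = character(0))]

  pass_qual <- function(n) {
    q <- runif(n, 30.01, 100)
    demote <- runif(n) < config$low_qual_fraction
    q[demote] <- runif(sum(demote), 0, 30)
    q
  }

  # --- per-sample VCF records ---
  vcfs <- lapply(setNames(manifest$sample_id, manifest$sample_id), function(smp) {
    is_male <- manifest[sample_id == smp, sex] == "male"
    recs <- list()
    if (nrow(fixed_sites))
      recs$fixed <- fixed_sites[, .(contig, pos, ref, alt,
                                    qual = pass_qual(.N), gt = "1/1")]
    if (nrow(sex_sites)) {
      if (is_male) {
        recs$sex <- sex_sites[, .(contig, pos, ref, alt,
                                  qual = pass_qual(.N), gt = "1/1")]
      } else {
        emit <- runif(nrow(sex_sites)) < 0.5
        if (any(emit))
          recs$sex <- sex_sites[emit, .(contig, pos, ref, alt,
                                        qual = runif(.N, 0, 100), gt = "0/1")]
      }
    }
    if (is_male && nrow(decoy_sites))
      recs$decoy <- decoy_sites[, .(contig, pos, ref, alt,
                                    qual = runif(.N, 0, 30), gt = "1/1")]
    ns <- noise_sites[sample_id == smp]
    if (nrow(ns))
      recs$noise <- ns[, .(contig, pos, ref, alt, qual = runif(.N, 0, 100),
                           gt = "0/1")]
    out <- data.table::rbindlist(recs)
    if (!nrow(out))
      out <- data.table::data.table(contig = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    qual = numeric(), gt = character())
    data.table::setorder(out, contig, pos, alt)
    out
  })
  # pin the strict QUAL>30 boundary: first decoy record in the first male
  if (nrow(decoy_sites)) {
    first_male <- males[1L]
    dk <- decoy_sites[1L]
    vcfs[[first_male]][contig == dk$contig & pos == dk$pos, qual := 30]
  }

  # --- depth tables ---
  clamp_sites <- data.table::rbindlist(list(fixed_sites[, .(contig, pos)],
                                            sex_sites[, .(contig, pos)]))
  depth_tabs <- lapply(setNames(manifest$sample_id, manifest$sample_id), function(smp) {
    smp_sex <- manifest[sample_id == smp, sex]
    data.table::rbindlist(lapply(contigs, function(ctg) {
      d <- rpois(L, config$mean_depth)
      if (nrow(clamp_sites)) {
        cp <- clamp_sites[contig == ctg, pos]
        d[cp] <- pmax(d[cp], 3L)
      }
      b <- bl[contig == ctg]
      for (bi in seq_len(nrow(b))) {
        rng <- seq.int(b$start[bi], b$end[bi])
        if (b$zero_sex[bi] == smp_sex) {
          d[rng] <- 0L
        } else {
          forced <- manifest[sex != b$zero_sex[bi], sample_id][1:3]
          if (smp %in% forced) d[rng] <- pmax(d[rng], 10L)
        }
      }
      data.table::data.table(contig = ctg, pos = seq_len(L), depth = as.integer(d))
    }))
  })

  truth <- list(
    fixed_sites = fixed_sites[, .(contig, pos, ref, alt)],
    sex_sites = sex_sites[, .(contig, pos, window_index, ref, alt)],
    sex_windows = unique(sex_sites[, .(contig, window_index)]),
    noise_sites = noise_sites[, .(contig, pos, sample_id)],
    decoy_sites = decoy_sites[, .(contig, pos)],
    exclusive_blocks = bl,
    ortholog_truth = mutation_table(config)
  )
  class(truth) <- "truth_set"

  if (!is.null(dir)) {
    dir.create(file.path(dir, "depth"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
    for (smp in manifest$sample_id) {
      write_depth_table(depth_tabs[[smp]],
                        file.path(dir, "depth", paste0(smp, ".depth.tsv")))
      write_vcf(vcfs[[smp]], file.path(dir, "vcf", paste0(smp, ".vcf")),
                sample_name = smp, contig_lengths = reference$contig_lengths)
    }
    data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
    write_truth_set(truth, file.path(dir, "truth.tsv"))
  }
  list(depth = depth_tabs, vcfs = vcfs, manifest = manifest, truth = truth)
}

substr_base <- function(seq_chr, ctg, pos) {
  vapply(seq_along(ctg), function(i) substr(seq_chr[[ctg[i]]], pos[i], pos[i]),
         character(1L))
}

other_base <- function(b) {
  bases <- c("A", "C", "G", "T")
  vapply(b, function(x) sample(setdiff(bases, x), 1L), character(1L),
         USE.NAMES = FALSE)
}

#' Serialise / reload a planted truth set
#'
#' The truth set is written as a single long-format TSV with a `category`
#' column (`fixed`, `sex`, `sex_window`, `noise`, `decoy`, `exclusive_block`,
#' `ortholog`); unused fields are empty. Reloading reproduces the original
#' object bit-identically for a fixed seed.
#'
#' @param truth A `truth_set` as produced by [generate_cohort()].
#' @param path TSV path.
#' @return `write_truth_set()`: invisibly, `path`; `read_truth_set()`: the
#'   `truth_set` object.
#' @export
write_truth_set <- function(truth, path) {
  rows <- list(
    truth$fixed_sites[, .(category = "fixed", contig, pos,
                          ref = ref, alt = alt)],
    truth$sex_sites[, .(category = "sex", contig, pos, window_index,
                        ref = ref, alt = alt)],
    truth$sex_windows[, .(category = "sex_window", contig, window_index)],
    truth$noise_sites[, .(category = "noise", contig, pos, sample_id)],
    truth$decoy_sites[, .(category = "decoy", contig, pos)],
    truth$exclusive_blocks[, .(category = "exclusive_block", contig,
                               start, end, zero_sex)],
    truth$ortholog_truth[, .(category = "ortholog", pair_id, syn, nonsyn)]
  )
  long <- data.table::rbindlist(rows, fill = TRUE)
  data.table::fwrite(long, path, sep = "\t", na = "")
  invisible(path)
}

#' @rdname write_truth_set
#' @param path TSV path written by `write_truth_set()`.
#' @export
read_truth_set <- function(path) {
  long <- data.table::fread(path, sep = "\t", na.strings = "")
  pick <- function(cat, cols) {
    x <- long[category == cat, ..cols]
    for (j in names(x)) if (is.logical(x[[j]])) x[, (j) := character(0)]
    x[]
  }
  truth <- list(
    fixed_sites = pick("fixed", c("contig", "pos", "ref", "alt")),
    sex_sites = pick("sex", c("contig", "pos", "window_index", "ref", "alt")),
    sex_windows = pick("sex_window", c("contig", "window_index")),
    noise_sites = pick("noise", c("contig", "pos", "sample_id")),
    decoy_sites = pick("decoy", c("contig", "pos")),
    exclusive_blocks = pick("exclusive_block",
                            c("contig", "start", "end", "zero_sex")),
    ortholog_truth = pick("ortholog", c("pair_id", "syn", "nonsyn"))
  )
  class(truth) <- "truth_set"
  truth
}

#' Generate ortholog CDS/protein pairs with planted substitution classes
#'
#' Each configured pair starts from a random stop-free CDS of
#' `gene_length_bp`; the recorded numbers of synonymous-only and
#' nonsynonymous-only single-nucleotide codon changes (verified against the
#' standard genetic code, never touching the same codon twice and never
#' creating a stop) are applied to the copy. Both nucleotide and translated
#' FASTA files are emitted.
#'
#' @param config A `sim_config`.
#' @param dir Optional output directory; writes `orthologs_cds.fna` and
#'   `orthologs_prot.faa` (records `<pair>_a` / `<pair>_b`).
#' @return List with `cds` and `proteins` (named character vectors) and
#'   `ortholog_truth` (`data.table`: pair_id, syn, nonsyn).
#' @export
generate_ortholog_pairs <- function(config, dir = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  tab <- ng86_tables()
  muts <- mutation_table(config)
  n_codons <- config$gene_length_bp %/% 3L
  sense <- tab$codons[tab$aa != "*"]

  cds <- character(0); prot <- character(0)
  for (i in seq_len(nrow(muts))) {
    for (attempt in 1:20) {
      base_codons <- sample(sense, n_codons, replace = TRUE)
      mutated <- try(apply_codon_mutations(base_codons, muts$syn[i],
                                           muts$nonsyn[i], tab), silent = TRUE)
      if (!inherits(mutated, "try-error")) break
      if (attempt == 20) stop("could not plant mutations for ", muts$pair_id[i])
      message("regenerating CDS for ", muts$pair_id[i],
              ": sampled codons could not host the requested mutation class")
    }
    a <- paste(base_codons, collapse = "")
    b <- paste(mutated, collapse = "")
    cds[paste0(muts$pair_id[i], "_a")] <- a
    cds[paste0(muts$pair_id[i], "_b")] <- b
    prot[paste0(muts$pair_id[i], "_a")] <- translate_cds(a)
    prot[paste0(muts$pair_id[i], "_b")] <- translate_cds(b)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(Biostrings::DNAStringSet(cds), file.path(dir, "orthologs_cds.fna"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prot),
                                file.path(dir, "orthologs_prot.faa"))
  }
  list(cds = cds, proteins = prot, ortholog_truth = muts)
}

# Apply syn synonymous-only and nonsyn nonsynonymous-only single-nt changes
# to distinct codons; errors if placement fails (caller retries with a new CDS).
apply_codon_mutations <- function(codons, syn, nonsyn, tab) {
  out <- codons
  free <- seq_along(codons)
  place <- function(free, synonymous) {
    for (try_i in seq_len(50L)) {
      if (!length(free)) stop("no codon left to mutate")
      idx <- free[sample.int(length(free), 1L)]
      nb <- codon_neighbours(out[idx], tab)
      ok <- if (synonymous) nb$syn else nb$nonsyn
      if (length(ok)) {
        out[idx] <<- ok[sample.int(length(ok), 1L)]
        return(setdiff(free, idx))
      }
      free <- setdiff(free, idx)
    }
    stop("mutation class unavailable after bounded retries")
  }
  for (k in seq_len(syn)) free <- place(free, TRUE)
  for (k in seq_len(nonsyn)) free <- place(free, FALSE)
  out
}

# Single-nucleotide neighbours of a codon, split into synonymous and
# nonsynonymous (stop codons excluded from both classes).
codon_neighbours <- function(codon, tab) {
  bases <- c("A", "C", "G", "T")
  aa0 <- tab$aa[[codon]]
  nbs <- character(0)
  for (p in 1:3) for (b in setdiff(bases, substr(codon, p, p))) {
    nb <- codon
    substr(nb, p, p) <- b
    nbs <- c(nbs, nb)
  }
  aa <- tab$aa[nbs]
  list(syn = nbs[aa == aa0 & aa != "*"], nonsyn = nbs[aa != aa0 & aa != "*"])
}
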