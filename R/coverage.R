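#' Parse a samtools-depth-style per-position depth table
#'
#' Expects the dense `-aa` layout: three tab-separated columns (contig,
#' 1-based position, depth), sorted by contig then position, with exactly
#' one row per reference position and no gaps.
#'
#' @param path Depth TSV path.
#' @return `data.table` with columns contig, pos, depth.
#' @export
parse_depth_table <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) != 3L)
    stop("depth table must have 3 columns (contig, pos, depth): ", path)
  data.table::setnames(dt, c("contig", "pos", "depth"))
  pos_n <- suppressWarnings(as.numeric(dt$pos))
  depth_n <- suppressWarnings(as.numeric(dt$depth))
  bad <- which(!is.finite(pos_n) | !is.finite(depth_n) | pos_n < 1 |
                 depth_n < 0 | pos_n %% 1 != 0 | depth_n %% 1 != 0)
  if (length(bad))
    stop("malformed depth row at line ", bad[1L], " of ", path)
  dt[, `:=`(pos = as.integer(pos_n), depth = as.integer(depth_n))]
  # dense, sorted, duplicate-free per contig
  chk <- dt[, .(first = pos[1L], dup = anyDuplicated(pos),
                gap = { d <- diff(pos); if (length(d) && any(d != 1L)) pos[which(d != 1L)[1L]] else NA_integer_ }),
            by = contig]
  if (any(chk$dup > 0L)) {
    ctg <- chk[dup > 0L, contig][1L]
    stop("duplicated position in depth table: contig ", ctg, " position ",
         dt[contig == ctg, pos[anyDuplicated(pos)]])
  }
  if (any(!is.na(chk$gap))) {
    r <- chk[!is.na(gap)][1L]
    stop("gap or unsorted positions in depth table: contig ", r$contig,
         " after position ", r$gap)
  }
  dt[]
}

#' Assemble per-sample depth tables into a dense depth matrix
#'
#' @param tables Named list of per-sample depth tables (as returned by
#'   [parse_depth_table()]); all samples must cover the identical set of
#'   (contig, position) rows.
#' @return A `depth_matrix`: `data.table` with columns contig, pos and one
#'   integer depth column per sample; sample names in `attr(, "samples")`.
#' @export
depth_matrix <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L, !is.null(names(tables)))
  frame <- tables[[1L]][, .(contig, pos)]
  out <- data.table::copy(frame)
  for (smp in names(tables)) {
    tb <- tables[[smp]]
    if (nrow(tb) != nrow(frame) ||
        !identical(tb$contig, frame$contig) || !identical(tb$pos, frame$pos))
      stop("depth table for sample '", smp,
           "' does not cover the same positions as the first sample")
    out[, (smp) := tb$depth]
  }
  data.table::setattr(out, "samples", names(tables))
  data.table::setattr(out, "class", c("depth_matrix", class(out)))
  out
}

#' Read a directory of per-sample depth tables
#'
#' @param dir Directory containing `<sample>.depth.tsv` files.
#' @param samples Optional sample names to read (defaults to all files).
#' @return A `depth_matrix`.
#' @export
read_depth_dir <- function(dir, samples = NULL) {
  files <- list.files(dir, pattern = "\\.depth\\.tsv$", full.names = TRUE)
  names(files) <- sub("\\.depth\\.tsv$", "", basename(files))
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(files))
    if (length(missing)) stop("no depth table for sample(s): ",
                              paste(missing, collapse = ", "))
    files <- files[samples]
  }
  depth_matrix(lapply(files, parse_depth_table))
}

dm_samples <- function(dm) attr(dm, "samples")

check_samples_present <- function(dm, samples) {
  missing <- setdiff(samples, dm_samples(dm))
  if (length(missing))
    stop("sample(s) not present in depth matrix: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Coverage and depth summary for a sample or pooled group
#'
#' Group depth at a position is the arithmetic sum of the member samples'
#' depths (equivalent to pooling their alignments). Coverage is the
#' fraction of positions with pooled depth at or above `min_covered_depth`
#' (default 1, i.e. any read).
#'
#' @param dm A `depth_matrix`.
#' @param samples Character vector of member samples (default: all).
#' @param min_covered_depth Depth floor for a position to count as covered.
#' @param group Label for the summary.
#' @return A `coverage_summary` list: group, samples, n_positions,
#'   covered_fraction, mean_depth, histogram (`data.table` depth/count).
#' @export
coverage_summary <- function(dm, samples = dm_samples(dm),
                             min_covered_depth = 1L, group = NULL) {
  if (!length(samples)) stop("empty sample group")
  check_samples_present(dm, samples)
  pooled <- if (length(samples) == 1L) dm[[samples]] else
    Reduce(`+`, lapply(samples, function(s) dm[[s]]))
  n <- length(pooled)
  hist_dt <- data.table::data.table(depth = pooled)[, .(count = .N), by = depth]
  data.table::setorder(hist_dt, depth)
  out <- list(
    group = if (is.null(group)) paste(samples, collapse = "+") else group,
    samples = samples,
    n_positions = n,
    covered_fraction = sum(pooled >= min_covered_depth) / n,
    mean_depth = sum(as.numeric(pooled)) / n,
    histogram = hist_dt
  )
  class(out) <- "coverage_summary"
  out
}

#' @method print coverage_summary
#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage summary [%s]: %d positions, %.4f covered, mean depth %.2f\n",
              x$group, x$n_positions, x$covered_fraction, x$mean_depth))
  invisible(x)
}

#' Positions covered exclusively in one sex
#'
#' A position qualifies when every sample of the zero sex has depth 0 and
#' at least `min_samples` samples of the covered sex have depth at or above
#' `min_depth`. Also reports the number of distinct contigs carrying at
#' least one qualifying position.
#'
#' @param dm A `depth_matrix`.
#' @param zero_samples Samples required to have zero depth.
#' @param covered_samples Samples of the other sex.
#' @param min_depth Depth floor in the covered sex (default 10).
#' @param min_samples Minimum covered-sex samples reaching `min_depth`
#'   (default 3).
#' @return List with `sites` (`data.table`: contig, pos,
#'   supporting_samples) and `n_contigs`.
#' @export
sex_exclusive_positions <- function(dm, zero_samples, covered_samples,
                                    min_depth = 10L, min_samples = 3L) {
  if (!length(zero_samples) || !length(covered_samples))
    stop("both sample groups must be non-empty")
  if (length(intersect(zero_samples, covered_samples)))
    stop("zero and covered sample groups must be disjoint")
  check_samples_present(dm, c(zero_samples, covered_samples))
  zero_ok <- Reduce(`&`, lapply(zero_samples, function(s) dm[[s]] == 0L))
  support <- Reduce(`+`, lapply(covered_samples, function(s)
    as.integer(dm[[s]] >= min_depth)))
  hit <- zero_ok & support >= min_samples
  sites <- dm[hit, .(contig, pos)]
  sites[, supporting_samples := support[hit]]
  list(sites = sites[], n_contigs = data.table::uniqueN(sites$contig))
}
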