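#' Call variant-density peaks over 10 kb segment counts
#'
#' A peak is a window whose variant count reaches the threshold. The
#' headline rule uses `count >= threshold` (30 or more variants); set
#' `strict = TRUE` for the `count > threshold` comparator (used by the
#' "more than 25" style of report). Also reports the number of windows
#' with at least one variant and the number of distinct contigs carrying
#' such a window.
#'
#' @param segments A `segment_counts` object from [per_segment_counts()].
#' @param threshold Minimum variant count (default 30); must be >= 1.
#' @param strict Use strictly-greater comparison instead of >=.
#' @return A `peak_scan` list: `peaks` (`data.table`: contig, window_index,
#'   start, end, count), `threshold`, `strict`, `n_nonempty_windows`,
#'   `n_contigs_nonempty`.
#' @export
scan_clusters <- function(segments, threshold = 30L, strict = FALSE) {
  stopifnot(inherits(segments, "segment_counts"))
  if (threshold < 1L) stop("threshold must be at least 1")
  win <- segments$windows
  peaks <- if (strict) win[count > threshold] else win[count >= threshold]
  nonempty <- win[count > 0L]
  out <- list(
    peaks = peaks[],
    threshold = threshold,
    strict = strict,
    n_nonempty_windows = nrow(nonempty),
    n_contigs_nonempty = data.table::uniqueN(nonempty$contig)
  )
  class(out) <- "peak_scan"
  out
}

#' Peak table with first/last variant positions per peak window
#'
#' One row per peak: contig, the positions of the first and last variant
#' inside the window, and the variant count; rows sorted by contig then
#' start. A peak window containing no sites is an input inconsistency and
#' raises an error.
#'
#' @param scan A `peak_scan` from [scan_clusters()] (or its `peaks` table).
#' @param sites The site list the segment counts were built from.
#' @return `data.table`: contig, window_index, first_variant_pos,
#'   last_variant_pos, n_variants.
#' @export
peak_table <- function(scan, sites) {
  peaks <- if (inherits(scan, "peak_scan")) scan$peaks else scan
  if (!nrow(peaks))
    return(data.table::data.table(contig = character(), window_index = integer(),
                                  first_variant_pos = integer(),
                                  last_variant_pos = integer(),
                                  n_variants = integer()))
  u <- sites[, .(contig, pos)]
  out <- peaks[, {
    inwin <- u[contig == .BY$contig & pos >= start & pos <= end, pos]
    if (!length(inwin))
      stop("peak window ", .BY$contig, ":", start, "-", end,
           " contains no sites: inconsistent inputs")
    .(first_variant_pos = min(inwin), last_variant_pos = max(inwin),
      n_variants = count)
  }, by = .(contig, window_index)]
  data.table::setorder(out, contig, first_variant_pos)
  out[]
}

# Distance between a 1-based closed query interval [a, b] and a 0-based
# half-open gene [s, e): 0 on any overlap, else the bedtools-closest style
# gap (adjacent features are 1 apart). For a point query a == b this is
# 0 when s < p <= e, else min(|p - (s+1)|, |p - e|).
interval_gene_distance <- function(a, b, s, e) {
  gs <- s + 1L   # gene span in 1-based closed coordinates: [gs, e]
  data.table::fifelse(pmax(a, gs) <= pmin(b, e), 0L,
                      data.table::fifelse(e < a, a - e, gs - b))
}

#' Nearest gene for point or interval queries
#'
#' For every query, finds the gene minimising the strand-blind distance
#' (0 on overlap; otherwise the gap in bp, with adjacent features 1 bp
#' apart, matching `bedtools closest -d`). Ties are broken by the gene
#' that comes first in coordinate-sorted order, matching `-t first`.
#' Queries on contigs with no annotated gene get an explicit no-gene row
#' (NA gene, NA distance).
#'
#' @param queries `data.table` with columns contig and either `pos` (point
#'   queries) or `pos_start`/`pos_end` (1-based closed intervals).
#' @param genes Gene table (contig, start, end, name, short_name), 0-based
#'   half-open, sorted by contig then start; unsorted input is rejected.
#' @return `data.table`: one row per query with contig, pos_start, pos_end,
#'   gene_name, short_name, gene_start, gene_end, distance, in_gene.
#' @export
nearest_gene <- function(queries, genes) {
  q <- data.table::copy(data.table::as.data.table(queries))
  if (!"pos_start" %in% names(q)) {
    stopifnot("pos" %in% names(q))
    q[, `:=`(pos_start = pos, pos_end = pos)]
  }
  stopifnot(all(q$pos_start <= q$pos_end))
  if (nrow(genes) >= 2L) {
    unsorted <- genes[, .(bad = is.unsorted(start)), by = contig][bad == TRUE]
    if (nrow(unsorted))
      stop("gene table is not coordinate-sorted (contig ",
           unsorted$contig[1L], "); sort by contig then start first")
  }
  if (!nrow(q)) {
    return(data.table::data.table(contig = character(), pos_start = integer(),
                                  pos_end = integer(), gene_name = character(),
                                  short_name = character(),
                                  gene_start = integer(), gene_end = integer(),
                                  distance = integer(), in_gene = logical()))
  }
  q[, query_id := .I]
  res <- q[, {
    g <- genes[contig == .BY$contig]
    if (!nrow(g)) {
      .(pos_start = pos_start, pos_end = pos_end,
        gene_name = NA_character_, short_name = NA_character_,
        gene_start = NA_integer_, gene_end = NA_integer_,
        distance = NA_integer_, in_gene = FALSE, query_id = query_id)
    } else {
      dmat <- outer(seq_len(.N), seq_len(nrow(g)), function(i, j)
        interval_gene_distance(pos_start[i], pos_end[i], g$start[j], g$end[j]))
      best <- max.col(-dmat, ties.method = "first")
      dbest <- dmat[cbind(seq_len(.N), best)]
      .(pos_start = pos_start, pos_end = pos_end,
        gene_name = g$name[best], short_name = g$short_name[best],
        gene_start = g$start[best], gene_end = g$end[best],
        distance = as.integer(dbest), in_gene = dbest == 0L,
        query_id = query_id)
    }
  }, by = contig]
  data.table::setorder(res, query_id)
  res[, query_id := NULL]
  res[]
}

#' Distinct nearest genes across peak assignments
#'
#' Counts the unique gene short names across one-assignment-per-peak
#' nearest-gene rows (no-gene assignments excluded) and returns the
#' per-peak in-gene flags alongside.
#'
#' @param assignments Output of [nearest_gene()], one row per peak.
#' @return List with `n_distinct_genes`, `n_assignments` and `in_gene`
#'   (logical vector, one flag per assignment).
#' @export
distinct_gene_count <- function(assignments) {
  list(
    n_distinct_genes = data.table::uniqueN(assignments[!is.na(short_name),
                                                       short_name]),
    n_assignments = nrow(assignments),
    in_gene = assignments$in_gene
  )
}
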