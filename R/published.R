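#' Published sturgeon sex-variation peak table
#'
#' The 15-row peak table reported for Russian sturgeon (*Acipenser
#' gueldenstaedtii*) whole-genome data mapped to the sterlet female
#' reference: the 10 kb segments carrying 30 or more sex-associated
#' variants, with the first/last variant position per segment, the variant
#' count, and the nearest gene on the reference annotation. Shipped as a
#' plain-text fixture so the peak-table conventions of this package can be
#' exercised against real published values.
#'
#' @return `data.table` with columns reference_sequence, start, end,
#'   variants, nearest_gene, short_name, in_gene.
#' @export
published_peak_table <- function() {
  path <- system.file("extdata", "published_peak_table.tsv",
                      package = "sexvarscan", mustWork = TRUE)
  data.table::fread(path, sep = "\t")
}

#' Worked summaries over the published peak table
#'
#' Recomputes, with the package's own peak-table conventions, the headline
#' summaries implied by the published table: the number of clusters at or
#' above the 30-variant threshold, the largest per-cluster variant count,
#' the number of distinct nearest-gene symbols after deduplication, and
#' the number of clusters falling inside their nearest gene.
#'
#' @param tab Peak table (default [published_peak_table()]).
#' @param threshold Cluster threshold (default 30).
#' @return List: n_clusters_at_threshold, max_cluster_variants,
#'   n_distinct_genes, n_in_gene.
#' @export
published_peak_summaries <- function(tab = published_peak_table(),
                                     threshold = 30L) {
  assignments <- data.table::data.table(
    short_name = tab$short_name,
    in_gene = tab$in_gene == "+"
  )
  dedup <- distinct_gene_count(assignments)
  list(
    n_clusters_at_threshold = sum(tab$variants >= threshold),
    max_cluster_variants = max(tab$variants),
    n_distinct_genes = dedup$n_distinct_genes,
    n_in_gene = sum(dedup$in_gene)
  )
}
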