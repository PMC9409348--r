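# Naive position-by-position reference implementations used as independent
# oracles. Deliberately written as plain loops over rows: slow, obvious,
# and structurally unrelated to the vectorised package code they check.

bf_coverage <- function(dm, samples, min_covered_depth = 1L) {
  covered <- 0L; total_depth <- 0
  for (i in seq_len(nrow(dm))) {
    d <- 0L
    for (s in samples) d <- d + dm[[s]][i]
    if (d >= min_covered_depth) covered <- covered + 1L
    total_depth <- total_depth + d
  }
  list(covered_fraction = covered / nrow(dm),
       mean_depth = total_depth / nrow(dm))
}

bf_sex_exclusive <- function(dm, zero_samples, covered_samples,
                             min_depth = 10L, min_samples = 3L) {
  hits <- list()
  for (i in seq_len(nrow(dm))) {
    all_zero <- TRUE
    for (s in zero_samples) if (dm[[s]][i] != 0L) { all_zero <- FALSE; break }
    if (!all_zero) next
    n_cov <- 0L
    for (s in covered_samples) if (dm[[s]][i] >= min_depth) n_cov <- n_cov + 1L
    if (n_cov >= min_samples)
      hits[[length(hits) + 1L]] <- data.frame(contig = dm$contig[i],
                                              pos = dm$pos[i],
                                              supporting_samples = n_cov)
  }
  if (!length(hits)) return(data.frame(contig = character(), pos = integer(),
                                       supporting_samples = integer()))
  do.call(rbind, hits)
}

bf_fixed_variants <- function(merged, samples) {
  keep <- logical(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    ok <- TRUE
    for (s in samples) {
      g <- merged[[paste0("gt_", s)]][i]
      if (is.na(g) || g != "1/1") { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  merged[keep]
}

bf_sex_associated <- function(merged, males, females, dm, min_depth_exclusive = 2L) {
  # positions disqualified by any female 1/1 at any ALT key
  bad <- character(0)
  for (i in seq_len(nrow(merged))) {
    for (s in females) {
      g <- merged[[paste0("gt_", s)]][i]
      if (!is.na(g) && g == "1/1")
        bad <- c(bad, paste(merged$contig[i], merged$pos[i]))
    }
  }
  keep <- logical(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    if (paste(merged$contig[i], merged$pos[i]) %in% bad) next
    ok <- TRUE
    for (s in males) {
      g <- merged[[paste0("gt_", s)]][i]
      if (is.na(g) || g != "1/1") { ok <- FALSE; break }
    }
    if (!ok) next
    for (s in females) {
      g <- merged[[paste0("gt_", s)]][i]
      if (!is.na(g) && !(g %in% c("0/1", "0/0"))) { ok <- FALSE; break }
    }
    if (!ok) next
    row <- which(dm$contig == merged$contig[i] & dm$pos == merged$pos[i])
    stopifnot(length(row) == 1L)
    for (s in c(males, females)) {
      if (dm[[s]][row] <= min_depth_exclusive) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  merged[keep]
}

bf_spacing <- function(sites) {
  u <- unique(as.data.frame(sites[, c("contig", "pos")]))
  dists <- integer(0)
  for (ctg in unique(u$contig)) {
    p <- sort(u$pos[u$contig == ctg])
    if (length(p) >= 2L)
      for (i in 2:length(p)) dists <- c(dists, p[i] - p[i - 1L])
  }
  list(mean_distance = if (length(dists)) mean(dists) else NA_real_,
       n_distances = length(dists), distances = dists)
}

bf_segment_counts <- function(sites, contig_lengths, window = 10000L) {
  rows <- list()
  for (ctg in names(contig_lengths)) {
    L <- contig_lengths[[ctg]]
    w <- 0L
    while (w * window < L) {
      lo <- w * window + 1L
      hi <- min((w + 1L) * window, L)
      cnt <- 0L
      for (i in seq_len(nrow(sites)))
        if (sites$contig[i] == ctg && sites$pos[i] >= lo && sites$pos[i] <= hi)
          cnt <- cnt + 1L
      rows[[length(rows) + 1L]] <- data.frame(contig = ctg, window_index = w,
                                              start = lo, end = hi, count = cnt)
      w <- w + 1L
    }
  }
  do.call(rbind, rows)
}

# 1-based closed query interval vs 0-based half-open gene, bedtools-style.
bf_point_gene_distance <- function(a, b, s, e) {
  gs <- s + 1L
  if (max(a, gs) <= min(b, e)) return(0L)
  if (e < a) return(a - e)
  gs - b
}

bf_nearest_gene <- function(queries, genes) {
  out <- list()
  for (i in seq_len(nrow(queries))) {
    a <- if ("pos_start" %in% names(queries)) queries$pos_start[i] else queries$pos[i]
    b <- if ("pos_end" %in% names(queries)) queries$pos_end[i] else queries$pos[i]
    g <- genes[genes$contig == queries$contig[i], ]
    g <- g[order(g$start, g$end), ]
    if (!nrow(g)) {
      out[[i]] <- data.frame(contig = queries$contig[i], name = NA_character_,
                             distance = NA_integer_)
      next
    }
    best_d <- Inf; best_j <- NA_integer_
    for (j in seq_len(nrow(g))) {
      d <- bf_point_gene_distance(a, b, g$start[j], g$end[j])
      if (d < best_d) { best_d <- d; best_j <- j }   # strict: first wins ties
    }
    out[[i]] <- data.frame(contig = queries$contig[i], name = g$name[best_j],
                           distance = as.integer(best_d))
  }
  do.call(rbind, out)
}

# Independent NG86 difference counter: recursive enumeration of minimal
# substitution pathways between two codons (stop-blocked paths excluded,
# all-blocked fallback to unblocked counting), standard genetic code from
# a locally built lookup.
bf_codon_aa <- local({
  code <- NULL
  function(codon) {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    unname(code[codon])
  }
})

bf_pathways <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  recurse <- function(cur, remaining, allow_stop) {
    if (!length(remaining)) return(list(c(0, 0)))
    res <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && bf_codon_aa(nxt) == "*" && nxt != c2) next
      step <- if (bf_codon_aa(cur) == bf_codon_aa(nxt)) c(1, 0) else c(0, 1)
      for (sub in recurse(nxt, setdiff(remaining, p), allow_stop))
        res[[length(res) + 1L]] <- step + sub
    }
    res
  }
  paths <- recurse(c1, pos, allow_stop = FALSE)
  if (!length(paths)) paths <- recurse(c1, pos, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}

bf_ng86_diffs <- function(cds_a, cds_b) {
  stopifnot(nchar(cds_a) == nchar(cds_b))
  n <- nchar(cds_a) / 3
  sd <- 0; nd <- 0
  for (k in seq_len(n)) {
    ca <- substr(cds_a, 3 * k - 2, 3 * k)
    cb <- substr(cds_b, 3 * k - 2, 3 * k)
    if (ca != cb) {
      d <- bf_pathways(ca, cb)
      sd <- sd + d[1L]; nd <- nd + d[2L]
    }
  }
  c(Sd = sd, Nd = nd)
}

# Random sense-codon CDS for property tests.
random_sense_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Keep the codons of `cds` whose (1-based) codon indices are in `keep`.
split_cds_keep <- function(cds, keep) {
  n <- nchar(cds) / 3
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  cods[keep]
}

# Independent table-lookup translation (no initiator-codon special casing).
translate_oracle <- function(cds) {
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(unname(Biostrings::GENETIC_CODE[cods]), collapse = "")
}
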