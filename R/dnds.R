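# Cached standard-genetic-code lookup tables for the NG86 estimator.
.ng86_cache <- new.env(parent = emptyenv())

# Codon list, amino-acid map and per-codon synonymous site counts under the
# standard genetic code. The synonymous site count of a codon is the sum
# over its three positions of (synonymous single-nt changes)/3; a change
# that creates a stop codon counts as nonsynonymous.
ng86_tables <- function() {
  if (!is.null(.ng86_cache$tab)) return(.ng86_cache$tab)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- setNames(as.character(code), codons)
  bases <- c("A", "C", "G", "T")
  syn_sites <- setNames(numeric(length(codons)), codons)
  for (cd in codons) {
    if (aa[[cd]] == "*") { syn_sites[[cd]] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cd, p, p))) {
        nb <- cd
        substr(nb, p, p) <- b
        if (aa[[nb]] == aa[[cd]]) s <- s + 1 / 3
      }
    }
    syn_sites[[cd]] <- s
  }
  .ng86_cache$tab <- list(codons = codons, aa = aa, syn_sites = syn_sites)
  .ng86_cache$tab
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                     no.init.codon = TRUE))
}

split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Back-translate a protein alignment to a gap-free codon alignment
#'
#' Maps every aligned amino-acid column to its source codon and drops
#' every column in which either protein has a gap (the `-nogap` behaviour
#' of pal2nal). Terminal stop codons on the CDS are stripped before the
#' check; internal stops and any CDS/protein translation mismatch are hard
#' errors. Ambiguity codes are unsupported.
#'
#' @param prot_a,prot_b Aligned protein sequences (equal length, `-` gaps).
#' @param cds_a,cds_b Ungapped coding sequences whose translations equal
#'   the degapped proteins.
#' @param pair_id Optional identifier carried through to results.
#' @return A `codon_alignment` list: `pair_id`, `cds_a`, `cds_b` (aligned,
#'   gap-free, equal length divisible by 3) and `n_codons`.
#' @export
codon_align <- function(prot_a, prot_b, cds_a, cds_b, pair_id = NA_character_) {
  if (nchar(prot_a) != nchar(prot_b))
    stop("aligned proteins must have equal length")
  if (grepl("[^ACGT]", cds_a) || grepl("[^ACGT]", cds_b))
    stop("CDS must contain only A/C/G/T (ambiguity codes unsupported)")
  strip_and_check <- function(cds, prot, label) {
    pa <- gsub("-", "", prot, fixed = TRUE)
    tr <- translate_cds(cds)
    if (nchar(tr) == nchar(pa) + 1L && substr(tr, nchar(tr), nchar(tr)) == "*") {
      cds <- substr(cds, 1L, nchar(cds) - 3L)
      tr <- substr(tr, 1L, nchar(tr) - 1L)
    }
    if (nchar(tr) != nchar(pa))
      stop("CDS/protein length mismatch for sequence ", label)
    mism <- which(strsplit(tr, "")[[1L]] != strsplit(pa, "")[[1L]])
    if (length(mism))
      stop("translation mismatch for sequence ", label, " at residue ",
           mism[1L], " (CDS gives '", substr(tr, mism[1L], mism[1L]),
           "', protein has '", substr(pa, mism[1L], mism[1L]), "')")
    if (grepl("\\*", tr))
      stop("internal stop codon in CDS for sequence ", label)
    cds
  }
  cds_a <- strip_and_check(cds_a, prot_a, "a")
  cds_b <- strip_and_check(cds_b, prot_b, "b")
  cols_a <- strsplit(prot_a, "")[[1L]]
  cols_b <- strsplit(prot_b, "")[[1L]]
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  ia <- cumsum(cols_a != "-")
  ib <- cumsum(cols_b != "-")
  keep <- cols_a != "-" & cols_b != "-"
  out <- list(pair_id = pair_id,
              cds_a = paste(cod_a[ia[keep]], collapse = ""),
              cds_b = paste(cod_b[ib[keep]], collapse = ""),
              n_codons = sum(keep))
  class(out) <- "codon_alignment"
  out
}

# Average synonymous/nonsynonymous differences between two codons over all
# minimal substitution pathways. Pathways passing through a stop codon are
# excluded; if every pathway is blocked, all pathways are used. Returns
# c(sd, nd).
codon_pathway_diffs <- function(c1, c2, tab) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(0, 0))
  perms <- switch(k,
                  list(pos),
                  list(pos, pos[2:1]),
                  {
                    p <- pos
                    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  score_path <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      aa_cur <- tab$aa[[cur]]
      aa_nxt <- tab$aa[[nxt]]
      if (aa_nxt == "*" && nxt != c2) return(NULL)       # blocked intermediate
      if (aa_cur == aa_nxt) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  scores <- lapply(perms, score_path)
  ok <- !vapply(scores, is.null, logical(1L))
  if (!any(ok)) {          # all pathways pass through a stop: use them anyway
    scores <- lapply(perms, function(order) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (tab$aa[[cur]] == tab$aa[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
    ok <- rep(TRUE, length(scores))
  }
  Reduce(`+`, scores[ok]) / sum(ok)
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) counting method
#'
#' Synonymous site counts per codon are averaged over the two sequences;
#' differences in multi-difference codons are averaged over all minimal
#' substitution pathways with equal weights. Proportions are corrected
#' with the Jukes-Cantor formula d = -(3/4) ln(1 - (4/3) p); a proportion
#' at or above 3/4 is reported as saturated (NA distance, raw p retained).
#' omega = dN/dS is reported only when dS > 0.
#'
#' @param alignment A `codon_alignment` from [codon_align()], or a
#'   length-2 character vector of equal-length gap-free CDS.
#' @return A `data.table` row: pair_id, n_codons, S, N, Sd, Nd, pS, pN,
#'   dS, dN, omega, saturated.
#' @export
ng86_dnds <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 2L) {
    alignment <- list(pair_id = NA_character_, cds_a = alignment[[1L]],
                      cds_b = alignment[[2L]],
                      n_codons = nchar(alignment[[1L]]) %/% 3L)
  }
  a <- alignment$cds_a
  b <- alignment$cds_b
  if (nchar(a) != nchar(b) || nchar(a) %% 3L != 0L)
    stop("codon alignment sequences must have equal length divisible by 3")
  tab <- ng86_tables()
  cod_a <- split_codons(a)
  cod_b <- split_codons(b)
  if (any(tab$aa[cod_a] == "*") || any(tab$aa[cod_b] == "*"))
    stop("stop codon inside codon alignment")
  s_a <- sum(tab$syn_sites[cod_a])
  s_b <- sum(tab$syn_sites[cod_b])
  S <- (s_a + s_b) / 2
  N <- 3 * length(cod_a) - S
  diffs <- which(cod_a != cod_b)
  sd_nd <- c(0, 0)
  for (i in diffs) sd_nd <- sd_nd + codon_pathway_diffs(cod_a[i], cod_b[i], tab)
  Sd <- sd_nd[1L]; Nd <- sd_nd[2L]
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  data.table::data.table(
    pair_id = alignment$pair_id, n_codons = length(cod_a),
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    dS = dS, dN = dN, omega = omega,
    saturated = pS >= 3 / 4 || pN >= 3 / 4
  )
}

#' dN/dS over a batch of codon alignments
#'
#' @param alignments List of `codon_alignment` objects.
#' @return `data.table` with one [ng86_dnds()] row per alignment, plus a
#'   `selection_class` column from [classify_selection()].
#' @export
ng86_batch <- function(alignments) {
  out <- data.table::rbindlist(lapply(alignments, ng86_dnds))
  out[, selection_class := classify_selection(omega)]
  out[]
}

#' Plausible-dS filter
#'
#' Keeps results whose dS lies inside `[lo, hi]` (both boundaries kept):
#' pairs below `lo` are too similar and pairs above `hi` too divergent for
#' a reliable dN/dS estimate. Saturated (NA) dS values are dropped.
#'
#' @param results `data.table` with a `dS` column.
#' @param lo,hi Inclusive bounds (defaults 0.01 and 2).
#' @return The kept subset, with `n_kept`/`n_dropped` attributes.
#' @export
ds_filter <- function(results, lo = 0.01, hi = 2.0) {
  if (lo >= hi) stop("ds_filter: lo must be strictly below hi")
  keep <- !is.na(results$dS) & results$dS >= lo & results$dS <= hi
  out <- results[keep]
  data.table::setattr(out, "n_kept", sum(keep))
  data.table::setattr(out, "n_dropped", sum(!keep))
  message("ds_filter: kept ", sum(keep), " of ", length(keep), " pairs")
  out
}

#' Selection class from an omega (dN/dS) value
#'
#' @param omega Numeric vector; NA (undefined ratio, e.g. dS = 0) maps to
#'   "undefined", never silently to purifying.
#' @return Character vector: adaptive (> 1), purifying (< 1), neutral
#'   (= 1) or undefined.
#' @export
classify_selection <- function(omega) {
  data.table::fcase(
    is.na(omega), "undefined",
    omega > 1, "adaptive",
    omega < 1, "purifying",
    default = "neutral"
  )
}
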