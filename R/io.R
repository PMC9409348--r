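#' Read reference contig lengths
#'
#' Accepts either a FASTA file or a samtools-faidx-style `.fai` index and
#' returns the contig lengths as a named integer vector, in file order.
#'
#' @param path Path to a FASTA file (`.fa`/`.fasta`) or a `.fai` index.
#' @return Named integer vector of contig lengths.
#' @export
read_contig_lengths <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.fai$", path)) {
    fai <- data.table::fread(path, header = FALSE)
    if (ncol(fai) < 2L)
      stop("malformed .fai index: expected at least 2 columns in ", path)
    return(setNames(as.integer(fai[[2L]]), as.character(fai[[1L]])))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(Biostrings::width(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Write a faidx-style index for a FASTA file written by this package
#'
#' Computes the five standard `.fai` columns (name, length, byte offset of
#' first base, bases per line, bytes per line) assuming the fixed line width
#' used by [write_fasta()].
#'
#' @param seqs A named `DNAStringSet` (or named character vector).
#' @param fasta_path Path of the FASTA file the index describes.
#' @param width Line width the FASTA was written with.
#' @return Invisibly, the path of the `.fai` file written.
#' @export
write_fai <- function(seqs, fasta_path, width = 80L) {
  lens <- if (inherits(seqs, "XStringSet")) Biostrings::width(seqs) else nchar(seqs)
  nms <- names(seqs)
  offset <- numeric(length(lens))
  cur <- 0
  for (i in seq_along(lens)) {
    cur <- cur + nchar(nms[i]) + 2L            # ">name\n"
    offset[i] <- cur
    n_lines <- ceiling(lens[i] / width)
    cur <- cur + lens[i] + n_lines             # bases + newlines
  }
  out <- paste0(fasta_path, ".fai")
  data.table::fwrite(
    data.table::data.table(nms, lens, format(offset, scientific = FALSE, trim = TRUE),
                           width, width + 1L),
    out, sep = "\t", col.names = FALSE, quote = FALSE
  )
  invisible(out)
}

#' Write sequences as FASTA with a fixed line width
#'
#' @param seqs Named `DNAStringSet`, `AAStringSet` or named character vector.
#' @param path Output path.
#' @param width Line width (bases per line).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (!inherits(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' Genes are 0-based half-open intervals. Column 4 holds the gene name;
#' an optional column 5 holds a short symbol (defaults to the name).
#' Strand, if present, is ignored: nearest-gene distances are strand-blind.
#'
#' @param path BED file path.
#' @return `data.table` with columns contig, start, end, name, short_name.
#' @export
read_genes_bed <- function(path) {
  stopifnot(file.exists(path))
  bed <- data.table::fread(path, header = FALSE)
  if (ncol(bed) < 4L) stop("gene BED needs at least 4 columns (chrom, start, end, name): ", path)
  genes <- data.table::data.table(
    contig = as.character(bed[[1L]]),
    start = as.integer(bed[[2L]]),
    end = as.integer(bed[[3L]]),
    name = as.character(bed[[4L]]),
    short_name = if (ncol(bed) >= 5L) as.character(bed[[5L]]) else as.character(bed[[4L]])
  )
  if (any(genes$start >= genes$end)) stop("gene BED has empty or inverted intervals: ", path)
  genes[]
}

#' Write gene intervals as BED
#'
#' @param genes `data.table` as returned by [read_genes_bed()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genes_bed <- function(genes, path) {
  data.table::fwrite(genes[, .(contig, start, end, name, short_name)], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-sample VCF into a variant-record table
#'
#' Parses a minimal VCF v4.2 dialect (CHROM, POS, REF, ALT, QUAL, FORMAT=GT,
#' one sample column) via \pkg{vcfR}. Multi-allelic ALT entries are split
#' into one record per ALT allele.
#'
#' @param path VCF file path.
#' @return `data.table` with columns contig, pos, ref, alt, qual, gt and an
#'   attribute `sample` carrying the sample name from the header line.
#' @export
read_vcf <- function(path) {
  stopifnot(file.exists(path))
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_mat <- v@gt
  sample_name <- if (!is.null(gt_mat) && ncol(gt_mat) >= 2L) colnames(gt_mat)[2L] else NA_character_
  if (nrow(fix) == 0L) {
    out <- data.table::data.table(contig = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  qual = numeric(), gt = character())
    data.table::setattr(out, "sample", sample_name)
    return(out)
  }
  gt <- sub(":.*$", "", gt_mat[, 2L])
  out <- data.table::data.table(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    qual = as.numeric(fix$QUAL),
    gt = gt
  )
  # split multi-allelic records: n-th ALT keeps the genotype recoded to that allele
  multi <- grepl(",", out$alt, fixed = TRUE)
  if (any(multi)) {
    expanded <- data.table::rbindlist(lapply(which(multi), function(r) {
      alts <- strsplit(out$alt[r], ",", fixed = TRUE)[[1L]]
      g <- vapply(seq_along(alts), function(i) recode_gt_for_allele(out$gt[r], i),
                  character(1L))
      keep <- is.na(g) | g != "0/0"
      data.table::data.table(contig = out$contig[r], pos = out$pos[r],
                             ref = out$ref[r], alt = alts[keep],
                             qual = out$qual[r], gt = g[keep])
    }))
    out <- data.table::rbindlist(list(out[!multi], expanded))
  }
  data.table::setorder(out, contig, pos, alt)
  data.table::setattr(out, "sample", sample_name)
  out[]
}

# Recode a diploid GT string against allele index i (1-based among ALTs):
# alleles equal to i become 1, all others 0; missing stays missing.
recode_gt_for_allele <- function(gt, i) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  alleles <- strsplit(gsub("|", "/", gt, fixed = TRUE), "/", fixed = TRUE)[[1L]]
  paste(sort(ifelse(alleles == as.character(i), "1", "0")), collapse = "/")
}

#' Write a variant-record table as a single-sample VCF v4.2
#'
#' @param records `data.table` with columns contig, pos, ref, alt, qual, gt.
#' @param path Output path.
#' @param sample_name Sample column name for the header.
#' @param contig_lengths Optional named integer vector; emitted as
#'   `##contig` header lines when supplied.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(records, path, sample_name, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sexvarscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sample_name), collapse = "\t"))
  body <- character(0)
  if (nrow(records) > 0L) {
    rec <- data.table::copy(records)
    data.table::setorder(rec, contig, pos, alt)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT\t%s",
                    rec$contig, rec$pos, rec$ref, rec$alt,
                    sprintf("%.2f", rec$qual), rec$gt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a per-sample depth table (samtools depth -aa layout)
#'
#' @param dt `data.table` with columns contig, pos, depth.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_depth_table <- function(dt, path) {
  data.table::fwrite(dt[, .(contig, pos, depth)], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
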