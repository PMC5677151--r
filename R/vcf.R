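# Minimal VCF 4.2 output for simulated blocks (phased GT, one contig per
# block) and read-back through VariantAnnotation.

#' Write simulated blocks or genotypes to a VCF 4.2 file
#'
#' Haplotype incidence is encoded as phased `GT` fields under consecutive
#' pairing (haplotypes 1+2 form individual 1, and so on); each block becomes
#' one contig.  Blocks without segregating sites contribute only their
#' contig header line.
#'
#' @param x A list of `sim_block` objects (from [simulate_blocks()]) or a
#'   [genotype_matrix()] (dosages are written as unphased `GT`).
#' @param path Output path.
#' @param sample_prefix Sample name prefix (default `"ind"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, sample_prefix = "ind") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=popconcord", con)
  if (inherits(x, "genotype_matrix")) {
    n_ind <- ncol(x$dosage)
    contigs <- names(x$contig_lengths)
    lens <- x$contig_lengths
    gt_rows <- function(ct) {
      sel <- x$contig == ct
      pos <- x$positions[sel]
      if (is.unsorted(pos, strictly = TRUE))
        stop("internal consistency error: unsorted positions in ", ct,
             call. = FALSE)
      dos <- x$dosage[sel, , drop = FALSE]
      gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow(dos), ncol(dos))
      list(pos = pos, gt = gt)
    }
  } else {
    blocks <- x
    n_ind <- blocks[[1L]]$n_haplotypes %/% 2L
    contigs <- paste0("block", vapply(blocks, `[[`, numeric(1), "id"))
    lens <- stats::setNames(vapply(blocks, `[[`, numeric(1), "L"), contigs)
    gt_rows <- function(ct) {
      b <- blocks[[match(ct, contigs)]]
      if (is.unsorted(b$positions, strictly = TRUE))
        stop("internal consistency error: unsorted positions in ", ct,
             call. = FALSE)
      h <- b$haplotypes
      i1 <- seq(1L, ncol(h), 2L)
      gt <- matrix(paste0(h[, i1, drop = FALSE], "|",
                          h[, i1 + 1L, drop = FALSE]),
                   nrow(h), length(i1))
      list(pos = b$positions, gt = gt)
    }
  }
  for (ct in contigs)
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ct,
                       as.integer(lens[[ct]])), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     paste0(sample_prefix, seq_len(n_ind))),
                   collapse = "\t"), con)
  for (ct in contigs) {
    rows <- gt_rows(ct)
    if (!length(rows$pos)) next
    lines <- paste(ct, rows$pos, ".", "A", "T", ".", "PASS", ".", "GT",
                   apply(rows$gt, 1L, paste, collapse = "\t"),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF into a genotype (dosage) matrix
#'
#' Uses VariantAnnotation to parse the file; any `GT` separator (`/` or
#' `|`) is accepted and alt-allele dosages are summed.  Contig lengths come
#' from the `##contig` header lines.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package", call. = FALSE)
  v <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(v)$GT
  dos <- apply(gt, c(1, 2), function(s) {
    a <- strsplit(s, "[/|]")[[1L]]
    sum(as.integer(a))
  })
  dos <- matrix(as.integer(dos), nrow(gt), ncol(gt))
  rr <- SummarizedExperiment::rowRanges(v)
  contig <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  sl <- GenomeInfoDb::seqlengths(rr)
  if (any(is.na(sl)))
    sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(ct)
      max(pos[contig == ct]), numeric(1))
  genotype_matrix(dos, positions = pos, contig = contig,
                  contig_lengths = sl)
}
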