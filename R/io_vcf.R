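#' Write a SNP genotype matrix as VCF v4.2
#'
#' Genotypes are diploid dosages (0, 1, 2 copies of ALT; NA = missing),
#' emitted as `0/0`, `0/1`, `1/1`, `./.`. Internal 0-based positions are
#' converted to the 1-based VCF convention on output.
#'
#' @param gt a [genotype_matrix].
#' @param path output path.
#' @param contigs named vector of contig lengths for the header (optional).
#' @return invisibly, `path`.
#' @export
write_snp_vcf <- function(gt, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=panpav", con)
  if (!is.null(contigs))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  acc <- colnames(gt$dosage)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", acc), collapse = "\t"), con)
  gtstr <- matrix("./.", nrow(gt$dosage), ncol(gt$dosage))
  gtstr[gt$dosage == 0L] <- "0/0"
  gtstr[gt$dosage == 1L] <- "0/1"
  gtstr[gt$dosage == 2L] <- "1/1"
  body <- paste(gt$sites$chrom, gt$sites$pos + 1L,
                gt$sites$id %||% paste0("var", seq_len(nrow(gt$sites))),
                gt$sites$ref, gt$sites$alt, ".", "PASS", ".", "GT",
                apply(gtstr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write a PAV cluster set as VCF v4.2
#'
#' One record per cluster. Sequence-resolved REF/ALT are used for DEL/INS up
#' to `max_resolved` bp; longer events are written as symbolic `<DEL>`/`<INS>`
#' with `SVTYPE`, `END` and `SVLEN` INFO keys. GT is `1/1` present, `0/0`
#' absent, `./.` missing.
#'
#' @param clusters a `pav_cluster_set` (see [merge_pavs]) with genotypes.
#' @param genome the reference `genome_assembly` (for REF bases).
#' @param path output path.
#' @param max_resolved longest event written with explicit sequence.
#' @return invisibly, `path`.
#' @export
write_pav_vcf <- function(clusters, genome, path, max_resolved = 10000L) {
  cl <- clusters$clusters
  geno <- clusters$genotypes   # cluster x accession: 1 present, 0 absent, NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", "##source=panpav",
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=INS,Description="Insertion">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  lens <- chrom_lengths(genome)
  writeLines(sprintf("##contig=<ID=%s,length=%d>", names(lens),
                     as.integer(lens)), con)
  acc <- colnames(geno)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", acc), collapse = "\t"), con)
  gtstr <- matrix("./.", nrow(geno), ncol(geno))
  gtstr[geno == 1] <- "1/1"
  gtstr[geno == 0] <- "0/0"
  for (i in seq_len(nrow(cl))) {
    chr <- genome$chromosomes[[cl$chrom[i]]]
    if (cl$subtype[i] == "DEL") {
      svlen <- -(cl$end[i] - cl$start[i])
      pos0 <- cl$start[i] - 1L        # pad base before the event
      if (pos0 < 0) pos0 <- 0L
      if (-svlen <= max_resolved) {
        ref <- as.character(Biostrings::subseq(chr, pos0 + 1L, cl$end[i]))
        alt <- substr(ref, 1L, 1L)
      } else {
        ref <- as.character(Biostrings::subseq(chr, pos0 + 1L, pos0 + 1L))
        alt <- "<DEL>"
      }
      info <- sprintf("SVTYPE=DEL;END=%d;SVLEN=%d", cl$end[i], svlen)
    } else {
      svlen <- nchar(cl$seq[i])
      pos0 <- max(cl$start[i] - 1L, 0L)
      base <- as.character(Biostrings::subseq(chr, pos0 + 1L, pos0 + 1L))
      if (svlen <= max_resolved) {
        ref <- base
        alt <- paste0(base, cl$seq[i])
      } else {
        ref <- base
        alt <- "<INS>"
      }
      info <- sprintf("SVTYPE=INS;END=%d;SVLEN=%d", pos0 + 1L, svlen)
    }
    writeLines(paste(c(cl$chrom[i], pos0 + 1L, cl$cluster_id[i], ref, alt,
                       ".", "PASS", info, "GT", gtstr[i, ]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF emitted by this package into a genotype matrix
#'
#' Uses \pkg{vcfR} for parsing. Dosage coding: `0/0` -> 0, `0/1` or `1/0` ->
#' 1, `1/1` -> 2, `./.` -> NA. Positions are converted back to the internal
#' 0-based convention.
#'
#' @param path VCF path.
#' @return a [genotype_matrix].
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_genotypes requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gtm <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gtm), ncol(gtm),
                dimnames = dimnames(gtm))
  dos[gtm %in% c("0/0", "0|0")] <- 0L
  dos[gtm %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gtm %in% c("1/1", "1|1")] <- 2L
  info <- vcfR::getINFO(v)
  genotype_matrix(
    sites = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
                       id = fix$ID, ref = fix$REF, alt = fix$ALT,
                       info = info, stringsAsFactors = FALSE),
    dosage = dos)
}

#' Genotype matrix container
#'
#' @param sites data frame with at least `chrom`, `pos` (0-based), `ref`,
#'   `alt`; one row per variant.
#' @param dosage integer matrix, variants x accessions, ALT dosage 0/1/2 or
#'   NA for missing.
#' @param labels optional named character vector mapping accession ->
#'   population label.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, dosage, labels = NULL) {
  stopifnot(nrow(sites) == nrow(dosage))
  if (is.null(colnames(dosage))) stop("dosage needs accession column names")
  structure(list(sites = sites, dosage = dosage, labels = labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "variants x",
      ncol(x$dosage), "accessions\n")
  invisible(x)
}

#' Per-variant allele counts
#'
#' @param gt a [genotype_matrix].
#' @param accessions optional subset of accession names.
#' @return data frame with `c` (ALT allele count), `n` (called allele count),
#'   `maf` and `missing` (fraction of accessions uncalled).
#' @export
allele_counts <- function(gt, accessions = NULL) {
  d <- gt$dosage
  if (!is.null(accessions)) d <- d[, accessions, drop = FALSE]
  called <- !is.na(d)
  n <- 2L * rowSums(called)
  c_alt <- rowSums(d, na.rm = TRUE)
  maf <- ifelse(n > 0, pmin(c_alt, n - c_alt) / n, NA_real_)
  data.frame(c = c_alt, n = n, maf = maf,
             missing = 1 - rowSums(called) / ncol(d))
}
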