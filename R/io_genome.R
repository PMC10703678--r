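#' Genome assembly container
#'
#' A light container for one haploid assembly: chromosome sequences plus the
#' annotation tracks the pipeline consumes (gene models, TE copies, assembly
#' gaps, centromeres). All coordinates are 0-based half-open.
#'
#' @param accession_id character label for the accession.
#' @param chromosomes a named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences.
#' @param genes data frame: `gene_id`, `chrom`, `strand` (+/-), `start`, `end`.
#' @param exons data frame: `gene_id`, `start`, `end` (CDS exons, non-
#'   overlapping, sorted within gene).
#' @param te data frame: `chrom`, `start`, `end`, `te_class` (LTR/DNA),
#'   `template_id`.
#' @param gaps,centromeres data frames: `chrom`, `start`, `end`.
#' @return an object of class `genome_assembly`.
#' @export
genome_assembly <- function(accession_id, chromosomes,
                            genes = NULL, exons = NULL, te = NULL,
                            gaps = NULL, centromeres = NULL) {
  if (!methods::is(chromosomes, "DNAStringSet"))
    chromosomes <- Biostrings::DNAStringSet(chromosomes)
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosomes must have unique names")
  g <- structure(list(
    accession_id = accession_id,
    chromosomes = chromosomes,
    genes = genes %||% data.frame(gene_id = character(), chrom = character(),
                                  strand = character(), start = integer(),
                                  end = integer(), stringsAsFactors = FALSE),
    exons = exons %||% data.frame(gene_id = character(), start = integer(),
                                  end = integer(), stringsAsFactors = FALSE),
    te = te %||% data.frame(chrom = character(), start = integer(),
                            end = integer(), te_class = character(),
                            template_id = character(), stringsAsFactors = FALSE),
    gaps = gaps %||% empty_intervals(),
    centromeres = centromeres %||% empty_intervals()
  ), class = "genome_assembly")
  validate_genome(g)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
validate_genome <- function(g) {
  len <- stats::setNames(Biostrings::width(g$chromosomes),
                         names(g$chromosomes))
  chk <- function(df, what) {
    if (nrow(df) == 0) return(invisible())
    if (!all(df$chrom %in% names(len)))
      stop(what, ": unknown chromosome")
    if (any(df$start < 0 | df$end > len[df$chrom] | df$start > df$end))
      stop(what, ": interval outside chromosome bounds")
  }
  chk(g$te, "te"); chk(g$gaps, "gaps"); chk(g$centromeres, "centromeres")
  if (nrow(g$genes) > 0) {
    chk(g$genes, "genes")
    if (!all(g$genes$strand %in% c("+", "-"))) stop("genes: bad strand")
    ex <- g$exons
    if (!all(ex$gene_id %in% g$genes$gene_id)) stop("exons: orphan gene_id")
    for (gid in unique(ex$gene_id)) {
      e <- ex[ex$gene_id == gid, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (any(e$start[-1] < e$end[-nrow(e)])) stop("exons overlap in ", gid)
    }
  }
  invisible(g)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly", x$accession_id, "\n")
  cat(" ", length(x$chromosomes), "chromosomes,",
      sum(Biostrings::width(x$chromosomes)), "bp\n")
  cat(" ", nrow(x$genes), "genes,", nrow(x$te), "TE copies,",
      nrow(x$gaps), "gaps,", nrow(x$centromeres), "centromere intervals\n")
  invisible(x)
}

#' Named chromosome lengths of an assembly
#' @param g a `genome_assembly`.
#' @return named integer vector.
#' @export
chrom_lengths <- function(g) {
  stats::setNames(Biostrings::width(g$chromosomes), names(g$chromosomes))
}

#' Write a genome assembly to disk
#'
#' Emits `<prefix>.fa` (60-column FASTA), `<prefix>.genes.gff3`,
#' `<prefix>.te.bed`, `<prefix>.gaps.bed` and `<prefix>.centromeres.bed`.
#' Output is deterministic: identical assemblies produce byte-identical files.
#'
#' @param g a `genome_assembly`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(g, prefix) {
  paths <- c(fasta = paste0(prefix, ".fa"),
             gff = paste0(prefix, ".genes.gff3"),
             te = paste0(prefix, ".te.bed"),
             gaps = paste0(prefix, ".gaps.bed"),
             cen = paste0(prefix, ".centromeres.bed"))
  Biostrings::writeXStringSet(g$chromosomes, paths["fasta"], width = 60L)
  write_gff3(g, paths["gff"])
  write_bed(cbind(g$te[c("chrom", "start", "end")],
                  name = paste0(g$te$te_class, ":", g$te$template_id)),
            paths["te"])
  write_bed(g$gaps, paths["gaps"])
  write_bed(g$centromeres, paths["cen"])
  invisible(paths)
}

#' @keywords internal
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", intersect("name", names(df)))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @keywords internal
read_bed <- function(path) {
  if (file.size(path) == 0) return(empty_intervals())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

## GFF3 emission: gene -> mRNA -> exon + CDS; 1-based inclusive on output.
#' @keywords internal
write_gff3 <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- g$genes[order(g$genes$chrom, g$genes$start), , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    writeLines(sprintf("%s\tpanpav\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom[i], genes$start[i] + 1L, genes$end[i],
                       genes$strand[i], gid), con)
    writeLines(sprintf("%s\tpanpav\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                       genes$chrom[i], genes$start[i] + 1L, genes$end[i],
                       genes$strand[i], gid, gid), con)
    ex <- g$exons[g$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf(
        "%s\tpanpav\texon\t%d\t%d\t.\t%s\t.\tParent=%s.1",
        genes$chrom[i], ex$start[j] + 1L, ex$end[j], genes$strand[i], gid), con)
      writeLines(sprintf(
        "%s\tpanpav\tCDS\t%d\t%d\t.\t%s\t.\tParent=%s.1",
        genes$chrom[i], ex$start[j] + 1L, ex$end[j], genes$strand[i], gid), con)
    }
  }
  invisible(path)
}

#' Extract the spliced CDS sequence of one gene
#'
#' Exons are concatenated in genomic order, then reverse-complemented for
#' minus-strand genes.
#'
#' @param g a `genome_assembly`.
#' @param gene_id gene identifier present in `g$genes`.
#' @return a character scalar.
#' @export
cds_sequence <- function(g, gene_id) {
  gi <- g$genes[g$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(gi) != 1) stop("unknown gene_id: ", gene_id)
  ex <- g$exons[g$exons$gene_id == gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  chr <- g$chromosomes[[gi$chrom]]
  parts <- vapply(seq_len(nrow(ex)), function(j) {
    as.character(Biostrings::subseq(chr, ex$start[j] + 1L, ex$end[j]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (gi$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}
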