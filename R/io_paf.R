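#' Read a PAF alignment into gapless anchor blocks
#'
#' Each `M`/`=`/`X` run of the `cg:Z:` CIGAR becomes one gapless
#' [alignment block][alignment_blocks]; `I`/`D` runs split blocks so that
#' downstream SV calling is pure coordinate arithmetic. Query coordinates are
#' reported on the forward strand (the PAF convention) and minus-strand
#' records keep `strand = "-"` with the query interval walked from the high
#' end. Records without a `cg` tag fall back to one coarse block spanning the
#' whole alignment, with a warning naming the line.
#'
#' PAF columns used: qname qlen qstart qend strand tname tlen tstart tend
#' nmatch alnlen mapq tags. The target is treated as the reference.
#'
#' @param path path to a PAF file (plain text).
#' @return a data frame of blocks: `ref_chrom, ref_start, ref_end,
#'   query_chrom, query_start, query_end, strand, n_matches` (0-based
#'   half-open).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("malformed PAF line ", i)
    qname <- f[1]; qstart <- as.integer(f[3]); qend <- as.integer(f[4])
    strand <- f[5]
    tname <- f[6]; tstart <- as.integer(f[8]); tend <- as.integer(f[9])
    cg <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (length(cg) == 0) {
      warning("PAF line ", i, " has no cg tag; using one coarse block")
      out[[i]] <- data.frame(
        ref_chrom = tname, ref_start = tstart, ref_end = tend,
        query_chrom = qname, query_start = qstart, query_end = qend,
        strand = strand, n_matches = min(tend - tstart, qend - qstart),
        stringsAsFactors = FALSE)
      next
    }
    out[[i]] <- cigar_to_blocks(sub("^cg:Z:", "", cg[1]), tname, tstart,
                                qname, qstart, qend, strand)
  }
  blocks <- do.call(rbind, out)
  rownames(blocks) <- NULL
  blocks
}

#' @keywords internal
cigar_to_blocks <- function(cigar, tname, tstart, qname, qstart, qend,
                            strand) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  t <- tstart
  # walk the query in alignment orientation; on '-' the alignment starts at
  # the forward-strand high end and walks down
  q <- if (strand == "+") qstart else qend
  rows <- list()
  for (k in seq_along(ops)) {
    L <- lens[k]
    kind <- kinds[k]
    if (kind %in% c("M", "=", "X")) {
      if (strand == "+") {
        rows[[length(rows) + 1L]] <- c(t, t + L, q, q + L)
        q <- q + L
      } else {
        rows[[length(rows) + 1L]] <- c(t, t + L, q - L, q)
        q <- q - L
      }
      t <- t + L
    } else if (kind %in% c("D", "N")) {
      t <- t + L
    } else if (kind == "I") {
      q <- if (strand == "+") q + L else q - L
    } # S/H/P consume nothing we track at block level
  }
  m <- do.call(rbind, rows)
  data.frame(
    ref_chrom = tname, ref_start = m[, 1], ref_end = m[, 2],
    query_chrom = qname, query_start = m[, 3], query_end = m[, 4],
    strand = strand, n_matches = m[, 2] - m[, 1],
    stringsAsFactors = FALSE)
}
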