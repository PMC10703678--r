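#' Interval algebra on 0-based half-open genomic intervals
#'
#' All coordinates inside this package are 0-based half-open, the BED
#' convention: an interval `[start, end)` of length `end - start`. These
#' helpers wrap [GenomicRanges] so every module shares one set of semantics;
#' conversion to the 1-based closed convention happens only at the
#' GenomicRanges boundary (and on VCF/GFF3 emission).
#'
#' @param x,a,b data frames with columns `chrom`, `start`, `end` (half-open).
#' @name intervals
NULL

#' @keywords internal
as_granges0 <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) > 0 && any(x$end < x$start))
    stop("interval with end < start")
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' @keywords internal
as_df0 <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             stringsAsFactors = FALSE)
}

#' Merge (union) possibly overlapping intervals
#'
#' Book-ended intervals (`[0,5)`, `[5,9)`) are merged, matching
#' `bedtools merge` on half-open input.
#'
#' @rdname intervals
#' @return a sorted data frame of disjoint intervals.
#' @export
interval_merge <- function(x) {
  if (nrow(x) == 0) return(empty_intervals())
  as_df0(GenomicRanges::reduce(as_granges0(x)))
}

#' Base-pair intersection of two interval sets
#' @rdname intervals
#' @export
interval_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_intervals())
  out <- suppressWarnings(
    GenomicRanges::intersect(as_granges0(a), as_granges0(b)))
  as_df0(out)
}

#' Subtract interval set `b` from `a`
#' @rdname intervals
#' @export
interval_subtract <- function(a, b) {
  if (nrow(a) == 0) return(empty_intervals())
  if (nrow(b) == 0) return(interval_merge(a))
  out <- suppressWarnings(
    GenomicRanges::setdiff(as_granges0(a), as_granges0(b)))
  as_df0(out)
}

#' Total number of bases covered by an interval set
#' @rdname intervals
#' @export
interval_bases <- function(x) {
  if (nrow(x) == 0) return(0)
  m <- interval_merge(x)
  sum(m$end - m$start)
}

#' Does any interval of `a` overlap any interval of `b`?
#'
#' Returns a logical vector along the rows of `a`. Half-open semantics:
#' `[0,10)` does not overlap `[10,20)`.
#'
#' @rdname intervals
#' @export
interval_overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  ga <- as_granges0(a)
  gb <- as_granges0(b)
  suppressWarnings(IRanges::overlapsAny(ga, gb))
}

#' Closest interval in `b` for each interval of `a`
#'
#' @rdname intervals
#' @return data frame with `index` (row of `b`, NA when `b` has no interval on
#'   the chromosome) and `distance` (0 when touching or overlapping; gap in bp
#'   otherwise), matching the distance convention used for PAV-to-gene
#'   annotation.
#' @export
interval_closest <- function(a, b) {
  n <- nrow(a)
  res <- data.frame(index = rep(NA_integer_, n), distance = rep(NA_real_, n))
  if (n == 0 || nrow(b) == 0) return(res)
  for (i in seq_len(n)) {
    same <- which(b$chrom == a$chrom[i])
    if (length(same) == 0) next
    gap <- pmax(b$start[same] - a$end[i], a$start[i] - b$end[same], 0)
    j <- which.min(gap)
    res$index[i] <- same[j]
    res$distance[i] <- gap[j]
  }
  res
}

#' Jaccard similarity (base-pair) between two interval sets
#' @rdname intervals
#' @export
interval_jaccard <- function(a, b) {
  inter <- interval_bases(interval_intersect(a, b))
  uni <- interval_bases(rbind(interval_merge(a), interval_merge(b)))
  if (uni == 0) return(NA_real_)
  inter / uni
}

## one master seed fans out to named sub-generators so adding a generator
## does not perturb the draws of another
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((abs(seed) * 7919 + h) %% 2147483647L)
}

with_seed <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, name))
  force(expr)
}
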