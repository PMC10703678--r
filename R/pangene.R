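#' Classify gene-family occupancy
#'
#' With N genomes, a family present in all N is `core`; in N-2..N-1
#' `softcore`; in exactly 1 `private`; otherwise `dispensable` (2..N-3).
#' With the default thresholds and N = 32 this instantiates the usual
#' 32 / 30-31 / 2-29 / 1 bounds. For small N where the windows collide, the
#' documented precedence is core, then softcore, then private, then
#' dispensable.
#'
#' @param matrix binary occupancy matrix (families x genomes) or a data
#'   frame coercible to one.
#' @param softcore_span how far below N the softcore window extends
#'   (default 2: N-2..N-1).
#' @return list of class `occupancy_classes`: `class` (factor per family),
#'   `counts`, `fractions`, `n_genomes`.
#' @export
classify_occupancy <- function(matrix, softcore_span = 2L) {
  m <- as.matrix(matrix)
  if (!all(m %in% c(0, 1))) stop("occupancy matrix must be binary")
  N <- ncol(m)
  if (N < 4) stop("need at least 4 genomes")
  k <- rowSums(m)
  if (any(k == 0)) stop("family with zero occupancy")
  cls <- occupancy_class_of(k, N, softcore_span)
  counts <- table(factor(cls, levels = c("core", "softcore", "dispensable",
                                         "private")))
  structure(list(class = cls, counts = counts,
                 fractions = counts / length(k), n_genomes = N),
            class = "occupancy_classes")
}

#' Occupancy class from per-family genome counts
#'
#' The same classification rule applied directly to occupancy counts (how
#' many genomes carry each family), without a matrix.
#'
#' @param k integer vector of occupancy counts (1..N).
#' @param N number of genomes.
#' @param softcore_span see [classify_occupancy].
#' @return character vector of classes.
#' @export
occupancy_class_of <- function(k, N, softcore_span = 2L) {
  stopifnot(all(k >= 1), all(k <= N))
  ifelse(k == N, "core",
         ifelse(k >= N - softcore_span, "softcore",
                ifelse(k == 1, "private", "dispensable")))
}

#' @export
print.occupancy_classes <- function(x, ...) {
  cat("occupancy over", x$n_genomes, "genomes:\n")
  print(x$counts)
  invisible(x)
}

#' Pan/core rarefaction curves
#'
#' For each subsample size k = 1..N, draws `n_draws` uniform samples of k
#' genomes without replacement; the pan size is the number of families
#' present in at least one sampled genome and the core size the number
#' present in all k.
#'
#' @param matrix binary occupancy matrix (families x genomes).
#' @param n_draws draws per subsample size.
#' @param seed integer seed.
#' @return data frame per k: `k`, `pan_mean`, `pan_sd`, `core_mean`,
#'   `core_sd`.
#' @export
rarefaction <- function(matrix, n_draws = 100L, seed = 1L) {
  m <- as.matrix(matrix)
  N <- ncol(m)
  with_seed(seed, "rarefaction", {
    out <- lapply(seq_len(N), function(k) {
      pan <- core <- numeric(n_draws)
      for (d in seq_len(n_draws)) {
        cols <- sample.int(N, k)
        sub <- m[, cols, drop = FALSE]
        rs <- rowSums(sub)
        pan[d] <- sum(rs >= 1)
        core[d] <- sum(rs == k)
      }
      data.frame(k = k, pan_mean = mean(pan), pan_sd = stats::sd(pan),
                 core_mean = mean(core), core_sd = stats::sd(core))
    })
    do.call(rbind, out)
  })
}

#' Nucleotide diversity of a multiple alignment
#'
#' pi = D / L / (N (N - 1) / 2), where L is the number of conserved
#' (gap-free) columns, D the total count of pairwise mismatches over those
#' columns summed across all unordered sequence pairs, and N the number of
#' sequences.
#'
#' @param msa character vector of aligned sequences (equal length; `-` or
#'   `.` for gaps), or a [Biostrings::DNAStringSet].
#' @return the diversity value.
#' @export
alignment_pi <- function(msa) {
  if (methods::is(msa, "XStringSet")) msa <- as.character(msa)
  N <- length(msa)
  if (N < 2) stop("need at least 2 sequences")
  if (length(unique(nchar(msa))) != 1) stop("rows differ in length")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  conserved <- colSums(m == "-" | m == ".") == 0
  L <- sum(conserved)
  if (L == 0) stop("conserved alignment length is zero")
  m <- m[, conserved, drop = FALSE]
  D <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      D <- D + sum(m[i, ] != m[j, ])
    }
  }
  D / L / (N * (N - 1) / 2)
}

#' Read an orthogroup table into an occupancy matrix
#'
#' Consumes the tab-separated orthogroup dialect (first column the family
#' id, one column per genome, comma-separated gene lists, empty when
#' absent).
#'
#' @param path TSV path.
#' @return binary matrix, families x genomes.
#' @export
read_orthogroups <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  fam <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  occ <- (m != "" & !is.na(m)) * 1L
  rownames(occ) <- fam
  occ
}
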