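#' Bonferroni genome-wide significance threshold
#'
#' `alpha / n_tests`, the uniform threshold for association scans; the
#' negative log10 is reported to 2 decimals.
#'
#' @param n_tests total number of tested variants (>= 1).
#' @param alpha family-wise error target.
#' @return list with `threshold` and `neglog10` (2 d.p.).
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  thr <- alpha / n_tests
  list(threshold = thr, neglog10 = round(-log10(thr), 2))
}

#' Filter variants on MAF and missing rate
#'
#' Retains variants with minor allele frequency at least `maf_min` and
#' missing-genotype fraction at most `missing_max`. Preset defaults: SNPs
#' 0.05/0.1, PAVs 0.05/0.5.
#'
#' @param gt a [genotype_matrix].
#' @param class `"SNP"` or `"PAV"` preset.
#' @param maf_min,missing_max override the preset.
#' @return the filtered [genotype_matrix].
#' @export
variant_filters <- function(gt, class = c("SNP", "PAV"), maf_min = 0.05,
                            missing_max = NULL) {
  class <- match.arg(class)
  if (is.null(missing_max)) missing_max <- if (class == "SNP") 0.1 else 0.5
  ac <- allele_counts(gt)
  keep <- !is.na(ac$maf) & ac$maf >= maf_min & ac$missing <= missing_max
  genotype_matrix(gt$sites[keep, , drop = FALSE],
                  gt$dosage[keep, , drop = FALSE], gt$labels)
}

#' Define candidate regions around significant variants
#'
#' Implements the iterative 200-kb extension: seed at a significant
#' variant, look 200 kb up- and downstream, and keep extending from the
#' last significant variant until no further significant variant appears.
#' This is equivalent to single-linkage clustering of the significant
#' variants with an inter-variant gap of at most `ext`; region boundaries
#' are the first and last member positions and the peak is the member with
#' the smallest P (ties: leftmost).
#'
#' @param results data frame `chrom`, `pos`, `p`.
#' @param threshold significance threshold on P.
#' @param ext extension distance in bp.
#' @return data frame of regions: `chrom`, `start`, `end`, `n_variants`,
#'   `peak_pos`, `peak_p`.
#' @export
define_candidate_regions <- function(results, threshold, ext = 200000L) {
  sig <- results[!is.na(results$p) & results$p <= threshold, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_variants = integer(),
                      peak_pos = integer(), peak_p = numeric()))
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  new_cluster <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                     diff(sig$pos) > ext)
  cid <- cumsum(new_cluster)
  out <- lapply(split(seq_len(nrow(sig)), cid), function(idx) {
    s <- sig[idx, , drop = FALSE]
    peak <- which(s$p == min(s$p))[1]
    data.frame(chrom = s$chrom[1], start = min(s$pos), end = max(s$pos),
               n_variants = nrow(s), peak_pos = s$pos[peak],
               peak_p = s$p[peak], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regions reproducible across environments
#'
#' A region is reliable when regions overlapping it exist in at least
#' `min_support` of the per-environment (location x year) region lists.
#'
#' @param region_sets list of region data frames from
#'   [define_candidate_regions].
#' @param min_support minimum supporting environments.
#' @return merged data frame of reliable regions with a `support` column.
#' @export
reliable_regions <- function(region_sets, min_support = 2L) {
  all_r <- do.call(rbind, lapply(seq_along(region_sets), function(i) {
    r <- region_sets[[i]][, c("chrom", "start", "end"), drop = FALSE]
    if (nrow(r) > 0) r$set <- i
    r
  }))
  if (is.null(all_r) || nrow(all_r) == 0)
    return(cbind(empty_intervals(), support = integer()))
  merged <- interval_merge(all_r[c("chrom", "start", "end")])
  support <- vapply(seq_len(nrow(merged)), function(i) {
    hit <- interval_overlaps_any(all_r[c("chrom", "start", "end")],
                                 merged[i, , drop = FALSE])
    length(unique(all_r$set[hit]))
  }, integer(1))
  out <- merged[support >= min_support, , drop = FALSE]
  out$support <- support[support >= min_support]
  rownames(out) <- NULL
  out
}

#' Per-variant dosage score test (association stand-in)
#'
#' A plain trend test of phenotype on genotype dosage (t-test on the
#' Pearson correlation), used to drive synthetic end-to-end runs of the
#' post-processing; it performs no population-structure correction, so the
#' P values of a mixed-model scan are the intended production input.
#'
#' @param gt a [genotype_matrix].
#' @param phenotype named numeric vector over accessions.
#' @return data frame `chrom`, `pos`, `p`.
#' @export
assoc_scan <- function(gt, phenotype) {
  acc <- intersect(colnames(gt$dosage), names(phenotype))
  y <- phenotype[acc]
  d <- gt$dosage[, acc, drop = FALSE]
  p <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4 || stats::sd(x[ok]) == 0) return(NA_real_)
    r <- stats::cor(x[ok], y[ok])
    tt <- r * sqrt((sum(ok) - 2) / max(1 - r^2, 1e-12))
    2 * stats::pt(-abs(tt), sum(ok) - 2)
  }, numeric(1))
  data.frame(chrom = gt$sites$chrom, pos = gt$sites$pos, p = p,
             stringsAsFactors = FALSE)
}

#' Gene haplotypes from variants in and around a gene
#'
#' Builds the joint allele string over the selected variant sites within
#' the gene body plus `flank` bp; accessions with a missing or heterozygous
#' call at any selected site are excluded. Haplotype groups are numbered by
#' descending size (Hap1 the largest); groups below `min_group` are
#' reported but flagged small.
#'
#' @param gt a [genotype_matrix].
#' @param gene one-row gene record (`chrom`, `start`, `end`).
#' @param flank flank in bp.
#' @param sites optional logical/integer index selecting among the in-window
#'   variants (site filter).
#' @param min_group group-size flag threshold.
#' @return list of class `haplotype_table`: `assignment` (accession -> Hap
#'   label), `groups` (data frame `hap`, `n`, `small`, `haplotype`),
#'   `positions`.
#' @export
gene_haplotypes <- function(gt, gene, flank = 2000L, sites = NULL,
                            min_group = 10L) {
  inwin <- which(gt$sites$chrom == gene$chrom &
                   gt$sites$pos >= gene$start - flank &
                   gt$sites$pos < gene$end + flank)
  if (!is.null(sites)) inwin <- inwin[sites]
  if (length(inwin) == 0) stop("zero selected sites for haplotype analysis")
  d <- gt$dosage[inwin, , drop = FALSE]
  ref <- gt$sites$ref[inwin]; alt <- gt$sites$alt[inwin]
  ok <- colSums(is.na(d) | d == 1L) == 0
  alle <- matrix(ref, nrow = length(inwin), ncol = ncol(d))
  altm <- matrix(alt, nrow = length(inwin), ncol = ncol(d))
  idx <- which(d == 2L)
  alle[idx] <- altm[idx]
  hap <- apply(alle[, ok, drop = FALSE], 2, paste, collapse = "")
  names(hap) <- colnames(d)[ok]
  tab <- sort(table(hap), decreasing = TRUE)
  labels <- stats::setNames(paste0("Hap", seq_along(tab)), names(tab))
  groups <- data.frame(hap = unname(labels), n = as.integer(tab),
                       small = as.integer(tab) < min_group,
                       haplotype = names(tab), stringsAsFactors = FALSE)
  structure(list(assignment = stats::setNames(unname(labels[hap]),
                                              names(hap)),
                 groups = groups,
                 positions = gt$sites$pos[inwin]),
            class = "haplotype_table")
}

#' Kruskal-Wallis + Nemenyi haplotype-phenotype test
#'
#' Groups below `min_group` are dropped; with two eligible groups the test
#' falls back to a two-sided Wilcoxon rank-sum, with more a Kruskal-Wallis
#' test followed by the Nemenyi all-pairs post-hoc (rank sums compared on
#' the Studentized range distribution) and a compact letter display in
#' which groups sharing a letter do not differ at `alpha`.
#'
#' @param haps a `haplotype_table`.
#' @param pheno named numeric vector (accession -> trait value; replicate
#'   tables should be reduced to per-accession means first, see
#'   [phenotype_means]).
#' @param min_group minimum group size.
#' @param alpha significance level for the letter display.
#' @return list: `testable`, `method`, `statistic`, `p`, `pairwise`
#'   (matrix of Nemenyi P values or NULL), `letters` (named per group),
#'   `group_stats`.
#' @export
haplotype_phenotype_test <- function(haps, pheno, min_group = 10L,
                                     alpha = 0.05) {
  acc <- intersect(names(haps$assignment), names(pheno))
  acc <- acc[!is.na(pheno[acc])]
  g <- haps$assignment[acc]
  sizes <- table(g)
  eligible <- names(sizes)[sizes >= min_group]
  keep <- g %in% eligible
  g <- factor(g[keep]); y <- pheno[acc][keep]
  if (length(eligible) < 2)
    return(list(testable = FALSE, method = NA_character_,
                statistic = NA_real_, p = NA_real_, pairwise = NULL,
                letters = NULL, group_stats = NULL))
  stats_df <- data.frame(hap = levels(g),
                         n = as.integer(table(g)),
                         mean = as.numeric(tapply(y, g, mean)),
                         median = as.numeric(tapply(y, g, stats::median)))
  if (stats::var(y) == 0) {   # constant phenotype: no evidence at all
    return(list(testable = TRUE,
                method = if (nlevels(g) == 2) "wilcoxon"
                         else "kruskal_nemenyi",
                statistic = 0, p = 1, pairwise = NULL,
                letters = stats::setNames(rep("a", nlevels(g)), levels(g)),
                group_stats = stats_df))
  }
  if (nlevels(g) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(y ~ g, exact = FALSE))
    sig <- !is.na(wt$p.value) && wt$p.value <= alpha
    letters <- stats::setNames(if (sig) c("a", "b") else c("a", "a"),
                               levels(g))
    return(list(testable = TRUE, method = "wilcoxon",
                statistic = unname(wt$statistic), p = wt$p.value,
                pairwise = NULL, letters = letters,
                group_stats = stats_df))
  }
  kw <- stats::kruskal.test(y, g)
  pw <- nemenyi_pairwise(y, g)
  letters <- compact_letters(pw, order(-stats_df$mean), levels(g), alpha)
  list(testable = TRUE, method = "kruskal_nemenyi",
       statistic = unname(kw$statistic), p = kw$p.value, pairwise = pw,
       letters = letters, group_stats = stats_df)
}

#' All-pairs Nemenyi post-hoc P values
#'
#' Mean ranks over the pooled sample are compared with the Studentized
#' range statistic `q = |Rbar_i - Rbar_j| / sqrt(N(N+1)/12 (1/n_i + 1/n_j))`
#' referred to `ptukey(q * sqrt(2), k, Inf)` (ties corrected through the
#' pooled rank variance).
#'
#' @param y numeric response.
#' @param g grouping factor (k >= 3 levels).
#' @return symmetric matrix of P values.
#' @export
nemenyi_pairwise <- function(y, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  N <- length(y)
  r <- rank(y)
  rbar <- tapply(r, g, mean)
  n <- table(g)
  # sample variance of the pooled ranks equals N(N+1)/12 without ties and
  # carries the tie correction automatically
  sig2 <- stats::var(r)
  p <- matrix(1, k, k, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(sig2 * (1 / n[i] + 1 / n[j]))
      q <- abs(rbar[i] - rbar[j]) / se * sqrt(2)
      p[i, j] <- p[j, i] <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
    }
  }
  p
}

#' Compact letter display from a pairwise P matrix
#'
#' Groups are swept in the given order (typically by descending mean);
#' maximal runs whose members are pairwise non-significant share a letter.
#'
#' @param pmat symmetric pairwise P matrix.
#' @param ord integer order of the groups for the sweep.
#' @param labels group labels.
#' @param alpha significance level.
#' @return named character vector of letter strings.
#' @export
compact_letters <- function(pmat, ord, labels, alpha = 0.05) {
  k <- length(labels)
  runs <- list()
  for (i in seq_len(k)) {   # maximal non-significant run starting at each i
    j <- i
    while (j < k) {
      block <- ord[i:(j + 1)]
      ok <- all(pmat[block, block][upper.tri(diag(length(block)))] > alpha)
      if (ok) j <- j + 1 else break
    }
    runs[[length(runs) + 1L]] <- ord[i:j]
  }
  runs <- unique(lapply(runs, sort))
  # drop runs strictly contained in another
  keep <- vapply(seq_along(runs), function(a) {
    !any(vapply(seq_along(runs), function(b) {
      a != b && all(runs[[a]] %in% runs[[b]])
    }, logical(1)))
  }, logical(1))
  runs <- runs[keep]
  letters_vec <- stats::setNames(rep("", k), labels)
  for (ri in seq_along(runs)) {
    letters_vec[runs[[ri]]] <- paste0(letters_vec[runs[[ri]]],
                                      letters[ri])
  }
  letters_vec
}

#' Reduce replicated phenotypes to per-accession means
#'
#' @param df data frame with `accession` and a numeric `value` column (and
#'   optionally replicate metadata, ignored).
#' @param trait name of the value column.
#' @return named numeric vector.
#' @export
phenotype_means <- function(df, trait = "value") {
  m <- tapply(df[[trait]], df$accession, mean, na.rm = TRUE)
  stats::setNames(as.numeric(m), names(m))
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test per term: with universe size M, term size
#' K, gene-set size n and overlap k, `P = P(X >= k)`; Benjamini-Hochberg
#' adjustment across terms; enriched iff adjusted P <= `alpha`.
#'
#' @param gene_set character vector (subset of `universe`).
#' @param term_map data frame `gene_id`, `term`.
#' @param universe character vector of all genes.
#' @param alpha adjusted-P threshold.
#' @return data frame per term: `term`, `k`, `K`, `n`, `M`, `p`, `p_adj`,
#'   `enriched`.
#' @export
hypergeometric_enrichment <- function(gene_set, term_map, universe,
                                      alpha = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of universe")
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  M <- length(unique(universe))
  n <- length(unique(gene_set))
  terms <- unique(tm$term)
  out <- lapply(terms, function(t) {
    tg <- unique(tm$gene_id[tm$term == t])
    K <- length(tg)
    k <- length(intersect(tg, gene_set))
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, K = K, n = n, M = M, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_adj <- stats::p.adjust(res$p, "BH")
  res$enriched <- res$p_adj <= alpha
  res[order(res$p), , drop = FALSE]
}
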