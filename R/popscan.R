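#' Sliding windows over chromosomes
#'
#' Windows start at 0 and advance by `step`; only fully contained windows
#' are produced, so a chromosome of length `len` yields
#' `floor((len - window) / step) + 1` windows.
#'
#' @param chrom_lengths named lengths.
#' @param window,step sizes in bp.
#' @return interval data frame.
#' @keywords internal
make_windows <- function(chrom_lengths, window, step) {
  out <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    if (len < window) return(NULL)
    starts <- seq(0L, len - window, by = step)
    data.frame(chrom = cn, start = as.integer(starts),
               end = as.integer(starts + window))
  })
  do.call(rbind, out)
}

window_track <- function(windows, value, statistic, chrom_lengths) {
  tr <- cbind(windows, value = value)
  attr(tr, "statistic") <- statistic
  attr(tr, "chrom_lengths") <- chrom_lengths
  class(tr) <- c("window_track", "data.frame")
  tr
}

accessions_of <- function(gt, pop) {
  if (is.null(pop)) return(colnames(gt$dosage))
  if (all(pop %in% colnames(gt$dosage))) return(pop)
  if (is.null(gt$labels)) stop("genotype matrix carries no population labels")
  acc <- names(gt$labels)[gt$labels %in% pop]
  if (length(acc) == 0) stop("unknown population label: ",
                             paste(pop, collapse = ","))
  acc
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site heterozygosity `h = 2 c (n - c) / (n (n - 1))` from the ALT
#' allele count `c` and called allele count `n`, summed over the sites in
#' each window and divided by the window length in bp (sites with fewer
#' than two called alleles are skipped; windows with no usable site are
#' reported missing, and invariant windows are 0 where sites exist).
#'
#' @param gt a [genotype_matrix].
#' @param pop population label(s) or accession names; NULL = all.
#' @param chrom_lengths named chromosome lengths.
#' @param window,step window and step size in bp.
#' @return a `window_track` data frame (`chrom`, `start`, `end`, `value`).
#' @export
windowed_pi <- function(gt, pop = NULL, chrom_lengths,
                        window = 20000L, step = 2000L) {
  acc <- accessions_of(gt, pop)
  ac <- allele_counts(gt, acc)
  usable <- ac$n >= 2
  h <- ifelse(usable, 2 * ac$c * (ac$n - ac$c) / (ac$n * (ac$n - 1)), 0)
  win <- make_windows(chrom_lengths, window, step)
  val <- window_sums(win, gt$sites$chrom[usable], gt$sites$pos[usable],
                     h[usable])
  window_track(win, ifelse(val$n_sites > 0, val$sum / window, NA_real_),
               "pi", chrom_lengths)
}

## sum of per-site values and site counts per window
#' @keywords internal
window_sums <- function(win, chrom, pos, value) {
  s <- numeric(nrow(win)); n <- integer(nrow(win))
  for (cn in unique(win$chrom)) {
    wi <- which(win$chrom == cn)
    si <- which(chrom == cn)
    if (length(si) == 0) next
    o <- order(pos[si])
    p <- pos[si][o]; v <- value[si][o]
    cs <- c(0, cumsum(v))
    lo <- findInterval(win$start[wi] - 0.5, p) # sites with pos >= start
    hi <- findInterval(win$end[wi] - 0.5, p)   # sites with pos < end
    s[wi] <- cs[hi + 1] - cs[lo + 1]
    n[wi] <- hi - lo
  }
  list(sum = s, n_sites = n)
}

#' Windowed Weir-Cockerham FST
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) of the Weir-Cockerham
#' (1984) estimator for two populations of diploid genotypes; the window
#' value is the weighted estimator `sum(a) / sum(a + b + c)` over the sites
#' in the window. Sites monomorphic across both populations, or with fewer
#' than two called allele copies in either population, are skipped.
#'
#' @param gt a [genotype_matrix].
#' @param popA,popB population labels or accession vectors.
#' @param chrom_lengths named chromosome lengths.
#' @param window,step window and step in bp.
#' @return a `window_track`.
#' @export
windowed_fst <- function(gt, popA, popB, chrom_lengths,
                         window = 20000L, step = 2000L) {
  comp <- fst_site_components(gt, popA, popB)
  win <- make_windows(chrom_lengths, window, step)
  keep <- comp$usable
  num <- window_sums(win, gt$sites$chrom[keep], gt$sites$pos[keep],
                     comp$a[keep])
  den <- window_sums(win, gt$sites$chrom[keep], gt$sites$pos[keep],
                     (comp$a + comp$b + comp$c)[keep])
  val <- ifelse(num$n_sites > 0 & den$sum != 0, num$sum / den$sum, NA_real_)
  window_track(win, val, "fst", chrom_lengths)
}

#' Per-site Weir-Cockerham components for two populations
#'
#' @param gt a [genotype_matrix].
#' @param popA,popB population labels or accession vectors.
#' @return list of vectors `a`, `b`, `c` and logical `usable`.
#' @export
fst_site_components <- function(gt, popA, popB) {
  accA <- accessions_of(gt, popA); accB <- accessions_of(gt, popB)
  if (length(accA) == 0 || length(accB) == 0) stop("empty population")
  stat <- function(acc) {
    d <- gt$dosage[, acc, drop = FALSE]
    called <- !is.na(d)
    n <- rowSums(called)
    p <- ifelse(n > 0, rowSums(d, na.rm = TRUE) / (2 * n), NA_real_)
    het <- ifelse(n > 0, rowSums(d == 1L, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = het)
  }
  A <- stat(accA); B <- stat(accB)
  r <- 2
  nbar <- (A$n + B$n) / r
  usable <- A$n >= 1 & B$n >= 1 & nbar > 1
  n_c <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / n_c) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  usable <- usable & poly & !is.na(a)
  list(a = a, b = b, c = cc, usable = usable)
}

#' Ratio track of two diversity tracks
#'
#' Per-window `pi_wild / pi_cultivated`; the value is missing where the
#' denominator window is missing or zero (flagged rather than infinite).
#'
#' @param num,den `window_track`s on identical windows.
#' @return a `window_track` named `pi_ratio`.
#' @export
pi_ratio_track <- function(num, den) {
  stopifnot(nrow(num) == nrow(den),
            all(num$start == den$start), all(num$chrom == den$chrom))
  val <- ifelse(!is.na(den$value) & den$value > 0 & !is.na(num$value),
                num$value / den$value, NA_real_)
  window_track(num[c("chrom", "start", "end")], val, "pi_ratio",
               attr(num, "chrom_lengths"))
}

#' Smooth a window track
#'
#' Each output window's value is the mean of the input-window values whose
#' midpoints fall inside it; output windows containing no midpoint are
#' missing.
#'
#' @param track a `window_track`.
#' @param window,step smoothing window and step in bp.
#' @return a `window_track` named `<statistic>_smooth`.
#' @export
smooth_track <- function(track, window = 100000L, step = 10000L) {
  lens <- attr(track, "chrom_lengths")
  win <- make_windows(lens, window, step)
  mid <- (track$start + track$end) / 2
  ok <- !is.na(track$value)
  sums <- window_sums(win, track$chrom[ok], mid[ok], track$value[ok])
  val <- ifelse(sums$n_sites > 0, sums$sum / sums$n_sites, NA_real_)
  window_track(win, val,
               paste0(attr(track, "statistic") %||% "stat", "_smooth"), lens)
}

#' Select the top quantile of a track and merge into regions
#'
#' The threshold is the k-th largest non-missing value with
#' `k = max(1, floor(q * n))` (order-statistic quantile, no interpolation);
#' windows at or above it are selected and adjacent or overlapping selected
#' windows are merged into regions. On a constant track the threshold
#' equals the constant and every window is selected (degenerate case,
#' intentional).
#'
#' @param track a `window_track` with at least 20 non-missing windows.
#' @param q upper-tail fraction.
#' @return interval data frame of merged regions, with the threshold in
#'   `attr(, "threshold")`.
#' @export
top_quantile_regions <- function(track, q = 0.05) {
  v <- track$value
  ok <- !is.na(v)
  if (sum(ok) == 0) stop("all windows missing")
  if (sum(ok) < 20) stop("need at least 20 non-missing windows")
  k <- max(1L, floor(q * sum(ok)))
  thr <- sort(v[ok], decreasing = TRUE)[k]
  sel <- ok & v >= thr
  out <- interval_merge(track[sel, c("chrom", "start", "end")])
  attr(out, "threshold") <- thr
  out
}

#' Intersect selective-sweep evidence tracks
#'
#' Regions supported by every supplied interval set: base-pair intersection
#' across all sets, merged. Provenance (the names of the supporting sets)
#' is attached.
#'
#' @param tracks named list (length >= 2) of interval data frames.
#' @return a `sweep_set`: merged interval data frame with
#'   `attr(, "provenance")`.
#' @export
intersect_sweeps <- function(tracks) {
  stopifnot(length(tracks) >= 2)
  out <- interval_merge(tracks[[1]])
  for (i in 2:length(tracks)) out <- interval_intersect(out, tracks[[i]])
  out <- interval_merge(out)
  attr(out, "provenance") <- names(tracks) %||%
    paste0("track", seq_along(tracks))
  class(out) <- c("sweep_set", "data.frame")
  out
}

#' Linkage-disequilibrium decay
#'
#' Sites are filtered to minor allele frequency at least `maf_min` and
#' heterozygous-genotype fraction at most `het_max`; for every remaining
#' SNP pair within `max_dist` on the same chromosome, r-squared is the
#' squared Pearson correlation of genotype dosages (composite LD for
#' unphased data), averaged per distance bin.
#'
#' @param gt a [genotype_matrix].
#' @param max_dist maximum pair distance in bp.
#' @param maf_min,het_max site filters.
#' @param bin distance bin width in bp.
#' @return data frame: `dist_lo`, `dist_hi`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(gt, max_dist = 500000L, maf_min = 0.01, het_max = 0.8,
                     bin = 1000L) {
  ac <- allele_counts(gt)
  het <- rowMeans(gt$dosage == 1L, na.rm = TRUE)
  keep <- which(!is.na(ac$maf) & ac$maf >= maf_min &
                  (is.nan(het) | het <= het_max))
  if (length(keep) < 2)
    return(data.frame(dist_lo = integer(), dist_hi = integer(),
                      mean_r2 = numeric(), n_pairs = integer()))
  sites <- gt$sites[keep, , drop = FALSE]
  d <- gt$dosage[keep, , drop = FALSE]
  r2 <- list(); dist <- list()
  chunk <- 300L
  for (cn in unique(sites$chrom)) {
    idx <- which(sites$chrom == cn)
    idx <- idx[order(sites$pos[idx])]
    pos <- sites$pos[idx]
    n <- length(idx)
    lo <- 1L
    while (lo <= n) {
      hi <- min(lo + chunk - 1L, n)
      # every site reachable from the chunk within max_dist
      far <- hi
      while (far < n && pos[far + 1L] - pos[hi] <= max_dist) far <- far + 1L
      cm <- suppressWarnings(
        stats::cor(t(d[idx[lo:far], , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      dm <- abs(outer(pos[lo:far], pos[lo:far], "-"))
      sel <- upper.tri(cm) & dm <= max_dist & !is.na(cm) &
        row(cm) <= (hi - lo + 1L)   # left member inside the chunk
      r2[[length(r2) + 1L]] <- cm[sel]^2
      dist[[length(dist) + 1L]] <- dm[sel]
      lo <- hi + 1L
    }
  }
  r2 <- unlist(r2); dist <- unlist(dist)
  if (length(r2) == 0)
    return(data.frame(dist_lo = integer(), dist_hi = integer(),
                      mean_r2 = numeric(), n_pairs = integer()))
  b <- pmax(ceiling(dist / bin), 1)
  agg <- tapply(r2, b, mean)
  n <- tapply(r2, b, length)
  bi <- as.integer(names(agg))
  data.frame(dist_lo = (bi - 1L) * bin, dist_hi = bi * bin,
             mean_r2 = as.numeric(agg), n_pairs = as.integer(n))
}

FOURFOLD_PREFIX <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Extract fourfold-degenerate (4DTv) SNP sites
#'
#' Keeps SNPs at the third position of fourfold-degenerate codon families
#' (codons whose first two bases fix the amino acid), read strand-aware
#' from the reference genome. A SNP covered by several overlapping CDS is
#' kept only when it is fourfold-degenerate in all of them; genes whose CDS
#' length is not divisible by 3 are skipped with a warning.
#'
#' @param gt a [genotype_matrix] of SNPs.
#' @param genome reference `genome_assembly` with genes and exons.
#' @return the subset [genotype_matrix] at 4DTv sites.
#' @export
extract_4dtv <- function(gt, genome) {
  status <- new.env(parent = emptyenv())  # "chrom:pos" -> TRUE/FALSE
  for (gid in genome$genes$gene_id) {
    gi <- genome$genes[genome$genes$gene_id == gid, ]
    ex <- genome$exons[genome$exons$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds_pos <- unlist(lapply(seq_len(nrow(ex)), function(j) {
      seq(ex$start[j], ex$end[j] - 1L)
    }))
    if (length(cds_pos) %% 3 != 0) {
      warning("CDS length not divisible by 3, gene skipped: ", gid)
      next
    }
    cds <- cds_sequence(genome, gid)
    if (gi$strand == "-") cds_pos <- rev(cds_pos)
    codon_idx <- ceiling(seq_along(cds_pos) / 3)
    within <- (seq_along(cds_pos) - 1L) %% 3L
    prefixes <- vapply(seq_len(length(cds_pos) / 3), function(k) {
      substr(cds, 3 * k - 2, 3 * k - 1)
    }, character(1))
    is4d <- prefixes[codon_idx] %in% FOURFOLD_PREFIX & within == 2L
    keys <- paste0(gi$chrom, ":", cds_pos)
    for (k in seq_along(keys)) {
      prev <- status[[keys[k]]]
      status[[keys[k]]] <- if (is.null(prev)) is4d[k] else prev && is4d[k]
    }
  }
  snp_keys <- paste0(gt$sites$chrom, ":", gt$sites$pos)
  keep <- vapply(snp_keys, function(k) isTRUE(status[[k]]), logical(1))
  genotype_matrix(gt$sites[keep, , drop = FALSE],
                  gt$dosage[keep, , drop = FALSE], gt$labels)
}

#' PAV frequency shift between wild and cultivated populations
#'
#' Per PAV: presence frequency in each population (carriers / called) and a
#' two-sided Fisher exact test on the 2x2 table of called carrier and
#' non-carrier accessions, with Benjamini-Hochberg adjustment across PAVs.
#' PAVs with fewer than `min_called` called genotypes in either group are
#' flagged untested.
#'
#' @param pav a [genotype_matrix] of PAV genotypes (dosage 2 or 1 = carrier,
#'   0 = non-carrier, NA = missing).
#' @param wild,cultivated accession name vectors (or labels resolved via
#'   `pav$labels`).
#' @param alpha adjusted-P threshold.
#' @param min_called minimum called genotypes per group.
#' @return data frame per PAV: `freq_wild`, `freq_cultivated`, `p`, `p_adj`,
#'   `significant`, `tested`.
#' @export
pav_frequency_shift <- function(pav, wild, cultivated, alpha = 0.05,
                                min_called = 5L) {
  accW <- accessions_of(pav, wild)
  accC <- accessions_of(pav, cultivated)
  dW <- pav$dosage[, accW, drop = FALSE]
  dC <- pav$dosage[, accC, drop = FALSE]
  carW <- rowSums(dW > 0, na.rm = TRUE); calW <- rowSums(!is.na(dW))
  carC <- rowSums(dC > 0, na.rm = TRUE); calC <- rowSums(!is.na(dC))
  n <- nrow(pav$sites)
  res <- data.frame(freq_wild = ifelse(calW > 0, carW / calW, NA_real_),
                    freq_cultivated = ifelse(calC > 0, carC / calC, NA_real_),
                    p = NA_real_, p_adj = NA_real_, significant = FALSE,
                    tested = calW >= min_called & calC >= min_called)
  for (i in which(res$tested)) {
    tab <- matrix(c(carW[i], calW[i] - carW[i],
                    carC[i], calC[i] - carC[i]), nrow = 2)
    res$p[i] <- stats::fisher.test(tab)$p.value
  }
  res$p_adj[res$tested] <- stats::p.adjust(res$p[res$tested], "BH")
  res$significant <- res$tested & !is.na(res$p_adj) & res$p_adj <= alpha
  res
}
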