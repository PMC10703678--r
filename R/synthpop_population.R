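#' Simulate a structured diploid-coded population
#'
#' Emulates the statistical structure a resequencing panel of a selfing
#' crop presents to the downstream analyses: one wild population (W1) and
#' three cultivated subpopulations (C1-C3) of homozygous diploid calls.
#'
#' SNPs: wild allele frequencies are drawn from a U-shaped Beta(0.5, 0.5)
#' spectrum and the site count is calibrated so the expected per-site
#' heterozygosity over the genome matches `target_pi_wild`; cultivated
#' frequencies derive from the wild ones by Balding-Nichols drift with
#' `F = 1 - target_pi_cultivated / target_pi_wild`, which makes the
#' cultivated panel retain that diversity fraction in expectation. Inside
#' one designated sweep region the cultivated drift is strengthened so
#' cultivated diversity drops by `1 / sweep_pi_factor` (and differentiation
#' rises), giving a known ground-truth target for the composite scan.
#'
#' PAVs: presence frequencies are skewed low; `n_shifted_pav` of them are
#' set to contrasting wild/cultivated frequencies. Phenotypes are the sum
#' of causal-variant effects plus Gaussian noise scaled to the configured
#' heritability (heritability 1 means the phenotype equals the genetic
#' score exactly). FPKM values are log-normal per gene; accessions carrying
#' a PAV linked to a gene have that gene's FPKM multiplied by
#' `fpkm_pav_downshift`.
#'
#' @param config a [sim_config].
#' @return list: `snp` and `pav` ([genotype_matrix]s with labels),
#'   `labels`, `phenotype` (named vector), `fpkm` (genes x accessions),
#'   `truth` (sweep region, shifted PAV indices, causal table,
#'   PAV-to-gene map).
#' @export
simulate_population <- function(config) {
  if (config$n_wild + config$n_cultivated < 4)
    stop("need at least 4 accessions")
  if (config$heritability <= 0 || config$heritability > 1)
    stop("heritability must be in (0, 1]")
  lens <- stats::setNames(rep(config$chrom_length, config$n_chrom),
                          sprintf("chr%d", seq_len(config$n_chrom)))
  acc_w <- sprintf("W%03d", seq_len(config$n_wild))
  acc_c <- sprintf("C%03d", seq_len(config$n_cultivated))
  accs <- c(acc_w, acc_c)
  cult_pops <- paste0("C", rep_len(1:3, config$n_cultivated))
  labels <- stats::setNames(c(rep("W1", config$n_wild), cult_pops), accs)
  sweep_region <- data.frame(chrom = names(lens)[1],
                             start = as.integer(0.30 * lens[[1]]),
                             end = as.integer(0.40 * lens[[1]]))
  snp <- with_seed(config$seed, "population_snps",
                   simulate_snps(config, lens, accs, labels, sweep_region))
  pav <- with_seed(config$seed, "population_pavs",
                   simulate_pavs(config, lens, accs, labels))
  ph <- with_seed(config$seed, "phenotype",
                  simulate_phenotype(config, snp, pav$gt))
  fp <- with_seed(config$seed, "fpkm",
                  simulate_fpkm(config, pav$gt, accs))
  list(snp = snp, pav = pav$gt, labels = labels, phenotype = ph$phenotype,
       fpkm = fp$fpkm,
       truth = list(sweep_region = sweep_region,
                    shifted_pav = pav$shifted,
                    causal = ph$causal,
                    pav_gene_map = fp$map))
}

#' @keywords internal
simulate_snps <- function(config, lens, accs, labels, sweep_region) {
  L <- sum(lens)
  # calibrate the site count against the realized frequency draw
  n0 <- ceiling(config$target_pi_wild * L / 0.2)
  p_w <- stats::rbeta(n0, 0.5, 0.5)
  p_w <- pmin(pmax(p_w, 0.01), 0.99)
  cum <- cumsum(2 * p_w * (1 - p_w))
  n_sites <- min(n0, which(cum >= config$target_pi_wild * L)[1],
                 na.rm = TRUE)
  p_w <- p_w[seq_len(n_sites)]
  chrom <- sample(names(lens), n_sites, replace = TRUE,
                  prob = lens / sum(lens))
  pos <- vapply(chrom, function(cn) sample.int(lens[[cn]], 1) - 1L,
                integer(1))
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]; p_w <- p_w[o]
  F0 <- 1 - config$target_pi_cultivated / config$target_pi_wild
  in_sweep <- chrom == sweep_region$chrom & pos >= sweep_region$start &
    pos < sweep_region$end
  Fs <- ifelse(in_sweep, 1 - config$sweep_pi_factor * (1 - F0), F0)
  nu <- (1 - Fs) / Fs
  p_c <- stats::rbeta(n_sites, p_w * nu, (1 - p_w) * nu)
  is_wild <- labels[accs] == "W1"
  dos <- matrix(NA_integer_, n_sites, length(accs),
                dimnames = list(NULL, accs))
  for (a in seq_along(accs)) {
    p <- if (is_wild[a]) p_w else p_c
    hom_alt <- stats::runif(n_sites) < p
    g <- ifelse(hom_alt, 2L, 0L)
    if (config$het_rate > 0) {
      het <- stats::runif(n_sites) < config$het_rate
      g[het] <- 1L
    }
    g[stats::runif(n_sites) < config$missing_rate_snp] <- NA_integer_
    dos[, a] <- g
  }
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  genotype_matrix(
    data.frame(chrom = chrom, pos = pos,
               id = sprintf("snp%06d", seq_len(n_sites)), ref = ref,
               alt = alt, stringsAsFactors = FALSE),
    dos, labels)
}

#' @keywords internal
simulate_pavs <- function(config, lens, accs, labels) {
  n <- config$n_pav
  base_f <- stats::rbeta(n, 0.4, 2.4)
  f_w <- f_c <- base_f
  shifted <- integer(0)
  if (config$n_shifted_pav > 0) {
    shifted <- sample.int(n, min(config$n_shifted_pav, n))
    f_w[shifted] <- config$shift_freq_wild
    f_c[shifted] <- config$shift_freq_cultivated
  }
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  pos <- vapply(chrom, function(cn) sample.int(lens[[cn]], 1) - 1L,
                integer(1))
  o <- order(chrom, pos)
  remap <- match(seq_len(n), o)
  chrom <- chrom[o]; pos <- pos[o]; f_w <- f_w[o]; f_c <- f_c[o]
  shifted <- sort(remap[shifted])
  is_wild <- labels[accs] == "W1"
  dos <- matrix(NA_integer_, n, length(accs), dimnames = list(NULL, accs))
  for (a in seq_along(accs)) {
    f <- if (is_wild[a]) f_w else f_c
    g <- ifelse(stats::runif(n) < f, 2L, 0L)
    g[stats::runif(n) < config$missing_rate_pav] <- NA_integer_
    dos[, a] <- g
  }
  subtype <- sample(c("DEL", "INS"), n, replace = TRUE)
  gt <- genotype_matrix(
    data.frame(chrom = chrom, pos = pos,
               id = sprintf("pav%05d", seq_len(n)), ref = "N",
               alt = paste0("<", subtype, ">"), stringsAsFactors = FALSE),
    dos, labels)
  list(gt = gt, shifted = shifted)
}

#' @keywords internal
simulate_phenotype <- function(config, snp, pav) {
  pick <- function(gt, k, type) {
    if (k == 0 || nrow(gt$sites) == 0) return(NULL)
    ac <- allele_counts(gt)
    ok <- which(!is.na(ac$maf) & ac$maf >= 0.1)
    idx <- sample(ok, min(k, length(ok)))
    data.frame(type = type, index = idx,
               effect = stats::rnorm(length(idx), 0, 1))
  }
  causal <- rbind(pick(snp, config$n_causal_snp, "SNP"),
                  pick(pav, config$n_causal_pav, "PAV"))
  accs <- colnames(snp$dosage)
  g <- rep(0, length(accs))
  if (is.null(causal))
    causal <- data.frame(type = character(), index = integer(),
                         effect = numeric())
  for (i in seq_len(nrow(causal))) {
    d <- if (causal$type[i] == "SNP") snp$dosage[causal$index[i], accs]
         else pav$dosage[causal$index[i], accs]
    d[is.na(d)] <- 0L
    g <- g + causal$effect[i] * d
  }
  h2 <- config$heritability
  noise <- if (h2 == 1) rep(0, length(g)) else
    stats::rnorm(length(g), 0, sqrt(stats::var(g) * (1 - h2) / h2))
  list(phenotype = stats::setNames(g + noise, accs), causal = causal)
}

#' @keywords internal
simulate_fpkm <- function(config, pav, accs) {
  n_genes <- config$n_genes
  gene_ids <- sprintf("simgene%04d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, meanlog = 1.5, sdlog = 1)
  fpkm <- matrix(base, n_genes, length(accs),
                 dimnames = list(gene_ids, accs)) *
    matrix(stats::rlnorm(n_genes * length(accs), 0, 0.2), n_genes)
  n_linked <- min(50L, n_genes, nrow(pav$sites))
  map <- data.frame(pav_index = sample.int(nrow(pav$sites), n_linked),
                    gene_id = sample(gene_ids, n_linked))
  for (i in seq_len(nrow(map))) {
    carrier <- pav$dosage[map$pav_index[i], accs] > 0
    carrier[is.na(carrier)] <- FALSE
    fpkm[map$gene_id[i], carrier] <-
      fpkm[map$gene_id[i], carrier] * config$fpkm_pav_downshift
  }
  list(fpkm = fpkm, map = map)
}
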