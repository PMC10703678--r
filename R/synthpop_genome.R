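#' Simulation configuration
#'
#' One configuration object drives every synthetic input: the ancestral
#' genome, the per-accession derived assemblies and the structured
#' population. All randomness flows from `seed` through named sub-generators,
#' so adding one generator never perturbs the draws of another.
#'
#' Diversity targets default to the wild/cultivated nucleotide diversities of
#' a selfing crop panel (wild 6.7e-4, cultivated 4.2e-4 per site); SV counts
#' are per derived accession; `te_derived_fraction` is the fraction of
#' implanted insertions (and deletions) that are TE copies.
#'
#' @param seed master integer seed.
#' @param n_chrom,chrom_length chromosome count and length (bp).
#' @param n_genes,n_te genes and TE copies to place per genome.
#' @param n_te_templates size of the internal TE library (5-20).
#' @param n_gaps assembly gaps (N runs) per chromosome.
#' @param centromere_frac centromere length as a fraction of the chromosome.
#' @param sv_counts named integer vector of implanted events per accession
#'   (DEL, INS, INV, TDUP, CPX).
#' @param te_derived_fraction fraction of DEL/INS events that are TE-derived.
#' @param n_wild,n_cultivated population sizes.
#' @param target_pi_wild,target_pi_cultivated per-site diversity targets.
#' @param heritability trait heritability in (0, 1].
#' @param fpkm_pav_downshift multiplicative FPKM shift for PAV carriers.
#' @param het_rate probability of a heterozygous call (selfing default 0).
#' @param n_pav population PAV count; `n_shifted_pav` of them get their
#'   presence frequency set to `shift_freq_wild` in the wild and
#'   `shift_freq_cultivated` in the cultivated population.
#' @param n_shifted_pav,shift_freq_wild,shift_freq_cultivated see `n_pav`.
#' @param n_causal_snp,n_causal_pav causal variants behind the simulated
#'   trait.
#' @param missing_rate_snp,missing_rate_pav genotype missingness.
#' @param sweep_pi_factor residual fraction of cultivated diversity inside
#'   the simulated sweep region (0.2 = 5-fold reduction).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length = 1000000L,
                       n_genes = 100L, n_te = 200L,
                       n_te_templates = 10L, n_gaps = 2L,
                       centromere_frac = 0.08,
                       sv_counts = c(DEL = 15L, INS = 15L, INV = 3L,
                                     TDUP = 4L, CPX = 3L),
                       te_derived_fraction = 0.68,
                       n_wild = 30L, n_cultivated = 200L,
                       target_pi_wild = 0.00067,
                       target_pi_cultivated = 0.00042,
                       heritability = 0.5,
                       fpkm_pav_downshift = 0.3,
                       het_rate = 0,
                       n_pav = 300L, n_shifted_pav = 40L,
                       shift_freq_wild = 0.1,
                       shift_freq_cultivated = 0.7,
                       n_causal_snp = 3L, n_causal_pav = 2L,
                       missing_rate_snp = 0.02, missing_rate_pav = 0.05,
                       sweep_pi_factor = 0.2) {
  if (heritability <= 0 || heritability > 1)
    stop("heritability must be in (0, 1]")
  if (te_derived_fraction < 0 || te_derived_fraction > 1)
    stop("te_derived_fraction must be in [0, 1]")
  if (any(sv_counts < 0)) stop("sv_counts must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

rand_dna <- function(n, gc = 0.46) {
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

mutate_seq <- function(s, divergence) {
  v <- strsplit(s, "")[[1]]
  k <- rbinom(1, length(v), divergence)
  if (k > 0) {
    idx <- sample(length(v), k)
    v[idx] <- vapply(v[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(v, collapse = "")
}

## Non-overlapping placement outside forbidden zones. Features (plus a
## trailing margin) are first-fit packed into the free segments in random
## order, then positioned by distributing each segment's slack uniformly at
## random among the inter-feature gaps; errors out when the requested density
## cannot be packed.
place_intervals <- function(chrom_len, lengths, forbidden, margin = 100L,
                            what = "feature") {
  n <- length(lengths)
  if (n == 0) return(integer(0))
  free <- interval_subtract(data.frame(chrom = "x", start = 0L,
                                       end = chrom_len), forbidden)
  eff <- lengths + margin
  if (sum(eff) > sum(free$end - free$start))
    stop("capacity: requested ", what, " density (", sum(eff),
         " bp) exceeds free chromosome capacity (",
         sum(free$end - free$start), " bp)")
  ord <- sample.int(n)
  segs <- free[sample.int(nrow(free)), , drop = FALSE]
  assign_seg <- rep(NA_integer_, n)
  cap <- segs$end - segs$start
  for (i in ord) {
    j <- which(cap >= eff[i])
    if (length(j) == 0)
      stop("capacity: could not place ", what, " of length ", lengths[i],
           " on chromosome of length ", chrom_len)
    j <- j[1]
    assign_seg[i] <- j
    cap[j] <- cap[j] - eff[i]
  }
  out <- integer(n)
  for (j in seq_len(nrow(segs))) {
    members <- which(assign_seg == j)
    if (length(members) == 0) next
    members <- members[sample.int(length(members))]
    slack <- (segs$end[j] - segs$start[j]) - sum(eff[members])
    # split slack into k+1 random gaps
    cuts <- sort(sample.int(slack + 1L, length(members),
                            replace = TRUE) - 1L)
    pos <- segs$start[j] + cuts + cumsum(c(0L, eff[members][-length(members)]))
    out[members] <- pos
  }
  out
}

#' Generate a TE template library
#'
#' 5-20 template sequences; copies placed in genomes diverge from their
#' template by 1-5%, so TE-derived insertions from the same template share
#' well over 80% identity (exercising the insertion merge rule) while
#' unrelated insertions are random sequence.
#'
#' @param config a [sim_config].
#' @return data frame: `template_id`, `te_class`, `seq`.
#' @export
te_library <- function(config) {
  with_seed(config$seed, "te_library", {
    n <- config$n_te_templates
    stopifnot(n >= 5, n <= 20)
    cls <- rep(c("LTR", "DNA"), length.out = n)
    len <- ifelse(cls == "LTR", sample(1500:4000, n, replace = TRUE),
                  sample(300:1200, n, replace = TRUE))
    data.frame(template_id = sprintf("TE%02d", seq_len(n)), te_class = cls,
               seq = vapply(len, rand_dna, character(1)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate the ancestral (reference) genome
#'
#' Builds a genome with the configured numbers of genes and TE copies, one
#' centromere interval per chromosome and `n_gaps` N-runs per chromosome.
#' Deterministic for a fixed seed. Genes carry 3-6 CDS exons whose total
#' length is divisible by 3.
#'
#' @param config a [sim_config].
#' @return a [genome_assembly] with `attr(, "te_library")` attached.
#' @export
simulate_ancestral_genome <- function(config) {
  lib <- te_library(config)
  with_seed(config$seed, "ancestral_genome", {
    L <- config$chrom_length
    chroms <- character(config$n_chrom)
    te <- list(); genes <- list(); exons <- list()
    gaps <- list(); cens <- list()
    genes_per <- diff(round(seq(0, config$n_genes,
                                length.out = config$n_chrom + 1)))
    te_per <- diff(round(seq(0, config$n_te,
                             length.out = config$n_chrom + 1)))
    for (ci in seq_len(config$n_chrom)) {
      cname <- sprintf("chr%d", ci)
      seqv <- strsplit(rand_dna(L), "")[[1]]
      # centromere in the middle of the chromosome
      cen_len <- round(L * config$centromere_frac)
      cen_start <- as.integer((L - cen_len) %/% 2)
      cens[[ci]] <- data.frame(chrom = cname, start = cen_start,
                               end = cen_start + cen_len)
      forbidden <- data.frame(chrom = "x", start = cen_start,
                              end = cen_start + cen_len)
      # assembly gaps: N runs
      if (config$n_gaps > 0) {
        glen <- sample(500:3000, config$n_gaps, replace = TRUE)
        gstart <- place_intervals(L, glen, forbidden, margin = 5000L,
                                  what = "gap")
        for (k in seq_len(config$n_gaps))
          seqv[(gstart[k] + 1):(gstart[k] + glen[k])] <- "N"
        gaps[[ci]] <- data.frame(chrom = cname, start = gstart,
                                 end = gstart + glen)
        forbidden <- rbind(forbidden,
                           data.frame(chrom = "x", start = gstart,
                                      end = gstart + glen))
      } else gaps[[ci]] <- empty_intervals()
      # TE copies: template with 1-5% divergence, written into the sequence
      if (te_per[ci] > 0) {
        pick <- sample(nrow(lib), te_per[ci], replace = TRUE)
        tlen <- nchar(lib$seq[pick])
        tstart <- place_intervals(L, tlen, forbidden, margin = 50L,
                                  what = "TE")
        for (k in seq_len(te_per[ci])) {
          copy <- mutate_seq(lib$seq[pick[k]], runif(1, 0.01, 0.05))
          seqv[(tstart[k] + 1):(tstart[k] + tlen[k])] <-
            strsplit(copy, "")[[1]]
        }
        te[[ci]] <- data.frame(chrom = cname, start = tstart,
                               end = tstart + tlen,
                               te_class = lib$te_class[pick],
                               template_id = lib$template_id[pick],
                               stringsAsFactors = FALSE)
        forbidden <- rbind(forbidden,
                           data.frame(chrom = "x", start = tstart,
                                      end = tstart + tlen))
      } else te[[ci]] <- NULL
      # genes outside TEs/gaps/centromere; reserve room for introns so the
      # realized gene span never exceeds its allocation
      if (genes_per[ci] > 0) {
        glen2 <- sample(seq(1200, 3600, by = 3), genes_per[ci],
                        replace = TRUE)
        gstart2 <- place_intervals(L, glen2 + 2000L, forbidden,
                                   margin = 2100L, what = "gene")
        for (k in seq_len(genes_per[ci])) {
          gid <- sprintf("gene_%s_%03d", cname, k)
          n_ex <- sample(3:6, 1)
          # split the CDS into n_ex chunks, each a multiple of 3
          codons <- glen2[k] / 3
          cuts <- sort(sample(seq_len(codons - 1), n_ex - 1))
          clen <- diff(c(0, cuts, codons)) * 3
          intr <- sample(60:400, n_ex - 1, replace = TRUE)
          starts <- gstart2[k] + cumsum(c(0, clen[-n_ex] + intr))
          genes[[length(genes) + 1]] <- data.frame(
            gene_id = gid, chrom = cname,
            strand = sample(c("+", "-"), 1),
            start = gstart2[k], end = starts[n_ex] + clen[n_ex],
            stringsAsFactors = FALSE)
          exons[[length(exons) + 1]] <- data.frame(
            gene_id = gid, start = starts, end = starts + clen)
        }
      }
      chroms[ci] <- paste(seqv, collapse = "")
    }
    gbind <- function(x) if (length(x)) do.call(rbind, x) else NULL
    g <- genome_assembly(
      accession_id = "ancestral",
      chromosomes = stats::setNames(chroms,
                                    sprintf("chr%d", seq_len(config$n_chrom))),
      genes = gbind(genes), exons = gbind(exons), te = gbind(te),
      gaps = gbind(gaps), centromeres = gbind(cens))
    attr(g, "te_library") <- lib
    g
  })
}
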