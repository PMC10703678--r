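#' Classify a PAV as TE-derived or non-TE
#'
#' A PAV is TE-derived when at least `threshold` of its footprint is covered
#' by TE sequence; covered bases are counted after taking the union of the
#' (possibly overlapping) TE intervals. The footprint of a deletion is its
#' reference interval; for an insertion the caller supplies the TE
#' annotation of the inserted sequence itself (coordinates on the inserted
#' sequence, via [annotate_insertion_te]) or a donor interval.
#'
#' @param pav single-row record with `chrom`, `start`, `end` (footprint).
#' @param te_intervals data frame `chrom`, `start`, `end`, `te_class`.
#' @param threshold covered fraction at or above which the PAV is TE-derived
#'   (inclusive).
#' @return list with `te_status` ("TE-derived"/"non-TE"), `te_fraction` and
#'   `te_class` (majority class, NA when non-TE).
#' @export
classify_te <- function(pav, te_intervals, threshold = 0.90) {
  len <- pav$end - pav$start
  if (len <= 0) stop("integrity: zero-length PAV footprint")
  fp <- data.frame(chrom = pav$chrom, start = pav$start, end = pav$end)
  te <- te_intervals[te_intervals$chrom == pav$chrom, , drop = FALSE]
  covered <- interval_intersect(fp, te)
  frac <- interval_bases(covered) / len
  cls <- NA_character_
  if (frac >= threshold && nrow(te) > 0 && "te_class" %in% names(te)) {
    by_cls <- vapply(unique(te$te_class), function(k) {
      interval_bases(interval_intersect(fp, te[te$te_class == k, ,
                                               drop = FALSE]))
    }, numeric(1))
    cls <- names(by_cls)[which.max(by_cls)]
  }
  list(te_status = if (frac >= threshold) "TE-derived" else "non-TE",
       te_fraction = frac, te_class = cls)
}

#' Annotate an inserted sequence against the TE library
#'
#' Scores the inserted sequence against every library template with global
#' edit-distance identity; bases are attributed to the best template when
#' its identity passes `min_identity`, giving a footprint-style TE interval
#' on the insertion's own coordinates.
#'
#' @param seq inserted sequence (character).
#' @param lib TE library data frame (`template_id`, `te_class`, `seq`).
#' @param min_identity identity floor for calling the insertion a TE copy.
#' @return TE interval data frame on the insertion coordinate system
#'   (`chrom = "ins"`), empty when no template matches.
#' @export
annotate_insertion_te <- function(seq, lib, min_identity = 0.8) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    te_class = character(), stringsAsFactors = FALSE)
  if (nchar(seq) == 0 || nrow(lib) == 0) return(out)
  # cheap length pre-filter before the quadratic edit distance
  plausible <- which(abs(nchar(lib$seq) - nchar(seq)) / nchar(seq) < 0.5)
  if (length(plausible) == 0) return(out)
  ident <- vapply(plausible, function(i) seq_identity(seq, lib$seq[i]),
                  numeric(1))
  best <- which.max(ident)
  if (ident[best] < min_identity) return(out)
  data.frame(chrom = "ins", start = 0L, end = nchar(seq),
             te_class = lib$te_class[plausible[best]],
             stringsAsFactors = FALSE)
}

#' Genic context of a PAV
#'
#' One context per PAV with precedence coding > intron > upstream2kb >
#' downstream2kb > intergenic. Upstream/downstream 2-kb windows are
#' strand-aware (upstream of a minus-strand gene lies to the right of its
#' end). Distance is the gap between the PAV and the nearest gene body
#' (0 when touching or overlapping).
#'
#' @param pav single-row record with `chrom`, `start`, `end` (insertions:
#'   `start == end` junction is treated as a 1-bp footprint).
#' @param genes gene table (`gene_id`, `chrom`, `strand`, `start`, `end`).
#' @param exons exon table (`gene_id`, `start`, `end`).
#' @param flank flank size in bp.
#' @return list with `context`, `nearest_gene_id`, `distance`.
#' @export
genic_context <- function(pav, genes, exons, flank = 2000L) {
  fp <- data.frame(chrom = pav$chrom, start = pav$start,
                   end = max(pav$end, pav$start + 1L))
  g <- genes[genes$chrom == pav$chrom, , drop = FALSE]
  res <- list(context = "intergenic", nearest_gene_id = NA_character_,
              distance = NA_real_)
  if (nrow(genes) > 0) {
    cl <- interval_closest(fp, genes[c("chrom", "start", "end")])
    if (!is.na(cl$index[1])) {
      res$nearest_gene_id <- genes$gene_id[cl$index[1]]
      res$distance <- cl$distance[1]
    }
  }
  if (nrow(g) == 0) return(res)
  hit_gene <- interval_overlaps_any(fp, g[c("chrom", "start", "end")])
  if (hit_gene) {
    gid <- g$gene_id[which(interval_overlaps_any(
      g[c("chrom", "start", "end")], fp))]
    ex <- exons[exons$gene_id %in% gid, , drop = FALSE]
    ex$chrom <- pav$chrom
    in_exon <- nrow(ex) > 0 &&
      any(interval_overlaps_any(fp, ex[c("chrom", "start", "end")]))
    res$context <- if (in_exon) "coding" else "intron"
    res$nearest_gene_id <- gid[1]
    res$distance <- 0
    return(res)
  }
  up <- data.frame(chrom = g$chrom,
                   start = ifelse(g$strand == "+", g$start - flank, g$end),
                   end = ifelse(g$strand == "+", g$start, g$end + flank))
  up$start <- pmax(up$start, 0L)
  down <- data.frame(chrom = g$chrom,
                     start = ifelse(g$strand == "+", g$end,
                                    g$start - flank),
                     end = ifelse(g$strand == "+", g$end + flank, g$start))
  down$start <- pmax(down$start, 0L)
  hit_up <- interval_overlaps_any(up, fp)
  hit_down <- interval_overlaps_any(down, fp)
  if (any(hit_up)) {
    res$context <- "upstream2kb"
    res$nearest_gene_id <- g$gene_id[which(hit_up)[1]]
  } else if (any(hit_down)) {
    res$context <- "downstream2kb"
    res$nearest_gene_id <- g$gene_id[which(hit_down)[1]]
  }
  res
}

#' Annotate a PAV cluster set
#'
#' Applies [classify_te] and [genic_context] to every DEL/INS cluster.
#' Deletion footprints are taken on the reference; insertion TE content is
#' measured on the inserted sequence against the TE library when supplied.
#'
#' @param clusters a `pav_cluster_set`.
#' @param genome reference `genome_assembly` (genes, exons, TEs).
#' @param te_lib optional TE library for insertion self-annotation.
#' @param te_threshold TE-derived threshold.
#' @return data frame, one row per cluster: `cluster_id`, `subtype`,
#'   `te_status`, `te_class`, `te_fraction`, `context`, `nearest_gene_id`,
#'   `distance_to_gene`.
#' @export
annotate_pavs <- function(clusters, genome, te_lib = NULL,
                          te_threshold = 0.90) {
  cl <- clusters$clusters
  cl <- cl[cl$subtype %in% c("DEL", "INS"), , drop = FALSE]
  out <- vector("list", nrow(cl))
  for (i in seq_len(nrow(cl))) {
    if (cl$subtype[i] == "DEL") {
      te <- classify_te(list(chrom = cl$chrom[i], start = cl$start[i],
                             end = cl$end[i]),
                        genome$te, threshold = te_threshold)
    } else {
      ins_len <- nchar(cl$seq[i])
      ann <- if (!is.null(te_lib))
        annotate_insertion_te(cl$seq[i], te_lib) else
          data.frame(chrom = character(), start = integer(),
                     end = integer(), te_class = character())
      te <- classify_te(list(chrom = "ins", start = 0L, end = ins_len),
                        ann, threshold = te_threshold)
    }
    ctx <- genic_context(list(chrom = cl$chrom[i], start = cl$start[i],
                              end = cl$end[i]),
                         genome$genes, genome$exons)
    out[[i]] <- data.frame(
      cluster_id = cl$cluster_id[i], subtype = cl$subtype[i],
      te_status = te$te_status, te_class = te$te_class,
      te_fraction = te$te_fraction, context = ctx$context,
      nearest_gene_id = ctx$nearest_gene_id,
      distance_to_gene = ctx$distance, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene loss and pseudogenization from PAV footprints
#'
#' Operator definition: a gene is `lost` when the supplied deletions jointly
#' cover 100% of its CDS bases; `pseudogenized` when, short of loss, carried
#' PAVs delete at least one complete exon, change the CDS length by an
#' amount not divisible by 3, or remove the start or stop codon; otherwise
#' `intact`. Insertions landing inside CDS disrupt the frame by their
#' length.
#'
#' @param pavs data frame of PAV footprints (`subtype`, `chrom`, `start`,
#'   `end`, `seq`) carried by the assembly under scrutiny.
#' @param genome reference `genome_assembly`.
#' @return data frame: `gene_id`, `status`, `causal` (semicolon-joined row
#'   indices of causal PAVs; empty for intact genes).
#' @export
gene_impact <- function(pavs, genome) {
  genes <- genome$genes
  out <- vector("list", nrow(genes))
  pav_iv <- data.frame(chrom = pavs$chrom, start = pavs$start,
                       end = pmax(pavs$end, pavs$start + 1L))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    ex <- genome$exons[genome$exons$gene_id == gid, , drop = FALSE]
    if (nrow(ex) == 0) {
      warning("gene without CDS skipped: ", gid)
      next
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    ex$chrom <- genes$chrom[i]
    touches <- which(pav_iv$chrom == genes$chrom[i] &
                       pav_iv$start < genes$end[i] &
                       pav_iv$end > genes$start[i])
    status <- "intact"
    causal <- integer(0)
    if (length(touches) > 0) {
      p <- pavs[touches, , drop = FALSE]
      dels <- p[p$subtype == "DEL", , drop = FALSE]
      cds_bp <- sum(ex$end - ex$start)
      del_cov <- 0
      if (nrow(dels) > 0) {
        del_iv <- data.frame(chrom = ex$chrom[1], start = dels$start,
                             end = dels$end)
        del_cov <- interval_bases(
          interval_intersect(ex[c("chrom", "start", "end")], del_iv))
      }
      if (del_cov == cds_bp) {
        status <- "lost"
        causal <- touches[p$subtype == "DEL"]
      } else {
        # exon-level deletion, frame disruption, start/stop removal
        exon_deleted <- FALSE
        if (nrow(dels) > 0) {
          for (j in seq_len(nrow(ex))) {
            if (any(dels$start <= ex$start[j] & dels$end >= ex$end[j])) {
              exon_deleted <- TRUE; break
            }
          }
        }
        del_cds <- del_cov
        ins_in_cds <- p$subtype == "INS" &
          interval_overlaps_any(
            data.frame(chrom = ex$chrom[1], start = p$start,
                       end = pmax(p$end, p$start + 1L)),
            ex[c("chrom", "start", "end")])
        ins_len <- sum(nchar(p$seq[ins_in_cds]))
        frame_shift <- ((del_cds + ins_len) %% 3) != 0
        strand <- genes$strand[i]
        start_codon <- if (strand == "+")
          c(ex$start[1], ex$start[1] + 3L) else c(ex$end[nrow(ex)] - 3L,
                                                  ex$end[nrow(ex)])
        stop_codon <- if (strand == "+")
          c(ex$end[nrow(ex)] - 3L, ex$end[nrow(ex)]) else
            c(ex$start[1], ex$start[1] + 3L)
        codon_hit <- nrow(dels) > 0 &&
          (any(dels$start < start_codon[2] & dels$end > start_codon[1]) ||
             any(dels$start < stop_codon[2] & dels$end > stop_codon[1]))
        disrupted <- exon_deleted || (del_cds + ins_len > 0 && frame_shift) ||
          codon_hit
        if (disrupted) {
          status <- "pseudogenized"
          causal <- touches
        }
      }
    }
    out[[i]] <- data.frame(gene_id = gid, status = status,
                           causal = paste(causal, collapse = ";"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expression impact of PAVs on their genes
#'
#' For each gene with an associated PAV, compares FPKM between carrier and
#' non-carrier accessions: fold change uses a 0.1 pseudo-count on group
#' means, significance is a two-sided Wilcoxon rank-sum test with
#' Benjamini-Hochberg adjustment across genes, and a gene is called
#' significant when the adjusted P is at most `alpha` and the fold change
#' is at least `fc_min` or at most `1/fc_min`. Genes with fewer than
#' `min_group` accessions on either side are flagged untested. FPKM below 1
#' defines a silenced gene.
#'
#' @param fpkm numeric matrix, genes x accessions.
#' @param carrier logical matrix (same dim or gene-named rows over the same
#'   accessions): TRUE where the accession carries a PAV linked to the gene.
#' @param fc_min fold-change threshold (>= 1).
#' @param alpha adjusted-P threshold.
#' @param min_group minimum accessions per group.
#' @return data frame per gene: group means, `fold_change`, `p`, `p_adj`,
#'   `significant`, `silenced_carriers`, `silenced_noncarriers`, `tested`.
#' @export
expression_impact <- function(fpkm, carrier, fc_min = 1.5, alpha = 0.05,
                              min_group = 3L) {
  stopifnot(identical(dim(fpkm), dim(carrier)))
  n <- nrow(fpkm)
  res <- data.frame(gene_id = rownames(fpkm) %||% as.character(seq_len(n)),
                    mean_carrier = NA_real_, mean_noncarrier = NA_real_,
                    fold_change = NA_real_, p = NA_real_,
                    p_adj = NA_real_, significant = FALSE,
                    silenced_carriers = NA_real_,
                    silenced_noncarriers = NA_real_, tested = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    x <- fpkm[i, carrier[i, ]]
    y <- fpkm[i, !carrier[i, ]]
    res$silenced_carriers[i] <- mean(x < 1)
    res$silenced_noncarriers[i] <- mean(y < 1)
    res$mean_carrier[i] <- mean(x)
    res$mean_noncarrier[i] <- mean(y)
    res$fold_change[i] <- (mean(x) + 0.1) / (mean(y) + 0.1)
    if (length(x) < min_group || length(y) < min_group) next
    res$tested[i] <- TRUE
    res$p[i] <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
  res$p_adj[res$tested] <- stats::p.adjust(res$p[res$tested], "BH")
  res$significant <- res$tested & !is.na(res$p_adj) & res$p_adj <= alpha &
    (res$fold_change >= fc_min | res$fold_change <= 1 / fc_min)
  res
}
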