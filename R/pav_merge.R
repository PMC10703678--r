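#' Merge parameters for nonredundant PAV construction
#'
#' Defaults follow the population merging rule for assembly-based SV sets:
#' deletions and inversions merge at a reciprocal overlap ratio above 0.90,
#' insertions merge when their junctions are less than 10 bp apart and their
#' sequences exceed 80% identity.
#'
#' @param del_inv_overlap_min reciprocal overlap ratio threshold (strict
#'   `>`), in (0, 1].
#' @param ins_max_distance maximum junction distance in bp (strict `<`).
#' @param ins_identity_min identity threshold (strict `>`), in (0, 1].
#' @param mode `"reciprocal"` compares the intersection against both lengths
#'   (equivalently `|intersection| / max(len_a, len_b)`); `"one_sided"`
#'   compares against the shorter length only, letting a long event absorb
#'   short ones.
#' @return a list of class `merge_params`.
#' @export
merge_params <- function(del_inv_overlap_min = 0.90, ins_max_distance = 10L,
                         ins_identity_min = 0.80,
                         mode = c("reciprocal", "one_sided")) {
  stopifnot(del_inv_overlap_min > 0, del_inv_overlap_min <= 1,
            ins_max_distance >= 0,
            ins_identity_min > 0, ins_identity_min <= 1)
  structure(list(del_inv_overlap_min = del_inv_overlap_min,
                 ins_max_distance = ins_max_distance,
                 ins_identity_min = ins_identity_min,
                 mode = match.arg(mode)), class = "merge_params")
}

#' Pairwise merge-link test
#'
#' The symmetric relation under which two same-subtype SVs belong to one
#' PAV cluster.
#'
#' @param a,b single-row SV records (`subtype`, `ref_chrom`, `ref_start`,
#'   `ref_end`, `inserted_seq`).
#' @param params a [merge_params].
#' @return logical.
#' @export
pav_link <- function(a, b, params = merge_params()) {
  if (a$subtype != b$subtype)
    stop("internal: link test across subtypes (", a$subtype, " vs ",
         b$subtype, ")")
  if (a$ref_chrom != b$ref_chrom) return(FALSE)
  if (a$subtype %in% c("DEL", "INV")) {
    inter <- max(0, min(a$ref_end, b$ref_end) - max(a$ref_start, b$ref_start))
    la <- a$ref_end - a$ref_start
    lb <- b$ref_end - b$ref_start
    ratio <- if (params$mode == "reciprocal") inter / max(la, lb)
             else inter / min(la, lb)
    return(ratio > params$del_inv_overlap_min)
  }
  if (a$subtype == "INS") {
    if (abs(a$ref_start - b$ref_start) >= params$ins_max_distance)
      return(FALSE)
    return(seq_identity(a$inserted_seq, b$inserted_seq) >
             params$ins_identity_min)
  }
  FALSE
}

#' Merge per-accession SVs into nonredundant PAV clusters
#'
#' Single-linkage clustering under the [pav_link] relation, computed per
#' subtype. Candidate pairs are restricted to overlapping intervals
#' (DEL/INV) or nearby junctions (INS) before the exact link test, so the
#' result equals the brute-force transitive closure. The cluster
#' representative is the member supported by the most within-cluster links
#' (ties: longest event, then leftmost); clusters are ordered by
#' (chromosome, representative start). Inversions are clustered too but are
#' conventionally excluded from the PAV genotype matrix, which covers
#' deletions and insertions only.
#'
#' @param svs SV call data frame (rows from one or more accessions on a
#'   shared reference).
#' @param params a [merge_params].
#' @param subtypes subtypes to cluster.
#' @return a `pav_cluster_set`: list with `clusters` (data frame:
#'   `cluster_id`, `subtype`, `chrom`, `start`, `end`, `seq`, `n_members`,
#'   `n_accessions`), `members` (member SV rows plus `cluster_id`) and
#'   `genotypes` (NULL until genotyped).
#' @export
merge_pavs <- function(svs, params = merge_params(),
                       subtypes = c("DEL", "INS", "INV")) {
  svs <- svs[svs$subtype %in% subtypes, , drop = FALSE]
  members <- list()
  clusters <- list()
  for (st in intersect(subtypes, unique(svs$subtype))) {
    s <- svs[svs$subtype == st, , drop = FALSE]
    rownames(s) <- NULL
    n <- nrow(s)
    pairs <- candidate_pairs(s, st, params)
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      keep[k] <- pav_link(s[pairs[k, 1], ], s[pairs[k, 2], ], params)
    }
    g <- igraph::graph_from_edgelist(
      rbind(matrix(pairs[keep, , drop = FALSE], ncol = 2),
            cbind(seq_len(n), seq_len(n))), directed = FALSE)
    comp <- igraph::components(g)$membership[seq_len(n)]
    for (cid in unique(comp)) {
      idx <- which(comp == cid)
      m <- s[idx, , drop = FALSE]
      # support: distinct accessions whose member links to this member
      deg <- vapply(seq_along(idx), function(i) {
        linked <- vapply(seq_along(idx), function(j) {
          i == j || pav_link(m[i, ], m[j, ], params)
        }, logical(1))
        length(unique(m$accession_id[linked]))
      }, integer(1))
      len <- ifelse(m$subtype == "INS", nchar(m$inserted_seq),
                    m$ref_end - m$ref_start)
      rep_i <- order(-deg, -len, m$ref_start)[1]
      clusters[[length(clusters) + 1L]] <- data.frame(
        subtype = st, chrom = m$ref_chrom[rep_i],
        start = m$ref_start[rep_i], end = m$ref_end[rep_i],
        seq = m$inserted_seq[rep_i], n_members = nrow(m),
        n_accessions = length(unique(m$accession_id)),
        stringsAsFactors = FALSE)
      m$cluster_key <- length(clusters)
      members[[length(members) + 1L]] <- m
    }
  }
  cl <- do.call(rbind, clusters)
  mem <- do.call(rbind, members)
  if (is.null(cl)) {
    cl <- data.frame(subtype = character(), chrom = character(),
                     start = integer(), end = integer(), seq = character(),
                     n_members = integer(), n_accessions = integer())
    mem <- empty_sv_frame()
    mem$cluster_key <- integer(0)
  }
  ord <- order(cl$chrom, cl$start, cl$end, cl$subtype)
  cl <- cl[ord, , drop = FALSE]
  key_map <- stats::setNames(seq_len(nrow(cl)), ord)
  cl$cluster_id <- sprintf("pav%05d", seq_len(nrow(cl)))
  rownames(cl) <- NULL
  mem$cluster_id <- cl$cluster_id[key_map[as.character(mem$cluster_key)]]
  mem$cluster_key <- NULL
  structure(list(clusters = cl, members = mem, genotypes = NULL),
            class = "pav_cluster_set")
}

#' @keywords internal
candidate_pairs <- function(s, st, params) {
  n <- nrow(s)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  if (st %in% c("DEL", "INV")) {
    gr <- as_granges0(data.frame(chrom = s$ref_chrom, start = s$ref_start,
                                 end = s$ref_end))
    h <- GenomicRanges::findOverlaps(gr, gr)
  } else {
    gr <- as_granges0(data.frame(chrom = s$ref_chrom, start = s$ref_start,
                                 end = s$ref_start + 1L))
    h <- GenomicRanges::findOverlaps(gr, gr,
                                     maxgap = params$ins_max_distance)
  }
  q <- S4Vectors::queryHits(h)
  sj <- S4Vectors::subjectHits(h)
  keep <- q < sj
  cbind(q[keep], sj[keep])
}

#' @export
print.pav_cluster_set <- function(x, ...) {
  cat("pav_cluster_set:", nrow(x$clusters), "clusters (",
      paste(names(table(x$clusters$subtype)),
            table(x$clusters$subtype), collapse = ", "), ")\n")
  if (!is.null(x$genotypes))
    cat("  genotyped over", ncol(x$genotypes), "accessions\n")
  invisible(x)
}

#' Genotype PAV clusters across assemblies
#'
#' For each cluster and accession: `present` (1) when the accession
#' contributed a member SV; `absent` (0) when the accession's synteny net
#' covers the representative interval with no linked SV; `missing` (NA) when
#' the representative interval falls in an uncovered net region. DEL/INS
#' clusters only.
#'
#' @param clusters a `pav_cluster_set` from [merge_pavs].
#' @param nets named list of [build_net] results, one per accession (each
#'   built with `ref_lengths` so uncovered zones are known).
#' @return the cluster set with a `genotypes` matrix (clusters x accessions;
#'   1/0/NA) attached; clusters are subset to DEL/INS.
#' @export
genotype_from_assemblies <- function(clusters, nets) {
  keep <- clusters$clusters$subtype %in% c("DEL", "INS")
  cl <- clusters$clusters[keep, , drop = FALSE]
  accs <- names(nets)
  miss_from_members <- setdiff(unique(clusters$members$accession_id), accs)
  if (length(miss_from_members) > 0)
    warning("accessions absent from nets, genotyped missing: ",
            paste(miss_from_members, collapse = ", "))
  all_accs <- union(accs, miss_from_members)
  geno <- matrix(NA_integer_, nrow(cl), length(all_accs),
                 dimnames = list(cl$cluster_id, all_accs))
  rep_iv <- data.frame(chrom = cl$chrom,
                       start = cl$start,
                       end = ifelse(cl$subtype == "INS", cl$start + 1L,
                                    cl$end))
  for (acc in accs) {
    unc <- nets[[acc]]$uncovered
    hit_unc <- interval_overlaps_any(rep_iv, unc)
    geno[, acc] <- ifelse(hit_unc, NA_integer_, 0L)
  }
  mem <- clusters$members
  mem <- mem[mem$cluster_id %in% cl$cluster_id, , drop = FALSE]
  for (k in seq_len(nrow(mem)))
    geno[mem$cluster_id[k], mem$accession_id[k]] <- 1L
  out <- clusters
  out$clusters <- cl
  out$members <- mem
  out$genotypes <- geno
  out
}

#' Evaluation report from match counts
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative counts.
#' @return list of class `eval_report` with `precision`, `recall`, `f1`.
#' @export
eval_report <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  structure(list(true_positive = tp, false_positive = fp,
                 false_negative = fn, precision = precision, recall = recall,
                 f1 = f1_score(precision, recall),
                 undefined_recall = (tp + fn) == 0), class = "eval_report")
}

#' Harmonic mean of precision and recall
#' @param precision,recall values in `[0, 1]`.
#' @return the F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: TP=%d FP=%d FN=%d  precision=%.2f recall=%.2f f1=%.2f\n",
              x$true_positive, x$false_positive, x$false_negative,
              x$precision, x$recall, x$f1))
  if (x$undefined_recall) cat("  (recall undefined: empty truth)\n")
  invisible(x)
}

#' Score a call set against a truth set
#'
#' A call matches a truth record when the merge-link criterion for its
#' subtype holds ([pav_link] under `params`); matching is one-to-one, greedy
#' by overlap quality (reciprocal overlap ratio for DEL/INV, sequence
#' identity for INS).
#'
#' @param calls,truth SV data frames in the same reference coordinate
#'   system. `truth` may be a truth table from [derive_accession_genome]
#'   (columns are normalized internally).
#' @param params a [merge_params].
#' @param subtypes subtypes entering the evaluation.
#' @return an [eval_report] with a `matches` attribute (call row, truth row).
#' @export
evaluate_calls <- function(calls, truth, params = merge_params(),
                           subtypes = c("DEL", "INS")) {
  calls <- normalize_sv(calls); calls <- calls[calls$subtype %in% subtypes, ]
  truth <- normalize_sv(truth); truth <- truth[truth$subtype %in% subtypes, ]
  rownames(calls) <- NULL; rownames(truth) <- NULL
  if (nrow(truth) == 0 && nrow(calls) > 0)
    return(eval_report(0L, nrow(calls), 0L))
  quality <- function(a, b) {
    if (a$subtype %in% c("DEL", "INV")) {
      inter <- max(0, min(a$ref_end, b$ref_end) -
                     max(a$ref_start, b$ref_start))
      inter / max(a$ref_end - a$ref_start, b$ref_end - b$ref_start)
    } else seq_identity(a$inserted_seq, b$inserted_seq)
  }
  cand <- list()
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(truth))) {
      if (calls$subtype[i] != truth$subtype[j]) next
      if (calls$ref_chrom[i] != truth$ref_chrom[j]) next
      if (abs(calls$ref_start[i] - truth$ref_start[j]) > 1e6) next
      if (pav_link(calls[i, ], truth[j, ], params))
        cand[[length(cand) + 1L]] <- c(i, j,
                                       quality(calls[i, ], truth[j, ]))
    }
  }
  matched_call <- logical(nrow(calls)); matched_truth <- logical(nrow(truth))
  matches <- list()
  if (length(cand) > 0) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3]), , drop = FALSE]
    for (k in seq_len(nrow(cm))) {
      i <- cm[k, 1]; j <- cm[k, 2]
      if (matched_call[i] || matched_truth[j]) next
      matched_call[i] <- TRUE; matched_truth[j] <- TRUE
      matches[[length(matches) + 1L]] <- c(call = i, truth = j)
    }
  }
  rep <- eval_report(sum(matched_call),
                     sum(!matched_call), sum(!matched_truth))
  attr(rep, "matches") <- do.call(rbind, matches)
  rep
}

#' @keywords internal
normalize_sv <- function(x) {
  x <- as.data.frame(x)
  if (!"ref_chrom" %in% names(x) && "chrom" %in% names(x)) {
    x$ref_chrom <- x$chrom; x$ref_start <- x$start; x$ref_end <- x$end
  }
  if (!"inserted_seq" %in% names(x))
    x$inserted_seq <- if ("seq" %in% names(x)) x$seq else ""
  x
}

#' Carrier frequency spectrum of a genotyped PAV set
#'
#' Histogram of clusters by number of carrier accessions (genotype present;
#' missing genotypes are excluded from both the carrier count and the called
#' total of a cluster), plus the fraction of clusters carried by at most two
#' accessions.
#'
#' @param x a genotyped `pav_cluster_set`, or an integer vector of carrier
#'   counts per cluster.
#' @return list with `counts` (table over carrier count), `fraction_le2` and
#'   `n_clusters`.
#' @export
frequency_spectrum <- function(x) {
  carriers <- if (is.numeric(x)) x
              else rowSums(x$genotypes == 1L, na.rm = TRUE)
  list(counts = table(carriers),
       fraction_le2 = mean(carriers <= 2),
       n_clusters = length(carriers))
}
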