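#' Link SSR loci to genes within a flanking window
#'
#' A locus links to a gene iff it overlaps the gene body (side `within`,
#' distance 0) or the gap between the locus and the gene span is at most
#' `link_window_bp` (inclusive). Upstream/downstream is relative to the
#' gene's strand.
#'
#' @param loci Data.frame of loci (`locus_id`, `seqid`, `start`, `end`,
#'   0-based half-open).
#' @param genes Data.frame of gene models (`gene_id`, `seqid`, `start`,
#'   `end`, `strand`).
#' @param link_window_bp Maximum gap in bp (default 2000, inclusive).
#' @return Data.frame with `gene_id`, `locus_id`, `distance_bp`, `side`
#'   (upstream/downstream/within).
#' @export
link_ssrs_to_genes <- function(loci, genes, link_window_bp = 2000L) {
  empty <- data.frame(gene_id = character(), locus_id = character(),
                      distance_bp = integer(), side = character(),
                      stringsAsFactors = FALSE)
  if (nrow(loci) == 0 || nrow(genes) == 0) return(empty)
  gr_l <- intervals_to_granges(loci)
  gr_g <- intervals_to_granges(genes)
  hits <- GenomicRanges::findOverlaps(gr_l, gr_g,
                                      maxgap = link_window_bp,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(gr_l[qi], gr_g[si], ignore.strand = TRUE)
  locus_before <- loci$end[qi] <= genes$start[si]
  locus_after <- loci$start[qi] >= genes$end[si]
  side <- rep("within", length(qi))
  plus <- genes$strand[si] != "-"
  side[locus_before & plus] <- "upstream"
  side[locus_before & !plus] <- "downstream"
  side[locus_after & plus] <- "downstream"
  side[locus_after & !plus] <- "upstream"
  out <- data.frame(
    gene_id = genes$gene_id[si],
    locus_id = loci$locus_id[qi],
    distance_bp = as.integer(dist),
    side = side,
    stringsAsFactors = FALSE
  )
  out <- out[out$distance_bp <= link_window_bp, , drop = FALSE]
  out <- out[order(out$gene_id, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition samples by SSR presence at a locus
#'
#' @param locus_id Locus to partition on.
#' @param presence Data.frame with `sample`, `locus_id`, `present` (0/1
#'   or logical).
#' @param samples Character vector of all samples in the count matrix.
#' @return List with character vectors `present` and `absent`
#'   (disjoint, exhaustive).
#' @export
group_by_presence <- function(locus_id, presence, samples) {
  sub <- presence[presence$locus_id == locus_id, , drop = FALSE]
  missing <- setdiff(samples, sub$sample)
  if (length(missing) > 0) {
    stop("no presence call for sample(s): ", paste(missing, collapse = ", "))
  }
  pres <- sub$sample[as.logical(sub$present)]
  list(present = intersect(samples, pres),
       absent = setdiff(samples, pres))
}

#' NB likelihood-ratio test of SSR presence on a gene's expression
#'
#' Two-group NB LRT (shared dispersion, df = 1) of the gene's counts
#' between SSR-present and SSR-absent samples, with size factors entering
#' as model offsets. Groups with fewer than 2 samples are untestable.
#'
#' @param gene_counts Named integer vector of the gene's counts, names =
#'   samples.
#' @param groups Output of [group_by_presence()].
#' @param size_factors Named per-sample normalization factors.
#' @return List with `testable`, and when testable `stat`, `df`, `p`,
#'   `n_present`, `n_absent`; otherwise `reason`.
#' @export
lrt_ssr_expression <- function(gene_counts, groups, size_factors = NULL) {
  n_p <- length(groups$present)
  n_a <- length(groups$absent)
  if (n_p < 2 || n_a < 2) {
    return(list(testable = FALSE, n_present = n_p, n_absent = n_a,
                reason = sprintf("group too small (present=%d, absent=%d)",
                                 n_p, n_a)))
  }
  samples <- c(groups$present, groups$absent)
  labels <- rep(c("present", "absent"), c(n_p, n_a))
  sf <- if (is.null(size_factors)) rep(1, length(samples)) else
    size_factors[samples]
  res <- nb_lrt_two_group(gene_counts[samples], labels,
                          shared_dispersion = TRUE, size_factors = sf)
  list(testable = TRUE, stat = res$stat, df = res$df, p = res$p,
       n_present = n_p, n_absent = n_a)
}

#' Run every SSR-presence expression test with BH adjustment
#'
#' For each gene--locus link, partitions the samples by SSR presence and
#' runs the NB LRT; BH q-values are computed across exactly the testable
#' set, and untestable links are reported separately with their reasons.
#'
#' @param links Data.frame from [link_ssrs_to_genes()].
#' @param counts Gene x sample integer matrix.
#' @param presence Data.frame with `sample`, `locus_id`, `present`.
#' @param sf Optional named per-sample size factors; computed from
#'   `counts` when NULL.
#' @return List with `tested` (data.frame gene_id/locus_id/n_present/
#'   n_absent/stat/df/p/q) and `untestable` (data.frame with reasons).
#' @export
run_all_ssr_tests <- function(links, counts, presence, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  samples <- colnames(counts)
  tested <- list()
  untestable <- list()
  for (i in seq_len(nrow(links))) {
    gid <- links$gene_id[i]
    lid <- links$locus_id[i]
    if (!gid %in% rownames(counts)) {
      untestable[[length(untestable) + 1]] <- data.frame(
        gene_id = gid, locus_id = lid, reason = "gene not in count matrix",
        stringsAsFactors = FALSE)
      next
    }
    grp <- group_by_presence(lid, presence, samples)
    res <- lrt_ssr_expression(counts[gid, ], grp, sf)
    if (res$testable) {
      tested[[length(tested) + 1]] <- data.frame(
        gene_id = gid, locus_id = lid, n_present = res$n_present,
        n_absent = res$n_absent, stat = res$stat, df = res$df, p = res$p,
        stringsAsFactors = FALSE)
    } else {
      untestable[[length(untestable) + 1]] <- data.frame(
        gene_id = gid, locus_id = lid, reason = res$reason,
        stringsAsFactors = FALSE)
    }
  }
  tested_df <- if (length(tested) > 0) do.call(rbind, tested) else
    data.frame(gene_id = character(), locus_id = character(),
               n_present = integer(), n_absent = integer(), stat = numeric(),
               df = integer(), p = numeric(), stringsAsFactors = FALSE)
  tested_df$q <- if (nrow(tested_df) > 0) bh_adjust(tested_df$p) else numeric(0)
  untestable_df <- if (length(untestable) > 0) do.call(rbind, untestable) else
    data.frame(gene_id = character(), locus_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(tested = tested_df, untestable = untestable_df)
}

#' Fisher / hypergeometric term overrepresentation
#'
#' One-sided hypergeometric test of each term's overrepresentation in a
#' study gene set against a background set, with BH adjustment and log2
#' fold-enrichment. Terms with zero study hits are reported at p = 1 with
#' `log2_fc = NA`.
#'
#' @param study Character vector of study gene ids (subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param term_map Data.frame with `gene_id`, `term`.
#' @return Data.frame with `term`, `study_hits`, `study_size`,
#'   `background_hits`, `background_size`, `p`, `q`, `log2_fc`, sorted by
#'   p.
#' @export
fisher_overrepresentation <- function(study, background, term_map) {
  study <- unique(study)
  background <- unique(background)
  if (!all(study %in% background)) {
    stop("study set must be a subset of the background")
  }
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  terms <- unique(term_map$term)
  n_study <- length(study)
  n_bg <- length(background)
  rows <- lapply(terms, function(tm) {
    hits_bg <- unique(term_map$gene_id[term_map$term == tm])
    k <- sum(study %in% hits_bg)
    K <- length(hits_bg)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, n_bg - K, n_study, lower.tail = FALSE)
    fc <- if (k == 0) NA_real_ else
      log2((k / n_study) / (K / n_bg))
    data.frame(term = tm, study_hits = k, study_size = n_study,
               background_hits = K, background_size = n_bg,
               p = p, log2_fc = fc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), study_hits = integer(),
                      study_size = integer(), background_hits = integer(),
                      background_size = integer(), p = numeric(),
                      q = numeric(), log2_fc = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), c("term", "study_hits", "study_size",
                                       "background_hits", "background_size",
                                       "p", "q", "log2_fc")]
  rownames(out) <- NULL
  out
}
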