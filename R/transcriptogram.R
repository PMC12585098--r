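#' Filter a scored association edge list into an interaction graph
#'
#' Keeps edges with combined score strictly greater than the threshold;
#' nodes left without any retained edge are excluded from the ordering
#' universe.
#'
#' @param edges Data.frame with `node1`, `node2`, `score` (0--1000), as
#'   from [read_edges()].
#' @param score_threshold Strict lower bound on retained scores (default
#'   800).
#' @return A list of class `interaction_graph`: `nodes` (sorted character
#'   vector) and `edges` (data.frame).
#' @export
filter_graph <- function(edges, score_threshold = 800L) {
  keep <- edges$score > score_threshold
  e <- edges[keep, , drop = FALSE]
  e <- e[e$node1 != e$node2, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = sort(unique(c(e$node1, e$node2))), edges = e,
                 score_threshold = score_threshold),
            class = "interaction_graph")
}

#' Order genes along one dimension by simulated annealing
#'
#' Produces a permutation of the graph's genes that (heuristically)
#' minimizes the total edge positional distance, sum over edges of
#' |pos(u) - pos(v)|, so that the distance between genes reflects the
#' likelihood of their association. Pairwise position swaps with
#' geometric cooling (initial temperature cost/N, configurable ratio);
#' the search keeps the best arrangement seen and stops after
#' `n_iterations` sweeps without improvement, so the final cost never
#' exceeds the identity ordering's. Fixed seed gives a reproducible
#' ordering.
#'
#' @param graph An `interaction_graph` from [filter_graph()].
#' @param seed Integer RNG seed.
#' @param n_iterations Sweeps without improvement before stopping
#'   (default 300).
#' @param max_sweeps Hard cap on sweeps (default 5000).
#' @param cooling Geometric cooling ratio (default 0.995).
#' @return Character vector of gene ids in position order (position i of
#'   the ordering is element i + 1), with attribute `cost`.
#' @export
build_ordering <- function(graph, seed = 1L, n_iterations = 300L,
                           max_sweeps = 5000L, cooling = 0.995) {
  if (length(graph$nodes) == 0) stop("empty interaction graph")
  nodes <- graph$nodes
  u <- match(graph$edges$node1, nodes) - 1L
  v <- match(graph$edges$node2, nodes) - 1L
  set.seed(seed)
  arr <- anneal_order_cpp(u, v, length(nodes), as.integer(max_sweeps),
                          as.integer(n_iterations), cooling)
  ordering <- nodes[arr + 1L]
  attr(ordering, "cost") <- ordering_cost(ordering, graph$edges)
  ordering
}

#' Linear-arrangement cost of an ordering
#'
#' @param ordering Character vector of gene ids in position order.
#' @param edges Data.frame with `node1`, `node2`.
#' @return Sum over edges of the absolute positional distance.
#' @export
ordering_cost <- function(ordering, edges) {
  pos <- stats::setNames(seq_along(ordering), ordering)
  sum(abs(pos[edges$node1] - pos[edges$node2]))
}

#' Project an expression vector onto an ordering with window averaging
#'
#' Position i receives the arithmetic mean of the expression of genes at
#' positions max(0, i - r) .. min(N - 1, i + r) along the ordering;
#' interior windows cover exactly 2r + 1 genes and edge windows are
#' truncated. Genes missing from the expression vector are imputed as 0
#' with a warning.
#'
#' @param ordering Character vector of gene ids in position order.
#' @param expr Named numeric vector of per-gene expression.
#' @param radius Window half-width in genes (default 30; radius 0 returns
#'   the unsmoothed values).
#' @return Numeric vector of windowed means, one per position.
#' @export
project_expression <- function(ordering, expr, radius = 30L) {
  n <- length(ordering)
  if (radius >= n) stop("radius must be smaller than the ordering length")
  x <- expr[ordering]
  if (anyNA(x)) {
    warning(sum(is.na(x)), " ordered gene(s) missing from expression; ",
            "imputed as 0")
    x[is.na(x)] <- 0
  }
  x <- unname(x)
  if (radius == 0) return(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - radius)
  hi <- pmin(n, i + radius)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Relative expression profile with a replicate dispersion band
#'
#' Per position: (mean of case replicates + 0.5) / (mean of control
#' replicates + 0.5), with a band of +/- one standard deviation across
#' the per-replicate case ratios. The control condition relative to
#' itself is 1 everywhere.
#'
#' @param case_profiles Positions x replicates matrix of windowed case
#'   values.
#' @param control_profiles Positions x replicates matrix of windowed
#'   control values.
#' @return Data.frame with `position` (0-based), `relative`, `band`.
#' @export
relative_profile <- function(case_profiles, control_profiles) {
  stopifnot(ncol(case_profiles) >= 2, ncol(control_profiles) >= 2,
            nrow(case_profiles) == nrow(control_profiles))
  ctrl_mean <- rowMeans(control_profiles) + 0.5
  rel <- (rowMeans(case_profiles) + 0.5) / ctrl_mean
  rep_ratios <- sweep(case_profiles + 0.5, 1, ctrl_mean, "/")
  band <- apply(rep_ratios, 1, stats::sd)
  data.frame(position = seq_len(nrow(case_profiles)) - 1L,
             relative = rel, band = band)
}

#' Per-position Welch tests between case and control replicate profiles
#'
#' Welch two-sample t-test at every position on the per-replicate values
#' (windowed means for the radius-r track, unsmoothed values for radius
#' 0). Positions where both groups have zero variance and equal means
#' give p = 1.
#'
#' @param case_profiles Positions x replicates matrix for the case
#'   condition.
#' @param control_profiles Positions x replicates matrix for the control
#'   condition.
#' @return Numeric vector of p-values in (0, 1].
#' @export
window_test <- function(case_profiles, control_profiles) {
  stopifnot(nrow(case_profiles) == nrow(control_profiles),
            ncol(case_profiles) >= 2, ncol(control_profiles) >= 2)
  n1 <- ncol(case_profiles)
  n2 <- ncol(control_profiles)
  m1 <- rowMeans(case_profiles)
  m2 <- rowMeans(control_profiles)
  v1 <- rowSums((case_profiles - m1)^2) / (n1 - 1)
  v2 <- rowSums((control_profiles - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0 & m1 == m2] <- 1          # degenerate: no variance, no shift
  p[se2 == 0 & m1 != m2] <- .Machine$double.xmin
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Call peaks in a per-position p-value profile
#'
#' A peak is a maximal run of consecutive positions with p strictly below
#' the threshold.
#'
#' @param p Numeric vector of per-position p-values.
#' @param threshold Peak-calling p cutoff.
#' @param ordering Optional gene ordering; if given, member genes are
#'   attached.
#' @return Data.frame with `start`, `end` (0-based half-open position
#'   span), `n_positions`, `min_p`, and list-column `genes` when an
#'   ordering is supplied.
#' @export
call_peaks <- function(p, threshold, ordering = NULL) {
  below <- p < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0) {
    out <- data.frame(start = integer(), end = integer(),
                      n_positions = integer(), min_p = numeric())
    if (!is.null(ordering)) out$genes <- I(list())
    return(out)
  }
  out <- data.frame(
    start = starts[keep] - 1L,
    end = ends[keep],
    n_positions = r$lengths[keep],
    min_p = vapply(keep, function(j) min(p[starts[j]:ends[j]]), numeric(1))
  )
  if (!is.null(ordering)) {
    out$genes <- I(lapply(keep, function(j) ordering[starts[j]:ends[j]]))
  }
  rownames(out) <- NULL
  out
}

#' Windowed density of a GO (or any) term along the ordering
#'
#' Fraction of the genes in each window annotated with the term; genes
#' absent from the map count as unannotated.
#'
#' @param ordering Character vector of gene ids in position order.
#' @param term_map Data.frame with `gene_id`, `term`.
#' @param term Term id to profile.
#' @param window Full window width in genes (odd; default 61).
#' @return Numeric vector of densities in [0, 1], one per position.
#' @export
go_density <- function(ordering, term_map, term, window = 61L) {
  stopifnot(window %% 2 == 1)
  annotated <- term_map$gene_id[term_map$term == term]
  if (length(annotated) == 0) {
    warning("term not found in map: ", term)
    return(rep(0, length(ordering)))
  }
  ind <- as.numeric(ordering %in% annotated)
  names(ind) <- ordering
  project_expression(ordering, ind, radius = (window - 1L) %/% 2L)
}

#' Combined transcriptogram / per-gene DEG selection
#'
#' Selects genes that pass all three criteria: windowed (radius-r)
#' p-value below `p_r30` at the gene's position, unsmoothed (radius-0)
#' p-value below `p_r0`, and per-gene DE test p below `p_gene`. Genes in
#' the DE table absent from the ordering are excluded with a warning.
#'
#' @param ordering Character vector of gene ids in position order.
#' @param p_r Per-position windowed p-values.
#' @param p_0 Per-position radius-0 p-values.
#' @param de_results DEG table from [call_degs()].
#' @param p_r30,p_r0,p_gene Selection cutoffs (defaults 0.01, 0.05, 0.05).
#' @return Character vector of selected gene ids.
#' @export
select_candidate_degs <- function(ordering, p_r, p_0, de_results,
                                  p_r30 = 0.01, p_r0 = 0.05, p_gene = 0.05) {
  stopifnot(length(p_r) == length(ordering), length(p_0) == length(ordering))
  missing <- setdiff(de_results$gene, ordering)
  if (length(missing) > 0) {
    warning(length(missing), " gene(s) absent from the ordering; excluded")
  }
  pos <- match(de_results$gene, ordering)
  ok <- !is.na(pos) &
    p_r[pos] < p_r30 &
    p_0[pos] < p_r0 &
    de_results$p < p_gene
  de_results$gene[ok]
}

#' Full transcriptogram profile for one population
#'
#' Convenience wrapper: size-factor normalization of the population's
#' samples, log2(x + 1) windowed projection of every replicate, Welch
#' tests at radius r and radius 0 (drought vs control), and the relative
#' expression profile on the untransformed normalized scale.
#'
#' @param counts Gene x sample integer matrix.
#' @param sheet Sample sheet data.frame.
#' @param population Population label.
#' @param ordering Gene ordering from [build_ordering()].
#' @param radius Window half-width (default 30).
#' @return List of class `transcriptogram`: `position` (0-based),
#'   `gene`, `p_r`, `p_0`, `relative`, `band`, `radius`, `population`.
#' @export
transcriptogram_profile <- function(counts, sheet, population, ordering,
                                    radius = 30L) {
  samples <- sheet$sample[sheet$population == population]
  cond <- sheet$condition[sheet$population == population]
  m <- counts[, samples, drop = FALSE]
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  in_ord <- intersect(ordering, rownames(norm))
  if (length(in_ord) < length(ordering)) {
    warning(length(ordering) - length(in_ord),
            " ordered gene(s) missing from the count matrix; imputed as 0")
  }
  logn <- log2(norm + 1)
  win <- function(mat, r) {
    vapply(seq_len(ncol(mat)), function(j) {
      suppressWarnings(project_expression(ordering, mat[, j], radius = r))
    }, numeric(length(ordering)))
  }
  drt <- which(cond == "drought")
  ctl <- which(cond == "control")
  w_log_r <- win(logn, radius)
  w_log_0 <- win(logn, 0L)
  w_raw_r <- win(norm, radius)
  rel <- relative_profile(w_raw_r[, drt, drop = FALSE],
                          w_raw_r[, ctl, drop = FALSE])
  structure(list(
    position = seq_along(ordering) - 1L,
    gene = ordering,
    p_r = window_test(w_log_r[, drt, drop = FALSE],
                      w_log_r[, ctl, drop = FALSE]),
    p_0 = window_test(w_log_0[, drt, drop = FALSE],
                      w_log_0[, ctl, drop = FALSE]),
    relative = rel$relative,
    band = rel$band,
    radius = radius,
    population = population
  ), class = "transcriptogram")
}
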