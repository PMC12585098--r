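#' Simulation parameters
#'
#' Defaults emulate the study conditions at desk scale: a 2-population x
#' 2-condition x 3-replicate count design (12 libraries), baseline gene
#' means log-normal(log 100, 1), gene dispersions log-normal(log 0.1,
#' 0.5), 10% planted DE genes with fold changes drawn from a grid at or
#' above the 1.5 DEG threshold, a 2-fold SSR-linked expression effect,
#' and a 5-block modular association graph with intra-block score mass
#' above the 800 filter.
#'
#' @param genome_length Total genome length in bp.
#' @param n_chromosomes Number of chromosomes.
#' @param n_planted_ssrs Number of planted SSRs.
#' @param ssr_motif_lengths Motif lengths to draw from.
#' @param ssr_length_weights Sampling weights for the motif lengths.
#' @param ssr_repeat_range Range of planted repeat counts (min, max),
#'   drawn uniformly and clamped to meet the detection minimum for the
#'   motif length.
#' @param n_genes Number of genes in the count design.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean
#'   parameters.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal dispersion
#'   parameters.
#' @param de_fraction Fraction of genes planted as DE (per population).
#' @param de_fc_grid Fold changes for planted DE genes (all >= 1.5).
#' @param ssr_effect_fc Fold change planted on SSR-linked genes in
#'   SSR-present samples.
#' @param replicates Replicates per population x condition cell.
#' @param populations Population labels.
#' @param libsize_sdlog Log-normal sd of per-library size factors.
#' @param n_blocks,block_size Association-graph block structure.
#' @param p_intra,p_inter Intra-/inter-block edge probabilities.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 100000L,
                       n_chromosomes = 4L,
                       n_planted_ssrs = 50L,
                       ssr_motif_lengths = 1:6,
                       ssr_length_weights = c(0.05, 0.45, 0.3, 0.1, 0.05, 0.05),
                       ssr_repeat_range = c(6L, 15L),
                       n_genes = 400L,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       dispersion_meanlog = log(0.1),
                       dispersion_sdlog = 0.5,
                       de_fraction = 0.1,
                       de_fc_grid = c(1.5, 2, 3, 4),
                       ssr_effect_fc = 2,
                       replicates = 3L,
                       populations = c("RE", "RF"),
                       libsize_sdlog = 0.15,
                       n_blocks = 5L,
                       block_size = 40L,
                       p_intra = 0.3,
                       p_inter = 0.005) {
  stopifnot(de_fraction >= 0, de_fraction <= 1,
            p_intra >= 0, p_intra <= 1, p_inter >= 0, p_inter <= 1,
            all(de_fc_grid >= 1.5), block_size >= 2)
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

#' Simulate a genome with planted SSRs and gene models
#'
#' Background sequence is i.i.d. uniform over A/C/G/T; planted SSRs
#' (random primitive motif, repeat count meeting the detection minimum)
#' are inserted verbatim at non-overlapping rejection-sampled positions
#' with at least 150 bp clearance between plants. Gene models are placed
#' with known distances to planted SSRs, some within 2 kbp and some
#' beyond.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer RNG seed.
#' @param config A [pipeline_config()] (detection minimums for planted
#'   repeat counts).
#' @return List with `genome` (named character vector of chromosome
#'   sequences), `genes` (gene model data.frame), and `truth` (data.frame
#'   of planted SSRs: `seqid`, `start`, `end`, `motif`, `n_repeats`).
#' @export
simulate_genome <- function(params = sim_params(), seed = 1L,
                            config = pipeline_config()) {
  set.seed(seed)
  chrom_len <- params$genome_length %/% params$n_chromosomes
  chrom_ids <- sprintf("chr%02d", seq_len(params$n_chromosomes))
  genome <- vapply(chrom_ids, function(id) {
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
          collapse = "")
  }, character(1))

  # draw planted SSR descriptions
  k <- sample(params$ssr_motif_lengths, params$n_planted_ssrs, replace = TRUE,
              prob = params$ssr_length_weights)
  truth <- vector("list", params$n_planted_ssrs)
  occupied <- lapply(chrom_ids, function(id) cbind(start = integer(0),
                                                   end = integer(0)))
  names(occupied) <- chrom_ids
  for (i in seq_len(params$n_planted_ssrs)) {
    ki <- k[i]
    motif <- .random_primitive_motif(ki)
    nrep <- max(config$ssr_min_repeats[ki],
                sample(params$ssr_repeat_range[1]:params$ssr_repeat_range[2], 1))
    len <- ki * nrep
    if (chrom_len - len - 300L < 1L) {
      stop("genome too short for the requested planted SSRs")
    }
    placed <- FALSE
    for (try in 1:500) {
      chrom <- sample(chrom_ids, 1)
      start <- sample.int(chrom_len - len - 300L, 1) + 150L  # 0-based
      occ <- occupied[[chrom]]
      # 150 bp clearance so planted repeats never merge or extend
      if (nrow(occ) > 0 &&
          any(start < occ[, "end"] + 150L & start + len > occ[, "start"] - 150L)) {
        next
      }
      occupied[[chrom]] <- rbind(occ, cbind(start = start, end = start + len))
      placed <- TRUE
      break
    }
    if (!placed) stop("genome too short for the requested planted SSRs")
    truth[[i]] <- data.frame(seqid = chrom, start = start, end = start + len,
                             motif = motif, n_repeats = nrep,
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$seqid, truth$start), , drop = FALSE]
  rownames(truth) <- NULL

  # splice the repeats in; the flanking base on each side is forced to a
  # character that breaks the period, so a planted run can neither shift
  # its leftmost anchor nor gain a whole unit from chance context
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(truth))) {
    s <- genome[[truth$seqid[i]]]
    unit <- truth$motif[i]
    k <- nchar(unit)
    ins <- paste(rep(unit, truth$n_repeats[i]), collapse = "")
    substr(s, truth$start[i] + 1L, truth$end[i]) <- ins
    left_bad <- substr(unit, k, k)      # would extend the period leftwards
    right_bad <- substr(unit, 1, 1)     # would extend it rightwards
    substr(s, truth$start[i], truth$start[i]) <-
      sample(setdiff(bases, left_bad), 1)
    substr(s, truth$end[i] + 1L, truth$end[i] + 1L) <-
      sample(setdiff(bases, right_bad), 1)
    genome[[truth$seqid[i]]] <- s
  }

  genes <- .place_gene_models(params, chrom_ids, chrom_len, truth)
  list(genome = genome, genes = genes, truth = truth)
}

.random_primitive_motif <- function(k) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    if (.is_primitive(m)) return(m)
  }
}

.place_gene_models <- function(params, chrom_ids, chrom_len, truth) {
  # one gene near (within 2 kbp of) every other planted SSR, plus distant
  # genes, so linking is exercised in both directions
  genes <- list()
  gid <- 0L
  for (i in seq_len(nrow(truth))) {
    if (i %% 2 == 1) {
      gid <- gid + 1L
      gstart <- truth$end[i] + sample(50:1500, 1)
      gend <- min(gstart + 600L, chrom_len)
      if (gend - gstart < 100) next
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = sprintf("g%04d", gid), seqid = truth$seqid[i],
        start = gstart, end = gend,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    }
  }
  # distant genes: rejection-sampled to sit beyond 2 kbp of every plant,
  # so the linking stage always sees both linked and unlinked genes
  n_far <- max(4L, nrow(truth) %/% 5)
  placed_far <- 0L
  for (try in seq_len(200L * n_far)) {
    if (placed_far >= n_far) break
    chrom <- sample(chrom_ids, 1)
    gstart <- sample.int(chrom_len - 700L, 1)
    gend <- gstart + 600L
    near <- truth[truth$seqid == chrom, , drop = FALSE]
    if (nrow(near) > 0 &&
        any(gstart - near$end <= 2000L & near$start - gend <= 2000L)) {
      next
    }
    gid <- gid + 1L
    placed_far <- placed_far + 1L
    genes[[length(genes) + 1]] <- data.frame(
      gene_id = sprintf("g%04d", gid), seqid = chrom,
      start = gstart, end = gend,
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, genes)
  out[order(out$seqid, out$start), , drop = FALSE]
}

#' Simulate the 12-library count design with planted effects
#'
#' Counts are NB(mu_gs, alpha_g) with gene baselines and dispersions
#' drawn log-normal, per-library size factors drawn log-normal and
#' recorded, planted DE genes whose mean is multiplied by the true fold
#' change in drought samples of the target population, and planted
#' SSR-linked genes whose mean is multiplied by the effect fold change in
#' SSR-present samples.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer RNG seed.
#' @param ssr_linked Optional data.frame (`gene`, `locus_id`) of genes to
#'   receive the SSR presence effect.
#' @param presence Optional data.frame (`sample`, `locus_id`, `present`)
#'   giving per-sample presence for the SSR-linked effects.
#' @return List with `counts` (gene x sample integer matrix), `sheet`
#'   (sample sheet), and `truth` (list: `de` data.frame of planted DE
#'   genes with `gene`, `population`, `fc`, `direction`; `lib_size_factors`;
#'   `baseline`, `dispersion`; `ssr_linked`).
#' @export
simulate_counts <- function(params = sim_params(), seed = 1L,
                            ssr_linked = NULL, presence = NULL) {
  set.seed(seed)
  pops <- params$populations
  conds <- c("control", "drought")
  sheet <- expand.grid(replicate = seq_len(params$replicates),
                       condition = conds, population = pops,
                       stringsAsFactors = FALSE)
  sheet$sample <- sprintf("%s_%s_%d", sheet$population,
                          substr(sheet$condition, 1, 4), sheet$replicate)
  sheet <- sheet[, c("sample", "population", "condition", "replicate")]

  genes <- sprintf("g%04d", seq_len(params$n_genes))
  baseline <- stats::rlnorm(params$n_genes, params$baseline_meanlog,
                            params$baseline_sdlog)
  dispersion <- stats::rlnorm(params$n_genes, params$dispersion_meanlog,
                              params$dispersion_sdlog)
  lib_sf <- stats::rlnorm(nrow(sheet), 0, params$libsize_sdlog)
  names(lib_sf) <- sheet$sample

  n_de <- round(params$de_fraction * params$n_genes)
  de <- NULL
  if (n_de > 0) {
    de_genes <- sample(genes, n_de)
    fc_grid <- params$de_fc_grid
    de <- data.frame(
      gene = de_genes,
      population = sample(pops, n_de, replace = TRUE),
      fc = fc_grid[sample.int(length(fc_grid), n_de, replace = TRUE)],
      direction = sample(c("up", "down"), n_de, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }

  mu <- matrix(baseline, nrow = params$n_genes, ncol = nrow(sheet),
               dimnames = list(genes, sheet$sample))
  if (!is.null(de)) {
    for (i in seq_len(nrow(de))) {
      cols <- sheet$population == de$population[i] &
        sheet$condition == "drought"
      eff <- if (de$direction[i] == "up") de$fc[i] else 1 / de$fc[i]
      mu[de$gene[i], cols] <- mu[de$gene[i], cols] * eff
    }
  }
  if (!is.null(ssr_linked) && !is.null(presence)) {
    for (i in seq_len(nrow(ssr_linked))) {
      g <- ssr_linked$gene[i]
      if (!g %in% genes) next
      pres <- presence[presence$locus_id == ssr_linked$locus_id[i], ]
      pres_samples <- pres$sample[as.logical(pres$present)]
      cols <- sheet$sample %in% pres_samples
      mu[g, cols] <- mu[g, cols] * params$ssr_effect_fc
    }
  }
  mu <- sweep(mu, 2, lib_sf, "*")
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu,
                   size = rep(1 / dispersion, times = ncol(mu))),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )
  storage.mode(counts) <- "integer"
  list(counts = counts, sheet = sheet,
       truth = list(de = de, lib_size_factors = lib_sf,
                    baseline = stats::setNames(baseline, genes),
                    dispersion = stats::setNames(dispersion, genes),
                    ssr_linked = ssr_linked))
}

#' Simulate a modular scored association graph
#'
#' Stochastic block model over the gene universe: intra-block edges drawn
#' with probability `p_intra` and scores uniform in 801--1000 (surviving
#' the score filter), inter-block edges with probability `p_inter` and
#' scores uniform in 600--900 (straddling the 800 threshold so filtering
#' is exercised). Block membership is recorded as truth.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer RNG seed.
#' @param gene_ids Optional gene ids to use (defaults to g0001...).
#' @return List with `edges` (data.frame `node1`, `node2`, `score`) and
#'   `truth` (data.frame `gene`, `block`).
#' @export
simulate_ppi <- function(params = sim_params(), seed = 1L, gene_ids = NULL) {
  set.seed(seed)
  n <- params$n_blocks * params$block_size
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n))
  stopifnot(length(gene_ids) >= n)
  gene_ids <- gene_ids[seq_len(n)]
  block <- rep(seq_len(params$n_blocks), each = params$block_size)
  pairs <- utils::combn(n, 2)
  same <- block[pairs[1, ]] == block[pairs[2, ]]
  prob <- ifelse(same, params$p_intra, params$p_inter)
  keep <- stats::runif(ncol(pairs)) < prob
  i <- pairs[1, keep]
  j <- pairs[2, keep]
  intra <- same[keep]
  score <- integer(length(i))
  score[intra] <- sample(801:1000, sum(intra), replace = TRUE)
  score[!intra] <- sample(600:900, sum(!intra), replace = TRUE)
  edges <- data.frame(node1 = gene_ids[i], node2 = gene_ids[j],
                      score = score, stringsAsFactors = FALSE)
  list(edges = edges,
       truth = data.frame(gene = gene_ids, block = block,
                          stringsAsFactors = FALSE))
}

#' Simulate per-sample SSR presence and allele calls
#'
#' Each locus is assigned one of four generating regimes (exclusive to
#' either population, symmetric, or population-biased presence
#' probabilities), creating exclusive/equal/preferential loci by
#' construction; alleles are drawn from a small window around the planted
#' repeat count.
#'
#' @param loci Data.frame of loci (`locus_id`, `n_repeats`).
#' @param samples Data.frame with `sample`, `population`.
#' @param seed Integer RNG seed.
#' @param regime_weights Probabilities of the regimes `exclusive_a`,
#'   `exclusive_b`, `symmetric`, `biased_a`, `biased_b`.
#' @return List with `calls` (data.frame `sample`, `population`,
#'   `locus_id`, `repeat_count`, `present`) and `truth` (data.frame
#'   `locus_id`, `regime`).
#' @export
simulate_ssr_calls <- function(loci, samples, seed = 1L,
                               regime_weights = c(0.15, 0.1, 0.5, 0.15, 0.1)) {
  set.seed(seed)
  pops <- sort(unique(samples$population))
  stopifnot(length(pops) == 2)
  regimes <- c("exclusive_a", "exclusive_b", "symmetric", "biased_a",
               "biased_b")
  reg <- sample(regimes, nrow(loci), replace = TRUE, prob = regime_weights)
  calls <- list()
  for (i in seq_len(nrow(loci))) {
    pr <- switch(reg[i],
      exclusive_a = c(0.9, 0),
      exclusive_b = c(0, 0.9),
      symmetric = c(0.8, 0.8),
      biased_a = c(0.9, 0.4),
      biased_b = c(0.4, 0.9)
    )
    names(pr) <- pops
    present <- stats::rbinom(nrow(samples), 1, pr[samples$population])
    nrep <- loci$n_repeats[i]
    allele <- pmax(1L, nrep + sample(-1:1, nrow(samples), replace = TRUE,
                                     prob = c(0.2, 0.6, 0.2)))
    calls[[i]] <- data.frame(
      sample = samples$sample, population = samples$population,
      locus_id = loci$locus_id[i],
      repeat_count = ifelse(present == 1, allele, NA_integer_),
      present = present, stringsAsFactors = FALSE
    )
  }
  list(calls = do.call(rbind, calls),
       truth = data.frame(locus_id = loci$locus_id, regime = reg,
                          stringsAsFactors = FALSE))
}

#' Write a complete self-consistent synthetic dataset
#'
#' Generates the genome (FASTA + gene GFF3), the count matrix and sample
#' sheet, per-sample SSR presence/allele calls, the scored association
#' edge list, a gene-to-term map, and all truth tables, into one
#' directory.
#'
#' @param out_dir Output directory (created if needed).
#' @param params A [sim_params()] list.
#' @param seed Integer RNG seed; stage seeds are derived from it.
#' @param config A [pipeline_config()].
#' @return Invisibly, the list of generated objects.
#' @export
simulate_all <- function(out_dir, params = sim_params(), seed = 1L,
                         config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(params, seed = seed, config = config)
  write_fasta(gen$genome, file.path(out_dir, "genome.fa"))
  .write_gff3_genes(gen$genes, file.path(out_dir, "genes.gff3"))
  utils::write.table(gen$truth, file.path(out_dir, "truth_ssrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # loci ground truth for presence simulation: planted SSRs as loci,
  # keyed by coordinates so downstream stages can map them onto the
  # independently scanned and merged locus set
  loci <- data.frame(
    locus_id = sprintf("%s:%d:%s", gen$truth$seqid, gen$truth$start,
                       gen$truth$motif),
    gen$truth, stringsAsFactors = FALSE
  )

  sheet0 <- expand.grid(replicate = seq_len(params$replicates),
                        condition = c("control", "drought"),
                        population = params$populations,
                        stringsAsFactors = FALSE)
  sheet0$sample <- sprintf("%s_%s_%d", sheet0$population,
                           substr(sheet0$condition, 1, 4), sheet0$replicate)
  calls <- simulate_ssr_calls(loci, sheet0[, c("sample", "population")],
                              seed = seed + 1L)
  utils::write.table(calls$calls, file.path(out_dir, "ssr_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls$truth, file.path(out_dir, "truth_ssr_regimes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  links <- link_ssrs_to_genes(loci, gen$genes, config$link_window_bp)
  # plant the presence effect through one locus per gene (the nearest
  # link), so each affected gene carries a single coherent presence
  # pattern
  ssr_linked <- if (nrow(links) > 0) {
    nearest <- links[order(links$gene_id, links$distance_bp), ]
    nearest <- nearest[!duplicated(nearest$gene_id), ]
    data.frame(gene = nearest$gene_id, locus_id = nearest$locus_id,
               stringsAsFactors = FALSE)
  } else NULL
  cnt <- simulate_counts(params, seed = seed + 2L, ssr_linked = ssr_linked,
                         presence = calls$calls)
  tab <- data.frame(gene = rownames(cnt$counts), cnt$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(out_dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cnt$sheet, file.path(out_dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cnt$truth$de)) {
    utils::write.table(cnt$truth$de, file.path(out_dir, "truth_de.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ppi <- simulate_ppi(params, seed = seed + 3L,
                      gene_ids = rownames(cnt$counts))
  utils::write.table(ppi$edges, file.path(out_dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(ppi$truth, file.path(out_dir, "truth_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # toy GO map: one term per graph block plus a broad term
  term_map <- rbind(
    data.frame(gene_id = ppi$truth$gene,
               term = sprintf("GO:%07d", ppi$truth$block),
               stringsAsFactors = FALSE),
    data.frame(gene_id = ppi$truth$gene[seq(1, nrow(ppi$truth), by = 2)],
               term = "GO:9999999", stringsAsFactors = FALSE)
  )
  utils::write.table(term_map, file.path(out_dir, "term_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  write_config(config, file.path(out_dir, "config.txt"))
  invisible(list(genome = gen, loci = loci, calls = calls, counts = cnt,
                 ppi = ppi, links = links, term_map = term_map))
}

.write_gff3_genes <- function(genes, path) {
  gr <- intervals_to_granges(genes)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "ssrscape", type = "gene", ID = genes$gene_id
  )
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}
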