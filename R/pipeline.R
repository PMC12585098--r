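#' Run the full analysis pipeline
#'
#' Executes every stage end to end: SSR scan, locus merge, transcribed
#' classification, population diversity, DEG calling for both
#' populations, Venn partitioning, transcriptogram (ordering, projection,
#' peaks, combined selection), SSR-gene linking, presence/absence
#' expression tests, and term overrepresentation. Stages communicate
#' only via serialized files under `out_dir`, and a manifest records the
#' configuration snapshot, seeds and input checksums, so a re-run with
#' identical inputs reproduces identical outputs.
#'
#' @param out_dir Output directory for the report bundle.
#' @param input_dir Directory holding `genome.fa`, `genes.gff3`,
#'   `counts.tsv`, `samples.tsv`, `ssr_calls.tsv`, `edges.tsv`,
#'   `term_map.tsv` (the layout written by [simulate_all()]). Ignored
#'   when `simulate = TRUE`.
#' @param simulate Generate the inputs with [simulate_all()] into
#'   `out_dir/simulated` first.
#' @param seed Integer seed for simulation and the ordering search.
#' @param config A [pipeline_config()].
#' @param params A [sim_params()] (when simulating).
#' @return Invisibly, a list of class `pipeline_bundle` with every stage
#'   result and `out_dir`.
#' @export
run_full <- function(out_dir, input_dir = NULL, simulate = FALSE, seed = 1L,
                     config = pipeline_config(), params = sim_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (simulate) {
    input_dir <- file.path(out_dir, "simulated")
    simulate_all(input_dir, params = params, seed = seed, config = config)
  }
  if (is.null(input_dir)) stop("either input_dir or simulate = TRUE required")
  need <- c("genome.fa", "genes.gff3", "counts.tsv", "samples.tsv",
            "ssr_calls.tsv", "edges.tsv", "term_map.tsv")
  for (f in need) {
    if (!file.exists(file.path(input_dir, f))) {
      stop("missing input file: ", sub("[.].*$", "", f), " (", f, ")")
    }
  }

  # --- scan & merge ---
  genome <- read_fasta(file.path(input_dir, "genome.fa"))
  genome_size <- sum(Biostrings::width(genome))
  records <- detect_ssrs(genome, config)
  loci <- merge_loci(records, config$merge_window_bp)
  genes <- read_gff3_genes(file.path(input_dir, "genes.gff3"))
  loci <- classify_transcribed(loci, genes)
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  write_gff3_ssr(loci, file.path(out_dir, "ssr_loci.gff3"), seqlens)
  summary <- landscape_summary(records, loci, genome_size)
  bias <- chi2_class_bias(summary$counts_by_class,
                          config$min_class_representation, config$chi2_alpha)
  .write_tsv(bias, file.path(out_dir, "class_bias.tsv"))

  # --- population diversity ---
  calls <- read_ssr_calls(file.path(input_dir, "ssr_calls.tsv"))
  pops <- sort(unique(calls$population))
  # the call table may reference loci either by merged-locus id or by
  # the coordinate key "<seqid>:<start>:<motif>"; map the latter onto
  # the scanned loci (a merged locus inherits the key of its leftmost
  # member's start)
  if (!all(unique(calls$locus_id) %in% loci$locus_id)) {
    key <- sprintf("%s:%d:%s", loci$seqid, loci$start, loci$motif)
    idx <- match(calls$locus_id, key)
    unmapped <- unique(calls$locus_id[is.na(idx)])
    if (length(unmapped) > 0) {
      message(length(unmapped),
              " call locus/loci did not map onto a scanned locus; dropped")
    }
    calls <- calls[!is.na(idx), , drop = FALSE]
    calls$locus_id <- loci$locus_id[idx[!is.na(idx)]]
  }
  atab <- tabulate_alleles(calls, populations = pops)
  div <- diversity_summary(atab, loci)
  .write_tsv(div$per_locus, file.path(out_dir, "diversity_classes.tsv"))

  # --- DEGs ---
  cm <- read_counts(file.path(input_dir, "counts.tsv"),
                    file.path(input_dir, "samples.tsv"))
  deg <- lapply(pops, function(p) {
    call_degs(cm$counts, cm$sheet, p, config$fc_threshold, config$p_deg)
  })
  names(deg) <- pops
  for (p in pops) {
    .write_tsv(deg[[p]], file.path(out_dir, paste0("deg_", p, ".tsv")))
  }
  venn <- venn_partition(deg[[1]], deg[[2]], labels = pops)

  # --- transcriptogram ---
  edges <- read_edges(file.path(input_dir, "edges.tsv"))
  graph <- filter_graph(edges, config$score_threshold)
  ordering <- build_ordering(graph, seed = seed)
  .write_tsv(data.frame(position = seq_along(ordering) - 1L,
                        gene = ordering),
             file.path(out_dir, "gene_ordering.tsv"))
  tg <- lapply(pops, function(p) {
    transcriptogram_profile(cm$counts, cm$sheet, p, ordering,
                            radius = config$window_radius)
  })
  names(tg) <- pops
  peaks <- lapply(tg, function(t) call_peaks(t$p_r, config$p_r30, ordering))
  selected <- lapply(pops, function(p) {
    select_candidate_degs(ordering, tg[[p]]$p_r, tg[[p]]$p_0, deg[[p]],
                          config$p_r30, config$p_r0, config$p_deg)
  })
  names(selected) <- pops
  for (p in pops) {
    .write_tsv(data.frame(position = seq_along(ordering) - 1L,
                          gene = ordering, relative = tg[[p]]$relative,
                          band = tg[[p]]$band, p_r = tg[[p]]$p_r,
                          p_0 = tg[[p]]$p_0),
               file.path(out_dir, paste0("transcriptogram_", p, ".tsv")))
    .write_tsv(peaks[[p]][, c("start", "end", "n_positions", "min_p")],
               file.path(out_dir, paste0("peaks_", p, ".tsv")))
  }

  # --- SSR-expression link ---
  links <- link_ssrs_to_genes(loci, genes, config$link_window_bp)
  presence <- calls[, c("sample", "locus_id", "present")]
  # only loci with presence calls are testable
  links_called <- links[links$locus_id %in% presence$locus_id, , drop = FALSE]
  ssr_tests <- run_all_ssr_tests(links_called, cm$counts, presence)
  .write_tsv(ssr_tests$tested, file.path(out_dir, "ssr_expression_tests.tsv"))

  term_map <- read_term_map(file.path(input_dir, "term_map.tsv"))
  study <- unique(links_called$gene_id[links_called$gene_id %in%
                                         rownames(cm$counts)])
  enrich <- if (length(study) > 0) {
    fisher_overrepresentation(study, rownames(cm$counts), term_map)
  } else NULL
  if (!is.null(enrich)) {
    .write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
  }

  write_config(config, file.path(out_dir, "config_snapshot.txt"))
  bundle <- list(
    out_dir = out_dir, input_dir = input_dir, seed = seed, config = config,
    genome_size = genome_size, records = records, loci = loci,
    landscape = summary, class_bias = bias, diversity = div,
    deg = deg, venn = venn, ordering = ordering, transcriptograms = tg,
    peaks = peaks, selected = selected, links = links_called,
    ssr_tests = ssr_tests, enrichment = enrich, populations = pops
  )
  class(bundle) <- "pipeline_bundle"
  manifest <- .build_manifest(bundle, input_dir, need)
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  report_summary(bundle, file.path(out_dir, "summary.tsv"))
  invisible(bundle)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.build_manifest <- function(bundle, input_dir, files) {
  sums <- vapply(files, function(f) {
    as.character(tools::md5sum(file.path(input_dir, f)))
  }, character(1))
  # record the input location relative to the bundle when nested inside
  # it, so identical runs into different directories stay byte-identical
  shown_dir <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                                    normalizePath(bundle$out_dir)), "/?"),
                   "", normalizePath(input_dir))
  c(
    "# run manifest",
    paste0("seed = ", bundle$seed),
    paste0("input_dir = ", shown_dir),
    paste0("input_md5 ", files, " = ", sums),
    "config:",
    vapply(names(bundle$config), function(k) {
      paste0("  ", k, " = ", paste(bundle$config[[k]], collapse = ","))
    }, character(1))
  )
}

#' DEG total from printed up/down counts
#'
#' Reporting arithmetic: total differentially expressed genes as the sum
#' of the up- and down-regulated counts.
#'
#' @param n_up,n_down Non-negative counts.
#' @return `n_up + n_down`.
#' @examples
#' deg_total(5906, 5232)  # 11138
#' @export
deg_total <- function(n_up, n_down) {
  stopifnot(n_up >= 0, n_down >= 0)
  n_up + n_down
}

#' Summarize a pipeline bundle
#'
#' Emits the run's headline numbers (SSR totals by motif length, compound
#' count, density, DEG totals per population, transcriptogram peak
#' counts, selected candidate genes, significant SSR-expression links)
#' as a two-column TSV, and returns them as a named list.
#'
#' @param bundle A `pipeline_bundle` from [run_full()].
#' @param path Optional TSV output path.
#' @return Named list of summary values.
#' @export
report_summary <- function(bundle, path = NULL) {
  if (!inherits(bundle, "pipeline_bundle")) stop("incomplete bundle")
  ls <- bundle$landscape
  pops <- bundle$populations
  out <- list(
    genome_size_bp = bundle$genome_size,
    total_ssrs = ls$total_ssrs,
    n_compound = ls$n_compound,
    density_per_mb = ls$density_per_mb,
    n_sequences_with_ssr = ls$n_sequences_with_ssr,
    n_sequences_with_multiple = ls$n_sequences_with_multiple
  )
  for (k in 1:6) {
    out[[paste0("ssr_len_", k)]] <- unname(ls$counts_by_motif_length[k])
  }
  for (p in pops) {
    d <- bundle$deg[[p]]
    out[[paste0("deg_up_", p)]] <- sum(d$direction == "up")
    out[[paste0("deg_down_", p)]] <- sum(d$direction == "down")
    out[[paste0("deg_total_", p)]] <- sum(d$direction != "ns")
    out[[paste0("peaks_", p)]] <- nrow(bundle$peaks[[p]])
    out[[paste0("selected_", p)]] <- length(bundle$selected[[p]])
  }
  out$venn_shared_up <- unname(bundle$venn$counts["shared_up"])
  out$venn_shared_down <- unname(bundle$venn$counts["shared_down"])
  out$venn_discordant <- unname(bundle$venn$counts["discordant"])
  out$ssr_tests_n <- nrow(bundle$ssr_tests$tested)
  out$ssr_tests_p05 <- sum(bundle$ssr_tests$tested$p < 0.05)
  out$ssr_tests_q05 <- sum(bundle$ssr_tests$tested$q < 0.05)
  if (!is.null(path)) {
    .write_tsv(data.frame(item = names(out),
                          value = unlist(lapply(out, as.character))),
               path)
  }
  out
}
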