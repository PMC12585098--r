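#' Pipeline configuration
#'
#' Collects every numeric threshold the analysis uses into one validated
#' list. Defaults are the study-wide settings: association-score filter
#' strictly above 800, transcriptogram window radius 30 (61-gene interior
#' windows), DEG thresholds |FC| >= 1.5 at p < 0.05, combined-selection
#' cutoffs R30 p < 0.01 and R0 p < 0.05, 100 bp same-sequence locus merging,
#' 2 kbp SSR-to-gene linking, chi-square confidence 0.01 with a 0.5%
#' class-representation floor, and MISA-convention minimum repeat counts
#' (mono 10, di 6, tri/tetra/penta/hexa 5) with a 100 bp compound
#' interruption.
#'
#' @param window_radius Transcriptogram window half-width in genes.
#' @param score_threshold Association combined-score filter (strictly
#'   greater-than), on the 0-1000 scale.
#' @param fc_threshold Fold-change cutoff for DEG calling (applied
#'   symmetrically: FC >= fc_threshold or FC <= 1/fc_threshold).
#' @param p_deg Raw p-value cutoff for DEG calling.
#' @param p_r30,p_r0 Radius-30 and radius-0 p-value cutoffs for combined
#'   candidate selection.
#' @param merge_window_bp Maximum gap for merging same-sequence SSRs into
#'   one locus.
#' @param link_window_bp Maximum gap for linking an SSR locus to a gene
#'   (inclusive).
#' @param chi2_alpha Significance level for composition chi-square tests.
#' @param min_class_representation Minimum within-division share a motif
#'   class must exceed to be tested.
#' @param ssr_min_repeats Integer vector of length 6: minimum repeat count
#'   for motif lengths 1..6.
#' @param compound_max_interruption_bp Maximum gap between SSRs reported
#'   jointly as a compound.
#' @param rng_seed Integer seed recorded with the configuration.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_radius = 30L,
                            score_threshold = 800L,
                            fc_threshold = 1.5,
                            p_deg = 0.05,
                            p_r30 = 0.01,
                            p_r0 = 0.05,
                            merge_window_bp = 100L,
                            link_window_bp = 2000L,
                            chi2_alpha = 0.01,
                            min_class_representation = 0.005,
                            ssr_min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                            compound_max_interruption_bp = 100L,
                            rng_seed = 1L) {
  stopifnot(
    window_radius >= 1, score_threshold > 0, fc_threshold > 0,
    merge_window_bp > 0, link_window_bp > 0,
    compound_max_interruption_bp > 0,
    length(ssr_min_repeats) == 6, all(ssr_min_repeats >= 1)
  )
  for (p in c(p_deg, p_r30, p_r0, chi2_alpha)) {
    if (!(p > 0 && p < 1)) stop("p-value thresholds must lie in (0, 1)")
  }
  cfg <- list(
    window_radius = as.integer(window_radius),
    score_threshold = as.integer(score_threshold),
    fc_threshold = fc_threshold,
    p_deg = p_deg, p_r30 = p_r30, p_r0 = p_r0,
    merge_window_bp = as.integer(merge_window_bp),
    link_window_bp = as.integer(link_window_bp),
    chi2_alpha = chi2_alpha,
    min_class_representation = min_class_representation,
    ssr_min_repeats = as.integer(ssr_min_repeats),
    compound_max_interruption_bp = as.integer(compound_max_interruption_bp),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a configuration file
#'
#' Plain `key = value` text (one per line, `#` comments);
#' `ssr_min_repeats` takes six comma-separated integers. Keys not present
#' keep their defaults; unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(formals(pipeline_config))) {
      stop("unknown config key: ", key)
    }
    args[[key]] <- if (key == "ssr_min_repeats") {
      as.integer(strsplit(val, ",")[[1]])
    } else {
      as.numeric(val)
    }
  }
  do.call(pipeline_config, args)
}

#' Write a configuration snapshot
#'
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}
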