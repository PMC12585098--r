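#' Detect perfect microsatellites in sequences
#'
#' MISA-style scanner for perfect tandem repeats of primitive motifs of
#' length 1--6. Every maximal whole-unit run meeting the minimum repeat
#' count for its motif length is reported once, assigned to its shortest
#' primitive motif; runs are broken at N. Two or more SSRs separated by at
#' most `compound_max_interruption_bp` are additionally reported as one
#' compound record whose members are retained.
#'
#' Scanning is vectorized per period: positions where the sequence equals
#' itself shifted by k delimit maximal k-periodic stretches; a stretch of
#' length L yields floor(L/k) whole units anchored at its left end, and
#' the unit-level maximality of that run follows from the stretch being
#' maximal.
#'
#' @param seqs A named [Biostrings::DNAStringSet], named character vector,
#'   or single unnamed sequence string.
#' @param config A [pipeline_config()] supplying `ssr_min_repeats` and
#'   `compound_max_interruption_bp`.
#' @return Data.frame of SSR records with columns `ssr_id`, `seqid`,
#'   `start`, `end` (0-based half-open), `motif`, `motif_length`,
#'   `n_repeats`, `is_compound`, `in_compound`, and list-column `members`
#'   (member `ssr_id`s for compound rows).
#' @export
detect_ssrs <- function(seqs, config = pipeline_config()) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.character(seqs) && is.null(names(seqs))) {
    if (length(seqs) != 1) stop("multiple sequences require names")
    names(seqs) <- "seq1"
  }
  parts <- lapply(names(seqs), function(id) {
    .detect_one(id, seqs[[id]], config$ssr_min_repeats)
  })
  simple <- do.call(rbind, parts)
  if (is.null(simple) || nrow(simple) == 0) {
    return(.empty_ssr_df())
  }
  simple <- simple[order(simple$seqid, simple$start, simple$end), , drop = FALSE]
  simple$ssr_id <- sprintf("SSR%06d", seq_len(nrow(simple)))
  simple$is_compound <- FALSE
  simple$in_compound <- FALSE
  simple$members <- replicate(nrow(simple), character(0), simplify = FALSE)

  compounds <- .compound_groups(simple, config$compound_max_interruption_bp)
  out <- rbind(simple, compounds)
  rownames(out) <- NULL
  mark_compound_members(out)
}

.empty_ssr_df <- function() {
  data.frame(
    ssr_id = character(), seqid = character(), start = integer(),
    end = integer(), motif = character(), motif_length = integer(),
    n_repeats = integer(), is_compound = logical(), in_compound = logical(),
    members = I(list()), stringsAsFactors = FALSE
  )
}

.detect_one <- function(id, s, min_repeats) {
  n <- nchar(s)
  if (n == 0) return(NULL)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  is_n <- chars == "N"
  out <- vector("list", 6)
  for (k in 1:6) {
    min_len <- k * min_repeats[k]
    if (n < min_len) next
    idx <- seq_len(n - k)
    eq <- chars[idx] == chars[idx + k] & !is_n[idx] & !is_n[idx + k]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & (r$lengths + k) >= min_len)
    if (length(keep) == 0) next
    recs <- lapply(keep, function(j) {
      i <- starts[j]                       # 1-based start of periodic stretch
      L <- r$lengths[j] + k                # stretch length in bases
      motif <- substr(s, i, i + k - 1L)
      if (!.is_primitive(motif)) return(NULL)
      nrep <- L %/% k
      data.frame(seqid = id, start = i - 1L, end = i - 1L + nrep * k,
                 motif = motif, motif_length = k, n_repeats = nrep,
                 stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, recs)
  }
  do.call(rbind, out)
}

.is_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1) return(TRUE)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 &&
        motif == paste(rep(substr(motif, 1, d), k / d), collapse = "")) {
      return(FALSE)
    }
  }
  TRUE
}

.compound_groups <- function(simple, max_gap) {
  comp <- list()
  next_id <- 1L
  for (sid in unique(simple$seqid)) {
    rows <- which(simple$seqid == sid)
    if (length(rows) < 2) next
    starts <- simple$start[rows]
    ends <- simple$end[rows]
    # single linkage on inter-SSR gap (running envelope end handles overlaps)
    grp <- integer(length(rows))
    grp[1] <- 1L
    env_end <- ends[1]
    for (i in 2:length(rows)) {
      if (starts[i] - env_end <= max_gap) {
        grp[i] <- grp[i - 1]
      } else {
        grp[i] <- grp[i - 1] + 1L
      }
      env_end <- max(env_end, ends[i])
    }
    for (g in unique(grp)) {
      m <- rows[grp == g]
      if (length(m) < 2) next
      simple$in_compound[m] <- TRUE  # local copy; flags returned below
      comp[[length(comp) + 1]] <- data.frame(
        ssr_id = sprintf("CSSR%05d", next_id),
        seqid = sid, start = min(simple$start[m]), end = max(simple$end[m]),
        motif = NA_character_, motif_length = NA_integer_,
        n_repeats = NA_integer_, is_compound = TRUE, in_compound = FALSE,
        members = I(list(simple$ssr_id[m])), stringsAsFactors = FALSE
      )
    }
  }
  if (length(comp) == 0) {
    return(.empty_ssr_df())
  }
  do.call(rbind, comp)
}

# detect_ssrs loses the in_compound flags set inside .compound_groups'
# local copy; recompute them from the compound members.
#' Flag simple SSR records that belong to a compound
#' @param records Output of [detect_ssrs()].
#' @return The records with `in_compound` set on member rows.
#' @keywords internal
mark_compound_members <- function(records) {
  member_ids <- unlist(records$members[records$is_compound])
  records$in_compound <- !records$is_compound & records$ssr_id %in% member_ids
  records
}

#' Canonical motif class label
#'
#' The class of a motif is its equivalence class under cyclic rotation and
#' reverse complementation, written "X/Y" where X is the lexicographically
#' smallest string among all rotations of the motif and of its reverse
#' complement, and Y is the smallest rotation of the reverse complement of
#' X. The label is identical for a motif, any rotation of it, and its
#' reverse complement, collapsing strand and phase ambiguity (e.g. GA, AG,
#' TC and CT all map to "AG/CT").
#'
#' @param motif A primitive motif of length 1--6 over A/C/G/T (vectorized).
#' @return Character vector of class labels.
#' @examples
#' canonical_class("GA")   # "AG/CT"
#' canonical_class("TTC")  # "AAG/CTT"
#' @export
canonical_class <- function(motif) {
  if (length(motif) == 0) return(character(0))
  u <- unique(motif)
  bad <- grepl("[^ACGT]", u) | nchar(u) < 1 | nchar(u) > 6
  if (any(bad)) stop("invalid motif(s): ", paste(u[bad], collapse = ", "))
  if (!all(vapply(u, .is_primitive, logical(1)))) {
    stop("non-primitive motif(s): ",
         paste(u[!vapply(u, .is_primitive, logical(1))], collapse = ", "))
  }
  labels <- vapply(u, .canonical_one, character(1))
  unname(labels[match(motif, u)])
}

.rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i) {
    paste0(substr(m, i, k), substr(m, 1, i - 1))
  }, character(1))
}

.revcomp <- function(m) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(m, "")[[1]]), collapse = ""))
}

.canonical_one <- function(m) {
  x <- min(c(.rotations(m), .rotations(.revcomp(m))))
  y <- min(.rotations(.revcomp(x)))
  paste0(x, "/", y)
}

#' Merge nearby same-sequence SSRs into loci
#'
#' Single-linkage merge of simple SSR records on the same sequence with an
#' identical motif string whose gap (end of one to start of the next) is
#' at most `merge_window_bp`. The locus interval is the envelope of its
#' members. Compound records are ignored for merging.
#'
#' @param records Output of [detect_ssrs()].
#' @param merge_window_bp Maximum gap in bp (default 100).
#' @return Data.frame of loci: `locus_id`, `seqid`, `start`, `end`,
#'   `motif`, `motif_length`, `class`, `n_repeats` (maximum over members),
#'   `n_members`, list-column `members` (member ssr_ids), `transcribed`
#'   (initialized FALSE).
#' @export
merge_loci <- function(records, merge_window_bp = 100L) {
  simple <- records[!records$is_compound, , drop = FALSE]
  if (nrow(simple) == 0) {
    return(data.frame(locus_id = character(), seqid = character(),
                      start = integer(), end = integer(), motif = character(),
                      motif_length = integer(), class = character(),
                      n_repeats = integer(), n_members = integer(),
                      members = I(list()), transcribed = logical(),
                      stringsAsFactors = FALSE))
  }
  o <- order(simple$seqid, simple$start, simple$end)
  if (any(o != seq_along(o))) {
    warning("SSR records were not sorted by (seqid, start); sorting")
    simple <- simple[o, , drop = FALSE]
  }
  key <- paste(simple$seqid, simple$motif, sep = "\r")
  loci <- list()
  for (kk in unique(key)) {
    rows <- which(key == kk)
    grp <- integer(length(rows))
    grp[1] <- 1L
    if (length(rows) > 1) {
      env_end <- simple$end[rows[1]]
      for (i in 2:length(rows)) {
        gap <- simple$start[rows[i]] - env_end
        grp[i] <- if (gap <= merge_window_bp) grp[i - 1] else grp[i - 1] + 1L
        env_end <- max(env_end, simple$end[rows[i]])
      }
    }
    for (g in unique(grp)) {
      m <- rows[grp == g]
      loci[[length(loci) + 1]] <- data.frame(
        seqid = simple$seqid[m[1]],
        start = min(simple$start[m]), end = max(simple$end[m]),
        motif = simple$motif[m[1]],
        motif_length = simple$motif_length[m[1]],
        n_repeats = max(simple$n_repeats[m]),
        n_members = length(m),
        members = I(list(simple$ssr_id[m])),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, loci)
  out <- out[order(out$seqid, out$start, out$end, out$motif), , drop = FALSE]
  out$locus_id <- sprintf("L%06d", seq_len(nrow(out)))
  out$class <- canonical_class(out$motif)
  out$transcribed <- FALSE
  rownames(out) <- NULL
  out[, c("locus_id", "seqid", "start", "end", "motif", "motif_length",
          "class", "n_repeats", "n_members", "members", "transcribed")]
}

#' Flag transcribed SSR loci
#'
#' A locus is transcribed iff its interval overlaps (non-empty half-open
#' intersection) at least one transcript interval.
#'
#' @param loci Data.frame of loci from [merge_loci()].
#' @param transcript_intervals Data.frame with `seqid`, `start`, `end`
#'   (0-based half-open), same coordinate system as the loci.
#' @return The loci with the `transcribed` column set.
#' @export
classify_transcribed <- function(loci, transcript_intervals) {
  loci$transcribed <- FALSE
  if (nrow(loci) == 0 || is.null(transcript_intervals) ||
      nrow(transcript_intervals) == 0) {
    return(loci)
  }
  gr_l <- intervals_to_granges(loci)
  gr_t <- intervals_to_granges(transcript_intervals)
  hits <- GenomicRanges::findOverlaps(gr_l, gr_t, ignore.strand = TRUE)
  loci$transcribed[unique(S4Vectors::queryHits(hits))] <- TRUE
  loci
}

.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Summarize the genomic SSR landscape
#'
#' Tallies SSRs by motif length and canonical class, counts compound
#' formations, and reports density per Mb. By default simple monomeric
#' repeats are excluded from tallies and totals (the reporting convention
#' used here); per-length counts cover simple records outside compounds,
#' so per-length counts plus the compound count add up to the total.
#'
#' @param records Output of [detect_ssrs()].
#' @param loci Output of [merge_loci()]/[classify_transcribed()]; used for
#'   the per-class transcribed/untranscribed tallies.
#' @param genome_size_bp Total genome size in bp (> 0).
#' @param include_monomers Keep simple monomeric repeats (default FALSE).
#' @return A list of class `landscape_summary`: `total_ssrs`, `n_compound`,
#'   `counts_by_motif_length` (named 1..6), `counts_by_class` (data.frame
#'   class/motif_length/transcribed/untranscribed), `density_per_mb`,
#'   `n_sequences_with_ssr`, `n_sequences_with_multiple`.
#' @export
landscape_summary <- function(records, loci, genome_size_bp,
                              include_monomers = FALSE) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be > 0")
  records <- mark_compound_members(records)
  simple <- records[!records$is_compound, , drop = FALSE]
  if (!include_monomers) {
    simple <- simple[simple$motif_length > 1, , drop = FALSE]
    loci <- loci[loci$motif_length > 1, , drop = FALSE]
  }
  counted <- simple[!simple$in_compound, , drop = FALSE]
  by_len <- vapply(1:6, function(k) sum(counted$motif_length == k), integer(1))
  names(by_len) <- as.character(1:6)
  n_compound <- sum(records$is_compound)
  total <- sum(by_len) + n_compound

  if (nrow(loci) > 0) {
    agg_t <- stats::aggregate(
      cbind(transcribed = loci$transcribed,
            untranscribed = !loci$transcribed) ~ class + motif_length,
      data = loci, FUN = sum
    )
  } else {
    agg_t <- data.frame(class = character(), motif_length = integer(),
                        transcribed = integer(), untranscribed = integer())
  }

  comp_seq <- records$seqid[records$is_compound]
  tab <- table(c(counted$seqid, comp_seq))
  out <- list(
    total_ssrs = total,
    n_compound = n_compound,
    counts_by_motif_length = by_len,
    counts_by_class = agg_t,
    density_per_mb = .round2(total / (genome_size_bp / 1e6)),
    n_sequences_with_ssr = length(tab),
    n_sequences_with_multiple = sum(tab > 1)
  )
  class(out) <- "landscape_summary"
  out
}

#' SSR density per Mb from printed tallies
#'
#' Reporting arithmetic: total SSRs (per-length counts plus compounds)
#' divided by the genome size in Mb, rounded half-up to two decimals.
#'
#' @param counts_by_length Named or unnamed vector of per-length counts.
#' @param n_compound Number of compound SSRs.
#' @param genome_size_bp Genome size in bp.
#' @return List with `total` and `density_per_mb`.
#' @examples
#' ssr_density(c(38239, 13243, 1533, 607, 465), 932, 385104457)
#' @export
ssr_density <- function(counts_by_length, n_compound, genome_size_bp) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be > 0")
  total <- sum(counts_by_length) + n_compound
  list(total = total,
       density_per_mb = .round2(total / (genome_size_bp / 1e6)))
}

#' Chi-square tests of class composition bias
#'
#' Within each motif-length division, tests whether each canonical class's
#' (transcribed, untranscribed) split deviates from the division-wide
#' split: a one-df goodness-of-fit chi-square without continuity
#' correction. Classes at or below the representation floor (share of the
#' division total) are excluded from testing and marked as such.
#'
#' @param counts_by_class Data.frame with `class`, `motif_length`,
#'   `transcribed`, `untranscribed` (as in [landscape_summary()]).
#' @param min_class_representation Representation floor (default 0.005,
#'   i.e. a class must exceed 0.5% of its division).
#' @param alpha Significance level for the `significant` flag (default 0.01).
#' @return Data.frame with per-class `representation`, `tested`, `stat`,
#'   `df`, `p`, `significant`.
#' @export
chi2_class_bias <- function(counts_by_class, min_class_representation = 0.005,
                            alpha = 0.01) {
  df <- counts_by_class
  out <- df
  out$representation <- NA_real_
  out$tested <- FALSE
  out$stat <- NA_real_
  out$df <- NA_integer_
  out$p <- NA_real_
  out$significant <- FALSE
  for (len in unique(df$motif_length)) {
    rows <- which(df$motif_length == len)
    div_t <- sum(df$transcribed[rows])
    div_u <- sum(df$untranscribed[rows])
    div_total <- div_t + div_u
    if (div_total == 0) stop("division with zero total: motif length ", len)
    p_exp <- c(div_t, div_u) / div_total
    for (i in rows) {
      obs <- c(df$transcribed[i], df$untranscribed[i])
      rep_i <- sum(obs) / div_total
      out$representation[i] <- rep_i
      if (rep_i <= min_class_representation) next
      expd <- sum(obs) * p_exp
      contrib <- ifelse(expd > 0, (obs - expd)^2 / expd,
                        ifelse(obs > 0, Inf, 0))
      stat <- sum(contrib)
      out$tested[i] <- TRUE
      out$stat[i] <- stat
      out$df[i] <- 1L
      out$p[i] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
      out$significant[i] <- out$p[i] < alpha
    }
  }
  out
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("SSR landscape summary\n")
  cat("  total SSRs:           ", x$total_ssrs, "\n")
  cat("  compound formations:  ", x$n_compound, "\n")
  cat("  by motif length:      ",
      paste(names(x$counts_by_motif_length), x$counts_by_motif_length,
            sep = "=", collapse = " "), "\n")
  cat("  density (u/Mb):       ", sprintf("%.2f", x$density_per_mb), "\n")
  cat("  sequences with SSRs:  ", x$n_sequences_with_ssr,
      " (>1: ", x$n_sequences_with_multiple, ")\n", sep = "")
  invisible(x)
}
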