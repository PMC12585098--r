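#' Tabulate observed SSR alleles per population
#'
#' Builds, for each locus, the set of observed alleles (repeat counts) in
#' each population from per-sample calls. Duplicate observations collapse
#' by set union.
#'
#' @param calls Data.frame with columns `sample`, `population`, `locus_id`,
#'   `repeat_count`.
#' @param populations Valid population labels (default `c("RE", "RF")`).
#' @return A named list (by locus) of lists mapping population to an
#'   integer vector of distinct alleles; class `allele_table`.
#' @export
tabulate_alleles <- function(calls, populations = c("RE", "RF")) {
  calls <- calls[!is.na(calls$repeat_count), , drop = FALSE]
  if ("present" %in% names(calls)) {
    calls <- calls[as.logical(calls$present), , drop = FALSE]
  }
  if (nrow(calls) > 0) {
    bad <- setdiff(unique(calls$population), populations)
    if (length(bad) > 0) {
      stop("unknown population label(s): ", paste(bad, collapse = ", "))
    }
    if (any(calls$repeat_count < 1)) stop("repeat counts must be >= 1")
  }
  tab <- list()
  if (nrow(calls) > 0) {
    for (locus in unique(calls$locus_id)) {
      sub <- calls[calls$locus_id == locus, , drop = FALSE]
      entry <- lapply(populations, function(p) {
        sort(unique(as.integer(sub$repeat_count[sub$population == p])))
      })
      names(entry) <- populations
      tab[[locus]] <- entry
    }
  }
  structure(tab, populations = populations, class = "allele_table")
}

#' Classify a locus's diversity distribution between two populations
#'
#' Presence-based classification of where a locus's allelic diversity
#' resides: `exclusive_X` if only population X holds alleles; `equal` if
#' both allele sets are identical; `preferential_X` if the sets differ and
#' X holds strictly more distinct alleles. Differing sets of equal size
#' cannot be attributed to either side and are labeled `ambiguous`.
#'
#' @param alleles_a,alleles_b Integer vectors of distinct alleles for the
#'   two populations.
#' @param labels The two population labels, in the same order.
#' @return One of `exclusive_<A>`, `exclusive_<B>`, `equal`,
#'   `preferential_<A>`, `preferential_<B>`, `ambiguous`.
#' @export
classify_diversity <- function(alleles_a, alleles_b, labels = c("RE", "RF")) {
  a <- unique(alleles_a)
  b <- unique(alleles_b)
  if (length(a) == 0 && length(b) == 0) {
    stop("locus with no observed alleles in either population")
  }
  if (length(b) == 0) return(paste0("exclusive_", labels[1]))
  if (length(a) == 0) return(paste0("exclusive_", labels[2]))
  if (setequal(a, b)) return("equal")
  if (length(a) > length(b)) return(paste0("preferential_", labels[1]))
  if (length(b) > length(a)) return(paste0("preferential_", labels[2]))
  # equal-size differing sets: each side holds >= 1 private allele, so a
  # single attributable allele cannot exist; surfaced rather than forced
  priv_a <- setdiff(a, b)
  priv_b <- setdiff(b, a)
  if (length(priv_a) + length(priv_b) == 1) {
    side <- if (length(priv_a) == 1) labels[1] else labels[2]
    return(paste0("preferential_", side))
  }
  "ambiguous"
}

#' Cross-tabulate diversity classes
#'
#' Classifies every locus in an allele table and cross-tabulates the
#' classes by motif length, with a transcribed-only view.
#'
#' @param table An `allele_table` from [tabulate_alleles()].
#' @param loci Data.frame of loci carrying `locus_id`, `motif_length`,
#'   `transcribed`.
#' @return List with `per_locus` (data.frame locus_id/class), `by_length`
#'   (class x motif length counts, all loci) and `by_length_transcribed`
#'   (same, transcribed loci only).
#' @export
diversity_summary <- function(table, loci) {
  pops <- attr(table, "populations")
  classes <- c(paste0("exclusive_", pops), "equal",
               paste0("preferential_", pops), "ambiguous")
  per_locus <- data.frame(
    locus_id = names(table),
    class = vapply(table, function(e) {
      classify_diversity(e[[pops[1]]], e[[pops[2]]], pops)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_locus) <- NULL
  idx <- match(per_locus$locus_id, loci$locus_id)
  per_locus$motif_length <- loci$motif_length[idx]
  per_locus$transcribed <- loci$transcribed[idx]

  xt <- function(d) {
    lens <- sort(unique(loci$motif_length))
    m <- matrix(0L, nrow = length(classes), ncol = length(lens),
                dimnames = list(classes, as.character(lens)))
    if (nrow(d) > 0) {
      t0 <- table(factor(d$class, levels = classes),
                  factor(d$motif_length, levels = lens))
      m[] <- as.integer(t0)
    }
    m
  }
  list(
    per_locus = per_locus,
    by_length = xt(per_locus),
    by_length_transcribed = xt(per_locus[which(per_locus$transcribed), ,
                                         drop = FALSE])
  )
}

#' Chi-square test of exclusive-SSR bias between populations
#'
#' One-df goodness-of-fit of the (exclusive-to-A, exclusive-to-B) counts
#' against an expected 50/50 split.
#'
#' @param e_a,e_b Exclusive-locus counts for the two populations.
#' @return List with `stat` and `p`.
#' @examples
#' chi2_exclusive_bias(20, 5)  # stat 9, p ~ 0.0027
#' @export
chi2_exclusive_bias <- function(e_a, e_b) {
  total <- e_a + e_b
  if (total <= 0) stop("no exclusive loci to test")
  expd <- total / 2
  stat <- (e_a - expd)^2 / expd + (e_b - expd)^2 / expd
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Read per-sample SSR calls
#'
#' @param path TSV with header columns `sample`, `population`, `locus_id`,
#'   `repeat_count` (and optionally `present`).
#' @return Data.frame of calls.
#' @export
read_ssr_calls <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("sample", "population", "locus_id", "repeat_count")
  if (!all(req %in% names(df))) {
    stop("SSR call table must have columns: ", paste(req, collapse = ", "))
  }
  df
}
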