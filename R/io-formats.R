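#' Read a multi-record FASTA file
#'
#' Sequences are lifted to uppercase; any character outside A/C/G/T/N is
#' replaced by N with a warning. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_fasta <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(Biostrings::width(raw) == 0)) {
    stop("empty sequence(s): ",
         paste(ids[Biostrings::width(raw) == 0], collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained non-ACGTN characters; ",
            "replaced with N")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a FASTA file
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a scored association edge list
#'
#' Three whitespace-delimited columns: node, node, combined score on the
#' 0--1000 scale. Self-loops are dropped with a warning; duplicate
#' undirected pairs keep the maximum score.
#'
#' @param path Path to the edge list.
#' @return A data.frame with columns `node1`, `node2`, `score`.
#' @export
read_edges <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("node1", "node2", "score"),
                          colClasses = c("character", "character", "character"),
                          comment.char = "#")
  score_num <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score_num) || any(score_num != as.integer(score_num))) {
    stop("non-integer association score(s) in ", path)
  }
  score <- as.integer(score_num)
  if (any(score < 0 | score > 1000)) stop("association scores must be in 0..1000")
  df$score <- score
  self <- df$node1 == df$node2
  if (any(self)) {
    warning("dropped ", sum(self), " self-loop edge(s)")
    df <- df[!self, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    return(data.frame(node1 = character(), node2 = character(),
                      score = integer(), stringsAsFactors = FALSE))
  }
  # canonical undirected orientation, then max-score dedup
  a <- pmin(df$node1, df$node2)
  b <- pmax(df$node1, df$node2)
  key <- paste(a, b, sep = "\r")
  n_in <- nrow(df)
  agg <- tapply(df$score, key, max)
  keys <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(
    node1 = vapply(keys, `[`, character(1), 1),
    node2 = vapply(keys, `[`, character(1), 2),
    score = as.integer(agg),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (nrow(out) < n_in) {
    message("merged ", n_in - nrow(out), " duplicate undirected edge(s), keeping max score")
  }
  out[order(out$node1, out$node2), , drop = FALSE]
}

#' Read a count matrix and its sample sheet
#'
#' The count TSV has gene ids in the first column and one named column per
#' sample; the sheet TSV has columns `sample`, `population`, `condition`,
#' `replicate` and must cover exactly the matrix's samples.
#'
#' @param path Path to the gene x sample count TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return A list with `counts` (integer matrix, genes x samples) and
#'   `sheet` (data.frame).
#' @export
read_counts <- function(path, sample_sheet_path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count matrix needs a gene column plus >= 1 sample")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene id(s) in count matrix")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0) || any(m != floor(m))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  sheet <- utils::read.delim(sample_sheet_path, header = TRUE,
                             stringsAsFactors = FALSE)
  req <- c("sample", "population", "condition", "replicate")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  missing <- setdiff(colnames(m), sheet$sample)
  if (length(missing) > 0) {
    stop("sample(s) missing from sheet: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(sheet$sample, colnames(m))
  if (length(extra) > 0) {
    stop("sheet sample(s) absent from matrix: ", paste(extra, collapse = ", "))
  }
  sheet <- sheet[match(colnames(m), sheet$sample), , drop = FALSE]
  rownames(sheet) <- NULL
  list(counts = m, sheet = sheet)
}

#' Convert internal 0-based half-open intervals to GRanges
#'
#' Internal coordinates are 0-based half-open; GRanges (and GFF3) are
#' 1-based inclusive, so start maps to start + 1 and end is unchanged.
#'
#' @param df Data.frame with `seqid`, `start`, `end` and optionally `strand`.
#' @param seqlens Optional named vector of sequence lengths.
#' @return A [GenomicRanges::GRanges].
#' @export
intervals_to_granges <- function(df, seqlens = NULL) {
  stopifnot(all(df$start < df$end), all(df$start >= 0))
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (!is.null(seqlens)) {
    GenomeInfoDb::seqlengths(gr) <- seqlens[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Convert GRanges back to internal 0-based half-open intervals
#'
#' @param gr A [GenomicRanges::GRanges].
#' @return Data.frame with `seqid`, `start`, `end`, `strand` (0-based
#'   half-open).
#' @export
granges_to_intervals <- function(gr) {
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write merged SSR loci as GFF3
#'
#' Serializes loci (internally 0-based half-open) as 1-based inclusive
#' GFF3 `microsatellite` features with attributes `ID`, `motif`, `class`,
#' `repeats` and `transcribed`.
#'
#' @param loci Data.frame of loci as returned by [merge_loci()] (columns
#'   `locus_id`, `seqid`, `start`, `end`, `motif`, `class`, `n_repeats`,
#'   and optionally `transcribed`).
#' @param path Output path.
#' @param seqlens Optional named vector of declared sequence lengths; any
#'   locus extending past its sequence end is an error.
#' @return `path`, invisibly.
#' @export
write_gff3_ssr <- function(loci, path, seqlens = NULL) {
  if (!is.null(seqlens) && nrow(loci) > 0) {
    unknown <- setdiff(loci$seqid, names(seqlens))
    if (length(unknown) > 0) {
      stop("loci on undeclared sequence(s): ", paste(unknown, collapse = ", "))
    }
    over <- loci$end > seqlens[loci$seqid]
    if (any(over)) {
      stop("locus interval(s) off the sequence end: ",
           paste(loci$locus_id[over], collapse = ", "))
    }
  }
  if (nrow(loci) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- intervals_to_granges(loci)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "ssrscape",
    type = "microsatellite",
    ID = loci$locus_id,
    motif = loci$motif,
    class = loci$class,
    repeats = as.character(loci$n_repeats),
    transcribed = if ("transcribed" %in% names(loci)) {
      ifelse(loci$transcribed, "true", "false")
    } else "false"
  )
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read SSR loci back from GFF3
#'
#' Inverse of [write_gff3_ssr()]: restores internal 0-based half-open
#' coordinates and the locus attributes.
#'
#' @param path Path to a GFF3 file of `microsatellite` features.
#' @return Data.frame of loci.
#' @export
read_gff3_ssr <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(data.frame(locus_id = character(), seqid = character(),
                      start = integer(), end = integer(), motif = character(),
                      class = character(), n_repeats = integer(),
                      transcribed = logical(), stringsAsFactors = FALSE))
  }
  gr <- gr[gr$type == "microsatellite"]
  iv <- granges_to_intervals(gr)
  data.frame(
    locus_id = as.character(gr$ID),
    seqid = iv$seqid, start = iv$start, end = iv$end,
    motif = as.character(gr$motif),
    class = as.character(gr$class),
    n_repeats = as.integer(as.character(gr$repeats)),
    transcribed = as.character(gr$transcribed) == "true",
    stringsAsFactors = FALSE
  )
}

#' Read gene models from GFF3
#'
#' Extracts features of the requested type from a GFF3 file as a gene
#' table in internal 0-based half-open coordinates.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return Data.frame with `gene_id`, `seqid`, `start`, `end`, `strand`.
#' @export
read_gff3_genes <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  iv <- granges_to_intervals(gr)
  data.frame(
    gene_id = as.character(gr$ID),
    seqid = iv$seqid, start = iv$start, end = iv$end, strand = iv$strand,
    stringsAsFactors = FALSE
  )
}

#' Read a two-column gene-to-term map
#'
#' @param path TSV with columns gene id, term id (no header).
#' @return Data.frame with `gene_id`, `term`.
#' @export
read_term_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene_id", "term"))
  unique(df)
}

#' Printed percentage with round-half-up
#'
#' Computes `100 * numerator / denominator` rounded half-up to two
#' decimals, the convention used for all printed percentages.
#'
#' @param numerator,denominator Non-negative counts; `denominator > 0`.
#' @return The percentage, rounded half-up to 2 decimals.
#' @examples
#' percent_report(888, 2219)  # 40.02
#' @export
percent_report <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be > 0")
  v <- 100 * numerator / denominator
  floor(v * 100 + 0.5) / 100
}

#' Sequential filter accounting
#'
#' Total remaining after subtracting a list of exclusion counts from an
#' initial total; errors if the result would be negative.
#'
#' @param initial Initial count.
#' @param exclusions Numeric vector of excluded counts (each >= 0).
#' @return `initial - sum(exclusions)`.
#' @examples
#' filter_accounting(32201, c(95, 414, 245, 784))  # 30663
#' @export
filter_accounting <- function(initial, exclusions = integer()) {
  stopifnot(all(exclusions >= 0))
  out <- initial - sum(exclusions)
  if (out < 0) stop("exclusions exceed the initial count")
  out
}
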