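cfg <- pipeline_config()

test_that("simple repeat detection honors thresholds, primitivity and N breaks", {
  r <- detect_ssrs(c(s = "ACACACACACAC"), cfg)
  expect_equal(nrow(r), 1)
  expect_equal(r$motif, "AC")
  expect_equal(r$n_repeats, 6L)
  expect_equal(r$end - r$start, 12L)

  expect_equal(nrow(detect_ssrs(c(s = "ACACACACAC"), cfg)), 0)  # AC x5

  # primitive assignment: an AT run is never reported with motif ATAT...
  r <- detect_ssrs(c(s = strrep("AT", 12)), cfg)
  expect_equal(r$motif, "AT")
  expect_equal(r$n_repeats, 12L)

  # N breaks a run
  r <- detect_ssrs(c(s = paste0(strrep("AG", 6), "N", strrep("AG", 6))), cfg)
  expect_equal(nrow(r[!r$is_compound, ]), 2)

  expect_equal(nrow(detect_ssrs(c(s = ""), cfg)), 0)
})

test_that("maximality reports whole units anchored at the stretch start", {
  # AC x6 plus a trailing half unit: still 6 repeats from position 0
  r <- detect_ssrs(c(s = paste0(strrep("AC", 6), "ATT")), cfg)
  expect_equal(r$start, 0L)
  expect_equal(r$n_repeats, 6L)
  # preceded by a period-breaking base: anchor shifts right by one
  r <- detect_ssrs(c(s = paste0("G", strrep("AC", 6), "TT")), cfg)
  expect_equal(r$start, 1L)
})

test_that("compound records join SSRs separated by at most the interruption", {
  mid <- "GTCCGTACGG"  # 10 bp, no repeat
  s <- paste0(strrep("AC", 6), mid, strrep("AG", 6))
  r <- detect_ssrs(c(s = s), cfg)
  expect_equal(sum(!r$is_compound), 2)
  expect_equal(sum(r$is_compound), 1)
  comp <- r[r$is_compound, ]
  expect_equal(length(comp$members[[1]]), 2)
  expect_true(all(r$in_compound[!r$is_compound]))

  far <- paste(rep(c("GTCCGTACGG", "TGCAGTCCAA"), 6), collapse = "")  # 120 bp
  r2 <- detect_ssrs(c(s = paste0(strrep("AC", 6), far, strrep("AG", 6))), cfg)
  expect_equal(sum(r2$is_compound), 0)
})

test_that("detection matches the brute-force scanner on random sequences", {
  set.seed(421)
  for (rep in 1:4) {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)),  # AT-rich: more repeats
               collapse = "")
    got <- detect_ssrs(c(x = s), cfg)
    got <- got[!got$is_compound, c("start", "end", "motif", "n_repeats")]
    rownames(got) <- NULL
    want <- brute_force_ssrs(s, cfg$ssr_min_repeats)
    o <- order(want$start, nchar(want$motif))
    want <- want[o, , drop = FALSE]
    o2 <- order(got$start, nchar(got$motif))
    got <- got[o2, , drop = FALSE]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("detection is strand-consistent at the canonical class level", {
  set.seed(7)
  for (rep in 1:3) {
    s <- paste(c(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                 strrep("AG", 8), strrep("TTC", 6), strrep("A", 12)),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fwd <- detect_ssrs(c(x = s), cfg)
    rev <- detect_ssrs(c(x = rc), cfg)
    fc <- sort(canonical_class(fwd$motif[!fwd$is_compound]))
    rcl <- sort(canonical_class(rev$motif[!rev$is_compound]))
    expect_equal(fc, rcl)
  }
})

test_that("canonical classes match the independent definition and enumerate correctly", {
  expect_equal(canonical_class("GA"), "AG/CT")
  expect_equal(canonical_class("TTC"), "AAG/CTT")
  expect_equal(canonical_class("A"), "A/T")
  expect_equal(canonical_class("AT"), "AT/AT")
  expect_error(canonical_class("ATAT"), "non-primitive")
  expect_error(canonical_class("AX"), "invalid")

  bases <- c("A", "C", "G", "T")
  # every primitive motif up to length 4 agrees with the oracle
  for (k in 1:4) {
    motifs <- apply(expand.grid(rep(list(bases), k)), 1, paste, collapse = "")
    motifs <- motifs[vapply(motifs, oracle_is_primitive, logical(1))]
    expect_equal(canonical_class(motifs),
                 vapply(motifs, oracle_canonical_class, character(1),
                        USE.NAMES = FALSE))
  }
  # idempotence under re-canonicalization of the X part
  di <- apply(expand.grid(bases, bases), 1, paste, collapse = "")
  di <- di[vapply(di, oracle_is_primitive, logical(1))]
  cls <- unique(canonical_class(di))
  expect_setequal(cls, c("AC/GT", "AG/CT", "AT/AT", "CG/CG"))
  x_parts <- sub("/.*", "", cls)
  expect_equal(canonical_class(x_parts), cls)
})

test_that("locus merging needs identical motifs within the merge window", {
  mk <- function(starts, motif, seqid = "c") {
    k <- nchar(motif)
    data.frame(ssr_id = sprintf("S%d", seq_along(starts)), seqid = seqid,
               start = starts, end = starts + 6L * k, motif = motif,
               motif_length = k, n_repeats = 6L, is_compound = FALSE,
               in_compound = FALSE, members = I(replicate(length(starts),
                                                          character(0),
                                                          simplify = FALSE)),
               stringsAsFactors = FALSE)
  }
  # 50 bp apart: one locus
  r <- mk(c(0L, 62L), "AC")
  loci <- merge_loci(r, 100L)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_members, 2L)
  expect_equal(loci$start, 0L)
  expect_equal(loci$end, 74L)

  # 150 bp apart: two loci
  expect_equal(nrow(merge_loci(mk(c(0L, 162L), "AC"), 100L)), 2)

  # same distance, different motifs: two loci
  r2 <- rbind(mk(0L, "AC"), mk(62L, "AG"))
  r2$ssr_id <- c("S1", "S2")
  expect_equal(nrow(merge_loci(r2, 100L)), 2)

  # idempotent and order-independent
  r3 <- mk(c(0L, 62L, 300L), "AC")
  shuffled <- r3[c(3, 1, 2), ]
  expect_warning(l_shuf <- merge_loci(shuffled, 100L), "sorted")
  l_ord <- merge_loci(r3, 100L)
  expect_equal(l_shuf$start, l_ord$start)
  expect_equal(l_shuf$n_members, l_ord$n_members)
})

test_that("transcribed flags follow half-open overlap semantics", {
  loci <- data.frame(locus_id = c("L1", "L2"), seqid = "c",
                     start = c(100L, 100L), end = c(112L, 112L),
                     motif = "AC", motif_length = 2L, class = "AC/GT",
                     n_repeats = 6L, transcribed = FALSE)
  tr <- data.frame(seqid = "c", start = 0L, end = 500L)
  expect_true(all(classify_transcribed(loci, tr)$transcribed))
  # touching at the boundary is not overlap
  tr2 <- data.frame(seqid = "c", start = 112L, end = 500L)
  expect_false(any(classify_transcribed(loci, tr2)$transcribed))
  expect_false(any(classify_transcribed(loci, tr[0, ])$transcribed))
})

test_that("landscape summary reproduces brute-force tallies and density", {
  set.seed(99)
  s <- paste(c(sample(c("A", "C", "G", "T"), 20000, replace = TRUE,
                      prob = c(0.35, 0.15, 0.15, 0.35)),
               strrep("AG", 10), strrep("AAT", 8), strrep("A", 15)),
             collapse = "")
  recs <- detect_ssrs(c(x = s), cfg)
  loci <- merge_loci(recs, 100L)
  ls <- landscape_summary(recs, loci, nchar(s))
  simple <- recs[!recs$is_compound & !recs$in_compound &
                   recs$motif_length > 1, ]
  for (k in 2:6) {
    expect_equal(unname(ls$counts_by_motif_length[as.character(k)]),
                 sum(simple$motif_length == k))
  }
  expect_equal(ls$counts_by_motif_length[["1"]], 0L)  # monomers excluded
  expect_equal(ls$total_ssrs, sum(ls$counts_by_motif_length) + ls$n_compound)
  expect_equal(ls$density_per_mb,
               floor(ls$total_ssrs / (nchar(s) / 1e6) * 100 + 0.5) / 100)
  # the monomer toggle counts exactly the simple monomeric records that
  # sit outside compounds (oracle recount from the record table)
  with_mono <- landscape_summary(recs, loci, nchar(s), include_monomers = TRUE)
  marked <- ssrscape:::mark_compound_members(recs)
  expect_equal(with_mono$counts_by_motif_length[["1"]],
               sum(!marked$is_compound & !marked$in_compound &
                     marked$motif_length == 1))
  expect_gte(sum(!marked$is_compound & marked$motif_length == 1), 1L)
  expect_gte(with_mono$total_ssrs, ls$total_ssrs)

  expect_equal(landscape_summary(recs, loci, 1e6)$density_per_mb,
               landscape_summary(recs, loci, 1e6)$total_ssrs * 1.00)
  expect_error(landscape_summary(recs, loci, 0), "> 0")
})

test_that("class-composition chi-square matches the textbook formula and floor", {
  cc <- data.frame(
    class = c("AG/CT", "AC/GT", "AT/AT"),
    motif_length = 2L,
    transcribed = c(50L, 150L, 3L),
    untranscribed = c(50L, 650L, 1L)
  )
  res <- chi2_class_bias(cc, min_class_representation = 0.005)
  # division totals: 203 transcribed / 701 untranscribed of 904
  p_t <- 203 / 904
  obs <- c(50, 50)
  expd <- 100 * c(p_t, 1 - p_t)
  stat <- sum((obs - expd)^2 / expd)
  expect_equal(res$stat[res$class == "AG/CT"], stat)
  expect_equal(res$p[res$class == "AG/CT"],
               pchisq(stat, 1, lower.tail = FALSE))
  expect_equal(res$df[res$class == "AG/CT"], 1L)

  # a class whose split equals the division split scores zero
  cc2 <- data.frame(class = c("a", "b"), motif_length = 2L,
                    transcribed = c(20L, 200L), untranscribed = c(80L, 800L))
  res2 <- chi2_class_bias(cc2)
  expect_equal(res2$stat, c(0, 0))
  expect_equal(res2$p, c(1, 1))

  # representation at or below 0.5% is excluded from testing
  cc3 <- data.frame(class = c("big", "tiny"), motif_length = 2L,
                    transcribed = c(500L, 2L), untranscribed = c(494L, 2L))
  res3 <- chi2_class_bias(cc3)
  expect_false(res3$tested[res3$class == "tiny"])
  expect_true(res3$tested[res3$class == "big"])
  expect_error(chi2_class_bias(data.frame(class = "a", motif_length = 2L,
                                          transcribed = 0L,
                                          untranscribed = 0L)),
               "zero total")
})
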