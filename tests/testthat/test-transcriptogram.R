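test_that("graph filtering is strictly greater-than and drops isolated nodes", {
  e <- data.frame(node1 = c("a", "a", "b", "c"),
                  node2 = c("b", "c", "c", "d"),
                  score = c(801L, 800L, 900L, 799L))
  g <- filter_graph(e, 800L)
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$edges$score > 800))
  expect_setequal(g$nodes, c("a", "b", "c"))  # d kept no edge
})

test_that("annealed ordering reaches the exhaustive optimum on small graphs", {
  # two disjoint 4-cliques: 8 nodes, exhaustive oracle feasible
  ed <- do.call(rbind, lapply(list(1:4, 5:8), function(b) {
    p <- t(combn(b, 2))
    data.frame(node1 = sprintf("n%d", p[, 1]), node2 = sprintf("n%d", p[, 2]),
               score = 900L)
  }))
  g <- filter_graph(ed, 800L)
  o <- build_ordering(g, seed = 1)
  best <- exhaustive_min_arrangement(g$nodes, g$edges)
  expect_equal(attr(o, "cost"), best)

  # two disjoint 5-cliques: analytic block-contiguous minimum
  # (each contiguous k-clique costs (k^3 - k) / 6)
  ed5 <- do.call(rbind, lapply(list(1:5, 6:10), function(b) {
    p <- t(combn(b, 2))
    data.frame(node1 = sprintf("m%02d", p[, 1]),
               node2 = sprintf("m%02d", p[, 2]), score = 900L)
  }))
  g5 <- filter_graph(ed5, 800L)
  o5 <- build_ordering(g5, seed = 2)
  expect_equal(attr(o5, "cost"), 2 * (5^3 - 5) / 6)
  blocks <- substr(o5, 1, 3)  # cliques occupy consecutive positions
  expect_equal(length(rle(as.integer(factor(o5 %in% sprintf("m%02d", 1:5))))$lengths), 2)

  # a single edge puts its endpoints adjacent
  g1 <- filter_graph(data.frame(node1 = "a", node2 = "b", score = 900L), 800L)
  o1 <- build_ordering(g1, seed = 3)
  expect_equal(attr(o1, "cost"), 1)

  # determinism under a fixed seed
  expect_identical(build_ordering(g5, seed = 7), build_ordering(g5, seed = 7))
  expect_error(build_ordering(filter_graph(ed5[0, ], 800L)), "empty")
})

test_that("windowed projection matches brute force, is linear and contractive", {
  set.seed(8)
  n <- 200
  ordering <- sprintf("g%03d", 1:n)
  x <- setNames(rnorm(n, 10, 3), ordering)
  r <- 30L
  w <- project_expression(ordering, x, r)
  # brute-force window means, including truncated edges
  for (i in c(1, 2, 15, 31, 100, 170, 199, 200)) {
    lo <- max(1, i - r); hi <- min(n, i + r)
    expect_equal(w[i], mean(x[lo:hi]))
  }
  # interior window covers exactly 2r + 1 = 61 genes
  expect_equal(length(seq(100 - r, 100 + r)), 61)
  # constant input is a fixed point
  expect_equal(project_expression(ordering, setNames(rep(7, n), ordering), r),
               rep(7, n))
  # linearity
  y <- setNames(rnorm(n), ordering)
  expect_equal(project_expression(ordering, 2 * x + 3 * y, r),
               2 * w + 3 * project_expression(ordering, y, r))
  # smoothing contracts the range
  expect_lte(diff(range(w)), diff(range(x)))
  # missing genes impute to zero with a warning
  expect_warning(w2 <- project_expression(ordering, x[-5], r), "imputed")
  expect_error(project_expression(ordering, x, n), "radius")
})

test_that("relative profiles follow the ratio definition with pseudo-count", {
  n <- 5
  ctrl <- matrix(rep(c(100, 200, 300, 400, 500), 3), ncol = 3)
  r <- relative_profile(ctrl, ctrl)
  expect_equal(r$relative, rep(1, n))
  expect_equal(r$band, rep(0, n))
  r2 <- relative_profile(2 * ctrl, ctrl)
  # pseudo-count 0.5 keeps the ratio marginally below 2 at finite values
  expect_equal(r2$relative, (2 * ctrl[, 1] + 0.5) / (ctrl[, 1] + 0.5))
  expect_true(all(abs(r2$relative - 2) < 0.005))
  # hand computation on a toy profile
  case <- matrix(c(10, 20, 30, 40, 50,
                   12, 22, 32, 42, 52,
                   14, 24, 34, 44, 54), ncol = 3)
  rr <- relative_profile(case, ctrl)
  expect_equal(rr$relative,
               (rowMeans(case) + 0.5) / (rowMeans(ctrl) + 0.5))
  rat <- sweep(case + 0.5, 1, rowMeans(ctrl) + 0.5, "/")
  expect_equal(rr$band, apply(rat, 1, sd))
})

test_that("the per-position test matches Welch and is calibrated under the null", {
  case <- matrix(c(10, 10.1, 9.9), nrow = 1)
  ctrl <- matrix(c(20, 20.1, 19.9), nrow = 1)
  p <- window_test(case, ctrl)
  expect_lt(p, 0.01)
  expect_equal(p, t.test(case[1, ], ctrl[1, ])$p.value)

  same <- matrix(c(5, 5, 5), nrow = 1)
  expect_equal(window_test(same, same), 1)

  set.seed(14)
  a <- matrix(rnorm(300 * 3, 10), ncol = 3)
  b <- matrix(rnorm(300 * 3, 10), ncol = 3)
  p_vec <- window_test(a, b)
  oracle <- vapply(1:300, function(i) t.test(a[i, ], b[i, ])$p.value,
                   numeric(1))
  expect_equal(p_vec, oracle)
  expect_true(all(p_vec > 0 & p_vec <= 1))
})

test_that("peak calling counts maximal sub-threshold runs", {
  p <- c(0.5, 0.001, 0.001, 0.5, 0.001)
  pk <- call_peaks(p, 0.01)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$start, c(1L, 4L))
  expect_equal(pk$end, c(3L, 5L))
  expect_equal(pk$n_positions, c(2L, 1L))
  expect_equal(call_peaks(rep(0.5, 10), 0.01), call_peaks(rep(1, 10), 0.01))
  expect_equal(nrow(call_peaks(rep(0.5, 10), 0.01)), 0)
  # monotone in the threshold
  set.seed(4)
  pv <- runif(500)
  expect_lte(nrow(call_peaks(pv, 0.01)), nrow(call_peaks(pv, 0.05)) +
               sum(FALSE))
  for (th in c(0.01, 0.05, 0.1, 0.5)) {
    pk <- call_peaks(pv, th)
    if (nrow(pk) > 0) {
      # each peak is maximal: flanking positions are at or above threshold
      for (i in seq_len(nrow(pk))) {
        if (pk$start[i] > 0) expect_gte(pv[pk$start[i]], th)
        if (pk$end[i] < length(pv)) expect_gte(pv[pk$end[i] + 1], th)
        expect_true(all(pv[(pk$start[i] + 1):pk$end[i]] < th))
      }
    }
  }
})

test_that("term density tracks the windowed annotation fraction", {
  ordering <- sprintf("g%03d", 1:100)
  tm <- data.frame(gene_id = ordering[20:80], term = "GO:1")
  d <- go_density(ordering, tm, "GO:1", window = 61L)
  expect_equal(d[50], 1)  # centered block of exactly 61 annotated genes
  # brute-force fraction at arbitrary positions
  ind <- as.numeric(ordering %in% tm$gene_id)
  for (i in c(1, 10, 35, 77, 100)) {
    lo <- max(1, i - 30); hi <- min(100, i + 30)
    expect_equal(d[i], mean(ind[lo:hi]))
  }
  expect_warning(d0 <- go_density(ordering, tm, "GO:none"), "not found")
  expect_equal(d0, rep(0, 100))
})

test_that("combined candidate selection intersects the three criteria", {
  ordering <- c("a", "b", "c")
  de <- data.frame(gene = c("a", "b", "c", "zz"),
                   fold_change = 2, p = c(0.01, 0.01, 0.2, 0.001),
                   q = 0.05, direction = "up", stringsAsFactors = FALSE)
  p_r <- c(0.005, 0.005, 0.005)
  p_0 <- c(0.01, 0.2, 0.01)
  expect_warning(
    sel <- select_candidate_degs(ordering, p_r, p_0, de),
    "absent"
  )
  expect_equal(sel, "a")   # b fails R0, c fails the DE p, zz not ordered
  expect_equal(suppressWarnings(
    select_candidate_degs(ordering, rep(0.5, 3), p_0, de)), character(0))
})
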