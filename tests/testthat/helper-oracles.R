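# Independent oracles used across the suite. Each re-derives its answer
# from first principles (per-position scanning, explicit step-up loops,
# textbook formulas) rather than calling the code paths it checks.

# Quadratic per-position perfect-repeat scanner. For every start i and
# period k: the position must be the left anchor of its periodic stretch
# (no one-base extension leftwards), the motif must be primitive and
# N-free, and the stretch is walked forward base by base.
brute_force_ssrs <- function(s, min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  recs <- list()
  for (k in 1:6) {
    for (i in seq_len(n)) {
      if (i + k * min_repeats[k] - 1 > n) break
      motif <- chars[i:(i + k - 1)]
      if (any(motif == "N")) next
      # left anchor: the base before i must not continue the period
      if (i > 1 && chars[i - 1] != "N" && chars[i - 1 + k] != "N" &&
          chars[i - 1] == chars[i - 1 + k]) {
        next
      }
      # walk the periodic stretch forward
      j <- i + k
      while (j <= n && chars[j] != "N" && chars[j - k] != "N" &&
             chars[j] == chars[j - k]) {
        j <- j + 1
      }
      stretch_len <- j - i
      nrep <- stretch_len %/% k
      if (nrep < min_repeats[k]) next
      m <- paste(motif, collapse = "")
      if (!oracle_is_primitive(m)) next
      recs[[length(recs) + 1]] <- data.frame(
        start = i - 1L, end = i - 1L + nrep * k, motif = m,
        n_repeats = nrep, stringsAsFactors = FALSE
      )
    }
  }
  if (length(recs) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), n_repeats = integer()))
  }
  out <- do.call(rbind, recs)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

oracle_is_primitive <- function(m) {
  k <- nchar(m)
  if (k == 1) return(TRUE)
  for (d in seq_len(k - 1)) {
    if (k %% d != 0) next
    if (identical(strrep(substr(m, 1, d), k / d), m)) return(FALSE)
  }
  TRUE
}

# Step-up FDR adjustment written as the explicit definition.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exhaustive minimum linear-arrangement cost for small graphs.
exhaustive_min_arrangement <- function(nodes, edges) {
  stopifnot(length(nodes) <= 8)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (perm in perms(nodes)) {
    pos <- stats::setNames(seq_along(perm), perm)
    cost <- sum(abs(pos[edges$node1] - pos[edges$node2]))
    best <- min(best, cost)
  }
  best
}

# Canonical-class definition re-derived with its own string helpers.
oracle_canonical_class <- function(m) {
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  rots <- function(x) {
    k <- nchar(x)
    vapply(seq_len(k), function(i) paste0(substring(x, i, k),
                                          substring(x, 1, i - 1)),
           character(1))
  }
  x <- min(c(rots(m), rots(rc(m))))
  paste0(x, "/", min(rots(rc(x))))
}

# A small deterministic count-design fixture shared by several tests.
make_toy_counts <- function(seed = 101, n_genes = 60) {
  set.seed(seed)
  sheet <- expand.grid(replicate = 1:3, condition = c("control", "drought"),
                       population = c("RE", "RF"), stringsAsFactors = FALSE)
  sheet$sample <- sprintf("%s_%s_%d", sheet$population,
                          substr(sheet$condition, 1, 4), sheet$replicate)
  sheet <- sheet[, c("sample", "population", "condition", "replicate")]
  m <- matrix(rnbinom(n_genes * 12, mu = 100, size = 10), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sheet$sample))
  list(counts = m, sheet = sheet)
}
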