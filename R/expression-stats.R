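#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median, over genes with nonzero
#' counts in every sample, of the ratio of the sample's count to the
#' gene's geometric mean across samples.
#'
#' @param counts Gene x sample matrix of non-negative integers.
#' @return Named vector of positive size factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) stop("no gene has nonzero counts in all samples")
  lc <- log(counts[ref, , drop = FALSE])
  log_geo <- rowMeans(lc)
  sf <- exp(apply(lc - log_geo, 2, stats::median))
  stopifnot(all(sf > 0))
  sf
}

# NB log-likelihood with variance mu + alpha * mu^2 and per-sample
# normalization offsets sf (expected count mu * sf). alpha = 0 is Poisson;
# mu = 0 is a defined boundary (all-zero counts contribute 0).
.nb_ll <- function(x, mu, alpha, sf = 1) {
  if (mu <= 0) {
    return(if (all(x == 0)) 0 else -Inf)
  }
  m <- mu * sf
  if (alpha <= 0) {
    sum(stats::dpois(x, m, log = TRUE))
  } else {
    sum(stats::dnbinom(x, size = 1 / alpha, mu = m, log = TRUE))
  }
}

# Profile MLE of mu at fixed alpha. Closed form sum(x)/sum(sf) for the
# Poisson boundary and for constant offsets; otherwise Newton on the score.
.nb_mu_hat <- function(x, alpha, sf = 1) {
  if (length(sf) == 1) sf <- rep(sf, length(x))
  mu0 <- sum(x) / sum(sf)
  if (mu0 == 0) return(0)
  if (alpha <= 0 || max(sf) - min(sf) < 1e-12) return(mu0)
  r <- 1 / alpha
  mu <- mu0
  for (it in 1:50) {
    d <- mu * sf + r
    g <- sum(x) / mu - sum((x + r) * sf / d)
    h <- -sum(x) / mu^2 + sum((x + r) * sf^2 / d^2)
    step <- g / h
    mu_new <- mu - step
    if (!is.finite(mu_new) || mu_new <= 0) mu_new <- mu / 2
    if (abs(mu_new - mu) < 1e-10 * (mu + 1e-10)) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  mu
}

# Joint profile fit: common dispersion alpha, group-specific means.
# Bounded search over log(alpha), compared against the Poisson boundary.
# With cr_adjust the dispersion maximizes the Cox-Reid adjusted profile
# likelihood (penalty -0.5 log det(X'WX) = -0.5 log of the summed GLM
# working weights mu*sf/(1 + alpha*mu*sf) per group), correcting the
# downward bias of the plain dispersion MLE at small n; the returned
# log-likelihood is always the unpenalized one at the chosen alpha.
.nb_profile_fit <- function(x_groups, sf_groups, cr_adjust = FALSE) {
  prof <- function(alpha, penalized) {
    tot <- 0
    for (i in seq_along(x_groups)) {
      mu <- .nb_mu_hat(x_groups[[i]], alpha, sf_groups[[i]])
      tot <- tot + .nb_ll(x_groups[[i]], mu, alpha, sf_groups[[i]])
      if (penalized && mu > 0) {
        w <- mu * sf_groups[[i]] / (1 + alpha * mu * sf_groups[[i]])
        tot <- tot - 0.5 * log(sum(w))
      }
    }
    tot
  }
  ll0 <- prof(0, cr_adjust)
  opt <- stats::optimize(function(la) prof(exp(la), cr_adjust),
                         interval = c(log(1e-8), log(1e3)),
                         maximum = TRUE, tol = 1e-6)
  alpha <- if (opt$objective > ll0 + 1e-8) exp(opt$maximum) else 0
  mus <- vapply(seq_along(x_groups), function(i) {
    .nb_mu_hat(x_groups[[i]], alpha, sf_groups[[i]])
  }, numeric(1))
  list(alpha = alpha, log_likelihood = prof(alpha, FALSE), mu = mus)
}

#' Negative-binomial maximum-likelihood fit
#'
#' Fits mean and dispersion of NB(mu, alpha) with variance mu + alpha mu^2
#' by profile likelihood: the mean's MLE is the sample mean, and alpha is
#' found by bounded search over log(alpha) compared against the Poisson
#' boundary alpha = 0 (taken whenever the data are under-dispersed).
#' All-zero counts give mu = 0 with log-likelihood 0.
#'
#' @param counts Vector of non-negative integer counts, length >= 2.
#' @return A list of class `nb_fit`: `mu`, `alpha`, `log_likelihood`.
#' @export
nb_fit <- function(counts) {
  if (length(counts) < 2) stop("need >= 2 counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  fit <- .nb_profile_fit(list(counts), list(rep(1, length(counts))))
  structure(list(mu = fit$mu[1], alpha = fit$alpha,
                 log_likelihood = fit$log_likelihood),
            class = "nb_fit")
}

#' Two-group negative-binomial likelihood-ratio test
#'
#' Null model: one NB fit to all samples. Alternative: group-specific
#' means with either a shared dispersion (df = 1, the default) or
#' group-specific dispersions (df = 2). The statistic 2(l_alt - l_null),
#' floored at 0, is referred to the chi-square upper tail.
#'
#' @param counts Vector of non-negative integer counts.
#' @param group_labels Vector of two group labels, same length as `counts`.
#' @param shared_dispersion Share one dispersion across groups (default
#'   TRUE).
#' @param size_factors Optional per-sample normalization offsets (expected
#'   count mu * sf); default all 1.
#' @return List with `stat`, `df`, `p`, plus the null and alternative fits.
#' @export
nb_lrt_two_group <- function(counts, group_labels, shared_dispersion = TRUE,
                             size_factors = NULL) {
  stopifnot(length(counts) == length(group_labels))
  if (is.null(size_factors)) size_factors <- rep(1, length(counts))
  groups <- unique(group_labels)
  if (length(groups) != 2) stop("exactly two groups required, got: ",
                                paste(groups, collapse = ", "))
  idx <- lapply(groups, function(g) which(group_labels == g))
  for (i in 1:2) {
    if (length(idx[[i]]) == 0) stop("empty group: ", groups[i])
  }
  null_fit <- .nb_profile_fit(list(counts), list(size_factors),
                              cr_adjust = shared_dispersion)
  if (shared_dispersion) {
    # the shared dispersion is estimated once, from the pooled null fit,
    # and reused for the group-specific means: the alternative then nests
    # the null exactly (stat >= 0) and the statistic tracks chi-square(1)
    # closely at small n, where re-estimating the dispersion under the
    # alternative is markedly anti-conservative
    alpha <- null_fit$alpha
    mus <- vapply(idx, function(j) {
      .nb_mu_hat(counts[j], alpha, size_factors[j])
    }, numeric(1))
    ll_alt <- sum(vapply(seq_along(idx), function(i) {
      .nb_ll(counts[idx[[i]]], mus[i], alpha, size_factors[idx[[i]]])
    }, numeric(1)))
    alt_fit <- list(alpha = alpha, mu = mus, log_likelihood = ll_alt)
    df <- 1L
  } else {
    fits <- lapply(1:2, function(i) {
      .nb_profile_fit(list(counts[idx[[i]]]), list(size_factors[idx[[i]]]))
    })
    alt_fit <- list(alpha = vapply(fits, `[[`, numeric(1), "alpha"),
                    mu = vapply(fits, function(f) f$mu[1], numeric(1)),
                    log_likelihood = sum(vapply(fits, `[[`, numeric(1),
                                                "log_likelihood")))
    df <- 2L
    ll_alt <- alt_fit$log_likelihood
  }
  stat <- max(0, 2 * (ll_alt - null_fit$log_likelihood))
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE),
       null_fit = null_fit, alt_fit = alt_fit, groups = groups)
}

#' Call differentially expressed genes for one population
#'
#' For every gene in the population's samples: size-factor normalization,
#' fold change as (normalized drought mean + 0.5) / (normalized control
#' mean + 0.5), p from the two-group NB likelihood-ratio test with
#' normalization offsets, and a direction call at the fold-change and
#' p-value thresholds (up: FC >= fc_threshold and p < p_deg; down:
#' FC <= 1/fc_threshold and p < p_deg; otherwise ns). BH-adjusted
#' q-values are reported alongside.
#'
#' @param counts Gene x sample integer matrix.
#' @param sheet Sample sheet data.frame (`sample`, `population`,
#'   `condition`, `replicate`).
#' @param population Population to analyse (e.g. "RE").
#' @param fc_threshold Fold-change cutoff (default 1.5).
#' @param p_deg Raw p cutoff (default 0.05).
#' @param shared_dispersion Passed to [nb_lrt_two_group()].
#' @return Data.frame: `gene`, `base_mean`, `fold_change`, `p`, `q`,
#'   `direction`.
#' @export
call_degs <- function(counts, sheet, population, fc_threshold = 1.5,
                      p_deg = 0.05, shared_dispersion = TRUE) {
  samples <- sheet$sample[sheet$population == population]
  cond <- sheet$condition[sheet$population == population]
  if (sum(cond == "control") < 2 || sum(cond == "drought") < 2) {
    stop("need >= 2 control and >= 2 drought samples for ", population)
  }
  m <- counts[, samples, drop = FALSE]
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  ctrl <- cond == "control"
  drt <- cond == "drought"
  fc <- (rowMeans(norm[, drt, drop = FALSE]) + 0.5) /
    (rowMeans(norm[, ctrl, drop = FALSE]) + 0.5)
  p <- vapply(seq_len(nrow(m)), function(i) {
    nb_lrt_two_group(m[i, ], cond, shared_dispersion = shared_dispersion,
                     size_factors = sf)$p
  }, numeric(1))
  q <- bh_adjust(p)
  direction <- rep("ns", nrow(m))
  direction[fc >= fc_threshold & p < p_deg] <- "up"
  direction[fc <= 1 / fc_threshold & p < p_deg] <- "down"
  data.frame(
    gene = rownames(m),
    base_mean = rowMeans(norm),
    fold_change = fc, p = p, q = q, direction = direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Partition DEGs shared between and unique to two populations
#'
#' Disjoint partition of the union of DEGs from two populations into
#' shared (same direction), unique-to-one, and discordant (opposite
#' directions) bins.
#'
#' @param results_a,results_b DEG tables from [call_degs()].
#' @param labels Population labels for the two result sets.
#' @return List of class `venn_partition` with gene-id vectors
#'   `shared_up`, `shared_down`, `unique_<A>_up`, `unique_<A>_down`,
#'   `unique_<B>_up`, `unique_<B>_down`, `discordant`, plus `counts`.
#' @export
venn_partition <- function(results_a, results_b, labels = c("RE", "RF")) {
  dir_a <- stats::setNames(results_a$direction, results_a$gene)
  dir_b <- stats::setNames(results_b$direction, results_b$gene)
  deg_a <- names(dir_a)[dir_a != "ns"]
  deg_b <- names(dir_b)[dir_b != "ns"]
  all_deg <- union(deg_a, deg_b)
  da <- ifelse(all_deg %in% names(dir_a), dir_a[all_deg], "ns")
  db <- ifelse(all_deg %in% names(dir_b), dir_b[all_deg], "ns")
  out <- list(
    shared_up = all_deg[da == "up" & db == "up"],
    shared_down = all_deg[da == "down" & db == "down"],
    discordant = all_deg[(da == "up" & db == "down") |
                           (da == "down" & db == "up")]
  )
  out[[paste0("unique_", labels[1], "_up")]] <- all_deg[da == "up" & db == "ns"]
  out[[paste0("unique_", labels[1], "_down")]] <- all_deg[da == "down" & db == "ns"]
  out[[paste0("unique_", labels[2], "_up")]] <- all_deg[da == "ns" & db == "up"]
  out[[paste0("unique_", labels[2], "_down")]] <- all_deg[da == "ns" & db == "down"]
  out$counts <- vapply(out, length, integer(1))
  class(out) <- "venn_partition"
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (q_(i) = min over j >= i of p_(j) * m / j,
#' capped at 1), returned in the original order.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
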