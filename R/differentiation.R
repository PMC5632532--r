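# per-locus ingredients for the differentiation estimators: sample sizes,
# allele frequencies and per-allele heterozygote frequencies in each pop
diff_locus_data <- function(x, l, pops) {
  lapply(pops, function(p) {
    idx <- which(as.character(x$pop) == p)
    a1 <- x$a1[idx, l]; a2 <- x$a2[idx, l]
    ok <- !is.na(a1); a1 <- a1[ok]; a2 <- a2[ok]
    list(n = length(a1), a1 = a1, a2 = a2)
  })
}

#' Weir-Cockerham theta (F_ST)
#'
#' The Weir & Cockerham (1984) variance-component estimator of Wright's
#' F_ST: for every allele at every locus the among-population (a),
#' among-individual (b) and within-individual (c) components are formed
#' from sample sizes, allele frequencies and heterozygote frequencies,
#' and `theta = sum(a) / sum(a + b + c)` over all alleles and loci.
#' Missing calls are excluded locus by locus. Slightly negative estimates
#' around zero are expected sampling behaviour.
#'
#' @param x a [genotype_table] of unique MLLs.
#' @param pops populations to compare (default: all levels; pairwise use
#'   passes two).
#' @return multilocus theta, with per-locus values in attribute
#'   `"per_locus"`.
#' @export
wc_theta <- function(x, pops = levels(x$pop)) {
  stopifnot(length(pops) >= 2)
  cnt <- table(factor(as.character(x$pop), levels = pops))
  if (any(cnt < 2)) stop("each population needs at least 2 genets")
  num_tot <- den_tot <- 0
  per_locus <- numeric(n_loci(x))
  for (l in seq_len(n_loci(x))) {
    d <- diff_locus_data(x, l, pops)
    d <- d[vapply(d, function(z) z$n > 0, logical(1))]
    r <- length(d)
    if (r < 2) { per_locus[l] <- NA_real_; next }
    n_i <- vapply(d, `[[`, numeric(1), "n")
    alleles <- sort(unique(unlist(lapply(d, function(z) c(z$a1, z$a2)))))
    if (length(alleles) < 2) { per_locus[l] <- NA_real_; next }
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    num_l <- den_l <- 0
    for (al in alleles) {
      p_i <- vapply(d, function(z) (sum(z$a1 == al) + sum(z$a2 == al)) / (2 * z$n),
                    numeric(1))
      h_i <- vapply(d, function(z) mean((z$a1 == al) != (z$a2 == al)), numeric(1))
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num_l <- num_l + a
      den_l <- den_l + a + b + cc
    }
    per_locus[l] <- if (den_l > 0) num_l / den_l else NA_real_
    num_tot <- num_tot + num_l
    den_tot <- den_tot + den_l
  }
  theta <- if (den_tot > 0) num_tot / den_tot else NA_real_
  names(per_locus) <- x$loci
  attr(theta, "per_locus") <- per_locus
  theta
}

#' Nei G_ST family with Hedrick / Meirmans standardization
#'
#' Per locus, the Nei & Chesser sample-size-corrected heterozygosities
#' are computed over `k` populations (harmonic-mean sample size `ñ`,
#' mean observed heterozygosity `Ho`):
#' `Hs = ñ/(ñ-1) (1 - mean_i sum_a p_ia^2 - Ho/(2ñ))` and
#' `Ht = 1 - sum_a pbar_a^2 + Hs/(kñ) - Ho/(2kñ)`. From the multilocus
#' (locus-averaged) `Hs` and `Ht`:
#' `G_ST = (Ht - Hs)/Ht`,
#' `G'_ST = G_ST (k - 1 + Hs) / ((k - 1)(1 - Hs))` (Hedrick) and
#' `G''_ST = k (Ht - Hs) / ((k Ht - Hs)(1 - Hs))` (Meirmans & Hedrick),
#' the latter rescaled so fully differentiated populations reach 1 even
#' at high within-population diversity.
#'
#' @param x a [genotype_table] of unique MLLs.
#' @param pops populations to compare (default all).
#' @return list with `G_ST`, `G_ST_prime`, `G_ST_dprime`, `H_S`, `H_T`,
#'   `k`, and a `per_locus` data.frame; all `NA` when every locus is
#'   monomorphic overall (`H_T = 0`).
#' @export
gst_family <- function(x, pops = levels(x$pop)) {
  k <- length(pops)
  stopifnot(k >= 2)
  rows <- list()
  for (l in seq_len(n_loci(x))) {
    d <- diff_locus_data(x, l, pops)
    if (any(vapply(d, function(z) z$n == 0, logical(1)))) next
    n_i <- vapply(d, `[[`, numeric(1), "n")
    ntilde <- k / sum(1 / n_i)
    alleles <- sort(unique(unlist(lapply(d, function(z) c(z$a1, z$a2)))))
    P <- vapply(d, function(z)
      vapply(alleles, function(al)
        (sum(z$a1 == al) + sum(z$a2 == al)) / (2 * z$n), numeric(1)),
      numeric(length(alleles)))
    P <- matrix(P, nrow = length(alleles))
    Ho <- mean(vapply(d, function(z) mean(z$a1 != z$a2), numeric(1)))
    Hs <- ntilde / (ntilde - 1) *
      (1 - mean(colSums(P^2)) - Ho / (2 * ntilde))
    pbar <- rowMeans(P)
    Ht <- 1 - sum(pbar^2) + Hs / (k * ntilde) - Ho / (2 * k * ntilde)
    rows[[length(rows) + 1L]] <- data.frame(locus = x$loci[l], Hs = Hs, Ht = Ht)
  }
  per_locus <- do.call(rbind, rows)
  Hs <- mean(per_locus$Hs); Ht <- mean(per_locus$Ht)
  if (!is.finite(Ht) || Ht <= 0)
    return(list(G_ST = NA_real_, G_ST_prime = NA_real_, G_ST_dprime = NA_real_,
                H_S = Hs, H_T = Ht, k = k, per_locus = per_locus))
  Gst <- (Ht - Hs) / Ht
  Gp <- if (Hs < 1) Gst * (k - 1 + Hs) / ((k - 1) * (1 - Hs)) else NA_real_
  Gpp <- if (Hs < 1 && (k * Ht - Hs) > 0)
    k * (Ht - Hs) / ((k * Ht - Hs) * (1 - Hs)) else NA_real_
  list(G_ST = Gst, G_ST_prime = Gp, G_ST_dprime = Gpp,
       H_S = Hs, H_T = Ht, k = k, per_locus = per_locus)
}

#' Permutation p-value for a differentiation statistic
#'
#' Builds the null by randomly reassigning genets between the two
#' populations (sample sizes preserved) and recomputing the statistic;
#' `p = (#{permuted >= observed} + 1) / (n_perm + 1)`. The permutation
#' unit is the genet (one representative per MLL), never the ramet.
#'
#' @param x a [genotype_table] of unique MLLs from two populations.
#' @param statistic `"theta"` (Weir-Cockerham) or `"gst_dprime"`.
#' @param n_perm number of permutations (`>= 100`).
#' @param seed RNG seed.
#' @return list with `observed`, `p_value`, `n_perm`.
#' @export
diff_permutation_test <- function(x, statistic = c("theta", "gst_dprime"),
                                  n_perm = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- if (statistic == "theta") {
    function(t) as.numeric(wc_theta(t))
  } else {
    function(t) gst_family(t)$G_ST_dprime
  }
  obs <- stat_fun(x)
  labels <- as.character(x$pop)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    xp <- x
    xp$pop <- factor(sample(labels), levels = levels(x$pop))
    val <- stat_fun(xp)
    if (!is.na(val) && val >= obs - 1e-12) hits <- hits + 1L
  }
  list(observed = obs, p_value = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Pairwise differentiation report
#'
#' Runs [wc_theta], [gst_family] and (optionally) permutation tests for
#' every pair of populations in the table.
#'
#' @param x a [genotype_table] of unique MLLs.
#' @param n_perm permutations per test; 0 skips the tests.
#' @param seed RNG seed.
#' @return data.frame with one row per population pair.
#' @export
pairwise_differentiation <- function(x, n_perm = 1000, seed = NULL) {
  pops <- levels(x$pop)
  prs <- utils::combn(pops, 2)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(ncol(prs)), function(k) {
    sub <- x[as.character(x$pop) %in% prs[, k], ]
    th <- wc_theta(sub)
    g <- gst_family(sub)
    p_th <- p_g <- NA_real_
    if (n_perm > 0) {
      p_th <- diff_permutation_test(sub, "theta", n_perm = n_perm)$p_value
      p_g <- diff_permutation_test(sub, "gst_dprime", n_perm = n_perm)$p_value
    }
    data.frame(pop1 = prs[1, k], pop2 = prs[2, k],
               F_ST = as.numeric(th), p_F_ST = p_th,
               G_ST = g$G_ST, G_ST_prime = g$G_ST_prime,
               G_ST_dprime = g$G_ST_dprime, p_G_ST_dprime = p_g,
               H_S = g$H_S, H_T = g$H_T, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
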