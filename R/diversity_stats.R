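# per-locus, per-population building block: sample size, allele counts,
# frequencies, observed and unbiased expected heterozygosity
locus_pop_stats <- function(x, l, pop) {
  idx <- which(as.character(x$pop) == pop)
  a1 <- x$a1[idx, l]; a2 <- x$a2[idx, l]
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n == 0) return(list(n = 0L, counts = integer(0), f = numeric(0),
                          Ho = NA_real_, He = NA_real_))
  tab <- table(c(a1, a2))
  f <- as.numeric(tab) / sum(tab)
  names(f) <- names(tab)
  Ho <- mean(a1 != a2)
  He <- 1 - sum(f^2)                                # plug-in expected het
  He_ub <- (2 * n / (2 * n - 1)) * He               # Nei (1978) correction
  list(n = n, counts = as.integer(tab), alleles = names(tab), f = f,
       Ho = Ho, He = He, He_ub = He_ub)
}

#' Per-locus, per-population diversity summary
#'
#' Computes, for every locus and population of a table (conventionally one
#' already reduced to a single representative per multilocus lineage):
#' the number of alleles `Na`, rarefied allelic richness `AR`, private
#' allele count `Ap`, observed heterozygosity `Ho`, the expected
#' heterozygosity `He = 1 - sum f_i^2` (with Nei's 1978 small-sample
#' correction reported alongside as `He_unbiased`), and the inbreeding
#' coefficient `F_IS = 1 - Ho/He` (undefined at monomorphic loci)
#' together with the Weir-Cockerham within-population `f`. An
#' all-heterozygote two-allele locus thus yields Ho = 1.00, He = 0.50,
#' F_IS = -1.00 at any sample size.
#' Multilocus population values are unweighted means over loci (`A` and
#' `Ap` are sums); the multilocus `F_IS` uses the ratio of mean
#' heterozygosities.
#'
#' Allelic richness is rarefied to a common number of gene copies `m`:
#' `AR = sum_a [1 - C(2n - c_a, m) / C(2n, m)]`, the expected number of
#' alleles in a subsample of `m` gene copies. By default `m` is the
#' smallest number of scored gene copies over all locus-population cells.
#'
#' @param x a [genotype_table] restricted to unique MLLs.
#' @param rarefaction_size number of gene copies to rarefy to; `NULL` for
#'   the default above.
#' @return list with `per_locus` and `per_pop` data.frames.
#' @export
diversity_summary <- function(x, rarefaction_size = NULL) {
  pops <- levels(x$pop)
  cells <- expand.grid(locus = x$loci, population = pops,
                       stringsAsFactors = FALSE)
  stats <- Map(function(l, p) locus_pop_stats(x, match(l, x$loci), p),
               cells$locus, cells$population)
  copies <- vapply(stats, function(s) 2L * s$n, integer(1))
  if (is.null(rarefaction_size)) rarefaction_size <- min(copies[copies > 0])
  if (any(copies < rarefaction_size))
    stop("rarefaction size ", rarefaction_size,
         " exceeds the scored gene copies of some locus/population cell")
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    s <- stats[[k]]
    l <- cells$locus[k]; p <- cells$population[k]
    Na <- length(s$f)
    AR <- rarefied_richness(s$counts, rarefaction_size)
    other <- unlist(lapply(which(cells$locus == l & cells$population != p),
                           function(kk) stats[[kk]]$alleles))
    Ap <- sum(!(s$alleles %in% other))
    Fis <- if (!is.na(s$He) && s$He > 0) 1 - s$Ho / s$He else NA_real_
    fwc <- wc_f_locus(x, match(l, x$loci), p)
    rows[[k]] <- data.frame(locus = l, population = p, n = s$n, Na = Na,
                            AR = AR, Ap = Ap, Ho = s$Ho, He = s$He,
                            He_unbiased = s$He_ub, F_IS = Fis, f_WC = fwc,
                            stringsAsFactors = FALSE)
  }
  per_locus <- do.call(rbind, rows)
  per_pop <- do.call(rbind, lapply(pops, function(p) {
    d <- per_locus[per_locus$population == p, ]
    mHo <- mean(d$Ho, na.rm = TRUE); mHe <- mean(d$He, na.rm = TRUE)
    data.frame(population = p, n = max(d$n), A = sum(d$Na), AR = mean(d$AR),
               Ap = sum(d$Ap), Ho = mHo, He = mHe,
               F_IS = if (mHe > 0) 1 - mHo / mHe else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_locus = per_locus, per_pop = per_pop,
       rarefaction_size = rarefaction_size)
}

# expected allele count in a subsample of m gene copies (hypergeometric)
rarefied_richness <- function(counts, m) {
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  sum(vapply(counts, function(ci) {
    1 - exp(lchoose(tot - ci, m) - lchoose(tot, m))
  }, numeric(1)))
}

# Weir-Cockerham within-population f for one locus in one population,
# from genotype-level heterozygote frequencies per allele
wc_f_locus <- function(x, l, pop) {
  idx <- which(as.character(x$pop) == pop)
  a1 <- x$a1[idx, l]; a2 <- x$a2[idx, l]
  ok <- !is.na(a1); a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2) return(NA_real_)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(NA_real_)
  bsum <- csum <- 0
  for (al in alleles) {
    p <- (sum(a1 == al) + sum(a2 == al)) / (2 * n)
    h <- mean((a1 == al) != (a2 == al))   # heterozygotes carrying allele al
    b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
    bsum <- bsum + b
    csum <- csum + h / 2
  }
  if (bsum + csum <= 0) return(NA_real_)
  1 - csum / (bsum + csum)
}

#' Permutation test for Hardy-Weinberg equilibrium
#'
#' FSTAT-style allele randomization: the scored gene copies at one locus
#' within one population are shuffled among individuals, and the
#' two-sided p-value is the proportion of permutations whose `|F_IS|` is
#' at least the observed `|F_IS|` (with `+1/(n_perm+1)` smoothing).
#' Allele frequencies — hence `He` — are invariant under the shuffle, so
#' the test isolates the pairing of alleles into genotypes.
#'
#' @param x a [genotype_table] (unique MLLs).
#' @param locus locus name or index.
#' @param population population label.
#' @param n_perm number of permutations (`>= 100`).
#' @param seed RNG seed (mandatory for reproducible pipelines).
#' @return p-value, or `NA` for a monomorphic locus.
#' @export
hwe_permutation_test <- function(x, locus, population, n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  l <- if (is.character(locus)) match(locus, x$loci) else locus
  idx <- which(as.character(x$pop) == population)
  a1 <- x$a1[idx, l]; a2 <- x$a2[idx, l]
  ok <- !is.na(a1); a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2 || length(unique(c(a1, a2))) < 2) return(NA_real_)
  pool <- c(a1, a2)
  f <- as.numeric(table(pool)) / (2 * n)
  He <- (2 * n / (2 * n - 1)) * (1 - sum(f^2))
  fis_of <- function(h1, h2) abs(1 - mean(h1 != h2) / He)
  obs <- fis_of(a1, a2)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(pool)
    if (fis_of(perm[1:n], perm[(n + 1):(2 * n)]) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' Permutation test for linkage disequilibrium between two loci
#'
#' The statistic is the log-likelihood-ratio G of the two-locus genotype
#' contingency table; the null distribution is built by permuting one
#' locus's genotypes among individuals within the population, which
#' preserves both single-locus genotype distributions while destroying
#' their association.
#'
#' @param x a [genotype_table] (unique MLLs).
#' @param locus_pair vector of two locus names or indices.
#' @param population population label.
#' @param n_perm number of permutations (`>= 100`).
#' @param seed RNG seed.
#' @return p-value (smoothed), or `NA` if either locus is monomorphic in
#'   the population.
#' @export
linkage_permutation_test <- function(x, locus_pair, population,
                                     n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 100, length(locus_pair) == 2)
  if (!is.null(seed)) set.seed(seed)
  li <- vapply(locus_pair,
               function(l) if (is.character(l)) match(l, x$loci) else as.integer(l),
               integer(1))
  idx <- which(as.character(x$pop) == population)
  gA <- paste(x$a1[idx, li[1]], x$a2[idx, li[1]])
  gB <- paste(x$a1[idx, li[2]], x$a2[idx, li[2]])
  ok <- !is.na(x$a1[idx, li[1]]) & !is.na(x$a1[idx, li[2]])
  gA <- gA[ok]; gB <- gB[ok]
  if (length(unique(gA)) < 2 || length(unique(gB)) < 2) return(NA_real_)
  g_stat <- function(a, b) {
    tab <- table(a, b)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    O <- as.numeric(tab); E <- as.numeric(E)
    2 * sum(O[O > 0] * log(O[O > 0] / E[O > 0]))
  }
  obs <- g_stat(gA, gB)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (g_stat(gA, sample(gB)) >= obs - 1e-12) hits <- hits + 1L
  (hits + 1) / (n_perm + 1)
}

#' Null-allele screen (Brookfield estimator 1 + homozygote-excess test)
#'
#' Estimates the null-allele frequency as `r = (He - Ho) / (1 + He)`
#' (Brookfield's estimator 1) and raises a flag when `r` exceeds
#' `r_threshold` and a one-sided binomial test of the observed homozygote
#' count against the He-expected homozygosity is significant at
#' `alpha`. Chakraborty's estimator `(He - Ho) / (He + Ho)` — the
#' consistent one when null homozygotes are scored as blanks and excluded
#' from the sample, as this package does — is reported alongside. Loci
#' with fewer than 2 alleles or fewer than 5 scored individuals are
#' reported as not testable.
#'
#' @param x a [genotype_table] (unique MLLs).
#' @param locus locus name or index.
#' @param population population label.
#' @param r_threshold null-frequency flag threshold (default 0.1).
#' @param alpha significance level of the homozygote-excess test.
#' @return list with `testable`, `r` (Brookfield-1), `r_chakraborty`,
#'   `p_homozygote_excess`, `flag`.
#' @export
null_allele_test <- function(x, locus, population, r_threshold = 0.1,
                             alpha = 0.05) {
  l <- if (is.character(locus)) match(locus, x$loci) else locus
  s <- locus_pop_stats(x, l, population)
  if (s$n < 5 || length(s$f) < 2)
    return(list(testable = FALSE, r = NA_real_, r_chakraborty = NA_real_,
                p_homozygote_excess = NA_real_, flag = FALSE))
  r <- (s$He - s$Ho) / (1 + s$He)
  r_ch <- if (s$He + s$Ho > 0) (s$He - s$Ho) / (s$He + s$Ho) else NA_real_
  idx <- which(as.character(x$pop) == population)
  a1 <- x$a1[idx, l]; a2 <- x$a2[idx, l]
  ok <- !is.na(a1)
  n_hom <- sum(a1[ok] == a2[ok])
  p_hom_expected <- min(max(1 - s$He, 0), 1)
  pv <- stats::binom.test(n_hom, s$n, p_hom_expected,
                          alternative = "greater")$p.value
  list(testable = TRUE, r = r, r_chakraborty = r_ch,
       p_homozygote_excess = pv, flag = r > r_threshold && pv < alpha)
}

#' Locus QC screens over all loci and populations
#'
#' Convenience wrapper running [null_allele_test] on every locus and
#' [linkage_permutation_test] on every locus pair, within each
#' population, and translating the results into locus-level flags for
#' [apply_locus_qc]. A locus is null-flagged if the screen flags it in
#' any population; a linkage-significant pair (after Bonferroni
#' correction within the pair family) flags both members, mirroring the
#' practice of removing every locus showing disequilibrium with others.
#' Null-allele drops are applied before the linkage pass, and linkage is
#' evaluated only among surviving loci.
#'
#' @param x a [genotype_table] of unique MLGs/MLLs.
#' @param n_perm permutations per linkage test.
#' @param seed RNG seed.
#' @param alpha family-wise significance level (Bonferroni-adjusted per
#'   test within the linkage family).
#' @return list with `null_allele_flags`, `linkage_flags` (character
#'   vectors of locus names) and the raw test tables.
#' @export
locus_qc_flags <- function(x, n_perm = 1000, seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  pops <- levels(x$pop)
  null_tab <- do.call(rbind, lapply(x$loci, function(l) {
    do.call(rbind, lapply(pops, function(p) {
      res <- null_allele_test(x, l, p)
      data.frame(locus = l, population = p, r = res$r,
                 p = res$p_homozygote_excess, flag = res$flag,
                 stringsAsFactors = FALSE)
    }))
  }))
  null_flags <- unique(null_tab$locus[null_tab$flag])
  survivors <- setdiff(x$loci, null_flags)
  lk_rows <- list()
  if (length(survivors) >= 2) {
    prs <- utils::combn(survivors, 2)
    n_tests <- ncol(prs) * length(pops)
    for (k in seq_len(ncol(prs))) for (p in pops) {
      pv <- linkage_permutation_test(x, prs[, k], p, n_perm = n_perm)
      lk_rows[[length(lk_rows) + 1L]] <-
        data.frame(locus1 = prs[1, k], locus2 = prs[2, k], population = p,
                   p = pv, flag = !is.na(pv) && pv < alpha / n_tests,
                   stringsAsFactors = FALSE)
    }
  }
  lk_tab <- if (length(lk_rows)) do.call(rbind, lk_rows) else
    data.frame(locus1 = character(0), locus2 = character(0),
               population = character(0), p = numeric(0), flag = logical(0))
  linkage_flags <- unique(c(lk_tab$locus1[lk_tab$flag],
                            lk_tab$locus2[lk_tab$flag]))
  list(null_allele_flags = null_flags, linkage_flags = linkage_flags,
       null_table = null_tab, linkage_table = lk_tab)
}
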