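#' Assign multilocus genotypes (MLGs)
#'
#' Two individuals share an MLG if and only if their unordered allele pairs
#' are identical at every locus. A missing call matches nothing — not even
#' another missing call — so any individual with missing data founds its
#' own MLG. This is the conservative convention for clone detection:
#' missing values are treated as alleles different from everything else,
#' which can only split, never merge, candidate clones.
#'
#' @param x a [genotype_table].
#' @return integer vector of MLG ids, one per individual, numbered in
#'   first-appearance order starting at 1.
#' @export
assign_mlg <- function(x) {
  key <- character(n_ind(x))
  for (i in seq_len(n_ind(x))) {
    g <- paste(x$a1[i, ], x$a2[i, ], sep = "/")
    miss <- is.na(x$a1[i, ])
    # unique sentinel per individual: missing matches nothing
    if (any(miss)) g[miss] <- paste0("?", i)
    key[i] <- paste(g, collapse = "|")
  }
  match(key, unique(key))
}

# multiset intersection size of two sorted allele pairs (scalar)
pair_match_count <- function(a1, a2, b1, b2) {
  if (is.na(a1) && is.na(b1)) return(2L)   # both missing: no evidence of difference
  if (is.na(a1) || is.na(b1)) return(0L)   # missing vs scored: maximally different
  if (a1 == b1 && a2 == b2) return(2L)
  if (a1 == b1 || a1 == b2 || a2 == b1 || a2 == b2) return(1L)
  0L
}

#' Allele-sharing distance between two individuals
#'
#' Sum over loci of `2 - |multiset intersection of the two allele pairs|`,
#' so identical genotypes are at distance 0 and each allele mismatch adds
#' one. A missing call against a scored call contributes 2 (maximally
#' different); two missing calls at the same locus contribute 0, so an
#' otherwise-identical pair sharing a failed locus can still be collapsed
#' into one lineage.
#'
#' @param x a [genotype_table].
#' @param i,j individual indices or identifiers.
#' @return non-negative integer distance.
#' @export
allele_distance <- function(x, i, j) {
  if (is.character(i)) i <- match(i, x$ind)
  if (is.character(j)) j <- match(j, x$ind)
  d <- 0L
  for (l in seq_len(n_loci(x)))
    d <- d + 2L - pair_match_count(x$a1[i, l], x$a2[i, l], x$a1[j, l], x$a2[j, l])
  d
}

#' Pairwise allele-sharing distance matrix
#'
#' @param x a [genotype_table].
#' @param idx optional subset of individual indices.
#' @return symmetric integer matrix of [allele_distance] values.
#' @export
allele_distance_matrix <- function(x, idx = seq_len(n_ind(x))) {
  n <- length(idx)
  D <- matrix(0L, n, n)
  for (l in seq_len(n_loci(x))) {
    p1 <- x$a1[idx, l]; p2 <- x$a2[idx, l]
    miss <- is.na(p1)
    eq  <- outer(p1, p1, "==") & outer(p2, p2, "==")
    any1 <- outer(p1, p1, "==") | outer(p1, p2, "==") |
            outer(p2, p1, "==") | outer(p2, p2, "==")
    m <- matrix(0L, n, n)
    m[any1 & !is.na(any1)] <- 1L
    m[eq & !is.na(eq)] <- 2L
    # missing vs missing: contribute 0 distance; missing vs scored: 2
    m[miss, miss] <- 2L
    m[miss, !miss] <- 0L
    m[!miss, miss] <- 0L
    D <- D + 2L - m
  }
  diag(D) <- 0L
  D
}

#' Collapse MLGs into multilocus lineages (MLLs)
#'
#' Scoring errors and somatic mutations inflate MLG counts, so MLGs whose
#' representatives differ by no more than `threshold` alleles (default 1)
#' are merged into one multilocus lineage. Merging is by single linkage:
#' MLLs are the connected components of the graph joining MLG pairs at
#' distance `<= threshold`, so chains A-B-C with d(A,C) > threshold still
#' form one lineage. Labels are deterministic: each MLL takes the smallest
#' member MLG id.
#'
#' @param x a [genotype_table].
#' @param mlg integer MLG ids from [assign_mlg].
#' @param threshold maximum allele difference for two MLGs to be merged.
#' @return integer vector, MLL id for each MLG id `1..max(mlg)`; MLL ids
#'   are renumbered 1..G in order of smallest member MLG. Attribute
#'   `"chained"` lists merged pairs that exceeded the threshold distance
#'   (transitive merges).
#' @export
collapse_mll <- function(x, mlg, threshold = 1) {
  nG <- max(mlg)
  rep_idx <- match(seq_len(nG), mlg)       # first individual of each MLG
  D <- allele_distance_matrix(x, rep_idx)
  adj <- D <= threshold
  comp <- integer(nG)
  cid <- 0L
  for (s in seq_len(nG)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  # relabel by smallest member MLG id, renumbered 1..G
  first <- tapply(seq_len(nG), comp, min)
  ord <- rank(first)
  mll <- as.integer(ord[comp])
  chained <- list()
  for (k in unique(mll)) {
    members <- which(mll == k)
    if (length(members) > 1) {
      sub <- D[members, members, drop = FALSE]
      if (any(sub > threshold))
        chained[[length(chained) + 1L]] <- members
    }
  }
  attr(mll, "chained") <- chained
  mll
}

#' Estimate per-locus allele frequencies
#'
#' @param x a [genotype_table].
#' @param scheme `"per_genet"` (default; one copy per MLG, avoiding
#'   clone inflation), `"round_robin"` (frequencies at locus l estimated
#'   from the unique MLGs defined on all loci except l), or `"per_ramet"`
#'   (every individual counted).
#' @param mlg MLG ids from [assign_mlg]; required for the genet-based
#'   schemes (computed if omitted).
#' @return named list (by locus) of named numeric vectors of relative
#'   frequencies summing to 1 over the alleles observed at that locus.
#' @export
estimate_allele_freqs <- function(x, scheme = c("per_genet", "round_robin", "per_ramet"),
                                  mlg = NULL) {
  scheme <- match.arg(scheme)
  counts_at <- function(idx, l) {
    al <- c(x$a1[idx, l], x$a2[idx, l])
    al <- al[!is.na(al)]
    if (!length(al)) return(numeric(0))
    tab <- table(al)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    f
  }
  out <- vector("list", n_loci(x))
  names(out) <- x$loci
  if (scheme == "per_ramet") {
    for (l in seq_len(n_loci(x))) out[[l]] <- counts_at(seq_len(n_ind(x)), l)
    return(out)
  }
  if (is.null(mlg)) mlg <- assign_mlg(x)
  if (scheme == "per_genet") {
    rep_idx <- match(seq_len(max(mlg)), mlg)
    for (l in seq_len(n_loci(x))) out[[l]] <- counts_at(rep_idx, l)
    return(out)
  }
  # round_robin: unique MLGs on all loci but l, then count alleles at l
  for (l in seq_len(n_loci(x))) {
    sub <- x[, -l]
    mlg_l <- assign_mlg(sub)
    rep_idx <- match(seq_len(max(mlg_l)), mlg_l)
    out[[l]] <- counts_at(rep_idx, l)
  }
  out
}

#' Probability of a multilocus genotype under random mating
#'
#' Product over loci of the single-locus genotype probability with an
#' inbreeding correction: a homozygote (a,a) contributes
#' `f_a^2 + f_a (1 - f_a) F_IS` and a heterozygote (a,b) contributes
#' `2 f_a f_b (1 - F_IS)`. With `f_is = 0` this is the Hardy-Weinberg
#' expectation. Loci with missing calls in the focal genotype are skipped.
#' Negative per-locus terms (possible when `f_is < 0`) are clamped to 0
#' with a warning.
#'
#' @param x a [genotype_table].
#' @param i individual index or identifier whose MLG is evaluated.
#' @param freqs allele frequencies from [estimate_allele_freqs].
#' @param f_is inbreeding coefficient in `[-1, 1]` used in the correction.
#' @return probability in `[0, 1]`.
#' @export
p_gen <- function(x, i, freqs, f_is = 0) {
  stopifnot(f_is >= -1, f_is <= 1)
  if (is.character(i)) i <- match(i, x$ind)
  p <- 1
  for (l in seq_len(n_loci(x))) {
    a <- x$a1[i, l]; b <- x$a2[i, l]
    if (is.na(a)) next
    f <- freqs[[x$loci[l]]]
    fa <- f[as.character(a)]; fb <- f[as.character(b)]
    if (is.na(fa) || is.na(fb))
      stop("allele absent from frequency table at locus ", x$loci[l])
    term <- if (a == b) fa^2 + fa * (1 - fa) * f_is else 2 * fa * fb * (1 - f_is)
    if (term < 0) {
      warning("negative genotype probability clamped to 0 at locus ", x$loci[l])
      term <- 0
    }
    p <- p * term
  }
  unname(p)
}

#' Probability that repeated genotypes arose from separate sexual events
#'
#' For an MLG observed `n_repeats` times in a sample of `N_sample`
#' individuals, the probability that the repeats are independent products
#' of sexual reproduction rather than clones. Under the default
#' Parks-Werth convention the focal individual is taken as given and
#' `P_sex` is the binomial probability that at least `n_repeats - 1` of
#' the remaining `N_sample - 1` samples independently drew the same
#' genotype:
#' `P_sex = sum_{i >= n_repeats-1} C(N-1, i) pgen^i (1-pgen)^{N-1-i}`.
#' The `"binomial_n"` convention counts successes among all `N_sample`
#' draws instead. Small values (conventionally `< 0.001`) support
#' clonality.
#'
#' @param pgen genotype probability from [p_gen].
#' @param n_repeats observed number of ramets carrying the MLG (`>= 2`).
#' @param n_sample number of individuals in the sample.
#' @param convention `"parks_werth"` (default) or `"binomial_n"`.
#' @return probability in `[0, 1]`; monotone increasing in `pgen`.
#' @export
p_sex <- function(pgen, n_repeats, n_sample,
                  convention = c("parks_werth", "binomial_n")) {
  convention <- match.arg(convention)
  if (pgen < 0 || pgen > 1) stop("pgen must lie in [0, 1]")
  stopifnot(n_repeats >= 2, n_sample >= n_repeats)
  if (convention == "parks_werth")
    stats::pbinom(n_repeats - 2L, n_sample - 1L, pgen, lower.tail = FALSE)
  else
    stats::pbinom(n_repeats - 1L, n_sample, pgen, lower.tail = FALSE)
}

#' Clonal richness
#'
#' `R = (G - 1) / (N - 1)` for `G` distinct genets (MLLs) among `N`
#' sampled ramets: 0 when the whole sample is one clone, 1 when every
#' individual is a distinct genet.
#'
#' @param g number of distinct multilocus lineages.
#' @param n number of individuals sampled (`>= 2`).
#' @return richness in `[0, 1]`.
#' @export
clonal_richness <- function(g, n) {
  stopifnot(g >= 1, g <= n)
  if (n < 2) stop("clonal richness undefined for fewer than 2 individuals")
  (g - 1) / (n - 1)
}

#' Unbiased Simpson's complement of a clone-size distribution
#'
#' `D = 1 - sum n_i (n_i - 1) / (N (N - 1))`: the probability that two
#' ramets sampled without replacement belong to different genets. Also
#' returns the bounds attainable for the observed `N` and `G`:
#' `D_max = N (G - 1) / (G (N - 1))` (all genets equally represented) and
#' `D_min = 1 - (N - G + 1)(N - G) / (N (N - 1))` (one dominant genet,
#' all others singletons).
#'
#' @param ramet_counts positive integer vector of ramets per genet.
#' @return list with `D`, `D_min`, `D_max`.
#' @export
simpson_complement <- function(ramet_counts) {
  n_i <- as.numeric(ramet_counts)
  if (!length(n_i)) stop("empty ramet counts")
  stopifnot(all(n_i >= 1))
  N <- sum(n_i); G <- length(n_i)
  if (N < 2) stop("Simpson's complement undefined for N < 2")
  D <- 1 - sum(n_i * (n_i - 1)) / (N * (N - 1))
  D_max <- N * (G - 1) / (G * (N - 1))
  D_min <- 1 - (N - G + 1) * (N - G) / (N * (N - 1))
  list(D = D, D_min = D_min, D_max = D_max)
}

#' Genotypic evenness V
#'
#' Simpson's complement rescaled between its attainable bounds,
#' `V = (D - D_min) / (D_max - D_min)`: 0 when one genet dominates
#' maximally, 1 when all genets have equally many ramets. Undefined
#' (`NA`) for a single genet. Numerators smaller than 1e-12 in absolute
#' value are reported as exactly 0 (the analytic value at the dominant
#' configuration; naive evaluation leaves float noise of order 1e-16).
#'
#' @param ramet_counts positive integer vector of ramets per genet.
#' @return evenness in `[0, 1]`, or `NA` when `G = 1`.
#' @export
evenness_v <- function(ramet_counts) {
  G <- length(ramet_counts)
  if (G < 2) return(NA_real_)
  s <- simpson_complement(ramet_counts)
  num <- s$D - s$D_min
  den <- s$D_max - s$D_min
  if (abs(den) < 1e-12) return(1)  # all singleton genets: maximally even
  if (abs(num) < 1e-12) return(0)
  min(max(num / den, 0), 1)
}

#' Power-law slope of the clone-size distribution
#'
#' Least-squares fit of `log(number of MLLs of size >= x)` against
#' `log(x)` over the distinct observed clone sizes, weighted by the
#' cumulative counts so the sparse upper tail (one or two large clones)
#' does not dominate the slope; returns the negated slope (the Pareto
#' beta). At least two distinct sizes are needed for the fit to be
#' defined (two points give the exact line).
#'
#' @param ramet_counts positive integer vector of ramets per genet.
#' @return beta estimate, or `NA` with fewer than 2 distinct clone sizes.
#' @export
fit_pareto_beta <- function(ramet_counts) {
  sizes <- sort(unique(as.numeric(ramet_counts)))
  if (length(sizes) < 2) return(NA_real_)
  cum <- vapply(sizes, function(s) sum(ramet_counts >= s), numeric(1))
  fit <- stats::lm(log(cum) ~ log(sizes), weights = cum)
  -unname(stats::coef(fit)[2])
}

#' Full clonal partition of a sample
#'
#' Runs MLG assignment, MLL collapsing and Psex evaluation on one sample
#' (typically one population), returning everything downstream stages
#' need: the individual-to-MLG and MLG-to-MLL maps, ramets per MLL,
#' clonal richness and evenness, and Psex for every MLG observed at least
#' twice.
#'
#' @param x a [genotype_table] (one sample; population labels are ignored
#'   for the partition itself).
#' @param threshold MLL collapse distance (default 1 allele difference).
#' @param freq_scheme frequency scheme for [p_gen]; see
#'   [estimate_allele_freqs].
#' @param f_is inbreeding coefficient used inside [p_gen]; negative
#'   estimates are conventionally floored at 0 upstream.
#' @param psex_convention see [p_sex].
#' @param psex_alpha significance level below which repeats are called
#'   ramets of one genet (default 0.001).
#' @return object of class `clonal_partition`: list with `mlg_of`,
#'   `mll_of` (per MLG), `mll_of_ind`, `ramet_counts` (per MLL), `N`,
#'   `n_mlg`, `G`, `R`, `V`, `pareto_beta`, and `psex`, a data.frame of
#'   MLG id, ramet count, pgen and psex for repeated MLGs.
#' @export
clonal_partition <- function(x, threshold = 1,
                             freq_scheme = "per_genet", f_is = 0,
                             psex_convention = "parks_werth",
                             psex_alpha = 0.001) {
  mlg <- assign_mlg(x)
  mll <- collapse_mll(x, mlg, threshold = threshold)
  mll_ind <- mll[mlg]
  counts <- as.integer(table(mll_ind))
  N <- n_ind(x); G <- length(counts)
  freqs <- estimate_allele_freqs(x, scheme = freq_scheme, mlg = mlg)
  tab <- table(mlg)
  rep_ids <- as.integer(names(tab)[tab >= 2])
  psex <- data.frame(mlg = integer(0), n_ramets = integer(0),
                     pgen = numeric(0), psex = numeric(0),
                     clonal = logical(0))
  if (length(rep_ids)) {
    rows <- lapply(rep_ids, function(id) {
      i <- match(id, mlg)
      pg <- p_gen(x, i, freqs, f_is = f_is)
      ps <- p_sex(pg, as.integer(tab[as.character(id)]), N,
                  convention = psex_convention)
      data.frame(mlg = id, n_ramets = as.integer(tab[as.character(id)]),
                 pgen = pg, psex = ps, clonal = ps < psex_alpha)
    })
    psex <- do.call(rbind, rows)
  }
  structure(list(mlg_of = mlg, mll_of = mll, mll_of_ind = mll_ind,
                 ramet_counts = counts, N = N, n_mlg = max(mlg), G = G,
                 R = clonal_richness(G, N), V = evenness_v(counts),
                 pareto_beta = fit_pareto_beta(counts), psex = psex),
            class = "clonal_partition")
}

#' @export
print.clonal_partition <- function(x, ...) {
  cat("clonal_partition: N =", x$N, " MLG =", x$n_mlg, " MLL =", x$G, "\n")
  cat(sprintf("R = %.3f  V = %s  ramet counts: %s\n", x$R,
              ifelse(is.na(x$V), "NA", sprintf("%.3f", x$V)),
              paste(sort(x$ramet_counts, decreasing = TRUE), collapse = ",")))
  invisible(x)
}
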