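# small in-code fixtures shared across test files

# build a table from a list of genotype rows: each row is a list of
# c(a1, a2) pairs per locus (NA pair = missing call)
toy_table <- function(rows, pop = NULL, loci = NULL) {
  n <- length(rows)
  L <- length(rows[[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(L))
  if (is.null(pop)) pop <- rep("P1", n)
  a1 <- matrix(unlist(lapply(rows, function(r) vapply(r, `[`, numeric(1), 1))),
               nrow = n, byrow = TRUE)
  a2 <- matrix(unlist(lapply(rows, function(r) vapply(r, `[`, numeric(1), 2))),
               nrow = n, byrow = TRUE)
  genotype_table(sprintf("ind%02d", seq_len(n)), pop, loci, a1, a2)
}

# random valid table (no structure), used for round-trip property tests
random_table <- function(n = 10, L = 4, pops = c("A", "B"), miss_rate = 0.1) {
  a1 <- matrix(sample(100:120, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(100:120, n * L, replace = TRUE), n, L)
  miss <- matrix(runif(n * L) < miss_rate, n, L)
  a1[miss] <- NA; a2[miss] <- NA
  genotype_table(sprintf("s%03d", seq_len(n)),
                 sample(pops, n, replace = TRUE, prob = c(0.6, 0.4)),
                 sprintf("loc%d", seq_len(L)), a1, a2)
}

# single-population sample in Hardy-Weinberg equilibrium
hw_table <- function(n, freqs = c(0.4, 0.3, 0.2, 0.1), L = 1, pop = "P1") {
  al <- 100 + 2 * seq_along(freqs)
  a1 <- replicate(L, sample(al, n, replace = TRUE, prob = freqs))
  a2 <- replicate(L, sample(al, n, replace = TRUE, prob = freqs))
  genotype_table(sprintf("h%03d", seq_len(n)), rep(pop, n),
                 paste0("hw", seq_len(L)), a1, a2)
}

# brute-force multiset allele distance between two pair lists (oracle)
oracle_distance <- function(rowa, rowb) {
  d <- 0
  for (l in seq_along(rowa)) {
    pa <- rowa[[l]]; pb <- rowb[[l]]
    if (all(is.na(pa)) && all(is.na(pb))) next
    if (any(is.na(pa)) || any(is.na(pb))) { d <- d + 2; next }
    inter <- 0
    for (v in unique(pa)) inter <- inter + min(sum(pa == v), sum(pb == v))
    d <- d + 2 - inter
  }
  d
}

# all unordered integer compositions (partitions) of N
integer_partitions <- function(N, max_part = N) {
  if (N == 0) return(list(integer(0)))
  out <- list()
  for (first in seq(min(N, max_part), 1)) {
    for (rest in integer_partitions(N - first, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

withr_tempfile <- function() tempfile(fileext = ".csv")
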