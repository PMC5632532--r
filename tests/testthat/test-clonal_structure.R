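test_that("MLG assignment groups identical genotypes and splits on missing", {
  tab <- toy_table(list(
    list(c(101, 105), c(250, 252)),
    list(c(101, 105), c(250, 252)),   # identical -> same MLG
    list(c(101, 105), c(NA, NA)),     # missing matches nothing
    list(c(101, 105), c(NA, NA)),     # ... even another missing
    list(c(105, 101), c(252, 250))))  # unordered pairs
  mlg <- assign_mlg(tab)
  expect_equal(mlg[1], mlg[2])
  expect_equal(mlg[1], mlg[5])
  expect_false(mlg[3] == mlg[1])
  expect_false(mlg[3] == mlg[4])
  expect_equal(mlg, c(1, 1, 2, 3, 1))  # first-appearance numbering
})

test_that("allele distance counts allele differences and matches the multiset oracle", {
  rows <- list(
    list(c(101, 105), c(250, 252), c(300, 300)),
    list(c(101, 105), c(250, 252), c(300, 300)),
    list(c(101, 107), c(250, 252), c(300, 300)),
    list(c(107, 109), c(250, 252), c(300, 300)),
    list(c(101, 101), c(250, 252), c(300, 300)))
  tab <- toy_table(rows)
  expect_equal(allele_distance(tab, 1, 2), 0)
  expect_equal(allele_distance(tab, 1, 3), 1)  # one allele differs
  expect_equal(allele_distance(tab, 1, 4), 2)  # both alleles differ
  expect_equal(allele_distance(tab, 1, 5), 1)  # hom vs het sharing one allele
  # missing vs scored contributes 2; missing vs missing contributes 0
  tabm <- toy_table(list(list(c(101, 105), c(NA, NA)),
                         list(c(101, 105), c(250, 252)),
                         list(c(101, 105), c(NA, NA))))
  expect_equal(allele_distance(tabm, 1, 2), 2)
  expect_equal(allele_distance(tabm, 1, 3), 0)
  # random genotypes against the brute-force multiset oracle
  set.seed(11)
  for (k in 1:50) {
    r1 <- lapply(1:4, function(l) sort(sample(101:106, 2, replace = TRUE)))
    r2 <- lapply(1:4, function(l) sort(sample(101:106, 2, replace = TRUE)))
    t2 <- toy_table(list(r1, r2))
    expect_equal(allele_distance(t2, 1, 2), oracle_distance(r1, r2))
    expect_equal(allele_distance_matrix(t2)[1, 2], oracle_distance(r1, r2))
  }
})

test_that("MLL collapsing is single-linkage over the one-allele graph", {
  # chain: A-B distance 1, B-C distance 1, A-C distance 2 -> one MLL
  tab <- toy_table(list(
    list(c(101, 105), c(250, 252)),
    list(c(101, 107), c(250, 252)),
    list(c(107, 107), c(250, 252))))
  mlg <- assign_mlg(tab)
  D <- allele_distance_matrix(tab)
  expect_equal(D[1, 2], 1); expect_equal(D[2, 3], 1); expect_equal(D[1, 3], 2)
  mll <- collapse_mll(tab, mlg, threshold = 1)
  expect_equal(length(unique(mll)), 1)
  expect_length(attr(mll, "chained"), 1)
  # all pairwise distances >= 2: MLL count equals MLG count
  tab2 <- toy_table(list(
    list(c(101, 105), c(250, 252)),
    list(c(107, 109), c(250, 252)),
    list(c(101, 105), c(260, 262))))
  mlg2 <- assign_mlg(tab2)
  expect_equal(collapse_mll(tab2, mlg2), seq_len(3), ignore_attr = TRUE)
})

test_that("allele frequency schemes count genets, ramets or leave-one-out MLGs", {
  # two genets {(a,a)} and {(a,b)}, the first replicated 5 times
  rows <- c(replicate(5, list(list(c(101, 101), c(250, 252)))),
            list(list(c(101, 103), c(250, 252))))
  tab <- toy_table(rows)
  fg <- estimate_allele_freqs(tab, "per_genet")
  expect_equal(unname(fg[["L1"]]), c(0.75, 0.25))
  fr <- estimate_allele_freqs(tab, "per_ramet")
  expect_equal(unname(fr[["L1"]][1]), 11 / 12)
  expect_false(isTRUE(all.equal(fg[["L1"]][1], fr[["L1"]][1])))
  # round robin: MLGs redefined without the focal locus
  # inds 1-5 and 6 share the same L2 genotype, so without L1 they are one
  # MLG; frequencies at L1 then come from unique L2-defined genotypes
  rr <- estimate_allele_freqs(tab, "round_robin")
  # one MLG remains when L1 is ignored; its representative is ind 1 (101/101)
  expect_equal(unname(rr[["L1"]]), 1)
  # hand enumeration on a 3-locus toy
  tab3 <- toy_table(list(
    list(c(1, 2), c(5, 5), c(9, 9)),
    list(c(1, 2), c(5, 6), c(9, 9)),
    list(c(3, 3), c(5, 6), c(9, 9))))
  rr3 <- estimate_allele_freqs(tab3, "round_robin")
  # without L1: ind2 == ind3 on (L2, L3) -> 2 MLGs (reps ind1, ind2), both
  # carrying (1,2) at L1 -> equal frequencies and allele 3 unseen
  expect_equal(unname(rr3[["L1"]]), c(0.5, 0.5))
  # without L2: ind1 == ind2 on (L1, L3) -> 2 MLGs (reps ind1, ind3) whose
  # L2 alleles are (5,5) and (5,6)
  expect_equal(unname(rr3[["L2"]]), c(0.75, 0.25))
})

test_that("p_gen matches closed forms and hand-computed products", {
  tab <- toy_table(list(list(c(101, 101)), list(c(101, 103))))
  f1 <- list(L1 = c("101" = 1))
  expect_equal(p_gen(tab[1, 1], 1, f1), 1)
  fh <- list(L1 = c("101" = 0.5, "103" = 0.5))
  expect_equal(p_gen(tab, 2, fh), 0.5)
  expect_equal(p_gen(tab, 2, fh, f_is = 1), 0)
  expect_equal(p_gen(tab, 1, fh, f_is = 0.2), 0.25 + 0.25 * 0.2)
  # 3-locus product
  tab3 <- toy_table(list(list(c(1, 2), c(5, 5), c(9, 10))))
  fr <- list(L1 = c("1" = 0.2, "2" = 0.3, "3" = 0.5),
             L2 = c("5" = 0.6, "6" = 0.4),
             L3 = c("9" = 0.1, "10" = 0.9))
  expect_equal(p_gen(tab3, 1, fr),
               (2 * 0.2 * 0.3) * (0.36) * (2 * 0.1 * 0.9))
  # missing locus is skipped; unknown allele errors
  tabm <- toy_table(list(list(c(1, 2), c(NA, NA))))
  expect_equal(p_gen(tabm, 1, fr), 2 * 0.2 * 0.3)
  expect_error(p_gen(tab3, 1, list(L1 = c("1" = 1), L2 = fr$L2, L3 = fr$L3)),
               "absent")
})

test_that("p_sex obeys its limits, monotonicity and the binomial Monte-Carlo oracle", {
  expect_equal(p_sex(0, 2, 24), 0)
  expect_equal(p_sex(1, 2, 24), 1)
  pg <- seq(0.01, 0.9, length.out = 12)
  ps <- vapply(pg, p_sex, numeric(1), n_repeats = 3, n_sample = 24)
  expect_true(all(diff(ps) > 0))                       # increasing in pgen
  reps <- 2:6
  pr <- vapply(reps, function(k) p_sex(0.2, k, 24), numeric(1))
  expect_true(all(diff(pr) < 0))                       # decreasing in repeats
  # Monte-Carlo oracle: repeats among the N-1 remaining samples
  set.seed(99)
  draws <- stats::rbinom(1e6, 23, 0.01)
  mc <- mean(draws >= 1)
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(p_sex(0.01, 2, 24) - mc), 3 * se)
  expect_error(p_sex(1.2, 2, 24))
  expect_error(p_sex(0.5, 2, 1))
  # the alternative convention counts successes among all N draws
  expect_equal(p_sex(0.3, 2, 10, convention = "binomial_n"),
               stats::pbinom(1, 10, 0.3, lower.tail = FALSE))
})

test_that("clonal richness follows (G-1)/(N-1)", {
  expect_equal(clonal_richness(13, 23), 12 / 22)
  expect_equal(clonal_richness(10, 10), 1)
  expect_equal(clonal_richness(1, 24), 0)
  expect_error(clonal_richness(3, 1))
  expect_error(clonal_richness(5, 3))
})

test_that("Simpson's complement equals the pair-enumeration oracle exhaustively", {
  # oracle: probability two distinct sampled ramets are different genets,
  # enumerated over all ordered pairs
  oracle_D <- function(counts) {
    ids <- rep(seq_along(counts), counts)
    N <- length(ids)
    same <- 0
    for (i in 1:(N - 1)) for (j in (i + 1):N) same <- same + (ids[i] == ids[j])
    1 - same / choose(N, 2)
  }
  for (N in 2:12) {
    for (part in integer_partitions(N)) {
      s <- simpson_complement(part)
      expect_equal(s$D, oracle_D(part), tolerance = 1e-12)
      expect_true(s$D >= s$D_min - 1e-12 && s$D <= s$D_max + 1e-12)
    }
  }
  # named configurations
  s <- simpson_complement(c(19, 1, 1, 1, 1, 1))
  expect_equal(s$D, 1 - 342 / 552)
  expect_equal(s$D, s$D_min)
  se <- simpson_complement(c(4, 4, 4))
  expect_equal(se$D, se$D_max)
})

test_that("evenness V spans its bounds and is permutation-invariant", {
  expect_identical(evenness_v(c(19, 1, 1, 1, 1, 1)), 0)
  expect_equal(evenness_v(c(8, 8, 8)), 1)
  v <- evenness_v(c(14, 4, 3, 2, 1))
  s <- simpson_complement(c(14, 4, 3, 2, 1))
  expect_equal(v, (s$D - s$D_min) / (s$D_max - s$D_min))
  expect_gt(v, 0); expect_lt(v, 1)
  expect_equal(evenness_v(c(1, 2, 3, 4, 14)), v)  # order-invariant
  expect_true(is.na(evenness_v(c(24))))            # single genet: undefined
  expect_equal(evenness_v(c(1, 1, 1, 1)), 1)       # all singletons: even
})

test_that("pareto beta is recovered from power-law clone sizes", {
  set.seed(5)
  beta <- 1.5
  sizes <- floor(runif(500)^(-1 / beta))  # discrete survival s^(-beta)
  expect_lt(abs(fit_pareto_beta(sizes) - beta), 0.2)
  expect_true(is.na(fit_pareto_beta(c(4, 4, 4))))
  b <- fit_pareto_beta(c(19, 1, 1, 1, 1, 1))
  expect_equal(b, log(6) / log(19))  # exact two-point fit
})

test_that("clonal_partition recovers simulated truth and respects refinement", {
  cfg <- sim_config(seed = 31, n_per_pop = 24, genets_per_pop = 6,
                    pop_names = "P1", n_loci = 8,
                    clone_size_law = list(type = "dominant", n_dom = 19),
                    min_genet_dist = 3)
  sim <- simulate_dataset(cfg)
  part <- clonal_partition(sim$table)
  expect_equal(part$N, 24)
  expect_equal(part$n_mlg, 6)          # error-free: one MLG per genet
  expect_equal(part$G, 6)
  expect_equal(sort(part$ramet_counts, decreasing = TRUE),
               c(19, 1, 1, 1, 1, 1))
  expect_equal(part$R, 5 / 23)
  expect_identical(part$V, 0)
  # MLL is a coarsening of MLG; counts sum to N
  expect_equal(sum(part$ramet_counts), part$N)
  expect_true(part$G <= part$n_mlg)
  expect_true(all(part$psex$psex >= 0 & part$psex$psex <= 1))
  # R invariant to individual ordering
  perm <- sample(n_ind(sim$table))
  part_p <- clonal_partition(sim$table[perm, ])
  expect_equal(part_p$R, part$R)
  expect_equal(part_p$V, part$V)
})
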