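test_that("per-locus summary reproduces the heterozygote-excess closed forms", {
  # all individuals heterozygous (a,b), equal frequencies
  tab <- toy_table(replicate(24, list(list(c(343, 349), c(101, 103)))))
  d <- diversity_summary(tab)$per_locus
  expect_equal(d$Na, c(2, 2))
  expect_equal(d$Ho, c(1, 1))
  expect_equal(d$He, c(0.5, 0.5))
  expect_equal(d$F_IS, c(-1, -1))
  # the unbiased correction is reported alongside and exceeds He
  expect_equal(d$He_unbiased, (48 / 47) * d$He)
})

test_that("monomorphic loci report Na=1, zero heterozygosity, undefined F_IS", {
  tab <- toy_table(replicate(10, list(list(c(200, 200), c(101, 103)))))
  d <- diversity_summary(tab)$per_locus
  expect_equal(d$Na[1], 1)
  expect_equal(d$Ho[1], 0)
  expect_equal(d$He[1], 0)
  expect_true(is.na(d$F_IS[1]))
})

test_that("rarefied allelic richness hits the identity and is monotone", {
  set.seed(21)
  tab <- hw_table(30, freqs = c(0.5, 0.3, 0.15, 0.05), L = 2)
  d_full <- diversity_summary(tab, rarefaction_size = 60)$per_locus
  expect_equal(d_full$AR, d_full$Na)  # rarefy to the full sample: AR = Na
  sizes <- c(5, 10, 20, 40, 60)
  ar <- vapply(sizes, function(m)
    diversity_summary(tab, rarefaction_size = m)$per_locus$AR[1], numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
  expect_error(diversity_summary(tab, rarefaction_size = 61), "rarefaction")
})

test_that("private alleles are counted by cross-population scan", {
  tab <- toy_table(list(
    list(c(101, 103)), list(c(101, 105)),     # pop A: alleles 101,103,105
    list(c(101, 101)), list(c(101, 107))),    # pop B: alleles 101,107
    pop = c("A", "A", "B", "B"))
  d <- diversity_summary(tab, rarefaction_size = 4)
  pl <- d$per_locus
  expect_equal(pl$Ap[pl$population == "A"], 2)  # 103 and 105
  expect_equal(pl$Ap[pl$population == "B"], 1)  # 107
  total_alleles <- length(unique(c(tab$a1, tab$a2)))
  expect_lte(sum(pl$Ap), total_alleles)
})

test_that("HWE permutation test is seeded, detects excess, ignores monomorphism", {
  set.seed(3)
  tab <- hw_table(40, freqs = c(0.4, 0.3, 0.2, 0.1))
  p1 <- hwe_permutation_test(tab, 1, "P1", n_perm = 300, seed = 7)
  p2 <- hwe_permutation_test(tab, 1, "P1", n_perm = 300, seed = 7)
  expect_identical(p1, p2)
  expect_gt(p1, 0); expect_lte(p1, 1)
  # all-heterozygote sample: strong heterozygote excess, small p
  het <- toy_table(replicate(30, list(list(c(101, 103)))))
  p_het <- hwe_permutation_test(het, 1, "P1", n_perm = 300, seed = 1)
  expect_lt(p_het, 0.01)
  mono <- toy_table(replicate(10, list(list(c(101, 101)))))
  expect_true(is.na(hwe_permutation_test(mono, 1, "P1", n_perm = 100, seed = 1)))
})

test_that("linkage test flags a locus paired with itself and is reproducible", {
  set.seed(9)
  tab <- hw_table(40, freqs = c(0.4, 0.3, 0.2, 0.1), L = 1)
  dup <- genotype_table(tab$ind, as.character(tab$pop), c("hw1", "copy"),
                        cbind(tab$a1, tab$a1), cbind(tab$a2, tab$a2))
  p_dup <- linkage_permutation_test(dup, c("hw1", "copy"), "P1",
                                    n_perm = 499, seed = 5)
  expect_lt(p_dup, 0.01)  # perfect association sits at the minimum p
  ind <- hw_table(40, freqs = c(0.5, 0.3, 0.2), L = 2)
  pa <- linkage_permutation_test(ind, c(1, 2), "P1", n_perm = 300, seed = 11)
  pb <- linkage_permutation_test(ind, c(1, 2), "P1", n_perm = 300, seed = 11)
  expect_identical(pa, pb)
  mono <- toy_table(replicate(10, list(list(c(1, 1), c(2, 3)))))
  expect_true(is.na(linkage_permutation_test(mono, c(1, 2), "P1",
                                             n_perm = 100, seed = 1)))
})

test_that("Brookfield null-allele screen recovers an injected null frequency", {
  # balanced heterozygous locus: r = 0 and no flag
  bal <- toy_table(replicate(20, list(list(c(101, 103)))))
  res_bal <- null_allele_test(bal, 1, "P1")
  expect_true(res_bal$testable)
  expect_lt(res_bal$r, 0)   # Ho > He: negative estimate, never flagged
  expect_false(res_bal$flag)
  # simulate a locus with a true null allele at frequency 0.3
  set.seed(17)
  n <- 200
  vis <- c(101, 103, 105)
  draw <- function() {
    a <- ifelse(runif(2) < 0.3, 0, sample(vis, 2, replace = TRUE))
    a
  }
  g <- replicate(n, draw())
  a1 <- g[1, ]; a2 <- g[2, ]
  both_null <- a1 == 0 & a2 == 0
  vis_allele <- pmax(a1, a2)
  a1v <- ifelse(a1 == 0 | a2 == 0, vis_allele, a1)
  a2v <- ifelse(a1 == 0 | a2 == 0, vis_allele, a2)
  a1v[both_null] <- NA; a2v[both_null] <- NA
  tab <- genotype_table(sprintf("n%03d", 1:n), rep("P1", n), "L1",
                        matrix(a1v), matrix(a2v))
  res <- null_allele_test(tab, 1, "P1")
  expect_true(res$flag)
  expect_gt(res$r, 0.1)
  # Chakraborty's estimator is the consistent one under blank exclusion
  expect_lt(abs(res$r_chakraborty - 0.3), 0.1)
  # homozygote-only polymorphic locus is flagged
  hom <- toy_table(c(replicate(12, list(list(c(101, 101)))),
                     replicate(12, list(list(c(105, 105))))))
  res_hom <- null_allele_test(hom, 1, "P1")
  expect_true(res_hom$flag)
  # small or monomorphic samples are not testable
  tiny <- toy_table(replicate(4, list(list(c(101, 103)))))
  expect_false(null_allele_test(tiny, 1, "P1")$testable)
})

test_that("locus_qc_flags combines the screens into locus-level drop lists", {
  set.seed(23)
  # locus 1: homozygote-only polymorphic (null pattern); loci 2-4 clean HWE;
  # locus 5 duplicates locus 3 (perfect linkage)
  n <- 30
  hom <- sample(c(101, 105), n, replace = TRUE)
  clean <- replicate(3, {
    al <- c(201, 203, 205)
    cbind(sample(al, n, TRUE), sample(al, n, TRUE))
  })
  a1 <- cbind(hom, clean[, 1, 1], clean[, 1, 2], clean[, 1, 3], clean[, 1, 2])
  a2 <- cbind(hom, clean[, 2, 1], clean[, 2, 2], clean[, 2, 3], clean[, 2, 2])
  tab <- genotype_table(sprintf("q%02d", 1:n), rep("P1", n),
                        paste0("L", 1:5), a1, a2)
  fl <- locus_qc_flags(tab, n_perm = 300, seed = 2)
  expect_true("L1" %in% fl$null_allele_flags)
  expect_true(all(c("L3", "L5") %in% fl$linkage_flags))
  res <- apply_locus_qc(tab, fl$null_allele_flags, fl$linkage_flags)
  expect_true(all(c("L2", "L4") %in% res$table$loci))
  expect_false("L1" %in% res$table$loci)
})
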