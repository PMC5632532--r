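# Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

# allele-sharing distance between two raw genotype vectors (sorted pairs)
pair_dist_vec <- function(a1, a2, b1, b2) {
  d <- 0L
  for (l in seq_along(a1))
    d <- d + 2L - pair_match_count(a1[l], a2[l], b1[l], b2[l])
  d
}

#' Configuration for the clonal-population simulator
#'
#' Parameterizes [simulate_dataset]. Defaults emulate the sampling design
#' of a two-locality invasive-coral microsatellite survey: two
#' populations of ~24 colonies genotyped at ~10 loci carrying 1-5 alleles
#' each, with heavy clonal replication dominated by one genet per site.
#'
#' @param seed RNG seed (mandatory; the same seed reproduces the dataset
#'   byte for byte).
#' @param n_per_pop ramets (colonies) sampled per population.
#' @param genets_per_pop distinct genets per population.
#' @param pop_names population labels.
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus integer vector (recycled) of allele counts per
#'   locus.
#' @param dirichlet_conc concentration of the ancestral Dirichlet allele
#'   frequencies (1 = uniform on the simplex).
#' @param divergence_F Balding-Nichols divergence: population frequencies
#'   are drawn from `Dirichlet(ancestral * (1 - F) / F)`, so larger `F`
#'   means more drift between populations. Must lie in (0, 1).
#' @param f_is_sim probability that a genet is autozygous at a locus
#'   (both gene copies identical by descent), creating homozygote excess.
#' @param clone_size_law list describing the ramet counts per genet:
#'   `list(type = "dominant", n_dom = 19)` (one dominant clone, the rest
#'   as even as possible), `list(type = "uniform")`,
#'   `list(type = "pareto", beta = 1.5)` (power-law sizes), or
#'   `list(type = "fixed_counts", counts = list(popA = c(...), ...))`.
#' @param scoring_error_rate per-ramet probability that one randomly
#'   chosen allele is mis-scored by one repeat unit (the classic source
#'   of spurious one-allele MLG pairs).
#' @param missing_rate per-call probability of a failed amplification.
#' @param null_allele_freq numeric vector (recycled over loci) of null
#'   allele frequencies; carriers render as apparent homozygotes for the
#'   visible allele, null homozygotes as missing.
#' @param repeat_bp repeat-unit length in bp (allele sizes are
#'   `base + index * repeat_bp`).
#' @param min_genet_dist minimum pairwise allele distance enforced
#'   between genets within a population (0 disables; used by fixtures to
#'   keep clone recovery unambiguous).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_per_pop = 24, genets_per_pop = 6,
                       pop_names = c("TSB", "IGB"),
                       n_loci = 10, alleles_per_locus = c(2, 3, 4, 5),
                       dirichlet_conc = 1,
                       divergence_F = 0.1, f_is_sim = 0,
                       clone_size_law = list(type = "dominant", n_dom = 19),
                       scoring_error_rate = 0, missing_rate = 0,
                       null_allele_freq = 0, repeat_bp = 3,
                       min_genet_dist = 0) {
  stopifnot(divergence_F > 0, divergence_F < 1,
            f_is_sim >= 0, f_is_sim <= 1,
            scoring_error_rate >= 0, scoring_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(seed = seed, n_per_pop = n_per_pop,
                 genets_per_pop = genets_per_pop, pop_names = pop_names,
                 n_loci = n_loci,
                 alleles_per_locus = rep_len(alleles_per_locus, n_loci),
                 dirichlet_conc = dirichlet_conc,
                 divergence_F = divergence_F, f_is_sim = f_is_sim,
                 clone_size_law = clone_size_law,
                 scoring_error_rate = scoring_error_rate,
                 missing_rate = missing_rate,
                 null_allele_freq = rep_len(null_allele_freq, n_loci),
                 repeat_bp = repeat_bp, min_genet_dist = min_genet_dist),
            class = "sim_config")
}

clone_sizes_from_law <- function(law, n, g, pop) {
  sizes <- switch(law$type,
    fixed_counts = {
      # explicit counts are authoritative for both G and N
      if (is.list(law$counts)) law$counts[[pop]] else law$counts
    },
    dominant = {
      if (law$n_dom > n - (g - 1)) stop("dominant clone too large for ", g, " genets")
      rest <- n - law$n_dom
      base <- rep(rest %/% (g - 1), g - 1)
      extra <- rest %% (g - 1)
      if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
      c(law$n_dom, base)
    },
    uniform = {
      base <- rep(n %/% g, g)
      extra <- n %% g
      if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
      base
    },
    pareto = {
      pmf <- (1:n)^(-(law$beta + 1))
      s <- sample(1:n, g, replace = TRUE, prob = pmf)
      # adjust to the requested total, preserving the shape
      while (sum(s) != n) {
        if (sum(s) > n) {
          i <- which.max(s); if (s[i] > 1) s[i] <- s[i] - 1L else s <- s[-i]
        } else {
          i <- which.max(s); s[i] <- s[i] + 1L
        }
      }
      sort(s, decreasing = TRUE)
    },
    stop("unknown clone_size_law type: ", law$type))
  if (any(sizes < 1)) stop("infeasible clone sizes")
  as.integer(sizes)
}

#' Simulate a clonal microsatellite dataset with known truth
#'
#' Draws, for each population, allele frequencies under the
#' Balding-Nichols model, genet genotypes with optional inbreeding and
#' null alleles, replicates genets according to the configured clone-size
#' law, and finally applies per-ramet scoring errors and missing calls.
#' Fully deterministic under the config seed.
#'
#' @param config a [sim_config].
#' @return list with `table` (a [genotype_table]) and `truth`, a record
#'   of the simulated genet of every ramet, the pre-error genet
#'   genotypes, the drawn population allele frequencies, clone sizes, and
#'   every injected scoring error, null-allele masking and missing call.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  loci <- sprintf("Loc%02d", seq_len(L))
  base_bp <- sample(seq(120, 420, by = 10), L, replace = TRUE)
  sizes_of <- function(l) base_bp[l] + config$repeat_bp * seq_len(config$alleles_per_locus[l])
  anc <- lapply(seq_len(L), function(l)
    rdirichlet1(rep(config$dirichlet_conc, config$alleles_per_locus[l])))
  Fbn <- config$divergence_F
  pop_freqs <- lapply(config$pop_names, function(p)
    lapply(seq_len(L), function(l) {
      f <- if (length(anc[[l]]) == 1) 1 else rdirichlet1(anc[[l]] * (1 - Fbn) / Fbn)
      names(f) <- as.character(sizes_of(l))
      f
    }))
  names(pop_freqs) <- config$pop_names

  draw_genet <- function(freqs) {
    a1 <- a2 <- integer(L)
    for (l in seq_len(L)) {
      f <- freqs[[l]]
      al <- as.integer(names(f))
      # null allele: a hidden gene copy coded 0
      rnull <- config$null_allele_freq[l]
      draw_copy <- function() {
        if (rnull > 0 && stats::runif(1) < rnull) 0L
        else if (length(al) == 1) al else sample(al, 1, prob = f)
      }
      if (stats::runif(1) < config$f_is_sim) {
        v <- draw_copy(); a1[l] <- v; a2[l] <- v
      } else {
        a1[l] <- draw_copy(); a2[l] <- draw_copy()
      }
      if (a1[l] > a2[l]) { tmp <- a1[l]; a1[l] <- a2[l]; a2[l] <- tmp }
    }
    list(a1 = a1, a2 = a2)
  }

  ind <- character(0); pop <- character(0)
  A1 <- NULL; A2 <- NULL
  genet_of <- integer(0)
  truth_genets <- list(); clone_sizes <- list()
  errors <- list(); null_masked <- list(); missing_log <- list()
  genet_counter <- 0L
  for (p in config$pop_names) {
    g <- config$genets_per_pop
    cs <- clone_sizes_from_law(config$clone_size_law, config$n_per_pop, g, p)
    g <- length(cs)
    clone_sizes[[p]] <- cs
    genets <- list()
    for (k in seq_len(g)) {
      ok <- FALSE
      for (try in seq_len(500)) {
        cand <- draw_genet(pop_freqs[[p]])
        if (config$min_genet_dist <= 0 || length(genets) == 0 ||
            all(vapply(genets, function(gn)
              pair_dist_vec(cand$a1, cand$a2, gn$a1, gn$a2), integer(1)) >=
              config$min_genet_dist)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place genet ", k, " in ", p,
                    " at min distance ", config$min_genet_dist)
      genets[[k]] <- cand
    }
    truth_genets[[p]] <- genets
    for (k in seq_len(g)) {
      gid <- genet_counter + k
      for (r in seq_len(cs[k])) {
        i <- length(ind) + 1L
        ind <- c(ind, sprintf("%s_%03d", p, length(which(pop == p)) + 1L))
        pop <- c(pop, p)
        genet_of <- c(genet_of, gid)
        a1 <- genets[[k]]$a1; a2 <- genets[[k]]$a2
        # null rendering: one null copy -> visible homozygote; two -> missing
        for (l in seq_len(L)) {
          if (a1[l] == 0L && a2[l] == 0L) {
            a1[l] <- NA_integer_; a2[l] <- NA_integer_
            null_masked[[length(null_masked) + 1L]] <-
              data.frame(ind = ind[i], locus = loci[l], kind = "null_homozygote")
          } else if (a1[l] == 0L || a2[l] == 0L) {
            vis <- max(a1[l], a2[l])
            a1[l] <- vis; a2[l] <- vis
            null_masked[[length(null_masked) + 1L]] <-
              data.frame(ind = ind[i], locus = loci[l], kind = "null_carrier")
          }
        }
        # scoring error: one allele shifted one repeat unit
        if (config$scoring_error_rate > 0 &&
            stats::runif(1) < config$scoring_error_rate) {
          cand_l <- which(!is.na(a1))
          if (length(cand_l)) {
            l <- if (length(cand_l) == 1) cand_l else sample(cand_l, 1)
            slot <- sample(1:2, 1)
            shift <- sample(c(-1L, 1L), 1) * config$repeat_bp
            if (slot == 1) a1[l] <- a1[l] + shift else a2[l] <- a2[l] + shift
            if (a1[l] > a2[l]) { tmp <- a1[l]; a1[l] <- a2[l]; a2[l] <- tmp }
            errors[[length(errors) + 1L]] <-
              data.frame(ind = ind[i], locus = loci[l], shift_bp = shift)
          }
        }
        # random missing calls
        if (config$missing_rate > 0) {
          drop <- which(stats::runif(L) < config$missing_rate)
          for (l in drop) {
            if (!is.na(a1[l]))
              missing_log[[length(missing_log) + 1L]] <-
                data.frame(ind = ind[i], locus = loci[l])
            a1[l] <- NA_integer_; a2[l] <- NA_integer_
          }
        }
        A1 <- rbind(A1, a1); A2 <- rbind(A2, a2)
      }
    }
    genet_counter <- genet_counter + g
  }
  tab <- genotype_table(ind, pop, loci, A1, A2)
  bind_or_empty <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  truth <- list(
    config = config,
    genet_of = stats::setNames(genet_of, ind),
    genets = truth_genets,
    pop_freqs = pop_freqs,
    clone_sizes = clone_sizes,
    loci = loci,
    errors = bind_or_empty(errors, data.frame(ind = character(0),
                                              locus = character(0),
                                              shift_bp = integer(0))),
    null_masked = bind_or_empty(null_masked,
                                data.frame(ind = character(0),
                                           locus = character(0),
                                           kind = character(0))),
    missing = bind_or_empty(missing_log, data.frame(ind = character(0),
                                                    locus = character(0))))
  list(table = tab, truth = truth)
}

#' Two-species, two-locality fixture shaped like the coral survey
#'
#' Builds two synthetic datasets (one per species) each covering two
#' localities, with the clone-size structure of the published survey:
#' species 1 has 23 ramets in 13 genets at the first locality (largest
#' clone of 4) and 24 ramets in 6 genets dominated by a 19-ramet clone at
#' the second; species 2 has 24 ramets in 5 genets (dominant 14) and
#' 24 in 3 genets (dominant 22), plus 2 and 3 single-allele scoring
#' errors respectively, so its MLG counts (7 and 6) exceed its MLL counts
#' (5 and 3) exactly as lineage collapsing must recover. Genets within a
#' locality are kept at allele distance >= 3 so recovery is unambiguous;
#' the tables carry no missing data and emulate an already
#' quality-controlled panel of 8 loci. All truth is returned alongside.
#'
#' @param seed RNG seed.
#' @return list with `species1`, `species2` (each a list `table`,
#'   `truth`) and `expected`, a data.frame of the designed N, MLG, MLL
#'   per species/locality.
#' @export
make_paper_like_fixture <- function(seed = 1) {
  base1 <- sim_config(seed = seed, n_per_pop = 23, genets_per_pop = 13,
                      pop_names = c("TSB", "IGB"), n_loci = 8,
                      alleles_per_locus = c(2, 3, 4, 5, 2, 3, 4, 5),
                      divergence_F = 0.1, f_is_sim = 0,
                      clone_size_law = list(type = "fixed_counts",
                        counts = list(TSB = c(4, 3, 3, 2, 2, 2, 1, 1, 1, 1, 1, 1, 1),
                                      IGB = c(19, 1, 1, 1, 1, 1))),
                      min_genet_dist = 3)
  # fixed_counts carries its own per-pop genet numbers
  sp1 <- simulate_fixture_species(base1)
  base2 <- sim_config(seed = seed + 1000L, n_per_pop = 24, genets_per_pop = 5,
                      pop_names = c("TSB", "IGB"), n_loci = 8,
                      alleles_per_locus = c(2, 3, 4, 5, 2, 3, 4, 5),
                      divergence_F = 0.1, f_is_sim = 0,
                      clone_size_law = list(type = "fixed_counts",
                        counts = list(TSB = c(14, 4, 3, 2, 1),
                                      IGB = c(22, 1, 1))),
                      min_genet_dist = 3)
  sp2 <- simulate_fixture_species(base2, errors_per_pop = c(TSB = 2, IGB = 3))
  expected <- data.frame(
    species = c("species1", "species1", "species2", "species2"),
    population = c("TSB", "IGB", "TSB", "IGB"),
    N = c(23, 24, 24, 24),
    MLG = c(13, 6, 7, 6),
    MLL = c(13, 6, 5, 3))
  list(species1 = sp1, species2 = sp2, expected = expected)
}

# simulate one species table honoring per-pop fixed counts, then inject
# exactly `errors_per_pop` one-allele scoring errors into the dominant
# clone of each population (distinct loci, +1 repeat unit)
simulate_fixture_species <- function(config, errors_per_pop = NULL) {
  counts <- config$clone_size_law$counts
  # simulate_dataset uses genets_per_pop from fixed counts length per pop
  sim <- simulate_dataset_fixed(config, counts)
  if (!is.null(errors_per_pop)) {
    tab <- sim$table
    for (p in names(errors_per_pop)) {
      k <- errors_per_pop[[p]]
      if (k == 0) next
      pop_idx <- which(as.character(tab$pop) == p)
      gids <- sim$truth$genet_of[pop_idx]
      dom <- as.integer(names(which.max(table(gids))))
      ram <- pop_idx[gids == dom]
      victims <- ram[seq(2, length.out = k)]  # keep ramet 1 as the reference
      for (j in seq_len(k)) {
        i <- victims[j]
        l <- j  # distinct locus per error
        tab$a2[i, l] <- tab$a2[i, l] + config$repeat_bp
        sim$truth$errors <- rbind(sim$truth$errors,
          data.frame(ind = tab$ind[i], locus = tab$loci[l],
                     shift_bp = config$repeat_bp))
      }
    }
    sim$table <- tab
  }
  sim
}

# fixed-counts wrapper: allows a different genet count per population
simulate_dataset_fixed <- function(config, counts) {
  cfgs <- config
  cfgs$clone_size_law <- list(type = "fixed_counts", counts = counts)
  # genets_per_pop is ignored by the fixed_counts law
  simulate_dataset(cfgs)
}
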