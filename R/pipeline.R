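#' Pipeline configuration
#'
#' Bundles every tunable of [run_pipeline] with the package defaults:
#' GenAlEx missing code 0, at most one missing locus per retained
#' individual, MLL collapse at one allele difference, Psex threshold
#' 0.001 under the Parks-Werth convention with genet-based allele
#' frequencies, and mandatory RNG seed.
#'
#' @param seed RNG seed (mandatory; every permutation test derives its
#'   seed from it).
#' @param missing_code missing-data code in input files.
#' @param max_missing_loci individual filter threshold (see
#'   [filter_individuals_by_missing]).
#' @param mll_threshold allele-distance threshold for [collapse_mll].
#' @param psex_alpha significance level for calling ramets.
#' @param psex_convention see [p_sex].
#' @param freq_scheme see [estimate_allele_freqs].
#' @param rarefaction_size gene copies for allelic richness (`NULL` =
#'   smallest scored cell).
#' @param n_perm permutations for HWE/linkage/differentiation tests.
#' @param run_locus_qc whether to run the null-allele and linkage screens
#'   and drop flagged loci; disable for panels that are already
#'   quality-controlled.
#' @param qc_alpha family-wise alpha of the QC screens.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed, missing_code = 0L, max_missing_loci = 1,
                            mll_threshold = 1, psex_alpha = 0.001,
                            psex_convention = "parks_werth",
                            freq_scheme = "per_genet",
                            rarefaction_size = NULL, n_perm = 1000,
                            run_locus_qc = TRUE, qc_alpha = 0.05) {
  if (missing(seed)) stop("a seed is mandatory for pipeline runs")
  structure(as.list(environment()), class = "pipeline_config")
}

# one representative per MLL within each population: the member with the
# fewest missing loci, ties broken by input order
mll_representatives <- function(x, part_by_pop) {
  keep <- integer(0)
  for (p in names(part_by_pop)) {
    idx <- which(as.character(x$pop) == p)
    part <- part_by_pop[[p]]
    miss <- rowSums(is.na(x$a1[idx, , drop = FALSE]))
    for (k in sort(unique(part$mll_of_ind))) {
      members <- which(part$mll_of_ind == k)
      best <- members[order(miss[members], members)][1]
      keep <- c(keep, idx[best])
    }
  }
  sort(keep)
}

#' Run the full clonal population-genetics pipeline
#'
#' Fixed stage order: (1) import; (2) optional locus QC — the null-allele
#' and linkage screens are evaluated on one representative per
#' provisional MLG per population, null-allele drops applied first and
#' linkage evaluated among survivors; (3) the individual missing-data
#' filter; (4) clone discrimination per population (MLG assignment, MLL
#' collapsing, Psex), run twice so the Psex inbreeding correction can use
#' the per-population multilocus F_IS estimated on unique MLLs (floored
#' at 0); (5) per-locus and per-population diversity on exactly one
#' representative per MLL; (6) pairwise differentiation on the same
#' representatives. No statistic downstream of stage 4 ever sees ramet
#' duplicates.
#'
#' @param x a [genotype_table], or a path read with
#'   [read_genotype_table].
#' @param config a [pipeline_config].
#' @param dialect input dialect when `x` is a path.
#' @return object of class `clonepop_report`: list with `per_pop`
#'   (population, N, MLG, MLL, R, V, pareto_beta, A, AR, Ap, Ho, He,
#'   F_IS), `per_locus`, `clones` (individual-level MLG/MLL/Psex),
#'   `differentiation`, `locus_meta`, `qc`, `log`, `config`.
#' @export
run_pipeline <- function(x, config, dialect = "genalex") {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  if (is.character(x)) {
    x <- read_genotype_table(x, dialect = dialect,
                             missing_code = config$missing_code)
    note("imported ", n_ind(x), " individuals x ", n_loci(x), " loci")
  }
  validate_genotype_table(x)
  set.seed(config$seed)
  note("seed = ", config$seed)

  # stage 2: locus QC on provisional unique MLGs
  locus_meta <- data.frame(locus = x$loci, status = "retained",
                           stringsAsFactors = FALSE)
  qc <- NULL
  if (config$run_locus_qc) {
    mlg0 <- assign_mlg(x)
    rep0 <- match(seq_len(max(mlg0)), mlg0)
    qc <- locus_qc_flags(x[rep0, ], n_perm = config$n_perm,
                         seed = config$seed + 1L, alpha = config$qc_alpha)
    res <- apply_locus_qc(x, qc$null_allele_flags, qc$linkage_flags)
    x <- res$table
    locus_meta <- res$meta
    note("locus QC: dropped ",
         sum(locus_meta$status != "retained"), " of ",
         nrow(locus_meta), " loci (",
         paste(locus_meta$locus[locus_meta$status != "retained"],
               collapse = ", "), ")")
  } else note("locus QC skipped (panel treated as pre-screened)")

  # stage 3: individual missing filter
  before <- n_ind(x)
  x <- filter_individuals_by_missing(x, config$max_missing_loci)
  removed <- attr(x, "removed")
  note("missing filter (<= ", config$max_missing_loci, " loci): removed ",
       before - n_ind(x), " individuals",
       if (length(removed)) paste0(" (", paste(removed, collapse = ", "), ")") else "")

  # stage 4: clone discrimination per population, two passes for F_IS
  pops <- levels(x$pop)
  part1 <- lapply(pops, function(p) {
    clonal_partition(x[as.character(x$pop) == p, ],
                     threshold = config$mll_threshold,
                     freq_scheme = config$freq_scheme, f_is = 0,
                     psex_convention = config$psex_convention,
                     psex_alpha = config$psex_alpha)
  })
  names(part1) <- pops
  reps1 <- mll_representatives(x, part1)
  div1 <- diversity_summary(x[reps1, ],
                            rarefaction_size = config$rarefaction_size)
  parts <- lapply(pops, function(p) {
    fis <- div1$per_pop$F_IS[div1$per_pop$population == p]
    fis <- if (is.na(fis)) 0 else max(fis, 0)  # floor negative F_IS at 0
    clonal_partition(x[as.character(x$pop) == p, ],
                     threshold = config$mll_threshold,
                     freq_scheme = config$freq_scheme, f_is = fis,
                     psex_convention = config$psex_convention,
                     psex_alpha = config$psex_alpha)
  })
  names(parts) <- pops
  for (p in pops)
    note("clones [", p, "]: N=", parts[[p]]$N, " MLG=", parts[[p]]$n_mlg,
         " MLL=", parts[[p]]$G)

  # stage 5: diversity on unique MLLs
  reps <- mll_representatives(x, parts)
  xu <- x[reps, ]
  div <- diversity_summary(xu, rarefaction_size = config$rarefaction_size)
  note("diversity on ", n_ind(xu), " unique MLLs; rarefaction to ",
       div$rarefaction_size, " gene copies")

  # stage 6: differentiation on unique MLLs
  diff <- NULL
  if (length(pops) >= 2 &&
      all(table(factor(as.character(xu$pop), levels = pops)) >= 2)) {
    diff <- pairwise_differentiation(xu, n_perm = config$n_perm,
                                     seed = config$seed + 2L)
    note("differentiation over ", nrow(diff), " population pair(s)")
  } else note("differentiation skipped: a population has < 2 genets")

  per_pop <- do.call(rbind, lapply(pops, function(p) {
    pt <- parts[[p]]
    dv <- div$per_pop[div$per_pop$population == p, ]
    data.frame(population = p, N = pt$N, MLG = pt$n_mlg, MLL = pt$G,
               R = pt$R, V = pt$V, pareto_beta = pt$pareto_beta,
               A = dv$A, AR = dv$AR, Ap = dv$Ap,
               Ho = dv$Ho, He = dv$He, F_IS = dv$F_IS,
               stringsAsFactors = FALSE)
  }))
  clones <- do.call(rbind, lapply(pops, function(p) {
    pt <- parts[[p]]
    sub_ind <- x$ind[as.character(x$pop) == p]
    ps <- pt$psex
    psex_of_mlg <- stats::setNames(ps$psex, ps$mlg)
    data.frame(individual = sub_ind, population = p,
               mlg = pt$mlg_of, mll = pt$mll_of_ind,
               mll_size = pt$ramet_counts[pt$mll_of_ind],
               psex = unname(psex_of_mlg[as.character(pt$mlg_of)]),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_pop = per_pop, per_locus = div$per_locus,
                 clones = clones, differentiation = diff,
                 locus_meta = locus_meta, qc = qc,
                 rarefaction_size = div$rarefaction_size,
                 log = log, config = config),
            class = "clonepop_report")
}

#' @export
print.clonepop_report <- function(x, ...) {
  cat("clonepop pipeline report\n")
  cat("------------------------\n")
  print(x$per_pop, row.names = FALSE, digits = 3)
  if (!is.null(x$differentiation)) {
    cat("\npairwise differentiation:\n")
    print(x$differentiation, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits `per_pop.tsv`, `per_locus.tsv`, `clones.tsv`,
#' `differentiation.tsv` (when computed), `report.json` and `run.log`
#' into `dir`. Output is byte-stable for a fixed config and input.
#'
#' @param report a `clonepop_report` from [run_pipeline].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "clonepop_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$per_pop, "per_pop.tsv")
  wt(report$per_locus, "per_locus.tsv")
  wt(report$clones, "clones.tsv")
  if (!is.null(report$differentiation))
    wt(report$differentiation, "differentiation.tsv")
  json <- list(per_pop = report$per_pop,
               differentiation = report$differentiation,
               locus_meta = report$locus_meta,
               rarefaction_size = report$rarefaction_size,
               seed = report$config$seed)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}
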