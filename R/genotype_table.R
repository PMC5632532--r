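#' Diploid multilocus genotype table
#'
#' The universal input container of the package: a set of individuals
#' (coral colonies or other ramets), each assigned to a population and
#' scored at a common set of codominant microsatellite loci. Every
#' non-missing call is an unordered pair of integer allele sizes (fragment
#' lengths in bp); a missing call carries `NA` for both alleles. Ploidy is
#' fixed at two.
#'
#' @param ind character vector of individual identifiers (unique).
#' @param pop character or factor of population labels, one per individual.
#'   Every population must contain at least one individual.
#' @param loci character vector of locus names (unique).
#' @param a1,a2 integer matrices (individuals x loci) holding the two
#'   alleles of each call. Pairs are stored sorted so that `a1 <= a2`;
#'   missing calls are `NA` in both. Homozygotes repeat the same value.
#'
#' @return An object of class `genotype_table`: a list with elements
#'   `ind`, `pop` (factor), `loci`, `a1`, `a2`.
#' @export
genotype_table <- function(ind, pop, loci, a1, a2) {
  ind  <- as.character(ind)
  loci <- as.character(loci)
  pop  <- if (is.factor(pop)) factor(as.character(pop), levels = unique(as.character(pop)))
          else factor(as.character(pop), levels = unique(as.character(pop)))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- list(ind, loci)
  # store each pair sorted
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  x <- structure(list(ind = ind, pop = pop, loci = loci, a1 = a1, a2 = a2),
                 class = "genotype_table")
  validate_genotype_table(x)
  x
}

validate_genotype_table <- function(x) {
  stopifnot(inherits(x, "genotype_table"))
  n <- length(x$ind); L <- length(x$loci)
  if (anyDuplicated(x$ind)) stop("duplicated individual identifiers")
  if (anyDuplicated(x$loci)) stop("duplicated locus names")
  if (length(x$pop) != n) stop("population labels do not match individuals")
  if (!all(dim(x$a1) == c(n, L)) || !all(dim(x$a2) == c(n, L)))
    stop("allele matrices do not match individuals x loci")
  half <- xor(is.na(x$a1), is.na(x$a2))
  if (any(half))
    stop("half-missing call (one allele NA): every call must have two alleles or be fully missing")
  if (any(x$a1 <= 0, na.rm = TRUE) || any(x$a2 <= 0, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  if (any(tabulate(x$pop, nbins = nlevels(x$pop)) == 0))
    stop("empty population: ", paste(levels(x$pop)[tabulate(x$pop, nbins = nlevels(x$pop)) == 0], collapse = ", "))
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ind), "individuals x", length(x$loci), "loci\n")
  tab <- table(x$pop)
  cat("populations:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "), "\n")
  cat("missing calls:", sum(is.na(x$a1)), "of", length(x$a1), "\n")
  invisible(x)
}

#' Number of individuals / loci
#' @param x a `genotype_table`.
#' @return integer count.
#' @export
n_ind <- function(x) length(x$ind)

#' @rdname n_ind
#' @export
n_loci <- function(x) length(x$loci)

#' Subset a genotype table
#'
#' @param x a `genotype_table`.
#' @param i individual index (integer, logical or character).
#' @param j locus index (integer, logical or character).
#' @param ... unused.
#' @return a new `genotype_table`. Population levels are re-derived so that
#'   no empty population survives subsetting.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ind)
  if (missing(j)) j <- seq_along(x$loci)
  if (is.character(i)) i <- match(i, x$ind)
  if (is.character(j)) j <- match(j, x$loci)
  genotype_table(x$ind[i], as.character(x$pop)[i], x$loci[j],
                 x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE])
}

#' Per-individual count of missing loci
#' @param x a `genotype_table`.
#' @return named integer vector.
#' @export
missing_counts <- function(x) {
  cnt <- rowSums(is.na(x$a1))
  names(cnt) <- x$ind
  cnt
}

#' Restrict a table to individuals with little missing data
#'
#' Retains individuals whose number of missing loci does not exceed
#' `max_missing_loci` (default 1, the usual keep rule for clonal
#' microsatellite surveys: specimens failing at more than one locus are
#' discarded before clone discrimination).
#'
#' @param x a `genotype_table`.
#' @param max_missing_loci maximum tolerated number of missing loci.
#' @return the filtered `genotype_table`, with attribute `"removed"` listing
#'   the identifiers that were dropped.
#' @export
filter_individuals_by_missing <- function(x, max_missing_loci = 1) {
  stopifnot(max_missing_loci >= 0)
  keep <- missing_counts(x) <= max_missing_loci
  if (!any(keep)) stop("all individuals removed by the missing-data filter")
  out <- x[which(keep), ]
  attr(out, "removed") <- x$ind[!keep]
  out
}

#' Apply locus quality control
#'
#' Removes loci flagged by the diversity-stage screens. Null-allele flags
#' are applied first; linkage flags are taken at face value on the
#' survivors (the linkage screen is expected to have been run, or re-run,
#' on loci that survived the null-allele pass). Surviving genotype calls
#' are never altered.
#'
#' @param x a `genotype_table`.
#' @param null_allele_flags character vector of locus names flagged for
#'   null alleles (e.g. homozygote-only patterns), or `NULL`.
#' @param linkage_flags character vector of locus names flagged for linkage
#'   disequilibrium with other loci, or `NULL`.
#' @return list with `table` (filtered `genotype_table`) and `meta`, a
#'   data.frame with one row per input locus and its `status`:
#'   `retained`, `dropped_null_alleles` or `dropped_linkage`.
#' @export
apply_locus_qc <- function(x, null_allele_flags = NULL, linkage_flags = NULL) {
  status <- rep("retained", length(x$loci))
  names(status) <- x$loci
  status[x$loci %in% null_allele_flags] <- "dropped_null_alleles"
  # null-allele drops take precedence; linkage only marks survivors
  lk <- setdiff(intersect(linkage_flags, x$loci), null_allele_flags)
  status[lk] <- "dropped_linkage"
  keep <- status == "retained"
  if (sum(keep) < 2)
    stop("fewer than 2 loci retained after QC: clone discrimination is meaningless")
  meta <- data.frame(locus = x$loci, status = unname(status),
                     stringsAsFactors = FALSE)
  list(table = x[, which(keep)], meta = meta)
}
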