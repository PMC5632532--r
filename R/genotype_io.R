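#' Read a diploid genotype table from disk
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"genalex"`}{the GenAlEx codominant layout: a first header row
#'     `n_loci, n_individuals, n_pops, pop sizes...`; a second row with a
#'     dataset title followed (from column 3) by population names; a third
#'     row `Sample, Pop, <locus1>, , <locus2>, , ...` with one blank column
#'     after each locus name; then one data row per individual with two
#'     allele columns per locus.}
#'   \item{`"long"`}{a tidy file with columns
#'     `individual, population, locus, allele1, allele2`.}
#' }
#' Calls equal to `missing_code` at both alleles are recorded as missing.
#' A call with exactly one allele equal to `missing_code` (a half call) is
#' conservatively treated as fully missing.
#'
#' @param path path to a CSV file.
#' @param dialect `"genalex"` (default) or `"long"`.
#' @param missing_code integer code denoting a failed amplification
#'   (GenAlEx convention: 0).
#' @return a [genotype_table].
#' @export
read_genotype_table <- function(path, dialect = c("genalex", "long"),
                                missing_code = 0L) {
  dialect <- match.arg(dialect)
  if (dialect == "long") return(read_long_csv(path, missing_code))
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(raw) < 4) stop("GenAlEx file too short: ", path)
  nl <- as.integer(raw[1, 1]); ni <- as.integer(raw[1, 2])
  if (is.na(nl) || is.na(ni)) stop("malformed GenAlEx header row in ", path)
  hdr <- as.character(raw[3, ])
  locus_cols <- seq(3, by = 2, length.out = nl)
  if (max(locus_cols) + 1 > ncol(raw))
    stop("format error: expected ", 2 + 2 * nl,
         " columns (two per locus) in ", path, ", found ", ncol(raw))
  loci <- hdr[locus_cols]
  if (any(loci == "" | is.na(loci))) stop("missing locus name in header of ", path)
  dat <- raw[4:(3 + ni), , drop = FALSE]
  ind <- as.character(dat[[1]])
  pop <- as.character(dat[[2]])
  parse_allele_col <- function(col_idx) {
    tok <- trimws(as.character(dat[[col_idx]]))
    val <- suppressWarnings(as.integer(tok))
    bad <- which(is.na(val) & tok != "" & !is.na(tok))
    if (length(bad))
      stop(sprintf("parse error: non-integer allele token '%s' at row %d, column %d of %s",
                   tok[bad[1]], bad[1] + 3L, col_idx, path))
    val[tok == "" | is.na(tok)] <- missing_code
    val
  }
  a1 <- sapply(locus_cols, parse_allele_col)
  a2 <- sapply(locus_cols + 1L, parse_allele_col)
  if (ni == 1) { a1 <- matrix(a1, nrow = 1); a2 <- matrix(a2, nrow = 1) }
  miss <- a1 == missing_code | a2 == missing_code
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  genotype_table(ind, pop, loci, a1, a2)
}

read_long_csv <- function(path, missing_code = 0L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "character",
                                      "character", "character"))
  need <- c("individual", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(d)))
    stop("long-format file must have columns: ", paste(need, collapse = ", "))
  ind <- unique(d$individual)
  loci <- unique(d$locus)
  popmap <- tapply(d$population, d$individual, function(p) p[1])[ind]
  a1 <- matrix(NA_integer_, length(ind), length(loci), dimnames = list(ind, loci))
  a2 <- a1
  to_int <- function(tok, col) {
    val <- suppressWarnings(as.integer(tok))
    bad <- which(is.na(val) & trimws(tok) != "")
    if (length(bad))
      stop(sprintf("parse error: non-integer allele token '%s' at row %d, column %s of %s",
                   tok[bad[1]], bad[1] + 1L, col, path))
    val
  }
  v1 <- to_int(d$allele1, "allele1"); v2 <- to_int(d$allele2, "allele2")
  idx <- cbind(match(d$individual, ind), match(d$locus, loci))
  a1[idx] <- v1; a2[idx] <- v2
  miss <- is.na(a1) | is.na(a2) | a1 == missing_code | a2 == missing_code
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  genotype_table(ind, unname(popmap), loci, a1, a2)
}

#' Write a genotype table as GenAlEx-style CSV
#'
#' Emits the layout accepted by [read_genotype_table] with
#' `dialect = "genalex"`; missing calls are written as
#' `missing_code, missing_code`. Reading the file back reproduces the
#' table exactly (allele values, missing mask, population labels, order).
#'
#' @param x a [genotype_table].
#' @param path output file path.
#' @param missing_code integer code to write for missing calls (default 0).
#' @param title dataset title placed in the second header row.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(x, path, missing_code = 0L, title = "clonepop export") {
  validate_genotype_table(x)
  ntot <- 2L + 2L * length(x$loci)
  pops <- levels(x$pop)
  sizes <- as.integer(table(x$pop))
  pad <- function(v) c(v, rep("", max(0L, ntot - length(v))))
  r1 <- pad(c(length(x$loci), length(x$ind), length(pops), sizes))
  r2 <- pad(c(title, "", pops))
  r3 <- pad(c("Sample", "Pop", as.vector(rbind(x$loci, ""))))
  a1 <- x$a1; a2 <- x$a2
  a1[is.na(a1)] <- missing_code; a2[is.na(a2)] <- missing_code
  body <- matrix("", length(x$ind), ntot)
  body[, 1] <- x$ind
  body[, 2] <- as.character(x$pop)
  body[, seq(3, ntot, by = 2)] <- as.character(a1)
  body[, seq(4, ntot, by = 2)] <- as.character(a2)
  out <- rbind(r1, r2, r3, body)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
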