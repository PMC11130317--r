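#' @import data.table
#' @importFrom stats pnorm pchisq qnorm median quantile rnorm sd ks.test
#' @importFrom utils head
NULL

# Column aliases recognised by default. Matching is case-insensitive and the
# first alias present in the file wins.
.default_dialect <- list(
  snp  = c("snp", "rsid", "markername", "id", "variant_id"),
  chr  = c("chr", "chrom", "chromosome"),
  bp   = c("bp", "pos", "position", "base_pair_location"),
  a1   = c("a1", "effect_allele", "ea", "allele1"),
  a2   = c("a2", "other_allele", "nea", "allele2"),
  beta = c("beta", "b", "effect", "log_odds"),
  or   = c("or", "odds_ratio"),
  se   = c("se", "standard_error", "stderr"),
  p    = c("p", "pval", "p_value", "pvalue"),
  n    = c("n", "samplesize", "n_total"),
  eaf  = c("eaf", "af", "effect_allele_frequency", "freq", "maf")
)

.new_sumstats <- function(dt, trait_label, drops = integer()) {
  data.table::setDT(dt)
  data.table::setorder(dt, chr, bp)
  data.table::setattr(dt, "trait_label", trait_label)
  data.table::setattr(dt, "genome_build", "GRCh37")
  data.table::setattr(dt, "drops", drops)
  data.table::setattr(dt, "class", c("sumstats", class(dt)))
  dt
}

#' Attrition counts attached to a summary-statistics table
#'
#' Every filtering operation records, per filter, how many rows it removed.
#' The bookkeeping invariant `input rows = output rows + sum(drop_counts())`
#' holds for each operation.
#'
#' @param x A `sumstats` table.
#' @return Named integer vector of per-filter drop counts.
#' @export
drop_counts <- function(x) attr(x, "drops", exact = TRUE)

#' Trait label of a summary-statistics table
#' @param x A `sumstats` table.
#' @return Character scalar.
#' @export
trait_label <- function(x) attr(x, "trait_label", exact = TRUE)

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%d variants, %s)\n",
              trait_label(x) %||% "<unlabelled>", nrow(x),
              attr(x, "genome_build", exact = TRUE) %||% "GRCh37"))
  NextMethod()
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_col <- function(cols, aliases) {
  hit <- match(aliases, tolower(cols))
  hit <- hit[!is.na(hit)]
  if (length(hit)) cols[hit[1L]] else NA_character_
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a whitespace- or tab-delimited file with a header, resolves columns
#' through a dialect of case-insensitive aliases, converts odds ratios to
#' log-odds when no effect-size column is present, and drops rows violating
#' the per-variant invariants (single-base distinct alleles, `se > 0`,
#' `p` in (0, 1], finite `z`). Coordinates are GRCh37, 1-based inclusive.
#'
#' @param path Path to the file.
#' @param dialect Optional named list of extra column aliases, merged over
#'   the defaults (see `crosstrait:::.default_dialect`).
#' @param n_override Constant sample size used when the file has no N column.
#' @param trait_label Label stored on the returned table.
#' @return A `sumstats` table sorted by (chr, bp) with attrition counts in
#'   [drop_counts()].
#' @export
read_sumstats <- function(path, dialect = list(), n_override = NULL,
                          trait_label = basename(path)) {
  stopifnot(file.exists(path))
  raw <- data.table::fread(path, header = TRUE)
  dia <- .default_dialect
  for (nm in names(dialect)) dia[[nm]] <- c(dialect[[nm]], dia[[nm]])

  cols <- names(raw)
  got <- vapply(dia, function(al) .resolve_col(cols, tolower(al)),
                character(1))

  mandatory <- c("snp", "chr", "bp", "a1", "a2", "se", "p")
  missing_cols <- mandatory[is.na(got[mandatory])]
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (is.na(got["beta"]) && is.na(got["or"]))
    stop("missing mandatory column: beta (or OR)")
  if (is.na(got["n"]) && is.null(n_override))
    stop("missing mandatory column: n (supply n_override for a constant N)")

  dt <- data.table::data.table(
    snp = as.character(raw[[got["snp"]]]),
    chr = suppressWarnings(as.integer(gsub("^chr", "", raw[[got["chr"]]],
                                           ignore.case = TRUE))),
    bp  = suppressWarnings(as.integer(raw[[got["bp"]]])),
    a1  = toupper(as.character(raw[[got["a1"]]])),
    a2  = toupper(as.character(raw[[got["a2"]]])),
    se  = suppressWarnings(as.numeric(raw[[got["se"]]])),
    p   = suppressWarnings(as.numeric(raw[[got["p"]]]))
  )
  # all downstream math is on the log-odds scale
  beta_col <- if (!is.na(got["beta"]))
    suppressWarnings(as.numeric(raw[[got["beta"]]]))
  else
    log(suppressWarnings(as.numeric(raw[[got["or"]]])))
  n_col <- if (!is.na(got["n"]))
    suppressWarnings(as.numeric(raw[[got["n"]]]))
  else rep(as.numeric(n_override), nrow(raw))
  data.table::set(dt, j = "beta", value = beta_col)
  data.table::set(dt, j = "n", value = n_col)
  if (!is.na(got["eaf"]))
    data.table::set(dt, j = "eaf",
                    value = suppressWarnings(as.numeric(raw[[got["eaf"]]])))

  ok <- !is.na(dt$snp) & !is.na(dt$chr) & !is.na(dt$bp) &
    !is.na(dt$beta) & !is.na(dt$se) & !is.na(dt$p) & !is.na(dt$n) &
    dt$se > 0 & dt$p > 0 & dt$p <= 1 & dt$a1 != dt$a2 &
    is.finite(dt$beta / dt$se) & dt$n > 0
  dropped <- sum(!ok)
  dt <- dt[ok]
  if (nrow(dt) == 0L) stop("zero parsable rows in ", path)
  data.table::setcolorder(
    dt, intersect(c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p",
                    "n", "eaf"), names(dt)))
  .new_sumstats(dt, trait_label, drops = c(parse_invalid = dropped))
}

.BASES <- c("A", "C", "G", "T")
.is_snp <- function(a1, a2) a1 %in% .BASES & a2 %in% .BASES
.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Quality-control (munge) a summary-statistics table
#'
#' Removes non-SNP variants (indels, multi-base alleles), strand-ambiguous
#' palindromic variants (A/T, C/G), and duplicated identifiers (all copies
#' of a duplicated id are removed, since the correct record cannot be
#' adjudicated). Optionally restricts the table to a reference SNP list,
#' mirroring the conventional restriction to a well-imputed common panel.
#'
#' Idempotent: `munge(munge(t))` equals `munge(t)`.
#'
#' @param t A `sumstats` table.
#' @param reference_snps Character vector of snp ids to keep, or `NULL`.
#' @return Filtered `sumstats` table with per-filter attrition counts.
#' @export
munge <- function(t, reference_snps = NULL) {
  stopifnot(nrow(t) > 0L)
  n0 <- nrow(t)
  keep_snp <- .is_snp(t$a1, t$a2)
  n_nonsnp <- sum(!keep_snp)
  t <- t[keep_snp]
  keep_pal <- !.is_palindromic(t$a1, t$a2)
  n_pal <- sum(!keep_pal)
  t <- t[keep_pal]
  dup <- t$snp %in% t$snp[duplicated(t$snp)]
  n_dup <- sum(dup)
  t <- t[!dup]
  n_ref <- 0L
  if (!is.null(reference_snps) && length(reference_snps)) {
    keep_ref <- t$snp %in% reference_snps
    n_ref <- sum(!keep_ref)
    t <- t[keep_ref]
  }
  drops <- c(non_snp = n_nonsnp, palindromic = n_pal, duplicate = n_dup,
             not_in_reference = n_ref)
  if (nrow(t) == 0L)
    stop("munge removed every variant; attrition: ",
         paste(names(drops), drops, sep = "=", collapse = ", "))
  stopifnot(n0 == nrow(t) + sum(drops))
  .new_sumstats(data.table::copy(t), trait_label(t), drops = drops)
}

#' Genomic region (1-based inclusive)
#'
#' @param chrom Chromosome (integer).
#' @param start,stop Base-pair bounds, both inclusive, GRCh37.
#' @return A `region` object.
#' @export
region <- function(chrom, start, stop) {
  stopifnot(start <= stop)
  structure(list(chrom = as.integer(chrom), start = as.numeric(start),
                 stop = as.numeric(stop)), class = "region")
}

#' The MHC region on chromosome 6 (GRCh37)
#'
#' The default bounds are the GRC reference MHC interval
#' chr6:28,477,797-33,448,354; `extended = TRUE` widens the excluded
#' interval to the commonly used chr6:25,000,000-34,000,000.
#'
#' @param extended Use the extended 25-34 Mb interval.
#' @return A [region()].
#' @export
mhc_region <- function(extended = FALSE) {
  if (extended) region(6L, 25e6, 34e6) else region(6L, 28477797, 33448354)
}

#' Exclude a genomic region from a summary-statistics table
#'
#' Removes every variant with `chrom == r$chrom` and
#' `r$start <= pos <= r$stop` (both bounds inclusive).
#'
#' @param t A `sumstats` table.
#' @param r A [region()], e.g. [mhc_region()].
#' @return Filtered `sumstats` table.
#' @export
exclude_region <- function(t, r) {
  stopifnot(inherits(r, "region"))
  inside <- t$chr == r$chrom & t$bp >= r$start & t$bp <= r$stop
  out <- t[!inside]
  .new_sumstats(data.table::copy(out), trait_label(t),
                drops = c(in_region = sum(inside)))
}

#' Align two summary-statistics tables into paired z-statistics
#'
#' Intersects the two tables on snp id, orients trait 2 to trait 1's
#' effect allele (negating z where the allele pair is swapped), and drops
#' variants whose allele sets are incompatible.
#'
#' @param a,b Munged `sumstats` tables.
#' @return A `paired_sumstats` object: a data.table with columns
#'   `snp, chr, bp, z1, z2, n1, n2` plus a `drops` attribute.
#' @export
align_pair <- function(a, b) {
  common <- intersect(a$snp, b$snp)
  if (!length(common)) stop("no shared variants between the two tables")
  ai <- a[match(common, a$snp)]
  bi <- b[match(common, b$snp)]
  same    <- bi$a1 == ai$a1 & bi$a2 == ai$a2
  swapped <- bi$a1 == ai$a2 & bi$a2 == ai$a1
  keep <- same | swapped
  n_incompatible <- sum(!keep)
  z1 <- ai$beta / ai$se
  z2 <- (bi$beta / bi$se) * ifelse(swapped, -1, 1)
  out <- data.table::data.table(
    snp = ai$snp, chr = ai$chr, bp = ai$bp,
    z1 = z1, z2 = z2, n1 = ai$n, n2 = bi$n)[keep]
  data.table::setorder(out, chr, bp)
  data.table::setattr(out, "drops", c(incompatible_alleles = n_incompatible))
  data.table::setattr(out, "traits", c(trait_label(a), trait_label(b)))
  data.table::setattr(out, "class", c("paired_sumstats", class(out)))
  out
}

#' Write a munged table in the fixed exchange format
#'
#' Tab-delimited with columns `SNP CHR BP A1 A2 Z N P`.
#'
#' @param t A `sumstats` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(t, path) {
  out <- data.table::data.table(
    SNP = t$snp, CHR = t$chr, BP = t$bp, A1 = t$a1, A2 = t$a2,
    Z = t$beta / t$se, N = t$n, P = t$p)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
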