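# Gene-level overlap machinery: overlap counting at nominal significance,
# expected-vs-observed proportions with a one-sided exact binomial test,
# Fisher's combined probability, three-category shared-gene
# classification, and multi-trait intersections.

#' Read a gene-level association table
#'
#' Tab- or whitespace-delimited with columns
#' `GENE CHR START STOP NSNPS P` (case-insensitive), the layout of
#' standard gene-based association output.
#'
#' @param path File path.
#' @return data.table `gene, chr, start, stop, nsnps, p`.
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- data.table::fread(path, header = TRUE)
  nm <- tolower(names(raw))
  need <- c("gene", "p")
  if (!all(need %in% nm))
    stop("gene table must have at least GENE and P columns")
  data.table::setnames(raw, names(raw), nm)
  out <- raw[, .(gene = as.character(gene),
                 chr = if ("chr" %in% nm) chr else NA_integer_,
                 start = if ("start" %in% nm) start else NA_integer_,
                 stop = if ("stop" %in% nm) stop else NA_integer_,
                 nsnps = if ("nsnps" %in% nm) nsnps else NA_integer_,
                 p = as.numeric(p))]
  if (anyDuplicated(out$gene)) stop("duplicate gene ids in ", path)
  if (any(is.na(out$p) | out$p <= 0 | out$p > 1))
    stop("gene P values must lie in (0, 1]")
  out
}

#' Count gene overlap between a discovery and a target set
#'
#' Restricts both tables to their shared gene universe (exact-id
#' intersection), then counts `x` = discovery genes with `p < alpha`,
#' `y` = target genes with `p < alpha`, and `z` = genes below `alpha` in
#' both. All thresholds are strict (`<`).
#'
#' @param discovery,target Gene tables (`gene`, `p`).
#' @param alpha Nominal gene-level threshold (default 0.05).
#' @return List of class `overlap_counts`: `total_genes, x, y, z, alpha`.
#' @export
count_overlap <- function(discovery, target, alpha = 0.05) {
  d <- data.table::as.data.table(discovery)
  t <- data.table::as.data.table(target)
  universe <- intersect(d$gene, t$gene)
  if (!length(universe)) stop("empty shared gene universe")
  d <- d[match(universe, gene)]
  t <- t[match(universe, gene)]
  hit_d <- d$p < alpha
  hit_t <- t$p < alpha
  structure(list(total_genes = length(universe),
                 x = sum(hit_d), y = sum(hit_t),
                 z = sum(hit_d & hit_t), alpha = alpha),
            class = "overlap_counts")
}

#' One-sided exact binomial test of gene overlap
#'
#' Tests whether the observed overlap proportion `o_obs = z / y` exceeds
#' the expected proportion `e = x / total_genes` by chance, via the exact
#' upper binomial tail `P = sum_{k=z}^{y} C(y,k) e^k (1-e)^(y-k)`,
#' accumulated in log space for numerical stability.
#'
#' @param counts An [count_overlap()] result.
#' @param e_override Optional expected proportion replacing
#'   `x/total_genes` (e.g. to reproduce a rounded published call).
#' @return List of class `overlap_test`: `e, o_obs, p_binomial, z, y`.
#' @export
binomial_overlap_test <- function(counts, e_override = NULL) {
  stopifnot(inherits(counts, "overlap_counts") || is.list(counts))
  z <- counts$z; y <- counts$y
  stopifnot(y >= 1L, z >= 0L, z <= y)
  e <- if (!is.null(e_override)) e_override else counts$x / counts$total_genes
  if (e <= 0 || e >= 1) stop("expected proportion must lie strictly in (0,1)")
  p <- .binom_upper_tail(z, y, e)
  structure(list(e = e, o_obs = z / y, p_binomial = p, z = z, y = y),
            class = "overlap_test")
}

# upper tail P(X >= z), X ~ Binomial(y, e), via log-space accumulation
.binom_upper_tail <- function(z, y, e) {
  if (z <= 0L) return(1)
  k <- z:y
  lp <- lchoose(y, k) + k * log(e) + (y - k) * log1p(-e)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Genome-wide significance threshold for a gene universe
#'
#' `alpha / n_genes`; e.g. 0.05/19105 = 2.62e-6.
#'
#' @param alpha Family-wise level (default 0.05).
#' @param n_genes Number of genes tested.
#' @return Numeric threshold.
#' @export
gws_threshold <- function(alpha = 0.05, n_genes) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}

#' Fisher's combined probability for two P values
#'
#' `X = -2 (ln p1 + ln p2)` referred to the chi-square distribution with
#' 4 df; for 4 df the survival function has the closed form
#' `exp(-X/2) (1 + X/2)`, used here. Dependence between the two gene
#' P values is ignored (documented caveat).
#'
#' @param p1,p2 P values in (0, 1]; vectorised.
#' @return Combined P value(s).
#' @export
fisher_combine <- function(p1, p2) {
  if (any(p1 <= 0 | p2 <= 0 | p1 > 1 | p2 > 1))
    stop("P values must lie in (0, 1]")
  X <- -2 * (log(p1) + log(p2))
  exp(-X / 2) * (1 + X / 2)
}

#' Classify genes shared by two traits
#'
#' Three categories over the shared gene universe, with `gws` the
#' genome-wide gene threshold and 0.05 the nominal one (all strict `<`):
#' \itemize{
#'   \item `sentinel-shared`: GWS in both traits;
#'   \item `1`: GWS in trait 1 and nominal in trait 2;
#'   \item `2`: GWS in trait 2 and nominal in trait 1;
#'   \item `3`: nominal but not GWS in both traits, and the Fisher
#'     combined P reaches GWS (`p_fcp < gws`) -- putatively novel shared
#'     genes;
#'   \item `none`: everything else.
#' }
#' The categories are mutually exclusive and exhaustive.
#'
#' @param t1,t2 Gene tables (`gene`, `p`).
#' @param gws GWS threshold from [gws_threshold()].
#' @param alpha Nominal threshold (default 0.05).
#' @return data.table `gene, p1, p2, p_fcp, category`.
#' @export
classify_shared_genes <- function(t1, t2, gws, alpha = 0.05) {
  d1 <- data.table::as.data.table(t1)
  d2 <- data.table::as.data.table(t2)
  universe <- intersect(d1$gene, d2$gene)
  if (!length(universe)) stop("empty shared gene universe")
  p1 <- d1$p[match(universe, d1$gene)]
  p2 <- d2$p[match(universe, d2$gene)]
  p_fcp <- fisher_combine(p1, p2)
  category <- rep("none", length(universe))
  cat3 <- p1 >= gws & p1 < alpha & p2 >= gws & p2 < alpha & p_fcp < gws
  category[cat3] <- "3"
  category[p2 < gws & p1 < alpha] <- "2"
  category[p1 < gws & p2 < alpha] <- "1"
  category[p1 < gws & p2 < gws] <- "sentinel-shared"
  data.table::data.table(gene = universe, p1 = p1, p2 = p2,
                         p_fcp = p_fcp, category = category)
}

#' Intersections of shared genes across trait pairs
#'
#' Given classification tables for several trait pairs, records for each
#' gene the set of pairs in which it is shared -- by combined-P
#' significance (`mode = "fcp"`, `p_fcp < gws`) or by any non-`none`
#' category (`mode = "category"`) -- and reports the genes common to
#' requested pair subsets.
#'
#' @param results Named list of [classify_shared_genes()] tables, one per
#'   pair.
#' @param gws GWS threshold (needed for `mode = "fcp"`).
#' @param mode `"fcp"` or `"category"`.
#' @param subsets List of character vectors of pair names to intersect
#'   (default: the single all-pairs subset).
#' @return List: `membership` (data.table `gene, n_pairs, pairs`),
#'   `intersections` (named list of gene-id vectors).
#' @export
multi_trait_intersection <- function(results, gws = NULL,
                                     mode = c("fcp", "category"),
                                     subsets = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(results) >= 2L, !is.null(names(results)))
  if (mode == "fcp") stopifnot(!is.null(gws))
  hits <- lapply(results, function(r) {
    r <- data.table::as.data.table(r)
    if (mode == "fcp") r$gene[r$p_fcp < gws]
    else r$gene[r$category != "none"]
  })
  genes <- unique(unlist(hits, use.names = FALSE))
  member <- lapply(genes, function(g)
    names(hits)[vapply(hits, function(h) g %in% h, logical(1))])
  membership <- data.table::data.table(
    gene = genes,
    n_pairs = lengths(member),
    pairs = vapply(member, paste, character(1), collapse = ","))
  if (is.null(subsets)) subsets <- list(all = names(results))
  if (is.null(names(subsets)))
    names(subsets) <- vapply(subsets, paste, character(1), collapse = "+")
  inters <- lapply(subsets, function(ps) Reduce(intersect, hits[ps]))
  list(membership = membership, intersections = inters)
}
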