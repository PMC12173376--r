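#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more category genes in a query of size `n`
#' drawn without replacement from a universe of size `N` containing `K`
#' category genes, i.e. P(X >= k) for X ~ Hypergeometric(N, K, n). Computed
#' through the survival function of the hypergeometric distribution, which is
#' evaluated in a numerically stable way.
#'
#' @param k Observed overlap count.
#' @param K Category size within the universe.
#' @param n Query set size.
#' @param N Universe size.
#' @return The upper-tail probability, in (0, 1].
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10) # 66/252
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (any(c(k, K, n, N) != floor(c(k, K, n, N))))
    stop("hypergeometric arguments must be integers")
  if (K > N || n > N) stop("'K' and 'n' must not exceed 'N'")
  if (k < 0 || k > min(n, K))
    stop("'k' must satisfy 0 <= k <= min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved and each
#' adjusted value is at least the raw value.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the input order (empty in, empty out).
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation of protein groups within disease gene sets
#'
#' For every (disease gene set, category) pair, tests whether the category is
#' over-represented among the set's genes by the upper-tail hypergeometric
#' test, after intersecting both with the universe.
#'
#' @param query_sets Named list of [disease_gene_set()] objects.
#' @param categories Named list of category gene vectors (e.g. the universe's
#'   protein groups).
#' @param universe A [gene_universe()] object supplying N.
#' @return A data frame with one row per (set, category): `set_id`,
#'   `category`, `k`, `K`, `n`, `N`, `p`, `fdr` (BH across all rows) and
#'   `neg_log10_p`.
#' @export
overrepresentation_table <- function(query_sets, categories, universe) {
  if (!length(query_sets)) stop("no query sets supplied")
  if (!length(categories)) stop("no categories supplied")
  N <- length(universe$genes)
  cats <- lapply(categories, function(g) intersect(norm_symbols(g),
                                                   universe$genes))
  rows <- list()
  for (s in query_sets) {
    q <- intersect(s$genes, universe$genes)
    if (!length(q))
      stop("gene set '", s$disease_id,
           "' shares no genes with the universe (symbol-space mismatch?)")
    for (nm in names(cats)) {
      K <- length(cats[[nm]])
      k <- length(intersect(q, cats[[nm]]))
      p <- hypergeom_upper_tail(k, K, length(q), N)
      rows[[length(rows) + 1L]] <- data.frame(
        set_id = s$disease_id, category = nm, k = k, K = K,
        n = length(q), N = N, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$neg_log10_p <- -log10(out$p)
  rownames(out) <- NULL
  out
}

#' Direction-split pathway enrichment of a signed gene set
#'
#' Splits a signed query into up- and downregulated subsets and tests each
#' against a pathway database by the upper-tail hypergeometric test with BH
#' adjustment across pathways. Pathways are kept when FDR < `fdr_cut` and the
#' overlap has at least `min_genes` genes; up to `top_m` pathways per
#' direction are returned, ordered by ascending FDR, then raw p, then name.
#'
#' @param sign_of Named -1/+1 vector of gene perturbation signs (the query).
#' @param pathway_db Named list of pathway gene vectors.
#' @param universe A [gene_universe()] object.
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param min_genes Minimum overlap per pathway (default 3, i.e. more than 2).
#' @param top_m Maximum number of pathways returned per direction.
#' @return List with data frames `up` and `down` (columns `pathway`, `k`,
#'   `K`, `n`, `N`, `p`, `fdr`).
#' @export
pathway_enrichment <- function(sign_of, pathway_db, universe, fdr_cut = 0.05,
                               min_genes = 3, top_m = 10) {
  if (!length(pathway_db)) stop("empty pathway database")
  names(sign_of) <- norm_symbols(names(sign_of))
  db <- lapply(pathway_db, function(g) intersect(norm_symbols(g),
                                                 universe$genes))
  one_direction <- function(genes) {
    genes <- intersect(genes, universe$genes)
    n <- length(genes)
    N <- length(universe$genes)
    rows <- do.call(rbind, lapply(names(db), function(nm) {
      K <- length(db[[nm]])
      k <- if (K) length(intersect(genes, db[[nm]])) else 0L
      data.frame(pathway = nm, k = k, K = K, n = n, N = N,
                 p = if (n && K) hypergeom_upper_tail(k, K, n, N) else 1,
                 stringsAsFactors = FALSE)
    }))
    rows$fdr <- bh_adjust(rows$p)
    rows <- rows[rows$fdr < fdr_cut & rows$k >= min_genes, , drop = FALSE]
    rows <- rows[order(rows$fdr, rows$p, rows$pathway), , drop = FALSE]
    rows <- utils::head(rows, top_m)
    rownames(rows) <- NULL
    rows
  }
  list(up = one_direction(names(sign_of)[sign_of > 0]),
       down = one_direction(names(sign_of)[sign_of < 0]))
}
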