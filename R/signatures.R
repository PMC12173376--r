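#' Jaccard index of two gene sets
#'
#' Overlap-to-union ratio |A intersect B| / |A union B|; defined as 0 when
#' both sets are empty (with a message).
#'
#' @param a,b Character vectors of gene symbols.
#' @return Similarity in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(norm_symbols(a)); b <- unique(norm_symbols(b))
  u <- length(union(a, b))
  if (u == 0L) {
    message("jaccard of two empty sets defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard similarity matrix of disease gene sets
#'
#' @param sets Named list of [disease_gene_set()] objects.
#' @param pn_only Optional [pn_annotation()]; when supplied, similarity is
#'   computed on each set's PN subset instead of the full gene set.
#' @return Symmetric similarity matrix with unit diagonal, ids as dimnames.
#' @export
similarity_matrix <- function(sets, pn_only = NULL) {
  ids <- vapply(sets, function(s) s$disease_id, "")
  genes <- lapply(sets, function(s) {
    g <- s$genes
    if (!is.null(pn_only)) g <- intersect(g, pn_only$genes)
    g
  })
  n <- length(sets)
  m <- diag(1, n)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- jaccard(genes[[i]], genes[[j]])
  dimnames(m) <- list(ids, ids)
  m
}

#' Hierarchical clustering of diseases from a similarity matrix
#'
#' Agglomerative clustering on distance 1 - Jaccard with complete linkage,
#' cut to `n_clusters`. Rows are ordered lexicographically by id before
#' clustering so the result does not depend on input order.
#'
#' @param sim Symmetric similarity matrix with ids as dimnames.
#' @param n_clusters Number of clusters to cut to.
#' @return Named integer vector mapping disease id to cluster id.
#' @export
cluster_diseases <- function(sim, n_clusters) {
  if (n_clusters < 1) stop("'n_clusters' must be at least 1")
  ids <- rownames(sim)
  if (is.null(ids)) stop("similarity matrix needs dimnames")
  if (n_clusters > nrow(sim))
    stop("'n_clusters' exceeds the number of diseases")
  ord <- order(ids)
  d <- stats::as.dist(1 - sim[ord, ord])
  hc <- stats::hclust(d, method = "complete")
  stats::cutree(hc, k = n_clusters)
}

#' Gene-wise consensus signature of a disease cluster
#'
#' For each gene of a PN pathway appearing in at least one of the cluster's
#' signed disease gene sets: the mean perturbation sign across the sets that
#' contain it (a value in [-1, 1]) and the number of supporting sets.
#'
#' @param cluster_sets List of signed [disease_gene_set()] objects.
#' @param ann A [pn_annotation()].
#' @param pathway Pathway name from the annotation vocabulary.
#' @return A `signature_vector` data frame (`gene`, `value`, `support`)
#'   ordered by gene symbol, with the pathway as attribute.
#' @export
consensus_signature <- function(cluster_sets, ann, pathway) {
  if (!pathway %in% ann$pathway_vocab)
    stop("unknown pathway: ", pathway)
  signed <- Filter(function(s) !is.null(s$sign_of) && length(s$sign_of),
                   cluster_sets)
  if (!length(signed))
    stop("no signed gene sets in the cluster")
  pw <- ann$pathway_genes[[pathway]]
  rows <- lapply(signed, function(s) {
    g <- intersect(names(s$sign_of), pw)
    if (!length(g)) return(NULL)
    data.frame(gene = g, sign = as.numeric(s$sign_of[g]),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(structure(data.frame(gene = character(0), value = numeric(0),
                                support = integer(0)),
                     pathway = pathway, class = c("signature_vector",
                                                  "data.frame")))
  agg <- stats::aggregate(sign ~ gene, rows, function(x) c(mean(x), length(x)))
  out <- data.frame(gene = agg$gene, value = agg$sign[, 1],
                    support = as.integer(agg$sign[, 2]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pathway") <- pathway
  class(out) <- c("signature_vector", "data.frame")
  out
}

#' Directional similarity of two signed gene sets
#'
#' The fraction of genes in the overlap of the two sign maps carrying the
#' same perturbation direction in both.
#'
#' @param signs_a,signs_b Named -1/+1 vectors (zero signs are rejected:
#'   direction must be called upstream).
#' @return List with `ds` (proportion, `NA` when the overlap is empty) and
#'   `overlap` (overlap size).
#' @export
directional_similarity <- function(signs_a, signs_b) {
  check <- function(s, nm) {
    if (length(s) && (any(!s %in% c(-1, 1))))
      stop("'", nm, "' contains signs other than -1/+1 (direction uncalled?)")
  }
  check(signs_a, "signs_a"); check(signs_b, "signs_b")
  o <- intersect(names(signs_a), names(signs_b))
  if (!length(o)) return(list(ds = NA_real_, overlap = 0L))
  list(ds = mean(signs_a[o] == signs_b[o]), overlap = length(o))
}
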