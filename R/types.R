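#' @keywords internal
"_PACKAGE"

#' Protein-group labels recognised in a gene universe
#' @export
PROTEIN_GROUPS <- c("PN", "KINASE", "TF", "ION_CHANNEL")

norm_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

#' Construct a gene universe
#'
#' A gene universe is the reference symbol space for all over-representation
#' tests: it carries the universe size N of the hypergeometric test and the
#' protein-group memberships (proteostasis network, kinases, transcription
#' factors, ion channels) that provide group sizes K.
#'
#' @param genes Character vector of gene symbols. Symbols are uppercased and
#'   deduplicated; empty strings are dropped.
#' @param groups Named list of character vectors, one per protein group
#'   (names among `PROTEIN_GROUPS`). Every member must be in `genes`.
#' @return An object of class `gene_universe` with elements `genes` and
#'   `groups`.
#' @export
gene_universe <- function(genes, groups = list()) {
  genes <- unique(norm_symbols(genes))
  if (length(genes) == 0L) stop("gene universe must contain at least one gene")
  if (length(groups)) {
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
      stop("'groups' must be a named list")
    bad <- setdiff(names(groups), PROTEIN_GROUPS)
    if (length(bad))
      stop("unknown protein group(s): ", paste(bad, collapse = ", "))
    groups <- lapply(groups, function(g) unique(norm_symbols(g)))
    for (nm in names(groups)) {
      missing <- setdiff(groups[[nm]], genes)
      if (length(missing))
        stop("group ", nm, " contains ", length(missing),
             " gene(s) absent from the universe (e.g. ", missing[1], ")")
    }
  }
  structure(list(genes = genes, groups = groups), class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("Gene universe:", length(x$genes), "genes\n")
  for (nm in names(x$groups))
    cat("  ", nm, ": ", length(x$groups[[nm]]), " genes\n", sep = "")
  invisible(x)
}

#' Construct a proteostasis-network annotation
#'
#' Maps genes to proteostasis pathways (e.g. the autophagy-lysosome pathway,
#' the ubiquitin-proteasome system, extracellular proteostasis) and to
#' functional classes nested within those pathways. Both maps are
#' many-to-many, but each functional class belongs to exactly one pathway.
#'
#' @param gene,pathway,class Parallel character vectors (long format); `class`
#'   may contain `NA` for rows that annotate a pathway only.
#' @return An object of class `pn_annotation` with per-pathway and per-class
#'   gene lists, the class-to-pathway map and ordered vocabularies.
#' @export
pn_annotation <- function(gene, pathway, class = NULL) {
  gene <- norm_symbols(gene)
  pathway <- toupper(trimws(as.character(pathway)))
  if (length(gene) == 0L) stop("annotation has no rows")
  if (length(pathway) != length(gene))
    stop("'gene' and 'pathway' must have equal length")
  if (any(!nzchar(pathway))) stop("empty pathway name in annotation")
  if (is.null(class)) class <- rep(NA_character_, length(gene))
  class <- toupper(trimws(as.character(class)))
  class[!nzchar(class)] <- NA_character_
  if (length(class) != length(gene))
    stop("'class' must match 'gene' in length")

  tbl <- unique(data.frame(gene = gene, pathway = pathway, class = class,
                           stringsAsFactors = FALSE))
  # each class must map to exactly one pathway
  cls <- tbl[!is.na(tbl$class), , drop = FALSE]
  if (nrow(cls)) {
    map <- unique(cls[, c("class", "pathway")])
    dup <- map$class[duplicated(map$class)]
    if (length(dup)) {
      rows <- map[map$class %in% dup, ]
      stop("functional class mapped to multiple pathways: ",
           paste(sprintf("%s -> %s", rows$class, rows$pathway), collapse = "; "))
    }
    class_to_pathway <- stats::setNames(map$pathway, map$class)
  } else {
    class_to_pathway <- stats::setNames(character(0), character(0))
  }
  pathway_vocab <- unique(tbl$pathway)
  class_vocab <- unique(cls$class)
  structure(list(
    tbl = tbl,
    genes = unique(tbl$gene),
    pathway_genes = lapply(stats::setNames(nm = pathway_vocab),
                           function(p) unique(tbl$gene[tbl$pathway == p])),
    class_genes = lapply(stats::setNames(nm = class_vocab),
                         function(cl) unique(cls$gene[cls$class == cl])),
    class_to_pathway = class_to_pathway,
    pathway_vocab = pathway_vocab,
    class_vocab = class_vocab
  ), class = "pn_annotation")
}

#' @export
print.pn_annotation <- function(x, ...) {
  cat("PN annotation:", length(x$genes), "genes,",
      length(x$pathway_vocab), "pathways,",
      length(x$class_vocab), "functional classes\n")
  invisible(x)
}

#' Construct a ranked disease gene set
#'
#' The top-k genes most associated with a disease by an upstream ranking,
#' optionally signed by perturbation direction (+1 up, -1 down in disease).
#'
#' @param disease_id Disease identifier.
#' @param genes Character vector in rank order (rank 1 first). Uppercased;
#'   duplicates removed keeping the first occurrence.
#' @param disease_group Optional disease-group label (e.g. "CANCER").
#' @param sign_of Optional named numeric vector of -1/+1 perturbation signs;
#'   names must be a subset of `genes`.
#' @param k Maximum set size; genes beyond rank `k` are dropped.
#' @return An object of class `disease_gene_set`.
#' @export
disease_gene_set <- function(disease_id, genes, disease_group = NA_character_,
                             sign_of = NULL, k = Inf) {
  genes <- norm_symbols(genes)
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L)
    stop("disease gene set '", disease_id, "' is empty")
  if (is.finite(k)) {
    if (k < 1) stop("'k' must be a positive integer")
    genes <- genes[seq_len(min(length(genes), k))]
  }
  if (!is.null(sign_of)) {
    names(sign_of) <- norm_symbols(names(sign_of))
    sign_of <- sign_of[!duplicated(names(sign_of))]
    sign_of <- sign_of[names(sign_of) %in% genes]
    if (any(!sign_of %in% c(-1, 1)))
      stop("perturbation signs must be -1 or +1")
  }
  structure(list(disease_id = as.character(disease_id),
                 disease_group = as.character(disease_group),
                 genes = genes, sign_of = sign_of),
            class = "disease_gene_set")
}

#' @export
print.disease_gene_set <- function(x, ...) {
  cat("Disease gene set '", x$disease_id, "': ", length(x$genes), " genes",
      if (!is.null(x$sign_of)) paste0(" (", length(x$sign_of), " signed)"),
      "\n", sep = "")
  invisible(x)
}

#' Construct an expression study
#'
#' @param matrix Numeric genes x samples matrix of log2-scale expression with
#'   gene symbols as rownames and sample identifiers as colnames.
#' @param condition Named character vector mapping every sample (column) to a
#'   condition label such as `CONTROL`, `STAGE_1`, or `EXPOSED`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(matrix, condition) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (any(!is.finite(matrix))) stop("expression matrix contains non-finite values")
  condition <- condition[colnames(matrix)]
  if (any(is.na(condition)) || any(!nzchar(condition)))
    stop("every sample needs a condition label")
  rownames(matrix) <- norm_symbols(rownames(matrix))
  structure(list(matrix = matrix,
                 condition = stats::setNames(as.character(condition),
                                             colnames(matrix))),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples;", "conditions:",
      paste(sprintf("%s(%d)", names(table(x$condition)), table(x$condition)),
            collapse = ", "), "\n")
  invisible(x)
}

canonical_edges <- function(from, to) {
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- a != b
  e <- unique(cbind(a[keep], b[keep]))
  colnames(e) <- c("from", "to")
  e
}

#' Construct an undirected gene interaction network
#'
#' Edges are stored canonically (alphabetical order within a pair); self-loops
#' are dropped and duplicate edges collapsed.
#'
#' @param nodes Character vector of node names (isolated nodes allowed).
#' @param edges Two-column character matrix or data frame of node pairs.
#' @param stage_of Optional named character vector assigning a stage-of-onset
#'   label to nodes.
#' @return An object of class `interaction_network`.
#' @export
interaction_network <- function(nodes = character(), edges = NULL,
                                stage_of = NULL) {
  nodes <- unique(norm_symbols(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    e <- matrix(character(0), ncol = 2,
                dimnames = list(NULL, c("from", "to")))
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(edges) <- "character"
    from <- norm_symbols(edges[, 1]); to <- norm_symbols(edges[, 2])
    n_self <- sum(from == to)
    if (n_self > 0)
      message("dropped ", n_self, " self-loop(s)")
    e <- canonical_edges(from, to)
    # nodes named only in dropped self-loops are kept as isolates
    nodes <- unique(c(nodes, from, to))
  }
  if (!is.null(stage_of)) {
    names(stage_of) <- norm_symbols(names(stage_of))
    missing <- setdiff(names(stage_of), nodes)
    if (length(missing))
      stop("stage labels for nodes absent from network: ",
           paste(utils::head(missing, 3), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = e, stage_of = stage_of),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges))
    g <- igraph::add_edges(g, t(matrix(match(net$edges, net$nodes),
                                       ncol = 2)))
  g
}
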