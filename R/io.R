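#' Read ranked disease gene sets from GMT or TSV
#'
#' GMT input: one set per line, tab-separated
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...` with genes in rank order.
#' TSV input (header `set_id`, `gene`, and optionally `score` and `group`):
#' genes are ranked within each set by descending score, ties broken by
#' ascending symbol; without a score column the file order is the rank order.
#'
#' @param path Path to a `.gmt` or `.tsv` file.
#' @param k Maximum number of genes kept per set (rank order), default 500.
#' @param signs Optional path to a sidecar TSV (`set_id`, `gene`, `sign`)
#'   carrying -1/+1 perturbation signs.
#' @return A named list of [disease_gene_set()] objects.
#' @export
read_gene_sets <- function(path, k = 500, signs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (k < 1) stop("'k' must be a positive integer")
  sign_map <- NULL
  if (!is.null(signs)) sign_map <- read_signs(signs)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
      if (length(f) < 3)
        stop("malformed GMT line ", i, ": fewer than 3 fields")
      genes <- f[-(1:2)]
      if (!length(norm_symbols(genes)))
        stop("gene set '", f[1], "' is empty (GMT line ", i, ")")
      disease_gene_set(f[1], genes, k = k,
                       sign_of = sign_map[[f[1]]])
    })
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("set_id", "gene")
    if (!all(need %in% names(df)))
      stop("TSV gene-set file needs columns: ", paste(need, collapse = ", "))
    sets <- lapply(split(df, df$set_id), function(d) {
      if ("score" %in% names(d)) {
        d$gene_uc <- toupper(trimws(d$gene))
        d <- d[order(-d$score, d$gene_uc), , drop = FALSE]
      }
      grp <- if ("group" %in% names(d)) d$group[1] else NA_character_
      disease_gene_set(d$set_id[1], d$gene, disease_group = grp, k = k,
                       sign_of = sign_map[[d$set_id[1]]])
    })
  }
  stats::setNames(sets, vapply(sets, function(s) s$disease_id, ""))
}

#' Write disease gene sets to GMT (with optional sign sidecar)
#'
#' @param sets Named list of [disease_gene_set()] objects.
#' @param path Output GMT path; the description field is written as "NA".
#' @param signs Optional path for the sign sidecar TSV.
#' @export
write_gene_sets <- function(sets, path, signs = NULL) {
  lines <- vapply(sets, function(s)
    paste(c(s$disease_id, "NA", s$genes), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(signs)) {
    rows <- do.call(rbind, lapply(sets, function(s) {
      if (is.null(s$sign_of)) return(NULL)
      data.frame(set_id = s$disease_id, gene = names(s$sign_of),
                 sign = as.integer(s$sign_of), stringsAsFactors = FALSE)
    }))
    if (is.null(rows))
      rows <- data.frame(set_id = character(0), gene = character(0),
                         sign = integer(0))
    utils::write.table(rows, signs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-gene sign sidecar TSV
#'
#' @param path TSV with columns `set_id`, `gene`, `sign` (-1/+1).
#' @return Named list (by set) of named sign vectors.
#' @export
read_signs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("set_id", "gene", "sign")
  if (!all(need %in% names(df)))
    stop("sign file needs columns: ", paste(need, collapse = ", "))
  if (!nrow(df)) return(list())
  if (any(!df$sign %in% c(-1, 1))) stop("signs must be -1 or +1")
  lapply(split(df, df$set_id), function(d)
    stats::setNames(as.numeric(d$sign), toupper(trimws(d$gene))))
}

#' Read a proteostasis-network annotation TSV
#'
#' @param path TSV with columns `gene`, `pathway` and optionally `class`.
#' @return A [pn_annotation()] object.
#' @export
read_pn_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("annotation file is empty: ", path)
  need <- c("gene", "pathway")
  if (!all(need %in% names(df)))
    stop("annotation file needs columns: ", paste(need, collapse = ", "))
  pn_annotation(df$gene, df$pathway,
                if ("class" %in% names(df)) df$class else NULL)
}

#' Write a proteostasis-network annotation TSV
#' @param ann A [pn_annotation()] object.
#' @param path Output path.
#' @export
write_pn_annotation <- function(ann, path) {
  utils::write.table(ann$tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gene universe TSV
#'
#' @param path TSV with columns `gene` and optionally `group` (one row per
#'   gene-group membership; group `NONE` or empty means unlabelled).
#' @return A [gene_universe()] object.
#' @export
read_universe <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("universe file needs a 'gene' column")
  groups <- list()
  if ("group" %in% names(df)) {
    lab <- df[!is.na(df$group) & nzchar(df$group) & df$group != "NONE", ]
    groups <- lapply(split(lab$gene, lab$group), identity)
  }
  gene_universe(df$gene, groups)
}

#' Write a gene universe TSV
#' @param universe A [gene_universe()] object.
#' @param path Output path.
#' @export
write_universe <- function(universe, path) {
  rows <- data.frame(gene = universe$genes, group = "NONE",
                     stringsAsFactors = FALSE)
  extra <- do.call(rbind, lapply(names(universe$groups), function(nm)
    data.frame(gene = universe$groups[[nm]], group = nm,
               stringsAsFactors = FALSE)))
  if (!is.null(extra)) {
    rows <- rows[!rows$gene %in% extra$gene, , drop = FALSE]
    rows <- rbind(rows, extra)
  }
  rows <- rows[order(rows$gene, rows$group), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected edge list TSV
#'
#' Two tab-separated node columns (header optional, detected by the literal
#' header `from<TAB>to`). Self-loops are dropped with a message; duplicate
#' edges are collapsed.
#'
#' @param path Edge list path.
#' @param stage_of Optional path to a TSV (`node`, `stage`) of node stage
#'   labels.
#' @return An [interaction_network()] object.
#' @export
read_edge_list <- function(path, stage_of = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(tolower(lines[1]), "from\tto"))
    lines <- lines[-1]
  if (!length(lines)) {
    net <- interaction_network()
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, function(p)
      length(p) < 2 || !nzchar(trimws(p[1])) || !nzchar(trimws(p[2])), TRUE))
    if (length(bad))
      stop("malformed edge at line ", bad[1], " of ", path)
    e <- t(vapply(parts, function(p) p[1:2], character(2)))
    net <- interaction_network(edges = e)
  }
  if (!is.null(stage_of)) {
    df <- utils::read.delim(stage_of, stringsAsFactors = FALSE)
    if (!all(c("node", "stage") %in% names(df)))
      stop("stage file needs columns 'node' and 'stage'")
    st <- stats::setNames(df$stage, toupper(trimws(df$node)))
    st <- st[names(st) %in% net$nodes]
    net$stage_of <- st
  }
  net
}

#' Read an expression study from expression + metadata TSVs
#'
#' @param expr TSV of log2 expression: first column `gene`, remaining columns
#'   one per sample.
#' @param meta TSV with columns `sample`, `condition`.
#' @return An [expression_study()] object.
#' @export
read_expression_study <- function(expr, meta) {
  e <- utils::read.delim(expr, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(e)) stop("expression file needs a 'gene' column")
  m <- as.matrix(e[, setdiff(names(e), "gene"), drop = FALSE])
  rownames(m) <- e$gene
  md <- utils::read.delim(meta, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(md)))
    stop("metadata file needs columns 'sample' and 'condition'")
  missing <- setdiff(colnames(m), md$sample)
  if (length(missing))
    stop("samples without condition labels: ",
         paste(utils::head(missing, 3), collapse = ", "))
  expression_study(m, stats::setNames(md$condition, md$sample))
}

#' Write an expression study to expression + metadata TSVs
#' @param study An [expression_study()] object.
#' @param expr,meta Output paths.
#' @export
write_expression_study <- function(study, expr, meta) {
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(study$condition),
               condition = unname(study$condition)),
    meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr)
}
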