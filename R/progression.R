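#' Stage-wise differential expression with perturbation-onset calls
#'
#' Runs one moderated-t contrast per disease stage against the control
#' condition and records, for each gene, the earliest stage at which it is
#' significant after BH adjustment (its onset stage).
#'
#' @param study An [expression_study()] whose conditions include every stage
#'   and the control.
#' @param stages Ordered character vector of stage labels (earliest first).
#' @param control Control condition label.
#' @param alpha Adjusted-p significance cutoff per stage (default 0.05).
#' @return An object of class `stage_result`: list with `stages`, `tables`
#'   (one `de_table` per stage) and `onset` (named vector, `NA` for genes
#'   never significant).
#' @export
stagewise_de <- function(study, stages, control, alpha = 0.05) {
  missing <- setdiff(c(stages, control), unique(study$condition))
  if (length(missing))
    stop("condition(s) absent from metadata: ",
         paste(missing, collapse = ", "))
  tables <- lapply(stages, function(s)
    run_de(study, c(s, control), direction_alpha = alpha))
  names(tables) <- stages
  genes <- rownames(study$matrix)
  onset <- rep(NA_character_, length(genes))
  names(onset) <- genes
  for (s in rev(stages)) {          # earlier stages overwrite later ones
    tab <- tables[[s]]
    sig <- tab$gene[tab$adj_p < alpha]
    onset[sig] <- s
  }
  structure(list(stages = stages, tables = tables, onset = onset,
                 alpha = alpha),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat("Stage-wise DE over", length(x$stages), "stages;",
      sum(!is.na(x$onset)), "of", length(x$onset),
      "genes significant in at least one stage\n")
  invisible(x)
}

#' Per-stage proportions of affected pathway genes
#'
#' In onset mode (default), the affected pathway genes are partitioned by
#' their onset stage and per-stage proportions sum to 1. In any-stage mode a
#' gene counts at every stage where it is significant, so the proportions
#' need not sum to 1.
#'
#' @param result A `stage_result` from [stagewise_de()].
#' @param pathway_genes Nonempty character vector (e.g. the ALP or UPS genes).
#' @param mode `"onset"` or `"any-stage"`.
#' @return Named numeric vector of proportions per stage (`NA` throughout
#'   when no pathway gene is affected).
#' @export
stage_proportions <- function(result, pathway_genes,
                              mode = c("onset", "any-stage")) {
  mode <- match.arg(mode)
  pathway_genes <- unique(norm_symbols(pathway_genes))
  if (!length(pathway_genes)) stop("'pathway_genes' is empty")
  onset <- result$onset[intersect(names(result$onset), pathway_genes)]
  affected <- names(onset)[!is.na(onset)]
  if (!length(affected)) {
    warning("no affected pathway genes; proportions reported missing")
    return(stats::setNames(rep(NA_real_, length(result$stages)),
                           result$stages))
  }
  if (mode == "onset") {
    counts <- vapply(result$stages, function(s) sum(onset == s, na.rm = TRUE),
                     numeric(1))
  } else {
    counts <- vapply(result$stages, function(s) {
      tab <- result$tables[[s]]
      sum(tab$gene %in% affected & tab$adj_p < result$alpha)
    }, numeric(1))
  }
  counts / length(affected)
}

#' Node centralities of an interaction network
#'
#' Degree (number of incident edges) and betweenness (for each node, the sum
#' over unordered node pairs of the fraction of shortest paths passing
#' through it, endpoints excluded; unreachable pairs contribute 0).
#'
#' @param net An [interaction_network()].
#' @return Data frame `node`, `degree`, `betweenness`.
#' @export
centrality <- function(net) {
  if (!length(net$nodes))
    return(data.frame(node = character(0), degree = integer(0),
                      betweenness = numeric(0)))
  g <- as_igraph(net)
  data.frame(node = net$nodes,
             degree = as.integer(igraph::degree(g)),
             betweenness = as.numeric(
               igraph::betweenness(g, directed = FALSE, normalized = FALSE)),
             stringsAsFactors = FALSE)
}

#' Stage-wise centrality quartiles and rank-sum comparisons
#'
#' Summarises degree and betweenness per stage group (quartiles by linear
#' interpolation) and compares every pair of stage groups with a two-sided
#' Mann-Whitney rank-sum test. The tests are exploratory descriptors of the
#' boxplot contrast, not a calibrated inference.
#'
#' @param net An [interaction_network()] with `stage_of` labels.
#' @param stages Optional ordered subset of stage labels to summarise.
#' @return List with `summary` (stage, metric, n, q1, median, q3) and
#'   `tests` (metric, stage_a, stage_b, p) data frames.
#' @export
stage_centrality_summary <- function(net, stages = NULL) {
  if (is.null(net$stage_of))
    stop("network carries no stage labels")
  cen <- centrality(net)
  st <- net$stage_of[cen$node]
  if (is.null(stages)) stages <- unique(stats::na.omit(unname(st)))
  empty <- stages[!stages %in% st]
  if (length(empty)) {
    warning("stage(s) with no nodes omitted: ", paste(empty, collapse = ", "))
    stages <- setdiff(stages, empty)
  }
  metrics <- c("degree", "betweenness")
  summ <- do.call(rbind, lapply(stages, function(s) {
    idx <- which(st == s)
    do.call(rbind, lapply(metrics, function(m) {
      q <- stats::quantile(cen[[m]][idx], c(0.25, 0.5, 0.75), type = 7)
      data.frame(stage = s, metric = m, n = length(idx),
                 q1 = q[[1]], median = q[[2]], q3 = q[[3]],
                 stringsAsFactors = FALSE)
    }))
  }))
  tests <- NULL
  if (length(stages) > 1) {
    pairs <- utils::combn(stages, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      do.call(rbind, lapply(metrics, function(m) {
        x <- cen[[m]][st == a]; y <- cen[[m]][st == b]
        p <- if (length(unique(c(x, y))) == 1) 1 else
          suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
        data.frame(metric = m, stage_a = a, stage_b = b, p = p,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  rownames(summ) <- NULL
  list(summary = summ, tests = tests)
}
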