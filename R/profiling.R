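#' Proteostasis state labels
#'
#' Three perturbation states discriminate disease types by their UPS and
#' extracellular enrichment pattern (the ALP is enriched throughout and is
#' therefore not discriminative): state I = UPS+/extracellular-, state II =
#' UPS+/extracellular+, state III = UPS-/extracellular+. The remaining
#' UPS-/extracellular- cell is reported as UNCLASSIFIED.
#' @export
PROTEOSTASIS_STATES <- c("STATE_I_ALP_UPS_ERneg", "STATE_II_ALP_UPS_ERpos",
                         "STATE_III_ALP_ERpos", "UNCLASSIFIED")

#' Profile a disease gene set against the proteostasis network
#'
#' Computes the PN fraction (share of the disease gene set annotated to the
#' proteostasis network) and flags each PN pathway and functional class as
#' enriched when its raw upper-tail hypergeometric p-value is below `alpha`.
#'
#' Two universes are supported for the pathway/class tests. The default
#' (`universe_mode = "genome"`) tests the disease gene set against each
#' pathway within the full gene universe, so a pathway is flagged when the
#' disease set contains more of its genes than a random set of the same size
#' would. The alternative (`universe_mode = "pn"`) restricts both query and
#' universe to PN genes, testing the composition of the disease's PN subset
#' relative to the PN itself.
#'
#' @param set A [disease_gene_set()].
#' @param ann A [pn_annotation()].
#' @param universe A [gene_universe()]; query genes absent from it are
#'   dropped with a warning.
#' @param alpha Raw-p significance cutoff for the flags (default 0.01).
#' @param universe_mode `"genome"` (default) or `"pn"`, see Details.
#' @return An object of class `disease_profile` with elements `disease_id`,
#'   `pn_fraction`, `pathway_p`, `pathway_flag`, `class_p`, `class_flag`,
#'   `alpha`.
#' @export
profile_disease <- function(set, ann, universe, alpha = 0.01,
                            universe_mode = c("genome", "pn")) {
  universe_mode <- match.arg(universe_mode)
  stopifnot(alpha > 0, alpha < 1)
  genes <- intersect(set$genes, universe$genes)
  dropped <- length(set$genes) - length(genes)
  if (dropped > 0)
    warning(dropped, " gene(s) of '", set$disease_id,
            "' absent from the universe were dropped")
  if (!length(genes))
    stop("gene set '", set$disease_id, "' is empty after universe intersection")
  pn_genes <- intersect(ann$genes, universe$genes)
  pn_subset <- intersect(genes, pn_genes)
  pn_fraction <- length(pn_subset) / length(genes)

  if (universe_mode == "genome") {
    bg <- universe$genes
    query <- genes
  } else {
    bg <- pn_genes
    query <- pn_subset
  }
  test_cats <- function(cat_genes) {
    vapply(cat_genes, function(cg) {
      cg <- intersect(cg, bg)
      if (!length(query) || !length(cg)) return(1)
      hypergeom_upper_tail(length(intersect(query, cg)), length(cg),
                           length(query), length(bg))
    }, numeric(1))
  }
  if (!length(pn_subset))
    warning("'", set$disease_id, "' has no PN genes; all flags not-enriched")
  pathway_p <- test_cats(ann$pathway_genes)
  class_p <- test_cats(ann$class_genes)
  structure(list(disease_id = set$disease_id,
                 pn_fraction = pn_fraction,
                 pathway_p = pathway_p,
                 pathway_flag = pathway_p < alpha,
                 class_p = class_p,
                 class_flag = class_p < alpha,
                 alpha = alpha),
            class = "disease_profile")
}

#' @export
print.disease_profile <- function(x, ...) {
  cat("Proteostasis profile '", x$disease_id, "': PN fraction ",
      sprintf("%.3f", x$pn_fraction), "; enriched pathways: ",
      paste(names(x$pathway_flag)[x$pathway_flag], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Classify a disease profile into a proteostasis state
#'
#' Uses the UPS and EXTRACELLULAR pathway flags only; the ALP flag is
#' recorded in the profile but is enriched in all three states and is not
#' discriminative.
#'
#' @param profile A `disease_profile` from [profile_disease()].
#' @param ups,extracellular Names of the two discriminative pathways in the
#'   annotation vocabulary.
#' @return One of [PROTEOSTASIS_STATES].
#' @export
classify_state <- function(profile, ups = "UPS",
                           extracellular = "EXTRACELLULAR") {
  need <- c(ups, extracellular)
  missing <- setdiff(need, names(profile$pathway_flag))
  if (length(missing))
    stop("profile lacks pathway flag(s): ", paste(missing, collapse = ", "))
  u <- profile$pathway_flag[[ups]]
  e <- profile$pathway_flag[[extracellular]]
  if (u && !e) PROTEOSTASIS_STATES[1]
  else if (u && e) PROTEOSTASIS_STATES[2]
  else if (!u && e) PROTEOSTASIS_STATES[3]
  else PROTEOSTASIS_STATES[4]
}

#' Binary enrichment matrix across disease profiles
#'
#' @param profiles List of `disease_profile` objects sharing one annotation
#'   vocabulary.
#' @return Integer 0/1 matrix, diseases x (pathways then classes), in vocab
#'   order.
#' @export
profile_matrix <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  vocab <- c(names(profiles[[1]]$pathway_flag),
             names(profiles[[1]]$class_flag))
  rows <- lapply(profiles, function(p) {
    v <- c(names(p$pathway_flag), names(p$class_flag))
    if (!identical(v, vocab))
      stop("profile '", p$disease_id, "' has a mismatching vocabulary")
    as.integer(c(p$pathway_flag, p$class_flag))
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(vapply(profiles, function(p) p$disease_id, ""), vocab)
  m
}
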