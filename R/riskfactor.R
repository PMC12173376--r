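#' Signed PN gene set perturbed by an exposure
#'
#' Intersects the significantly perturbed genes of an exposure DE contrast
#' (non-zero direction calls) with the proteostasis network, carrying signs.
#'
#' @param de A `de_table` with direction calls (see [moderated_t()]).
#' @param ann A [pn_annotation()].
#' @return Named -1/+1 vector over the exposure's perturbed PN genes (empty,
#'   with a warning, when nothing is significant).
#' @export
exposure_pn_set <- function(de, ann) {
  signs <- de_signs(de)
  out <- signs[names(signs) %in% ann$genes]
  if (!length(out))
    warning("exposure perturbs no PN genes at the chosen cutoff")
  out
}

minmax <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[1] == r[2]) {
    warning("all raw similarities equal; normalized values reported missing")
    return(rep(NA_real_, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Score an exposure against a disease panel
#'
#' For every disease: the raw Jaccard similarity between the exposure's
#' perturbed PN genes and the disease gene set's PN subset, its min-max
#' normalization across the panel, and the directional similarity (fraction
#' of overlapping genes perturbed in the same direction) with the overlap
#' size. Three control baselines are computed the same way: the exposure's
#' perturbed kinases vs each disease's kinase subset, its perturbed
#' transcription factors vs each disease's TF subset, and a size-matched
#' random sample of all significantly perturbed exposure genes vs the full
#' disease gene set (seeded).
#'
#' @param exposure_sig Named -1/+1 vector of all significantly perturbed
#'   exposure genes (see [de_signs()]).
#' @param diseases Named list of [disease_gene_set()] objects (at least 2;
#'   normalization needs a panel).
#' @param ann A [pn_annotation()].
#' @param universe A [gene_universe()] carrying `KINASE` and `TF` groups for
#'   the control baselines (optional: controls are skipped when absent).
#' @param seed Integer seed for the random baseline.
#' @return An `exposure_report` data frame, one row per disease.
#' @export
score_exposure <- function(exposure_sig, diseases, ann, universe = NULL,
                           seed = 1L) {
  if (length(diseases) < 2)
    stop("normalization needs a panel of at least 2 diseases")
  exposure_pn <- exposure_sig[names(exposure_sig) %in% ann$genes]
  kin <- tf <- NULL
  if (!is.null(universe)) {
    kin <- universe$groups[["KINASE"]]
    tf <- universe$groups[["TF"]]
  }
  rnd <- local({
    pool <- names(exposure_sig)
    size <- min(length(exposure_pn), length(pool))
    with_stream(seed, "riskfactor_random_control",
                sample(pool, size))
  })
  one <- function(set) {
    dis_pn <- intersect(set$genes, ann$genes)
    ds <- list(ds = NA_real_, overlap = 0L)
    if (!is.null(set$sign_of)) {
      dis_signs <- set$sign_of[intersect(names(set$sign_of), dis_pn)]
      ds <- directional_similarity(exposure_pn, dis_signs)
    }
    data.frame(
      disease_id = set$disease_id,
      jaccard_pn = jaccard(names(exposure_pn), dis_pn),
      ds = ds$ds, overlap = ds$overlap,
      jaccard_kinase = if (is.null(kin)) NA_real_ else
        jaccard(intersect(names(exposure_sig), kin),
                intersect(set$genes, kin)),
      jaccard_tf = if (is.null(tf)) NA_real_ else
        jaccard(intersect(names(exposure_sig), tf),
                intersect(set$genes, tf)),
      jaccard_random = jaccard(rnd, set$genes),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(diseases, one))
  rownames(out) <- NULL
  out$jaccard_pn_norm <- minmax(out$jaccard_pn)
  out$jaccard_kinase_norm <- if (all(is.na(out$jaccard_kinase)))
    NA_real_ else minmax(out$jaccard_kinase)
  out$jaccard_tf_norm <- if (all(is.na(out$jaccard_tf)))
    NA_real_ else minmax(out$jaccard_tf)
  out$jaccard_random_norm <- minmax(out$jaccard_random)
  attr(out, "seed") <- seed
  class(out) <- c("exposure_report", "data.frame")
  out
}
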