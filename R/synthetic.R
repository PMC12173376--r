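# deterministic per-call RNG streams: each generator call draws from a seed
# derived from (seed, call name), so adding a generator never perturbs others
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer(((as.numeric(seed) %% 2^31) * 48271 + h) %% (2^31 - 1))
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(stream_seed(seed, name))
  expr
}

#' Specification of a synthetic study
#'
#' Collects the sizes, effect strengths and noise levels of the synthetic
#' gene universe and studies. All generator output is fully determined by
#' the spec together with its seed.
#'
#' @param n_genes Universe size (default 20000).
#' @param pn_size Number of proteostasis-network genes (default 2500).
#' @param pathway_sizes Named vector partitioning the PN into pathways.
#' @param group_sizes Named vector of control-group sizes (kinases,
#'   transcription factors, ion channels), disjoint from the PN.
#' @param k Disease gene-set size (default 500).
#' @param enrich_rate Sampling-weight multiplier for genes of a disease's
#'   enriched pathways (default 3).
#' @param intra_concordance Probability that a disease keeps its cluster's
#'   base perturbation sign for a gene; signs flip independently with
#'   probability `(1 - intra_concordance) / 2` (default 0.8).
#' @param effect_size Expression shift of affected genes in log2 units
#'   (default 1).
#' @param noise_sd Residual SD of log2 expression (default 0.5).
#' @param n_per_group Samples per condition in expression studies (default
#'   10).
#' @param n_stages Number of disease stages in staged studies (default 3).
#' @param exposure_frac Fraction of a disease's PN genes perturbed by an
#'   exposure study (default 0.5).
#' @param seed Integer master seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 20000, pn_size = 2500,
                           pathway_sizes = c(ALP = 800, UPS = 700,
                                             EXTRACELLULAR = 500,
                                             PROTEOSTASIS_REGULATION = 500),
                           group_sizes = c(KINASE = 600, TF = 1200,
                                           ION_CHANNEL = 300),
                           k = 500, enrich_rate = 3,
                           intra_concordance = 0.8,
                           effect_size = 1, noise_sd = 0.5,
                           n_per_group = 10, n_stages = 3,
                           exposure_frac = 0.5, seed = 1L) {
  if (sum(pathway_sizes) > pn_size)
    stop("pathway sizes exceed the PN size")
  if (pn_size + sum(group_sizes) > n_genes)
    stop("PN and control groups exceed the universe size")
  if (enrich_rate < 1) stop("'enrich_rate' must be >= 1")
  if (intra_concordance < 0 || intra_concordance > 1)
    stop("'intra_concordance' must lie in [0, 1]")
  if (k > n_genes) stop("'k' exceeds the universe size")
  structure(list(n_genes = n_genes, pn_size = pn_size,
                 pathway_sizes = pathway_sizes, group_sizes = group_sizes,
                 k = k, enrich_rate = enrich_rate,
                 intra_concordance = intra_concordance,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_per_group = n_per_group, n_stages = n_stages,
                 exposure_frac = exposure_frac,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

default_class_names <- list(
  ALP = c("AUTOPHAGY_MACHINERY", "LYSOSOMAL_ENZYMES"),
  UPS = c("UPS_E3_LIGASES", "UPS_PROTEASOME_SUBUNITS"),
  EXTRACELLULAR = c("EXTRACELLULAR_CHAPERONES", "EXTRACELLULAR_PROTEASES"),
  PROTEOSTASIS_REGULATION = c("MOLECULAR_CHAPERONES",
                              "STRESS_RESPONSE_REGULATORS"))

#' Generate a synthetic gene universe with PN annotation
#'
#' Synthetic symbols `G000001...` are randomly assigned (without overlap) to
#' the proteostasis network and the control protein groups; PN genes are
#' partitioned into pathways and, within each pathway, into two functional
#' classes.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `universe` (a [gene_universe()]) and `annotation`
#'   (a [pn_annotation()]).
#' @export
make_universe <- function(spec) {
  genes <- sprintf("G%06d", seq_len(spec$n_genes))
  with_stream(spec$seed, "make_universe", {
    perm <- sample(genes)
    pn <- perm[seq_len(spec$pn_size)]
    offset <- spec$pn_size
    groups <- list(PN = pn)
    for (nm in names(spec$group_sizes)) {
      groups[[nm]] <- perm[offset + seq_len(spec$group_sizes[[nm]])]
      offset <- offset + spec$group_sizes[[nm]]
    }
    # partition the PN into pathways (in declared order), leftovers to the last
    sizes <- spec$pathway_sizes
    sizes[length(sizes)] <- sizes[length(sizes)] + spec$pn_size - sum(sizes)
    idx <- rep(names(sizes), sizes)
    gene_col <- pn
    pathway_col <- idx
    class_col <- vapply(seq_along(pn), function(i) {
      pw <- idx[i]
      cls <- default_class_names[[pw]]
      if (is.null(cls)) cls <- paste0(pw, "_CLASS_", c("A", "B"))
      pos <- sum(idx[seq_len(i)] == pw)
      cls[1 + (pos > sum(idx == pw) / 2)]
    }, "")
    list(universe = gene_universe(genes, groups),
         annotation = pn_annotation(gene_col, pathway_col, class_col))
  })
}

state_enriched_pathways <- function(state) {
  state <- as.character(state)
  short <- c("I" = PROTEOSTASIS_STATES[1], "II" = PROTEOSTASIS_STATES[2],
             "III" = PROTEOSTASIS_STATES[3])
  if (state %in% names(short)) state <- short[[state]]
  if (!state %in% PROTEOSTASIS_STATES[1:3])
    stop("unknown proteostasis state: ", state)
  switch(state,
         STATE_I_ALP_UPS_ERneg = c("ALP", "UPS"),
         STATE_II_ALP_UPS_ERpos = c("ALP", "UPS", "EXTRACELLULAR"),
         STATE_III_ALP_ERpos = c("ALP", "EXTRACELLULAR"))
}

#' Base perturbation signature of a disease cluster
#'
#' One -1/+1 sign per universe gene, drawn from its own stream so that every
#' disease of the cluster flips from the same base.
#'
#' @param spec A [synthetic_spec()].
#' @param universe A [gene_universe()].
#' @param cluster Cluster name (enters the stream derivation).
#' @return Named -1/+1 vector over the universe genes.
#' @export
make_base_signature <- function(spec, universe, cluster) {
  with_stream(spec$seed, paste0("base_signature_", cluster),
              stats::setNames(sample(c(-1, 1), length(universe$genes),
                                     replace = TRUE),
                              universe$genes))
}

#' Generate a signed disease gene set with a planted proteostasis state
#'
#' Draws `k` genes without replacement with sampling weight `enrich_rate`
#' for genes of the state's enriched pathways (the ALP always; UPS and/or
#' extracellular proteostasis according to the state) and weight 1
#' otherwise. Signs start from the cluster's base signature and flip
#' independently with probability `(1 - intra_concordance) / 2`.
#'
#' @param spec A [synthetic_spec()].
#' @param disease_id Disease identifier (enters the stream derivation).
#' @param state A planted state (one of [PROTEOSTASIS_STATES][1:3] or the
#'   shorthand `"I"`, `"II"`, `"III"`).
#' @param universe,ann Output of [make_universe()].
#' @param base_signature Cluster base signs from [make_base_signature()];
#'   generated from the state name when omitted.
#' @param disease_group Optional group label stored on the set.
#' @return A signed [disease_gene_set()].
#' @export
make_disease_set <- function(spec, disease_id, state, universe, ann,
                             base_signature = NULL,
                             disease_group = NA_character_) {
  enriched <- state_enriched_pathways(state)
  if (is.null(base_signature))
    base_signature <- make_base_signature(spec, universe, as.character(state))
  w <- rep(1, length(universe$genes))
  names(w) <- universe$genes
  for (pw in enriched) {
    pg <- ann$pathway_genes[[pw]]
    if (is.null(pg)) stop("annotation lacks pathway ", pw)
    w[pg] <- spec$enrich_rate
  }
  with_stream(spec$seed, paste0("disease_", disease_id), {
    genes <- sample(universe$genes, spec$k, prob = w)
    flip <- stats::runif(spec$k) < (1 - spec$intra_concordance) / 2
    signs <- base_signature[genes] * ifelse(flip, -1, 1)
    disease_gene_set(disease_id, genes, disease_group = disease_group,
                     sign_of = signs, k = spec$k)
  })
}

#' Generate a panel of signed disease gene sets
#'
#' @param spec A [synthetic_spec()].
#' @param state_plan Named character vector mapping disease id to planted
#'   state; diseases sharing a state share a cluster base signature.
#' @param universe,ann Output of [make_universe()].
#' @return Named list of signed [disease_gene_set()] objects.
#' @export
make_disease_panel <- function(spec, state_plan, universe, ann) {
  states <- unique(state_plan)
  bases <- lapply(stats::setNames(nm = states), function(st)
    make_base_signature(spec, universe, as.character(st)))
  sets <- lapply(names(state_plan), function(id)
    make_disease_set(spec, id, state_plan[[id]], universe, ann,
                     base_signature = bases[[state_plan[[id]]]],
                     disease_group = as.character(state_plan[[id]])))
  stats::setNames(sets, names(state_plan))
}

#' Generate a staged expression study with a planted effect schedule
#'
#' Baseline log2 expression per gene is Normal(mu_g, noise_sd) with
#' mu_g ~ Uniform(4, 12). Affected genes are shifted by
#' `effect_size * w_s` in stage s, where `w_s = 1` for the `"early"`
#' schedule and `w_s = s / S` for the `"progressive"` schedule; controls are
#' unshifted.
#'
#' @param spec A [synthetic_spec()].
#' @param affected_genes Genes carrying the planted effect.
#' @param universe A [gene_universe()].
#' @param schedule `"early"` or `"progressive"`.
#' @param affected_signs Optional named -1/+1 shift directions for the
#'   affected genes (random signs when omitted).
#' @return An [expression_study()] with conditions `CONTROL`,
#'   `STAGE_1 ... STAGE_S`; the planted signs are attached as attribute
#'   `affected`.
#' @export
make_staged_expression <- function(spec, affected_genes, universe,
                                   schedule = c("early", "progressive"),
                                   affected_signs = NULL) {
  schedule <- match.arg(schedule)
  affected_genes <- intersect(norm_symbols(affected_genes), universe$genes)
  S <- spec$n_stages
  npg <- spec$n_per_group
  genes <- universe$genes
  G <- length(genes)
  conds <- c("CONTROL", paste0("STAGE_", seq_len(S)))
  with_stream(spec$seed, paste0("staged_expression_", schedule), {
    if (is.null(affected_signs))
      affected_signs <- stats::setNames(
        sample(c(-1, 1), length(affected_genes), replace = TRUE),
        affected_genes)
    else
      affected_signs <- affected_signs[affected_genes]
    mu <- stats::runif(G, 4, 12)
    n_samples <- npg * (S + 1)
    m <- matrix(stats::rnorm(G * n_samples, mean = mu, sd = spec$noise_sd),
                nrow = G)
    rownames(m) <- genes
    colnames(m) <- sprintf("S%03d", seq_len(n_samples))
    condition <- rep(conds, each = npg)
    w <- if (schedule == "early") rep(1, S) else seq_len(S) / S
    a_idx <- match(names(affected_signs), genes)
    for (s in seq_len(S)) {
      cols <- which(condition == paste0("STAGE_", s))
      m[a_idx, cols] <- m[a_idx, cols] +
        affected_signs * spec$effect_size * w[s]
    }
    study <- expression_study(m, stats::setNames(condition, colnames(m)))
    attr(study, "affected") <- affected_signs
    study
  })
}

#' Generate an exposure expression study with tunable concordance
#'
#' Perturbs a fraction of the target disease's signed genes in `EXPOSED`
#' samples; each perturbed gene's direction matches the disease sign with
#' probability `concordance` and is flipped otherwise.
#'
#' @param spec A [synthetic_spec()].
#' @param target_signs Named -1/+1 vector (the disease's signed PN genes).
#' @param concordance Probability of direction agreement, in [0, 1].
#' @param universe A [gene_universe()].
#' @param label Stream label so that several exposure studies can be drawn
#'   from one spec.
#' @return An [expression_study()] with conditions `CONTROL`/`EXPOSED`; the
#'   planted exposure signs are attached as attribute `exposure_signs`.
#' @export
make_exposure_study <- function(spec, target_signs, concordance, universe,
                                label = "exposure") {
  if (concordance < 0 || concordance > 1)
    stop("'concordance' must lie in [0, 1]")
  genes <- universe$genes
  G <- length(genes)
  npg <- spec$n_per_group
  with_stream(spec$seed, paste0("exposure_", label), {
    n_pert <- max(1L, round(spec$exposure_frac * length(target_signs)))
    perturbed <- sample(names(target_signs), n_pert)
    agree <- stats::runif(n_pert) < concordance
    signs <- target_signs[perturbed] * ifelse(agree, 1, -1)
    mu <- stats::runif(G, 4, 12)
    m <- matrix(stats::rnorm(G * 2 * npg, mean = mu, sd = spec$noise_sd),
                nrow = G)
    rownames(m) <- genes
    colnames(m) <- sprintf("S%03d", seq_len(2 * npg))
    condition <- rep(c("CONTROL", "EXPOSED"), each = npg)
    cols <- which(condition == "EXPOSED")
    m[match(perturbed, genes), cols] <-
      m[match(perturbed, genes), cols] + signs * spec$effect_size
    study <- expression_study(m, stats::setNames(condition, colnames(m)))
    attr(study, "exposure_signs") <- signs
    study
  })
}

#' Generate a preferential-attachment network with designated hub nodes
#'
#' Nodes arrive in random order; each attaches to existing nodes with
#' probability proportional to current degree + 1. Nodes of the hub stage
#' bring `m_hub` stubs, all others `m_base`, so hub-stage nodes end up most
#' central when `m_hub > m_base`.
#'
#' @param spec A [synthetic_spec()].
#' @param node_stages Named character vector mapping node name to stage
#'   label.
#' @param m_base,m_hub Stub counts for ordinary and hub nodes.
#' @param hub_stage Stage label designating the hub set (default `"mid"`).
#' @return An [interaction_network()] with `stage_of` set.
#' @export
make_hub_network <- function(spec, node_stages, m_base = 2, m_hub = 8,
                             hub_stage = "mid") {
  if (m_hub < m_base) stop("'m_hub' must be >= 'm_base'")
  nodes <- norm_symbols(names(node_stages))
  names(node_stages) <- nodes
  if (length(nodes) < 2) stop("need at least 2 nodes")
  with_stream(spec$seed, "hub_network", {
    ord <- sample(nodes)
    deg <- stats::setNames(integer(length(nodes)), ord)
    from <- character(0); to <- character(0)
    for (i in 2:length(ord)) {
      v <- ord[i]
      existing <- ord[seq_len(i - 1)]
      m <- if (identical(unname(node_stages[[v]]), hub_stage)) m_hub
           else m_base
      m <- min(m, length(existing))
      targets <- if (length(existing) == 1) existing
                 else sample(existing, m, prob = deg[existing] + 1)
      from <- c(from, rep(v, length(targets)))
      to <- c(to, targets)
      deg[v] <- deg[v] + length(targets)
      deg[targets] <- deg[targets] + 1L
    }
    interaction_network(nodes = nodes, edges = cbind(from, to),
                        stage_of = node_stages)
  })
}

#' Write a full synthetic input bundle to a directory
#'
#' Generates the universe, annotation, a disease panel, one staged and one
#' exposure expression study, and a hub network, and writes them in the
#' package's TSV/GMT formats. Output is byte-identical for identical
#' (spec, seed).
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param state_plan Named disease-to-state plan; a default 6-disease panel
#'   (2 per state) is used when omitted.
#' @return Invisibly, the named vector of written file paths.
#' @export
write_synthetic_inputs <- function(spec, dir, state_plan = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(state_plan))
    state_plan <- stats::setNames(
      rep(PROTEOSTASIS_STATES[1:3], each = 2),
      paste0("DISEASE_", sprintf("%02d", 1:6)))
  uni <- make_universe(spec)
  sets <- make_disease_panel(spec, state_plan, uni$universe, uni$annotation)
  path <- function(f) file.path(dir, f)
  write_universe(uni$universe, path("universe.tsv"))
  write_pn_annotation(uni$annotation, path("pn.tsv"))
  write_gene_sets(sets, path("sets.gmt"), signs = path("signs.tsv"))
  affected <- intersect(sets[[1]]$genes, uni$annotation$genes)
  staged <- make_staged_expression(spec, affected, uni$universe,
                                   schedule = "progressive")
  write_expression_study(staged, path("expr_staged.tsv"),
                         path("meta_staged.tsv"))
  target <- sets[[1]]$sign_of[intersect(names(sets[[1]]$sign_of),
                                        uni$annotation$genes)]
  expo <- make_exposure_study(spec, target, concordance = 0.8,
                              universe = uni$universe)
  write_expression_study(expo, path("expr_exposure.tsv"),
                         path("meta_exposure.tsv"))
  stages <- rep(c("early", "mid", "late"), length.out = length(affected))
  net <- make_hub_network(spec, stats::setNames(stages, affected))
  utils::write.table(data.frame(from = net$edges[, 1], to = net$edges[, 2]),
                     path("net.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(node = names(net$stage_of),
                                stage = unname(net$stage_of)),
                     path("stage_of.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(universe = path("universe.tsv"), pn = path("pn.tsv"),
             sets = path("sets.gmt"), signs = path("signs.tsv"),
             expr_staged = path("expr_staged.tsv"),
             meta_staged = path("meta_staged.tsv"),
             expr_exposure = path("expr_exposure.tsv"),
             meta_exposure = path("meta_exposure.tsv"),
             edges = path("net.tsv"), stage_of = path("stage_of.tsv"))
  invisible(files)
}
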