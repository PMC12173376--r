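config_hash <- function(config) {
  config <- config[setdiff(names(config), "out_dir")]  # analysis identity
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(config))], file = f)
  unname(tools::md5sum(f))
}

write_stage_tsv <- function(df, path, config, seed) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# proteosig %s\tconfig_hash=%s\tseed=%s",
                     as.character(utils::packageVersion("proteosig")),
                     config_hash(config), seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file holding one) with input
#' paths (`sets`, `pn`, `universe`, optionally `signs`, `expr`, `meta`,
#' `exposure_expr`, `exposure_meta`, `edges`, `stage_of`), analysis
#' parameters (`k`, `alpha_profile`, `direction_alpha`, `fdr_cut`,
#' `n_clusters`, `stages`, `control`, `seed`) and an output directory
#' (`out_dir`).
#'
#' @param config Named list or path to a YAML file.
#' @return The validated configuration list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(k = 500, alpha_profile = 0.01, direction_alpha = 0.05,
                   fdr_cut = 0.05, n_clusters = 4, seed = 1L,
                   stages = NULL, control = "CONTROL")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("alpha_profile", "direction_alpha", "fdr_cut")) {
    v <- config[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("config threshold '", nm, "' must lie in (0, 1)")
  }
  required <- c("out_dir", "sets", "pn", "universe")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config lacks required field(s): ", paste(missing, collapse = ", "))
  for (nm in intersect(c("sets", "pn", "universe", "signs", "expr", "meta",
                         "exposure_expr", "exposure_meta", "edges",
                         "stage_of"), names(config))) {
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]]))
      stop("config input '", nm, "' does not exist: ", config[[nm]])
  }
  config
}

#' Run the full proteostasis-signature pipeline
#'
#' Executes, as configured: protein-group enrichment, disease profiling,
#' state classification, similarity clustering, consensus signatures, and
#' (when expression inputs are present) stage-wise progression and
#' risk-factor scoring. Every output TSV carries a header comment with the
#' tool version, a configuration hash, and the seed.
#'
#' @param config See [run_config()].
#' @return A manifest data frame (`stage`, `path`, `rows`), with the
#'   configuration hash as attribute `config_hash`.
#' @export
run_all <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  manifest_rows <- list()
  emit <- function(stage, df, file) {
    path <- write_stage_tsv(df, file.path(config$out_dir, file),
                            config, seed)
    manifest_rows[[stage]] <<- data.frame(stage = stage, path = path,
                                          rows = nrow(df),
                                          stringsAsFactors = FALSE)
    message("stage ", stage, ": ", nrow(df), " rows -> ", path)
    invisible(path)
  }

  universe <- read_universe(config$universe)
  ann <- read_pn_annotation(config$pn)
  sets <- read_gene_sets(config$sets, k = config$k, signs = config$signs)
  message("loaded ", length(sets), " gene sets, universe of ",
          length(universe$genes), " genes")

  # protein-group over-representation (PN vs control groups)
  if (!length(universe$groups)) stop("universe carries no protein groups")
  enr <- overrepresentation_table(sets, universe$groups, universe)
  emit("enrich", enr, "enrich.tsv")

  # disease profiles and state labels
  profiles <- lapply(sets, profile_disease, ann = ann, universe = universe,
                     alpha = config$alpha_profile)
  pm <- profile_matrix(profiles)
  prof_df <- data.frame(disease_id = rownames(pm),
                        pn_fraction = vapply(profiles, function(p)
                          p$pn_fraction, numeric(1)),
                        pm, stringsAsFactors = FALSE, check.names = FALSE)
  emit("profile", prof_df, "profiles.tsv")
  states <- vapply(profiles, classify_state, "")
  emit("states", data.frame(disease_id = names(states),
                            state = unname(states),
                            stringsAsFactors = FALSE), "states.tsv")

  # similarity clustering and consensus signatures
  sim <- similarity_matrix(sets)
  cl <- cluster_diseases(sim, min(config$n_clusters, length(sets)))
  emit("cluster", data.frame(disease_id = names(cl), cluster = unname(cl),
                             stringsAsFactors = FALSE), "clusters.tsv")
  sig_pathways <- intersect(c("ALP", "UPS", "EXTRACELLULAR"),
                            ann$pathway_vocab)
  sig_rows <- list()
  for (k_cl in sort(unique(cl))) {
    members <- sets[names(cl)[cl == k_cl]]
    if (!any(vapply(members, function(s) !is.null(s$sign_of), TRUE))) next
    for (pw in sig_pathways) {
      sv <- consensus_signature(members, ann, pw)
      if (!nrow(sv)) next
      sig_rows[[length(sig_rows) + 1L]] <-
        data.frame(cluster = k_cl, pathway = pw,
                   as.data.frame(sv), stringsAsFactors = FALSE)
    }
  }
  sig_df <- if (length(sig_rows)) do.call(rbind, sig_rows) else
    data.frame(cluster = integer(0), pathway = character(0),
               gene = character(0), value = numeric(0),
               support = integer(0))
  emit("signature", sig_df, "signatures.tsv")

  # stage-wise progression (optional)
  if (!is.null(config$expr)) {
    study <- read_expression_study(config$expr, config$meta)
    stages <- config$stages
    if (is.null(stages))
      stages <- sort(setdiff(unique(study$condition), config$control))
    res <- stagewise_de(study, stages, config$control,
                        alpha = config$direction_alpha)
    emit("progression",
         data.frame(gene = names(res$onset), onset = unname(res$onset),
                    stringsAsFactors = FALSE), "progression.tsv")
    props <- do.call(rbind, lapply(
      intersect(c("ALP", "UPS"), ann$pathway_vocab), function(pw)
        data.frame(pathway = pw, stage = res$stages,
                   proportion = unname(
                     stage_proportions(res, ann$pathway_genes[[pw]])),
                   stringsAsFactors = FALSE)))
    if (!is.null(props))
      write_stage_tsv(props, file.path(config$out_dir, "stage_props.tsv"),
                      config, seed)
    if (!is.null(config$edges)) {
      net <- read_edge_list(config$edges, stage_of = config$stage_of)
      write_stage_tsv(centrality(net),
                      file.path(config$out_dir, "centrality.tsv"),
                      config, seed)
    }
  }

  # risk-factor scoring (optional)
  if (!is.null(config$exposure_expr)) {
    expo <- read_expression_study(config$exposure_expr,
                                  config$exposure_meta)
    case <- setdiff(unique(expo$condition), config$control)[1]
    de <- run_de(expo, c(case, config$control),
                 direction_alpha = config$direction_alpha)
    report <- score_exposure(de_signs(de), sets, ann, universe,
                             seed = config$seed)
    emit("riskfactor", as.data.frame(report), "riskfactor.tsv")
  }

  out <- do.call(rbind, manifest_rows)
  rownames(out) <- NULL
  attr(out, "config_hash") <- config_hash(config)
  out
}
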