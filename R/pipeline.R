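#' Fine map one region: tag, search, expand, rescore, group
#'
#' The core four-step strategy as a single call on in-memory data:
#' (1) cluster variants at r^2 > `r2_tag` into tagsets and restrict the
#' panel to the tags; (2) explore multi-SNP models over the tags
#' (exhaustively when the model space is small, otherwise by seeded
#' stochastic shotgun search); (3) retain the `n_keep` best models;
#' (4) expand them by tagset substitution, rescore every expanded model on
#' the full panel and normalise, then aggregate the posterior into SNP
#' groups.
#'
#' @param g a preprocessed [geno_matrix()] (full panel).
#' @param y response vector.
#' @param covariates optional covariate data.frame.
#' @param family `"quantitative"` or `"case-control"`.
#' @param n_exp prior expected number of causal variants (default 3).
#' @param r2_tag tagging threshold (default 0.99).
#' @param method `"auto"`, `"exhaustive"` or `"stochastic"`; `"auto"` picks
#'   exhaustive enumeration when at most `exhaustive_limit` tag models
#'   exist.
#' @param max_size cap on model size (default `min(10, n_tags)`).
#' @param n_iter,n_chains,n_keep,seed search settings (see
#'   [search_config()]).
#' @param exhaustive_limit model-count bound for auto-exhaustive (default
#'   5000).
#' @param ld optional precomputed [ld_matrix()] over `g`.
#' @return List with `tagmap`, `ld`, `visited`, `top`, `posterior` (the
#'   expanded, rescored `posterior_set`) and `groups` (a [snp_picker()]
#'   `group_set`).
#' @export
finemap_region <- function(g, y, covariates = NULL,
                           family = c("quantitative", "case-control"),
                           n_exp = 3, r2_tag = 0.99,
                           method = c("auto", "exhaustive", "stochastic"),
                           max_size = NULL, n_iter = 3000L, n_chains = 3L,
                           n_keep = 30000L, seed = 1L,
                           exhaustive_limit = 5000, ld = NULL) {
  family <- match.arg(family)
  method <- match.arg(method)
  ldm <- ld %||% ld_matrix(g)
  tagmap <- build_tagsets(g, ldm, r2_threshold = r2_tag)
  g_tags <- subset_variants(g, tags(tagmap))
  n_tags <- ncol(g_tags$dosages)
  cfg <- search_config(max_size = max_size, n_iter = n_iter,
                       n_chains = n_chains, seed = seed, n_keep = n_keep,
                       prior = default_prior(n_tags, n_exp))
  ms <- min(cfg$max_size %||% 10L, n_tags)
  if (method == "auto")
    method <- if (sum(choose(n_tags, 0:ms)) <= exhaustive_limit)
      "exhaustive" else "stochastic"
  visited <- if (method == "exhaustive")
    exhaustive_search(g_tags, y, covariates, family, cfg)
  else
    stochastic_search(g_tags, y, covariates, family, cfg)
  top <- top_models(visited, cfg$n_keep)
  expanded <- expand_models(top, tagmap)
  post <- rescore_expanded(expanded, g, y, covariates, family,
                           prior = default_prior(ncol(g$dosages), n_exp))
  groups <- snp_picker(post, ldm, variants = g$variants)
  list(tagmap = tagmap, ld = ldm, visited = visited, top = top,
       posterior = post, groups = groups, method = method)
}

pipeline_defaults <- function() {
  list(format = "auto", family = "quantitative", maf_min = 0.005,
       r2_tag = 0.99, n_exp = 3, n_exp_grid = c(1, 2, 3, 4, 5),
       method = "auto", max_size = NULL, n_iter = 3000L, n_chains = 3L,
       n_keep = 30000L, seed = 1L, outdir = ".")
}

#' Run the full fine-mapping pipeline from files
#'
#' Orchestrates genotype ingestion, preprocessing, [finemap_region()] and
#' the posterior summaries, writing a reproducible artefact bundle:
#' `models.tsv` (retained tag models), `expanded.tsv` (expanded posterior
#' with provenance), `groups.tsv` (SNP groups with MPPI/gMPPI),
#' `nsnp.tsv` (posterior over model size), `sensitivity.tsv`
#' (prior-expectation sweep) and `run.json` (the resolved configuration,
#' its hash, and run metadata). Every TSV carries the config hash as a
#' comment line.
#'
#' @param config named list or path to a JSON file. Required fields:
#'   `genotypes` (path) and `phenotype` (path to a
#'   `sample_id / phenotype / covariates...` TSV). Optional fields with
#'   defaults: `format` ("auto"), `family` ("quantitative"), `maf_min`
#'   (0.005), `r2_tag` (0.99), `n_exp` (3), `n_exp_grid` (1..5), `method`
#'   ("auto"), `max_size`, `n_iter` (3000), `n_chains` (3), `n_keep`
#'   (30000), `seed` (1), `outdir` (".").
#' @return Invisibly, a list with the fitted objects (`tagmap`, `visited`,
#'   `top`, `posterior`, `groups`, `nsnp`, `sensitivity`), the resolved
#'   `config` and the output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(pipeline_defaults(), config)
  for (req in c("genotypes", "phenotype"))
    if (is.null(cfg[[req]])) stop("config lacks required field '", req, "'")
  ## hash identifies the analysis, not where it is written
  hcfg <- cfg[setdiff(names(cfg), "outdir")]
  hash <- config_hash(as.character(
    jsonlite::toJSON(hcfg[order(names(hcfg))], auto_unbox = TRUE,
                     null = "null")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  g <- stage("read", read_genotypes(cfg$genotypes, cfg$format))
  ph <- stage("read", read_phenotypes(cfg$phenotype))
  common <- intersect(rownames(g$dosages), ph$sample_id)
  if (length(common) == 0L)
    stop("pipeline stage 'read' failed: no shared sample ids between ",
         "genotypes and phenotypes", call. = FALSE)
  g$dosages <- g$dosages[common, , drop = FALSE]
  g$missing <- g$missing[common, , drop = FALSE]
  pidx <- match(common, ph$sample_id)
  y <- ph$phenotype[pidx]
  covs <- if (!is.null(ph$covariates))
    ph$covariates[pidx, , drop = FALSE] else NULL
  g <- stage("preprocess", preprocess_genotypes(g, cfg$maf_min))
  fm <- stage("finemap", finemap_region(
    g, y, covariates = covs, family = cfg$family, n_exp = cfg$n_exp,
    r2_tag = cfg$r2_tag, method = cfg$method, max_size = cfg$max_size,
    n_iter = cfg$n_iter, n_chains = cfg$n_chains, n_keep = cfg$n_keep,
    seed = cfg$seed))
  nsnp <- nsnp_posterior(fm$posterior)
  sens <- reweight_prior(fm$posterior, cfg$n_exp_grid)$sensitivity
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    models = file.path(cfg$outdir, "models.tsv"),
    expanded = file.path(cfg$outdir, "expanded.tsv"),
    groups = file.path(cfg$outdir, "groups.tsv"),
    nsnp = file.path(cfg$outdir, "nsnp.tsv"),
    sensitivity = file.path(cfg$outdir, "sensitivity.tsv"),
    run = file.path(cfg$outdir, "run.json"))
  hc <- paste0("config_hash=", hash)
  write_models(normalise_posterior(as.data.frame(fm$top),
                                   prior = attr(fm$top, "prior")),
               paths$models, header_comment = hc)
  write_models(fm$posterior, paths$expanded, header_comment = hc)
  write_tsv_hashed <- function(df, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("# ", hc), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv_hashed(as.data.frame(fm$groups), paths$groups)
  write_tsv_hashed(nsnp, paths$nsnp)
  write_tsv_hashed(sens, paths$sensitivity)
  diag <- attr(fm$visited, "diagnostics")
  jsonlite::write_json(
    list(config = cfg, config_hash = hash,
         package_version = as.character(utils::packageVersion("shotgunfm")),
         search_method = fm$method,
         n_variants = ncol(g$dosages),
         n_tags = length(tags(fm$tagmap)),
         n_models_visited = nrow(fm$visited),
         n_models_expanded = nrow(fm$posterior),
         top20_jaccard = diag$top20_jaccard %||% NA),
    paths$run, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(fm, list(nsnp = nsnp, sensitivity = sens, config = cfg,
                       config_hash = hash, paths = paths)))
}
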