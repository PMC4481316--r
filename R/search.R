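#' Configuration for model-space search
#'
#' @param max_size cap on model size; default `min(10, N)` at search time.
#' @param n_iter Metropolis-Hastings iterations per chain.
#' @param n_chains number of independent chains.
#' @param seed master RNG seed; chain `c` uses `seed + c`.
#' @param n_keep number of top models retained by [top_models()].
#' @param prior optional [prior_spec()]; defaults to `prior_spec(N, 3)` over
#'   the searched panel.
#' @return An object of class `search_config`.
#' @export
search_config <- function(max_size = NULL, n_iter = 3000L, n_chains = 3L,
                          seed = 1L, n_keep = 30000L, prior = NULL) {
  stopifnot(is.null(max_size) || max_size >= 1, n_iter >= 1,
            n_chains >= 1, n_keep >= 1)
  structure(list(max_size = max_size, n_iter = as.integer(n_iter),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 n_keep = as.integer(n_keep), prior = prior),
            class = "search_config")
}

new_visited_set <- function(df, prior, n, family, panel, diagnostics = NULL) {
  rownames(df) <- NULL
  structure(df, class = c("visited_set", "data.frame"),
            prior = prior, n = n, family = family, panel = panel,
            diagnostics = diagnostics)
}

#' @export
print.visited_set <- function(x, ...) {
  cat("visited_set:", nrow(x), "models over",
      length(attr(x, "panel")), "variants\n")
  ord <- order(-(x$log_abf + x$log_prior))
  top <- utils::head(as.data.frame(x)[ord, c("model", "size", "log_abf")], 5L)
  top$model[top$model == ""] <- "(null)"
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}

resolve_search_setup <- function(g, y, covariates, family, config) {
  stopifnot(inherits(config, "search_config"))
  ctx <- make_score_context(g, y, covariates, family)
  N <- length(ctx$ids)
  list(ctx = ctx,
       N = N,
       max_size = as.integer(min(config$max_size %||% 10L, N)),
       prior = config$prior %||% default_prior(N, 3))
}

score_key <- function(ctx, key) {
  ids <- model_ids(key)
  s <- score_model(ctx, ids)
  if (!s$converged) return(-Inf)
  (s$loglik - ctx$loglik0) - (length(ids) / 2) * log(ctx$n)
}

#' Exhaustively enumerate and score all models
#'
#' Fits and scores every model of size up to `max_size` (plus the null
#' model) over the supplied panel -- the ground-truth enumerator against
#' which the stochastic search is validated, and a practical choice when the
#' tag panel is small. Guarded at 2e6 models.
#'
#' @param g a preprocessed [geno_matrix()] (typically restricted to tags).
#' @param y response vector.
#' @param covariates optional covariate data.frame.
#' @param family `"quantitative"` or `"case-control"`.
#' @param config a [search_config()].
#' @return A `visited_set` data.frame with columns `model`, `size`,
#'   `log_abf`, `log_prior`.
#' @export
exhaustive_search <- function(g, y, covariates = NULL,
                              family = c("quantitative", "case-control"),
                              config = search_config()) {
  family <- match.arg(family)
  setup <- resolve_search_setup(g, y, covariates, family, config)
  ctx <- setup$ctx
  n_models <- sum(choose(setup$N, 0:setup$max_size))
  if (n_models > 2e6)
    stop("exhaustive enumeration would visit ", format(n_models),
         " models; use stochastic_search")
  keys <- character(n_models)
  keys[1L] <- ""
  pos <- 1L
  for (k in seq_len(setup$max_size)) {
    cmb <- utils::combn(sort(ctx$ids), k)
    kk <- apply(cmb, 2L, paste, collapse = ",")
    keys[pos + seq_along(kk)] <- kk
    pos <- pos + length(kk)
  }
  la <- vapply(keys, function(key) score_key(ctx, key), numeric(1),
               USE.NAMES = FALSE)
  size <- lengths(model_members(keys))
  df <- data.frame(model = keys, size = size, log_abf = la,
                   log_prior = model_log_prior(size, setup$prior),
                   stringsAsFactors = FALSE)
  new_visited_set(df, setup$prior, ctx$n, family, ctx$ids)
}

## effective move probabilities given the current state; base mix
## add/drop/swap = 0.4/0.4/0.2, renormalised over feasible moves
move_probs <- function(size, n_absent, max_size) {
  p <- c(add = 0.4, drop = 0.4, swap = 0.2)
  if (size == 0L) p[c("drop", "swap")] <- 0
  if (n_absent == 0L) p[c("add", "swap")] <- 0
  if (size >= max_size) p["add"] <- 0
  s <- sum(p)
  if (s == 0) return(NULL)
  p / s
}

## log proposal density of a specific (move, m -> m') transition
log_q <- function(move, size, n_absent, max_size) {
  p <- move_probs(size, n_absent, max_size)
  if (is.null(p) || p[move] == 0) return(-Inf)
  log(p[[move]]) - switch(move,
    add  = log(n_absent),
    drop = log(size),
    swap = log(size) + log(n_absent))
}

#' Stochastic shotgun search over multi-SNP models
#'
#' Seeded multi-chain Metropolis-Hastings walk over model space targeting
#' the posterior `pp ~ BF * prior`, with add / drop / swap proposals in a
#' 0.4 / 0.4 / 0.2 mix. Every distinct model evaluated (whether or not the
#' proposal was accepted) is recorded with its BIC-approximate log Bayes
#' factor, and the union across chains is returned; with enough iterations
#' this concentrates on the same high-posterior models an exhaustive
#' enumeration would rank first. Fully reproducible: chain `c` is seeded
#' with `config$seed + c`.
#'
#' @inheritParams exhaustive_search
#' @return A `visited_set`; the attribute `"diagnostics"` holds per-chain
#'   best-score traces and the mean pairwise Jaccard overlap of the chains'
#'   top-20 model sets (a value below 0.5 triggers a convergence warning).
#' @export
stochastic_search <- function(g, y, covariates = NULL,
                              family = c("quantitative", "case-control"),
                              config = search_config()) {
  family <- match.arg(family)
  setup <- resolve_search_setup(g, y, covariates, family, config)
  ctx <- setup$ctx
  max_size <- setup$max_size
  ids <- sort(ctx$ids)
  ## env keys are "."-prefixed so the null model ("") is storable
  cache <- new.env(parent = emptyenv())
  get_score <- function(key) {
    ekey <- paste0(".", key)
    hit <- cache[[ekey]]
    if (!is.null(hit)) return(hit)
    la <- score_key(ctx, key)
    sz <- length(model_ids(key))
    val <- la + model_log_prior(sz, setup$prior)
    cache[[ekey]] <- val
    val
  }
  traces <- vector("list", config$n_chains)
  chain_tops <- vector("list", config$n_chains)
  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain)
    cur <- character()          # start at the null model
    cur_key <- ""
    cur_s <- get_score("")
    chain_seen <- new.env(parent = emptyenv())
    chain_seen[[paste0(".", cur_key)]] <- cur_s
    best <- numeric(config$n_iter)
    best_so_far <- cur_s
    accepted <- 0L
    for (it in seq_len(config$n_iter)) {
      size <- length(cur)
      absent <- setdiff(ids, cur)
      p <- move_probs(size, length(absent), max_size)
      if (is.null(p)) break                       # degenerate panel
      move <- sample(names(p), 1L, prob = p)
      if (move == "add") {
        prop <- c(cur, absent[sample.int(length(absent), 1L)])
      } else if (move == "drop") {
        prop <- cur[-sample.int(size, 1L)]
      } else {
        prop <- c(cur[-sample.int(size, 1L)],
                  absent[sample.int(length(absent), 1L)])
      }
      prop_key <- model_key(prop)
      prop_s <- get_score(prop_key)
      chain_seen[[paste0(".", prop_key)]] <- prop_s
      rev_move <- switch(move, add = "drop", drop = "add", swap = "swap")
      lq_fwd <- log_q(move, size, length(absent), max_size)
      lq_rev <- log_q(rev_move, length(prop), setup$N - length(prop),
                      max_size)
      log_alpha <- (prop_s - cur_s) + lq_rev - lq_fwd
      if (is.finite(log_alpha) && log(stats::runif(1L)) < log_alpha) {
        cur <- prop; cur_key <- prop_key; cur_s <- prop_s
        accepted <- accepted + 1L
      }
      if (cur_s > best_so_far) best_so_far <- cur_s
      best[it] <- best_so_far
    }
    if (accepted == 0L)
      warning("chain ", chain, " accepted no moves; score surface may be ",
              "degenerate (best score ", signif(best_so_far, 4), ")")
    traces[[chain]] <- best
    ekeys <- ls(chain_seen, all.names = TRUE)
    cs <- vapply(ekeys, function(k) chain_seen[[k]], numeric(1))
    ckeys <- substring(ekeys, 2L)
    chain_tops[[chain]] <- ckeys[order(-cs)][seq_len(min(20L, length(ckeys)))]
  }
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  jaccard <- if (config$n_chains > 1L) {
    prs <- utils::combn(config$n_chains, 2L)
    mean(apply(prs, 2L, function(ij)
      jac(chain_tops[[ij[1]]], chain_tops[[ij[2]]])))
  } else NA_real_
  if (!is.na(jaccard) && jaccard < 0.5)
    warning("chain agreement low (top-20 Jaccard ", signif(jaccard, 3),
            " < 0.5); consider more iterations")
  ekeys <- ls(cache, all.names = TRUE)
  keys <- substring(ekeys, 2L)
  size <- lengths(model_members(keys))
  lp <- model_log_prior(size, setup$prior)
  la <- vapply(ekeys, function(k) cache[[k]], numeric(1),
               USE.NAMES = FALSE) - lp
  df <- data.frame(model = keys, size = size, log_abf = la, log_prior = lp,
                   stringsAsFactors = FALSE)
  new_visited_set(df, setup$prior, ctx$n, family, ctx$ids,
                  diagnostics = list(best_trace = traces,
                                     top20_jaccard = jaccard))
}

#' Retain the highest-scoring visited models
#'
#' Keeps the `n_keep` models with the largest `log_abf + log_prior`
#' (mirroring "save the top 30,000 models visited"); ties are broken by
#' smaller size, then lexicographic model key. The null model is always
#' retained.
#'
#' @param v a `visited_set`.
#' @param n_keep number of models to keep.
#' @return A `visited_set` with at most `n_keep` models (plus the null).
#' @export
top_models <- function(v, n_keep = 30000L) {
  stopifnot(inherits(v, "visited_set"), n_keep >= 1)
  if (nrow(v) <= n_keep) return(v)
  score <- v$log_abf + v$log_prior
  ord <- order(-score, v$size, v$model, method = "radix")
  keep <- ord[seq_len(n_keep)]
  df <- as.data.frame(v)[keep, , drop = FALSE]
  if (!"" %in% df$model)
    df <- rbind(df, as.data.frame(v)[v$model == "", , drop = FALSE])
  new_visited_set(df, attr(v, "prior"), attr(v, "n"), attr(v, "family"),
                  attr(v, "panel"), attr(v, "diagnostics"))
}
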