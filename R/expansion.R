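#' Expand tag models by tagset substitution
#'
#' For each retained tag model, emits every model that can be formed by
#' replacing each of its tag SNPs with any member of that tag's tagset (the
#' Cartesian product over the model's tagsets), de-duplicated globally. The
#' null model passes through. Because substitution never adds a SNP, no
#' expanded model contains two members of the same tagset.
#'
#' If the total expanded count would exceed `max_expanded` (default 5e6),
#' expansion is restricted to the highest-posterior tag models whose
#' cumulative posterior mass reaches 0.9999.
#'
#' @param top a `visited_set` of retained tag models (see [top_models()]).
#' @param tagmap a [build_tagsets()] result; every SNP in every model of
#'   `top` must be one of its tags.
#' @param max_expanded guard on the number of expanded models.
#' @return Character vector of expanded model keys; the attribute
#'   `"provenance"` is a data.frame mapping each expanded model to the
#'   originating tag model(s).
#' @export
expand_models <- function(top, tagmap, max_expanded = 5e6) {
  stopifnot(inherits(tagmap, "tag_map"))
  tagsets <- attr(tagmap, "tagsets")
  keys <- top$model
  members <- model_members(keys)
  bad <- setdiff(unique(unlist(members)), names(tagsets))
  if (length(bad))
    stop("model(s) contain non-tag variants: ", paste(bad, collapse = ", "))
  counts <- vapply(members, function(m) prod(lengths(tagsets[m])),
                   numeric(1))
  if (sum(counts) > max_expanded) {
    pp <- normalise_posterior(as.data.frame(top),
                              prior = attr(top, "prior"))$pp
    ord <- order(-pp)
    cum <- cumsum(pp[ord])
    keep_n <- min(which(cum >= 0.9999))
    sel <- sort(ord[seq_len(keep_n)])
    keys <- keys[sel]; members <- members[sel]; counts <- counts[sel]
  }
  exp_keys <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    m <- members[[i]]
    if (length(m) == 0L) { exp_keys[[i]] <- ""; next }
    grid <- expand.grid(tagsets[m], stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    exp_keys[[i]] <- apply(as.matrix(grid), 1L,
                           function(r) paste(sort(r), collapse = ","))
  }
  prov <- data.frame(expanded = unlist(exp_keys),
                     origin = rep(keys, lengths(exp_keys)),
                     stringsAsFactors = FALSE)
  out <- unique(prov$expanded)
  attr(out, "provenance") <- prov
  out
}

#' Rescore expanded models on the full panel
#'
#' Refits each expanded model on the untagged genotype panel, scores it with
#' the BIC-approximate log Bayes factor plus the binomial size prior, and
#' normalises to a [normalise_posterior()] posterior set. By default the
#' prior's `N` is the full panel size (the prior is defined over the
#' region's analysed SNPs, not over the tags).
#'
#' @param models character vector of model keys (e.g. from
#'   [expand_models()]); the null model is added if absent.
#' @param g the full (untagged) preprocessed [geno_matrix()].
#' @param y response vector.
#' @param covariates optional covariate data.frame.
#' @param family `"quantitative"` or `"case-control"`.
#' @param prior a [prior_spec()]; default `prior_spec(ncol(g), 3)`.
#' @param keep_coef store per-model SNP coefficients (needed by
#'   [averaged_effects()]).
#' @return A `posterior_set` over the expanded models plus the null, with
#'   attributes `prior`, `n`, `panel` and (when available) `provenance`.
#' @export
rescore_expanded <- function(models, g, y, covariates = NULL,
                             family = c("quantitative", "case-control"),
                             prior = NULL, keep_coef = TRUE) {
  family <- match.arg(family)
  ctx <- make_score_context(g, y, covariates, family)
  prior <- prior %||% default_prior(length(ctx$ids), 3)
  prov <- attr(models, "provenance")
  keys <- unique(as.character(models))
  if (!"" %in% keys) keys <- c("", keys)
  members <- model_members(keys)
  la <- numeric(length(keys))
  coefs <- if (keep_coef) vector("list", length(keys)) else NULL
  for (i in seq_along(keys)) {
    s <- score_model(ctx, members[[i]])
    la[i] <- if (s$converged)
      (s$loglik - ctx$loglik0) - (length(members[[i]]) / 2) * log(ctx$n)
    else -Inf
    if (keep_coef) coefs[[i]] <- s$coef
  }
  size <- lengths(members)
  df <- data.frame(model = keys, size = size, log_abf = la,
                   log_prior = model_log_prior(size, prior),
                   stringsAsFactors = FALSE)
  if (keep_coef) df$coef <- coefs
  post <- normalise_posterior(df, prior = prior)
  attr(post, "n") <- ctx$n
  attr(post, "family") <- family
  attr(post, "panel") <- ctx$ids
  if (!is.null(prov)) {
    pl <- split(prov$origin, prov$expanded)
    post$provenance <- vapply(post$model, function(m) {
      o <- pl[[m]]
      if (is.null(o)) "" else paste(unique(o), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
    attr(post, "provenance") <- prov
  }
  post
}
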