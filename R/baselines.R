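#' Forward stepwise regression baseline
#'
#' The conventional conditional-regression approach to multi-signal fine
#' mapping: iteratively add the SNP whose addition to the running model has
#' the smallest likelihood-ratio p-value (1 df chi-square), stopping when
#' the best addition p-value reaches `alpha` or after `max_steps` steps.
#' Ties in p-value are broken by smaller position, then id. Per-step p
#' compares the listed model to the model above it; per-step BIC is on the
#' against-the-null scale used throughout the package.
#'
#' @param g a preprocessed [geno_matrix()].
#' @param y response vector.
#' @param covariates optional covariate data.frame.
#' @param family `"quantitative"` or `"case-control"`.
#' @param alpha stopping threshold on the addition p-value.
#' @param max_steps maximum number of SNPs added.
#' @return An object of class `stepwise_result`: data.frame with columns
#'   `step`, `variant`, `p`, `bic`.
#' @export
forward_stepwise <- function(g, y, covariates = NULL,
                             family = c("quantitative", "case-control"),
                             alpha = 1e-6, max_steps = 10L) {
  family <- match.arg(family)
  ctx <- make_score_context(g, y, covariates, family)
  pos <- stats::setNames(g$variants$pos, g$variants$id)
  current <- character()
  ll_cur <- ctx$loglik0
  rows <- list()
  for (step in seq_len(max_steps)) {
    remaining <- setdiff(ctx$ids, current)
    if (length(remaining) == 0L) break
    ll <- vapply(remaining, function(r) {
      s <- score_model(ctx, c(current, r))
      if (s$converged) s$loglik else -Inf
    }, numeric(1))
    p <- stats::pchisq(pmax(2 * (ll - ll_cur), 0), df = 1,
                       lower.tail = FALSE)
    p[!is.finite(ll)] <- 1
    cand <- remaining[p == min(p)]
    best <- cand[order_pos_id(cand, pos[cand])][1L]
    if (p[best] >= alpha) break
    current <- c(current, best)
    ll_cur <- ll[best]
    rows[[step]] <- data.frame(
      step = step, variant = best, p = p[[best]],
      bic = -2 * (ll_cur - ctx$loglik0) + length(current) * log(ctx$n),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(), variant = character(), p = numeric(),
               bic = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("stepwise_result", "data.frame"),
            alpha = alpha, n = ctx$n)
}

#' SNPs selected by a stepwise run at a given threshold
#'
#' Index SNPs are all SNPs added at any stage of the stepwise process whose
#' addition p-value is below `alpha` (p-values need not be monotone over
#' steps, so this is not simply a prefix of the steps).
#'
#' @param res a [forward_stepwise()] result.
#' @param alpha p-value threshold.
#' @return Character vector of selected variant ids.
#' @export
stepwise_selected <- function(res, alpha = attr(res, "alpha")) {
  res$variant[res$p < alpha]
}

#' r^2-based pseudo credible sets around index SNPs
#'
#' For each selected index SNP, the set of variants with r^2 above the
#' threshold with it (plus the index itself). Unlike [snp_picker()] groups,
#' these sets may overlap, so a causal variant can appear in more than one
#' set.
#'
#' @param selected character vector of index SNP ids.
#' @param ld an [ld_matrix()].
#' @param r2_threshold inclusion threshold (default 0.8).
#' @return An object of class `credible_sets`: named list (by index SNP) of
#'   member id vectors.
#' @export
pseudo_credible_sets <- function(selected, ld, r2_threshold = 0.8) {
  stopifnot(inherits(ld, "ld_matrix"))
  bad <- setdiff(selected, ld$ids)
  if (length(bad)) stop("unknown index SNPs: ", paste(bad, collapse = ", "))
  sets <- lapply(selected, function(s) {
    partners <- ld$ids[ld$r2[s, ] > r2_threshold]
    sort(unique(c(s, partners)))
  })
  names(sets) <- selected
  structure(sets, class = "credible_sets", r2_threshold = r2_threshold)
}

#' @export
print.credible_sets <- function(x, ...) {
  cat("credible_sets:", length(x), "sets (r2 >",
      attr(x, "r2_threshold"), ")\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d SNPs\n", nm, length(x[[nm]])))
  invisible(x)
}
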