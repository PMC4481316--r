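#' Binomial model-size prior
#'
#' Prior over multi-SNP models determined only by the number of SNPs a model
#' contains: each individual model of size k has prior mass
#' `q^k (1-q)^(N-k)`, so that the induced prior on the model size is
#' Binomial(N, q). `q` is set so that the expected number of causal variants
#' equals `n_exp` (default 3), i.e. `q = n_exp / N`.
#'
#' @param N number of variants in the analysed panel.
#' @param n_exp a priori expected number of causal variants in the region.
#' @return An object of class `prior_spec`: list with `N`, `n_exp`, `q`.
#' @export
prior_spec <- function(N, n_exp = 3) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1,
            is.numeric(n_exp), length(n_exp) == 1L, n_exp > 0)
  if (n_exp >= N) stop("n_exp must be smaller than the panel size N")
  structure(list(N = as.integer(N), n_exp = n_exp, q = n_exp / N),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("prior_spec: Binomial(N = %d, q = %.5g) size prior (E = %g)\n",
              x$N, x$q, x$n_exp))
  invisible(x)
}

#' Log prior mass of one model
#'
#' Natural-log prior of a single model of `size` SNPs under a [prior_spec()]:
#' `size * log(q) + (N - size) * log(1 - q)`. Summed over the
#' `choose(N, size)` distinct models of a size this reproduces the binomial
#' size prior.
#'
#' @param size model size (number of SNPs; 0 for the null model).
#' @param prior a [prior_spec()].
#' @return Log prior mass (vectorised over `size`).
#' @export
model_log_prior <- function(size, prior) {
  stopifnot(inherits(prior, "prior_spec"))
  if (any(size < 0 | size > prior$N))
    stop("model size must lie in [0, N]")
  size * log(prior$q) + (prior$N - size) * log1p(-prior$q)
}

## ---------------------------------------------------------------------------
## Model scoring context: precomputes whatever makes repeated per-model fits
## cheap. For the quantitative family, phenotype and dosages are residualised
## on the covariate design (Frisch-Waugh), so a model fit is a k x k solve on
## precomputed cross-products; SNP coefficients and the log-likelihood equal
## those of the full joint least-squares fit. For case-control, each model is
## a fresh IRLS logistic fit.
## ---------------------------------------------------------------------------
make_score_context <- function(g, y, covariates = NULL,
                               family = c("quantitative", "case-control")) {
  family <- match.arg(family)
  stopifnot(inherits(g, "geno_matrix"))
  X <- g$dosages
  n <- nrow(X)
  if (length(y) != n)
    stop("phenotype length (", length(y), ") != sample count (", n, ")")
  if (anyNA(y)) stop("phenotype contains missing values")
  if (anyNA(X)) stop("genotypes contain missing values; run preprocess_genotypes")
  W <- if (is.null(covariates)) {
    matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    cv <- as.data.frame(covariates)
    if (nrow(cv) != n) stop("covariate rows != sample count")
    stats::model.matrix(~ ., data = cv)
  }
  ctx <- list(family = family, ids = colnames(X), n = n, W = W)
  if (family == "quantitative") {
    qrW <- qr(W)
    yr <- qr.resid(qrW, y)
    Xr <- qr.resid(qrW, X)
    ctx$G <- crossprod(Xr)
    ctx$h <- drop(crossprod(Xr, yr))
    ctx$rss0 <- sum(yr^2)
    ctx$k0 <- ncol(W) + 1L               # + residual variance
    ctx$loglik0 <- gauss_loglik(ctx$rss0, n)
  } else {
    if (!all(y %in% c(0, 1)))
      stop("case-control phenotype must be coded 0/1")
    ctx$X <- X
    ctx$y <- y
    f0 <- logistic_fit(W, y)
    ctx$k0 <- ncol(W)
    ctx$loglik0 <- f0$loglik
  }
  ctx
}

gauss_loglik <- function(rss, n) {
  if (rss <= 0) return(Inf)
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

## IRLS via glm.fit with iteration cap; |beta| > beta_cap flags
## (quasi-)complete separation and the fit is treated as non-estimable.
logistic_fit <- function(Z, y, beta_cap = 30) {
  fit <- suppressWarnings(
    stats::glm.fit(Z, y, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100L)))
  cf <- fit$coefficients
  converged <- isTRUE(fit$converged) && !anyNA(cf) &&
    all(abs(cf) <= beta_cap)
  list(loglik = -fit$deviance / 2, coef = cf, converged = converged)
}

## Fit one model inside a context. Returns loglik, k, per-SNP coefficients
## (on the linear predictor scale) and a convergence flag.
score_model <- function(ctx, ids) {
  k <- length(ids)
  if (k == 0L)
    return(list(loglik = ctx$loglik0, k = ctx$k0,
                coef = stats::setNames(numeric(0), character(0)),
                converged = TRUE))
  if (ctx$family == "quantitative") {
    idx <- match(ids, ctx$ids)
    b <- tryCatch(solve(ctx$G[idx, idx, drop = FALSE], ctx$h[idx]),
                  error = function(e) NULL)
    if (is.null(b) || anyNA(b))
      return(list(loglik = -Inf, k = ctx$k0 + k,
                  coef = stats::setNames(rep(NA_real_, k), ids),
                  converged = FALSE))
    rss <- ctx$rss0 - sum(b * ctx$h[idx])
    if (rss <= 1e-10 * ctx$rss0)          # numerically perfect fit
      return(list(loglik = -Inf, k = ctx$k0 + k,
                  coef = stats::setNames(b, ids), converged = FALSE))
    list(loglik = gauss_loglik(rss, ctx$n), k = ctx$k0 + k,
         coef = stats::setNames(drop(b), ids), converged = TRUE)
  } else {
    Z <- cbind(ctx$W, ctx$X[, ids, drop = FALSE])
    f <- logistic_fit(Z, ctx$y)
    snp_coef <- f$coef[seq.int(ncol(ctx$W) + 1L, ncol(Z))]
    names(snp_coef) <- ids
    if (!f$converged)
      return(list(loglik = -Inf, k = ctx$k0 + k, coef = snp_coef,
                  converged = FALSE))
    list(loglik = f$loglik, k = ctx$k0 + k, coef = snp_coef,
         converged = TRUE)
  }
}

#' Maximum-likelihood fit of one multi-SNP model
#'
#' Fits the additive model `phenotype ~ covariates + dosages of the model's
#' SNPs`: ordinary least squares for the quantitative family (the Gaussian
#' log-likelihood is evaluated at the MLE of the residual variance), IRLS
#' logistic regression for the case-control family. Categorical covariates
#' are reference-coded. Non-convergence or (quasi-)complete separation
#' (any |coefficient| > 30 on the linear predictor scale) is flagged via
#' `converged = FALSE`; such models are excluded from posteriors by
#' receiving a log Bayes factor of `-Inf`.
#'
#' @param model character vector of variant ids (empty for the null model).
#' @param g a preprocessed [geno_matrix()].
#' @param phenotype numeric response (0/1 for case-control).
#' @param covariates optional data.frame of per-sample covariates, included
#'   in every model including the null.
#' @param family `"quantitative"` or `"case-control"`.
#' @return An object of class `regression_fit`: list with `loglik`, `k`
#'   (fitted parameter count, including intercept/covariates and, for the
#'   quantitative family, the residual variance), `coef` (per-SNP effects),
#'   `converged` and `n`.
#' @export
fit_glm <- function(model, g, phenotype, covariates = NULL,
                    family = c("quantitative", "case-control")) {
  family <- match.arg(family)
  model <- unique(as.character(model))
  bad <- setdiff(model, g$variants$id)
  if (length(bad)) stop("model contains unknown variants: ",
                        paste(bad, collapse = ", "))
  ctx <- make_score_context(g, phenotype, covariates, family)
  s <- score_model(ctx, model)
  structure(list(loglik = s$loglik, k = s$k, coef = s$coef,
                 converged = s$converged, n = ctx$n, family = family),
            class = "regression_fit")
}

#' BIC-approximate log Bayes factor against the null model
#'
#' Uses the BIC approximation `BIC_m = -2 (log L_m - log L_0) +
#' (k_m - k_0) log n` together with `BIC_m = -2 log BF_m`, i.e.
#' `log BF_m = (log L_m - log L_0) - ((k_m - k_0) / 2) log n` in natural
#' logs. Intercept, covariate and residual-variance parameters cancel in
#' `k_m - k_0`, which therefore equals the model size.
#'
#' @param fit_m [fit_glm()] result for the model.
#' @param fit_0 [fit_glm()] result for the null model on the same samples.
#' @param n sample count (defaults to the count recorded in the fits).
#' @return Natural-log approximate Bayes factor (`-Inf` for non-converged
#'   fits).
#' @export
log_abf <- function(fit_m, fit_0, n = NULL) {
  if (!is.null(fit_m$n) && !is.null(fit_0$n) && fit_m$n != fit_0$n)
    stop("fits use different sample counts")
  n <- n %||% fit_m$n
  if (is.null(n)) stop("sample count n is required")
  if (!isTRUE(fit_m$converged)) return(-Inf)
  (fit_m$loglik - fit_0$loglik) - ((fit_m$k - fit_0$k) / 2) * log(n)
}

#' Normalise scored models into a posterior set
#'
#' Computes `pp_m` proportional to `BF_m * pi_m` over the supplied model
#' collection in log space. The null model (empty key, `log_abf = 0`) is a
#' member of the collection and is added if absent.
#'
#' @param scored data.frame with columns `model` (comma-joined sorted
#'   variant ids, `""` for null), `size`, `log_abf`, `log_prior`; further
#'   columns (e.g. `coef`) are carried through.
#' @param prior optional [prior_spec()] used to fill the null model's prior
#'   if it has to be added (defaults to the `prior` attribute of `scored`).
#' @return The input with a `pp` column summing to 1, class `posterior_set`.
#' @export
normalise_posterior <- function(scored, prior = NULL) {
  if (is.null(scored) || nrow(scored) == 0L) stop("empty model collection")
  if (anyDuplicated(scored$model))
    stop("duplicated models in collection")
  prior <- prior %||% attr(scored, "prior")
  if (!"" %in% scored$model) {
    if (is.null(prior))
      stop("collection lacks the null model and no prior was supplied")
    null_row <- scored[0, , drop = FALSE]
    null_row[1L, c("model", "size", "log_abf", "log_prior")] <-
      list("", 0L, 0, model_log_prior(0L, prior))
    if ("coef" %in% names(scored))
      null_row$coef <- list(stats::setNames(numeric(0), character(0)))
    scored <- rbind(scored, null_row)
  }
  lw <- scored$log_abf + scored$log_prior
  scored$pp <- exp(lw - logsumexp(lw))
  rownames(scored) <- NULL
  class(scored) <- c("posterior_set", "data.frame")
  if (!is.null(prior)) attr(scored, "prior") <- prior
  scored
}

#' @export
print.posterior_set <- function(x, n = 6L, ...) {
  cat("posterior_set:", nrow(x), "models\n")
  ord <- order(-x$pp)
  top <- utils::head(x[ord, c("model", "size", "log_abf", "pp")], n)
  top$model[top$model == ""] <- "(null)"
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a scored-model table as TSV
#'
#' Columns: model (comma-joined ids, `(null)` for the empty model), size,
#' log_abf, log_prior, pp, plus provenance when present.
#'
#' @param post a `posterior_set` or visited-set data.frame.
#' @param path output path.
#' @param header_comment optional `#`-prefixed first line (e.g. config hash).
#' @return `path`, invisibly.
#' @export
write_models <- function(post, path, header_comment = NULL) {
  keep <- intersect(c("model", "size", "log_abf", "log_prior", "pp",
                      "provenance"), names(post))
  out <- as.data.frame(post)[, keep, drop = FALSE]
  out$model[out$model == ""] <- "(null)"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
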