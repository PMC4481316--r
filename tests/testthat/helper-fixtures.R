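## Shared fixture builders. Everything is generated in code; no data files.

## geno_matrix straight from a dosage matrix (ids v1, v2, ...; positions 1kb)
toy_geno <- function(dosages, ids = NULL) {
  dosages <- as.matrix(dosages)
  ids <- ids %||% paste0("v", seq_len(ncol(dosages)))
  geno_matrix(dosages,
              data.frame(id = ids, chrom = "1",
                         pos = seq_len(ncol(dosages)) * 1000L,
                         ref = "A", alt = "G", stringsAsFactors = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## panel of independent-ish binomial variants plus optional duplicated
## columns (exact copies -> r2 = 1 pairs for tagging/expansion tests)
random_panel <- function(n = 200, v = 5, duplicate = integer(0), seed = 1,
                         maf = 0.3) {
  set.seed(seed)
  X <- matrix(rbinom(n * v, 2, maf), n, v)
  for (d in duplicate) X <- cbind(X, X[, d])
  toy_geno(X)
}

## hand-set posterior over model keys (pp given; scores backfilled so that
## normalise_posterior would reproduce pp under a flat prior)
toy_posterior <- function(models, pp, coef = NULL, panel = NULL,
                          prior = NULL) {
  stopifnot(length(models) == length(pp), abs(sum(pp) - 1) < 1e-9)
  size <- lengths(shotgunfm:::model_members(models))
  df <- data.frame(model = models, size = size,
                   log_abf = log(pp) - min(log(pp[pp > 0])),
                   log_prior = 0, pp = pp, stringsAsFactors = FALSE)
  if (!is.null(coef)) df$coef <- coef
  structure(df, class = c("posterior_set", "data.frame"),
            panel = panel, prior = prior)
}

## ld_matrix from an explicit r2 matrix
toy_ld <- function(r2, ids = NULL) {
  ids <- ids %||% paste0("v", seq_len(ncol(r2)))
  dimnames(r2) <- list(ids, ids)
  structure(list(ids = ids, r2 = r2, dprime = NULL), class = "ld_matrix")
}

## quick variants table for snp_picker position tie-breaks
toy_variants <- function(ids) {
  data.frame(id = ids, chrom = "1", pos = seq_along(ids) * 1000L,
             ref = "A", alt = "G", maf = 0.3, stringsAsFactors = FALSE)
}

## small plain-text VCF written on the fly
write_toy_vcf <- function(path, gts = c("0/0", "0/1", "1/1"),
                          ids = c("rs1", "rs2"),
                          alt = rep("G", length(ids))) {
  samples <- paste0("s", seq_along(gts))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(ids)) {
    lines <- c(lines, paste(c("1", as.character(i * 100), ids[i], "A",
                              alt[i], ".", "PASS", ".", "GT", gts),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

## copy of a dosage column with exactly one entry nudged by one unit:
## r2 with the original stays just below 1 but above any tagging threshold
nudge1 <- function(x, i = 1L) {
  x[i] <- if (x[i] == 0) 1 else x[i] - 1
  x
}

## panel whose first variant appears in a tagset of 3 and second in a
## tagset of 2, plus two independent variants (v6, v7)
expansion_panel <- function(n = 1000, seed = 31) {
  set.seed(seed)
  a <- rbinom(n, 2, 0.4); b <- rbinom(n, 2, 0.3)
  X <- cbind(a, nudge1(a, 1L), nudge1(a, 2L), b, nudge1(b, 3L),
             rbinom(n, 2, 0.35), rbinom(n, 2, 0.45))
  toy_geno(X)
}

## independent longhand Pearson r^2 (the brute-force LD oracle)
pearson_r2_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  (num / den)^2
}

## independent OLS oracle: normal equations + Gaussian loglik from RSS
ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  rss <- sum((y - X1 %*% beta)^2)
  n <- length(y)
  list(beta = drop(beta), rss = rss,
       loglik = -(n / 2) * (log(2 * pi * rss / n) + 1))
}
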