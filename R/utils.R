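`%||%` <- function(a, b) if (is.null(a)) b else a

## numerically stable log(sum(exp(x))); -Inf entries contribute zero mass
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

## canonical model key: sorted variant ids joined by ","; "" is the null model
model_key <- function(ids) {
  if (length(ids) == 0L) return("")
  paste(sort(ids), collapse = ",")
}

model_ids <- function(key) {
  if (!nzchar(key)) return(character())
  strsplit(key, ",", fixed = TRUE)[[1L]]
}

## split a vector of model keys into member lists ("" -> character(0))
model_members <- function(keys) {
  out <- strsplit(keys, ",", fixed = TRUE)
  out[!nzchar(keys)] <- list(character())
  out
}

## short stable fingerprint of a character scalar (for config provenance)
config_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  b <- utf8ToInt(x)
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## order by (position, id) — the package-wide tie break for variants
order_pos_id <- function(ids, pos) {
  order(pos, ids, method = "radix")
}

## default size prior: expectation n_exp, capped at N/2 so the binomial
## stays proper on very small panels
default_prior <- function(N, n_exp = 3) {
  prior_spec(N, min(n_exp, N / 2))
}
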