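#' Specification for the LD-structured simulator
#'
#' Describes one simulated fine-mapping dataset: a mosaic-of-founders
#' genotype panel emulating a low-recombination region (blocks of high r^2
#' with decay along the region and |D'| near 1), plus an additive Gaussian
#' phenotype in which randomly chosen causal variants jointly explain a
#' fixed fraction of the phenotypic variance. Defaults follow the study
#' conditions used throughout the package's benchmarks: 2,000 samples,
#' between two and five causal variants drawn among SNPs with MAF > 0.01,
#' jointly explaining 10% of phenotypic variance.
#'
#' @param n_samples number of diploid samples.
#' @param n_variants number of variants in the panel.
#' @param n_founders number of founder haplotypes the sample mosaics copy
#'   from; fewer founders mean tighter LD.
#' @param founder_flip_rate per-adjacent-variant probability that a founder
#'   haplotype's allele run is re-drawn (controls LD-block length on the
#'   founders).
#' @param mosaic_switch_rate per-adjacent-variant probability that a sample
#'   haplotype switches to a random founder (the recombination analogue;
#'   0 gives |D'| = 1 everywhere).
#' @param maf_min causal-eligibility MAF filter (default 0.01).
#' @param n_causal number of causal variants, or a vector to draw from
#'   uniformly per dataset (default `2:5`).
#' @param var_explained target fraction of phenotypic variance jointly
#'   explained by the causal variants (default 0.10).
#' @param effect_dist `"equal"` (equal per-allele raw effects) or
#'   `"normal"` (standard normal raw effects before scaling).
#' @param exact_fraction if `TRUE`, the noise is orthogonalised against the
#'   genetic score and rescaled so the realised variance fraction equals
#'   `var_explained` exactly; by default only the genetic score is scaled
#'   and the noise draw keeps its sampling variability.
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 2000L, n_variants = 200L, n_founders = 8L,
                     founder_flip_rate = 0.1, mosaic_switch_rate = 0.005,
                     maf_min = 0.01, n_causal = 2:5, var_explained = 0.10,
                     effect_dist = c("equal", "normal"),
                     exact_fraction = FALSE, seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  stopifnot(n_samples >= 1, n_variants >= 1, n_founders >= 2,
            founder_flip_rate >= 0, founder_flip_rate <= 1,
            mosaic_switch_rate >= 0, mosaic_switch_rate <= 1,
            maf_min >= 0, all(n_causal >= 1),
            var_explained >= 0, var_explained < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 n_founders = as.integer(n_founders),
                 founder_flip_rate = founder_flip_rate,
                 mosaic_switch_rate = mosaic_switch_rate,
                 maf_min = maf_min, n_causal = as.integer(n_causal),
                 var_explained = var_explained, effect_dist = effect_dist,
                 exact_fraction = exact_fraction, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate LD-structured genotypes
#'
#' Draws `n_founders` binary founder haplotypes whose alleles run in blocks
#' (each founder's allele is re-drawn between adjacent variants with
#' probability `founder_flip_rate`), then builds each sample haplotype as a
#' mosaic over the founders, switching founder between adjacent variants
#' with probability `mosaic_switch_rate`. Dosages are sums of two such
#' haplotypes. With a switch rate of 0 every pair of variants is in
#' complete disequilibrium (|D'| = 1), mimicking a region without
#' historical recombination; increasing the switch rate decays r^2.
#'
#' @param spec a [sim_spec()].
#' @return A [geno_matrix()] with variants `v001..`, positions spaced 1 kb.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  simulate_genotypes_impl(spec)
}

simulate_genotypes_impl <- function(spec) {
  V <- spec$n_variants
  K <- spec$n_founders
  H <- 2L * spec$n_samples
  if (V < 1L || spec$n_samples < 1L) stop("degenerate simulation spec")
  ## founder alleles: per-founder Markov chain of allele runs
  f <- matrix(0L, K, V)
  f[, 1L] <- stats::rbinom(K, 1L, 0.5)
  if (V > 1L) {
    flip <- matrix(stats::runif(K * (V - 1L)) < spec$founder_flip_rate, K)
    redraw <- matrix(stats::rbinom(K * (V - 1L), 1L, 0.5), K)
    for (j in 2:V)
      f[, j] <- ifelse(flip[, j - 1L], redraw[, j - 1L], f[, j - 1L])
  }
  ## mosaic founder ids per sample haplotype
  ids <- matrix(0L, H, V)
  ids[, 1L] <- sample.int(K, H, replace = TRUE)
  if (V > 1L) {
    sw <- matrix(stats::runif(H * (V - 1L)) < spec$mosaic_switch_rate, H)
    nf <- matrix(sample.int(K, H * (V - 1L), replace = TRUE), H)
    for (j in 2:V)
      ids[, j] <- ifelse(sw[, j - 1L], nf[, j - 1L], ids[, j - 1L])
  }
  hap <- matrix(f[cbind(c(ids), rep(seq_len(V), each = H))], H, V)
  dos <- hap[seq(1L, H, by = 2L), , drop = FALSE] +
         hap[seq(2L, H, by = 2L), , drop = FALSE]
  rownames(dos) <- sprintf("s%04d", seq_len(spec$n_samples))
  variants <- data.frame(
    id = sprintf("v%03d", seq_len(V)),
    chrom = "1",
    pos = seq_len(V) * 1000L,
    ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  geno_matrix(dos, variants)
}

#' Simulate an additive Gaussian phenotype
#'
#' Chooses `n_causal` variants uniformly among those with MAF >
#' `maf_min`, forms an additive genetic score from their dosages (equal
#' per-allele raw effects by default), rescales the score so the causal
#' variants jointly explain `var_explained` of the phenotypic variance, and
#' adds Gaussian noise. With the default realised-sample scaling the score
#' variance is exact and the realised fraction varies only with the noise
#' draw; with `exact_fraction = TRUE` the fraction is exact by
#' construction.
#'
#' @param g a [geno_matrix()] (typically from [simulate_genotypes()]).
#' @param spec the [sim_spec()].
#' @return An object of class `sim_dataset`: list with `genotypes`,
#'   `phenotype`, `causal` (data.frame of id, beta), `var_explained`
#'   (target) and `realised_r2` (realised variance fraction of the genetic
#'   score).
#' @export
simulate_phenotype <- function(g, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  ## offset so the phenotype stream is decoupled from the genotype stream
  set.seed((spec$seed + 499979L) %% .Machine$integer.max)
  simulate_phenotype_impl(g, spec)
}

simulate_phenotype_impl <- function(g, spec) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- nrow(g$dosages)
  maf <- compute_maf(g$dosages)
  eligible <- g$variants$id[maf > spec$maf_min &
                              apply(g$dosages, 2L, stats::var) > 0]
  nc <- if (length(spec$n_causal) > 1L) {
    spec$n_causal[sample.int(length(spec$n_causal), 1L)]
  } else spec$n_causal
  if (length(eligible) < nc)
    stop("only ", length(eligible), " variants pass the MAF filter; ",
         nc, " causal variants requested")
  causal <- sort(eligible[sample.int(length(eligible), nc)])
  raw <- switch(spec$effect_dist,
                equal = rep(1, nc),
                normal = stats::rnorm(nc))
  Xc <- g$dosages[, causal, drop = FALSE]
  s <- drop(Xc %*% raw)
  v <- spec$var_explained
  if (v == 0 || stats::var(s) == 0) {
    beta <- rep(0, nc)
    s <- rep(0, n)
  } else {
    scale <- sqrt(v / stats::var(s))
    beta <- raw * scale
    s <- s * scale
  }
  e <- stats::rnorm(n, sd = sqrt(1 - v))
  if (spec$exact_fraction && v > 0) {
    e <- e - s * (stats::cov(e, s) / stats::var(s))   # orthogonalise
    e <- e * sqrt((1 - v) / stats::var(e))
  }
  y <- s + e
  realised <- if (v == 0) 0 else stats::var(s) / stats::var(y)
  structure(list(genotypes = g,
                 phenotype = y,
                 causal = data.frame(id = causal, beta = beta,
                                     stringsAsFactors = FALSE),
                 var_explained = v,
                 realised_r2 = realised),
            class = "sim_dataset")
}

#' Simulate genotypes and phenotype in one call
#'
#' @param spec a [sim_spec()].
#' @return A `sim_dataset` (see [simulate_phenotype()]).
#' @export
simulate_dataset <- function(spec) {
  g <- simulate_genotypes(spec)
  simulate_phenotype(g, spec)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$genotypes$dosages), "samples x",
      ncol(x$genotypes$dosages), "variants;",
      nrow(x$causal), "causal variants,",
      sprintf("realised variance fraction %.3f", x$realised_r2), "\n")
  invisible(x)
}

## normalise the various group containers to a plain list of member vectors
as_group_list <- function(groups) {
  if (inherits(groups, "group_set"))
    return(lapply(groups$groups, `[[`, "members"))
  if (inherits(groups, "credible_sets")) return(unclass(groups))
  if (is.list(groups)) return(groups)
  stop("cannot interpret groups of class ", paste(class(groups), collapse = "/"))
}

#' Discovery rate and FDR of selected SNP groups
#'
#' Discovery rate: the proportion of true causal variants appearing in at
#' least one selected group. FDR: the proportion of selected groups
#' containing no causal variant (0 when no group is selected, keeping
#' benchmark curves well defined).
#'
#' @param selected_groups a [snp_picker()] `group_set`, a
#'   [pseudo_credible_sets()] result, or a plain list of id vectors.
#' @param truth character vector of true causal variant ids (non-empty).
#' @return List with `discovery`, `fdr` and `hits` (logical per causal
#'   variant).
#' @export
evaluate_discovery <- function(selected_groups, truth) {
  if (length(truth) == 0L) stop("truth must name at least one causal variant")
  truth <- as.character(truth)
  gl <- as_group_list(selected_groups)
  hits <- stats::setNames(
    vapply(truth, function(v) any(vapply(gl, function(g) v %in% g,
                                         logical(1))), logical(1)),
    truth)
  fdr <- if (length(gl) == 0L) 0 else
    mean(vapply(gl, function(g) !any(truth %in% g), logical(1)))
  list(discovery = mean(hits), fdr = fdr, hits = hits)
}

#' Benchmark stochastic-search fine mapping against stepwise selection
#'
#' Replicates the simulation benchmark: for each replicate a dataset is
#' simulated, the full tag / search / expand / rescore / group pipeline is
#' run at each prior expectation in `n_exp`, groups are selected at each
#' gMPPI threshold, a forward stepwise run selects index SNPs at each
#' p-value threshold with r^2 > 0.8 pseudo credible sets, and discovery
#' rate and FDR are averaged across replicates. External selectors can be
#' benchmarked by supplying `external`, a function(sim_dataset) returning a
#' list of groups (id vectors).
#'
#' @param spec a [sim_spec()] template; replicate `i` uses `seed + i`.
#' @param n_reps number of replicates.
#' @param seed master seed.
#' @param gmppi_thresholds gMPPI selection thresholds (default 0.5, 0.9).
#' @param alpha_grid stepwise p-value thresholds (default 1e-6, 1e-8).
#' @param n_exp prior expectations to run (default 3 and 5).
#' @param n_iter,n_chains stochastic-search effort per replicate.
#' @param external optional named list of selector functions.
#' @return data.frame with one row per method x threshold: `method`,
#'   `threshold`, `discovery`, `fdr`, `n_reps`, `seed`.
#' @export
benchmark_methods <- function(spec, n_reps = 50L, seed = 1L,
                              gmppi_thresholds = c(0.5, 0.9),
                              alpha_grid = c(1e-6, 1e-8),
                              n_exp = c(3, 5),
                              n_iter = 3000L, n_chains = 3L,
                              external = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  acc <- list()
  add_row <- function(method, threshold, ev) {
    key <- paste(method, threshold, sep = "@")
    acc[[key]] <<- rbind(acc[[key]],
                         data.frame(method = method, threshold = threshold,
                                    discovery = ev$discovery, fdr = ev$fdr,
                                    stringsAsFactors = FALSE))
  }
  for (i in seq_len(n_reps)) {
    sp <- spec
    sp$seed <- as.integer(seed + i)
    ds <- simulate_dataset(sp)
    gp <- preprocess_genotypes(ds$genotypes, maf_min = 0.005)
    truth <- intersect(ds$causal$id, gp$variants$id)
    if (length(truth) == 0L) truth <- ds$causal$id
    ldm <- ld_matrix(gp)
    for (ne in n_exp) {
      fm <- finemap_region(gp, ds$phenotype, family = "quantitative",
                           n_exp = ne, seed = sp$seed,
                           n_iter = n_iter, n_chains = n_chains,
                           ld = ldm)
      for (t in gmppi_thresholds) {
        sel <- Filter(function(grp) grp$gmppi > t, fm$groups$groups)
        add_row(paste0("shotgun-", ne), t,
                evaluate_discovery(lapply(sel, `[[`, "members"), truth))
      }
    }
    sw <- forward_stepwise(gp, ds$phenotype, family = "quantitative",
                           alpha = max(alpha_grid), max_steps = 10L)
    for (a in alpha_grid) {
      sel <- stepwise_selected(sw, a)
      cs <- if (length(sel)) pseudo_credible_sets(sel, ldm) else list()
      add_row("stepwise", a, evaluate_discovery(cs, truth))
    }
    for (nm in names(external)) {
      add_row(nm, NA_real_, evaluate_discovery(external[[nm]](ds), truth))
    }
  }
  out <- do.call(rbind, lapply(acc, function(d)
    data.frame(method = d$method[1L], threshold = d$threshold[1L],
               discovery = mean(d$discovery), fdr = mean(d$fdr),
               n_reps = nrow(d), seed = seed, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$method, out$threshold), ]
}
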