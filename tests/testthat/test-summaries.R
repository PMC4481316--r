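test_that("MPPI and joint MPPI match longhand sums", {
  post <- toy_posterior(c("", "a", "a,b", "b,c"),
                        c(0.1, 0.3, 0.4, 0.2),
                        panel = c("a", "b", "c", "d"))
  m <- mppi(post)
  expect_equal(unname(m["a"]), 0.7)
  expect_equal(unname(m["b"]), 0.6)
  expect_equal(unname(m["c"]), 0.2)
  expect_equal(unname(m["d"]), 0)
  ## sum MPPI = posterior expected model size (exchange of sums)
  expect_equal(sum(m), sum(post$size * post$pp), tolerance = 1e-12)

  expect_equal(joint_mppi(post, "a", "b"), 0.4)
  expect_equal(joint_mppi(post, "a", "a"), unname(m["a"]))
  expect_equal(joint_mppi(post, "a", "c"), 0)   # disjoint supports

  ## mass 1 on one model
  p1 <- toy_posterior(c("", "a,b"), c(0, 1), panel = c("a", "b", "c"))
  expect_equal(unname(mppi(p1)), c(1, 1, 0))
})

test_that("gMPPI counts each model once", {
  post <- toy_posterior(c("", "a", "b", "a,b"),
                        c(0.1, 0.3, 0.3, 0.3))
  ## single-member group: gmppi = MPPI
  expect_equal(gmppi("a", post), 0.6)
  ## both members: models a, b, ab counted once each = 0.9, less than the
  ## MPPI sum 1.2 because a,b co-occur
  expect_equal(gmppi(c("a", "b"), post), 0.9)
  m <- mppi(post, panel = c("a", "b"))
  expect_lt(gmppi(c("a", "b"), post), sum(m))
  expect_gte(gmppi(c("a", "b"), post), max(m))

  ## never co-occurring members: gmppi = MPPI sum
  p2 <- toy_posterior(c("", "a", "b"), c(0.2, 0.5, 0.3))
  expect_equal(gmppi(c("a", "b"), p2), 0.8)
})

test_that("snp_picker stops at the r2 floor, giving singleton groups", {
  r2 <- diag(4) * 0.6 + 0.4 * diag(4)   # identity-ish; off-diag below
  r2 <- matrix(0.2, 4, 4); diag(r2) <- 1
  ld <- toy_ld(r2)
  post <- toy_posterior(c("", "v1", "v2"), c(0.2, 0.5, 0.3),
                        panel = ld$ids)
  gs <- snp_picker(post, ld, variants = toy_variants(ld$ids))
  expect_equal(lengths(lapply(gs$groups, `[[`, "members")),
               c(A = 1L, B = 1L))
  expect_equal(gs$groups$A$index_snp, "v1")   # max MPPI seeds first
})

test_that("snp_picker re-aggregates diluted twins and respects joint cap", {
  ## two near-duplicates with mass split across their single-SNP models
  r2 <- matrix(c(1, 0.999, 0.1,
                 0.999, 1, 0.1,
                 0.1, 0.1, 1), 3, 3, byrow = TRUE)
  ld <- toy_ld(r2)
  post <- toy_posterior(c("", "v1", "v2"), c(0.1, 0.5, 0.4),
                        panel = ld$ids)
  gs <- snp_picker(post, ld, variants = toy_variants(ld$ids))
  expect_equal(length(gs$groups), 1L)
  expect_setequal(gs$groups$A$members, c("v1", "v2"))
  expect_equal(gs$groups$A$gmppi, 0.9, tolerance = 1e-12)

  ## a candidate co-occurring with the seed (joint MPPI > 0.02) is excluded
  ## even in high LD: co-occurrence marks a distinct signal
  post2 <- toy_posterior(c("", "v1", "v1,v2"), c(0.1, 0.45, 0.45),
                         panel = ld$ids)
  gs2 <- snp_picker(post2, ld, variants = toy_variants(ld$ids))
  expect_false("v2" %in% gs2$groups[[1]]$members)
})

test_that("snp_picker applies the two-in-a-row MPPI stop with reset", {
  ## ordering by r2 with seed v1: v2 (pass), v3, v4 (both sub-floor), v5
  ## -> walk stops at v4; v5 not reached even though it passes
  r2 <- matrix(0, 5, 5); diag(r2) <- 1
  r2[1, 2:5] <- r2[2:5, 1] <- c(0.95, 0.9, 0.85, 0.8)
  ld <- toy_ld(r2)
  post <- toy_posterior(c("", "v1", "v2", "v5"),
                        c(0.05, 0.6, 0.2, 0.15), panel = ld$ids)
  gs <- snp_picker(post, ld, variants = toy_variants(ld$ids))
  expect_setequal(gs$groups[[1]]$members, c("v1", "v2"))
  ## v5 still seeds its own group afterwards (MPPI 0.15 > 0.01)
  expect_equal(gs$groups[[2]]$members, "v5")

  ## a single sub-floor SNP between passers does NOT stop the walk (reset),
  ## and sub-floor SNPs are never added
  post2 <- toy_posterior(c("", "v1", "v2", "v3", "v4"),
                         c(0.04, 0.5, 0.2, 0.0005, 0.2595),
                         panel = ld$ids)
  ## make v4 pass the r2 floor too
  gs2 <- snp_picker(post2, ld, variants = toy_variants(ld$ids))
  expect_setequal(gs2$groups[[1]]$members, c("v1", "v2", "v4"))
  expect_false("v3" %in% unlist(lapply(gs2$groups, `[[`, "members")))
})

test_that("snp_picker groups are disjoint and deterministic", {
  set.seed(40)
  spec <- sim_spec(n_samples = 500, n_variants = 20, n_causal = 2,
                   seed = 40)
  ds <- simulate_dataset(spec)
  g <- preprocess_genotypes(ds$genotypes, 0.005)
  fm <- finemap_region(g, ds$phenotype, seed = 4, n_iter = 500)
  gs1 <- snp_picker(fm$posterior, fm$ld, variants = g$variants)
  gs2 <- snp_picker(fm$posterior, fm$ld, variants = g$variants)
  expect_identical(gs1, gs2)
  members <- unlist(lapply(gs1$groups, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  expect_setequal(c(members, gs1$leftover), g$variants$id)
  for (grp in gs1$groups) {
    expect_gte(grp$gmppi, max(grp$mppi) - 1e-12)
    expect_lte(grp$gmppi, min(1, sum(mppi(fm$posterior)[grp$members])) + 1e-12)
  }
})

test_that("model-averaged effects are the pp-weighted coefficient sums", {
  post <- toy_posterior(
    c("", "a", "a,b"), c(0.2, 0.5, 0.3),
    coef = list(setNames(numeric(0), character(0)),
                c(a = 1.0), c(a = 0.8, b = -0.4)),
    panel = c("a", "b", "c"))
  eff <- averaged_effects(post)
  expect_equal(unname(eff["a"]), 0.5 * 1.0 + 0.3 * 0.8)
  expect_equal(unname(eff["b"]), 0.3 * -0.4)
  expect_equal(unname(eff["c"]), 0)   # SNP in no model
  ## mass 1 on one model -> that model's coefficient
  p1 <- toy_posterior(c("", "a"), c(0, 1),
                      coef = list(setNames(numeric(0), character(0)),
                                  c(a = 2.5)), panel = "a")
  expect_equal(unname(averaged_effects(p1)["a"]), 2.5)
  expect_error(averaged_effects(toy_posterior(c("", "a"), c(0.5, 0.5))),
               "coefficients")
})

test_that("model-size posterior aggregates and detects point mass", {
  post <- toy_posterior(c("", "a", "b", "a,b"), c(0.1, 0.2, 0.3, 0.4))
  ns <- nsnp_posterior(post)
  expect_equal(ns$posterior, c(0.1, 0.5, 0.4))
  expect_equal(sum(ns$posterior), 1, tolerance = 1e-12)
  p1 <- toy_posterior(c("", "a,b"), c(0, 1))
  expect_equal(nsnp_posterior(p1)$posterior, c(0, 0, 1))
})

test_that("prior reweighting is identity at the original n_exp and crosses
           families where the closed form says", {
  pr <- prior_spec(50, 3)
  df <- data.frame(model = c("", "a", "a,b"), size = c(0L, 1L, 2L),
                   log_abf = c(0, 4, 4.6), log_prior = model_log_prior(
                     c(0L, 1L, 2L), pr), stringsAsFactors = FALSE)
  post <- normalise_posterior(df, prior = pr)
  rw <- reweight_prior(post, c(1, 2, 3, 4, 5),
                       families = list(two = "a,b", one = "a"))
  ## identity at n_exp = 3
  same <- rw$posteriors[["3"]]
  expect_equal(same$pp, post$pp, tolerance = 1e-12)
  ## support ratio (size 2 / size 1) strictly increases with n_exp
  expect_true(all(diff(rw$sensitivity$ratio) > 0))
  ## closed form: ratio = exp(dla) * q/(1-q) crosses 1 at q* = 1/(1+exp(dla))
  dla <- 4.6 - 4
  q_star <- 1 / (1 + exp(dla))
  ne_star <- 50 * q_star
  lo <- reweight_prior(post, ne_star - 0.01,
                       families = list(two = "a,b", one = "a"))
  hi <- reweight_prior(post, ne_star + 0.01,
                       families = list(two = "a,b", one = "a"))
  expect_lt(lo$sensitivity$ratio, 1)
  expect_gt(hi$sensitivity$ratio, 1)
})

test_that("best model per size matches an exhaustive scan", {
  set.seed(44)
  g <- random_panel(n = 200, v = 5, seed = 44)
  y <- rnorm(200) + 0.4 * g$dosages[, 2]
  v <- exhaustive_search(g, y, config = search_config(max_size = 3))
  post <- normalise_posterior(as.data.frame(v), prior = attr(v, "prior"))
  tab <- best_model_per_size(post)
  expect_equal(tab$bic[tab$size == 0], 0)       # null row convention
  for (s in 1:3) {
    cand <- post[post$size == s, ]
    expect_equal(tab$model[tab$size == s],
                 cand$model[which.max(cand$log_abf)])
  }
  expect_equal(tab$bic, -2 * tab$log_abf)
})
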