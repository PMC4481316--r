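test_that("VCF genotypes decode to dosages and multi-allelics are rejected", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, gts = c("0/0", "0/1", "1/1"))
  g <- read_genotypes(path)
  expect_equal(unname(g$dosages[, "rs1"]), c(0, 1, 2))
  expect_equal(g$variants$pos, c(100L, 200L))
  expect_equal(g$variants$maf, c(0.5, 0.5))

  bad <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(bad, alt = c("G", "G,T"))
  expect_error(read_genotypes(bad), "multi-allelic")
})

test_that("dosage tables round-trip and flag problems", {
  g <- random_panel(n = 12, v = 4, seed = 3)
  g$dosages[3, 2] <- NA
  g$missing <- is.na(g$dosages)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_table(g, path)
  g2 <- read_genotypes(path, format = "dosage")
  expect_equal(g2$dosages, g$dosages)
  expect_true(g2$missing[3, 2])
  expect_equal(sum(g2$missing), 1L)

  txt <- readLines(path)
  fields <- strsplit(txt[2], "\t")[[1]]
  fields[3] <- "oops"
  txt[2] <- paste(fields, collapse = "\t")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(txt, bad)
  expect_error(read_genotypes(bad, format = "dosage"), "non-numeric dosage")
})

test_that("preprocessing removes by MAF/variance and mean-imputes", {
  X <- cbind(rep(0, 4),                 # monomorphic
             c(0, 1, 2, 1),
             c(0, 2, NA, 2))
  g <- toy_geno(X)
  out <- preprocess_genotypes(g, maf_min = 0.005)
  removed <- attr(out, "removed")
  expect_equal(removed$id, "v1")
  expect_equal(removed$reason, "constant")
  expect_equal(unname(out$dosages[3, "v3"]), 4 / 3)   # mean of 0,2,2
  expect_false(anyNA(out$dosages))

  ## boundary: maf <= threshold removed, just above retained
  n <- 1000
  X <- cbind(c(rep(1, 8), rep(0, n - 8)),    # maf 0.004
             c(rep(1, 12), rep(0, n - 12)),  # maf 0.006
             rbinom(n, 2, 0.5))
  g <- toy_geno(X)
  out <- preprocess_genotypes(g, maf_min = 0.005)
  expect_false("v1" %in% out$variants$id)
  expect_true("v2" %in% out$variants$id)
  expect_error(preprocess_genotypes(toy_geno(cbind(rep(0, 5))), 0.005),
               "no variants survive")
})

test_that("r2 matches a longhand Pearson oracle and required identities", {
  g <- toy_geno(cbind(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0)))
  ld <- ld_matrix(g)
  expect_equal(ld$r2[1, 2], 1)          # perfect negative correlation

  set.seed(42)
  X <- cbind(rbinom(20, 2, 0.4), rbinom(20, 2, 0.3))
  while (any(apply(X, 2, sd) == 0)) X <- cbind(rbinom(20, 2, 0.4),
                                               rbinom(20, 2, 0.3))
  ld <- ld_matrix(toy_geno(X))
  expect_equal(ld$r2[1, 2], pearson_r2_oracle(X[, 1], X[, 2]),
               tolerance = 1e-12)
  expect_equal(diag(ld$r2), rep(1, 2), ignore_attr = TRUE)
  expect_error(ld_matrix(toy_geno(cbind(c(0, 1, 2), c(1, 1, 1)))),
               "constant")
})

test_that("r2 is sample-permutation equivariant and coding-flip invariant", {
  g <- random_panel(n = 50, v = 6, seed = 9)
  ld <- ld_matrix(g)
  set.seed(1)
  perm <- sample(nrow(g$dosages))
  gp <- g
  gp$dosages <- g$dosages[perm, ]
  gp$missing <- g$missing[perm, ]
  expect_equal(ld_matrix(gp)$r2, ld$r2, tolerance = 1e-12)

  gf <- g
  gf$dosages[, 2] <- 2 - gf$dosages[, 2]
  gf$variants$maf <- shotgunfm:::compute_maf(gf$dosages)
  expect_equal(ld_matrix(gf)$r2, ld$r2, tolerance = 1e-12)
})

test_that("|D'| from the two-locus EM behaves at the extremes", {
  ## complete LD, no recombination: only 3 of 4 haplotypes present
  set.seed(5)
  h1 <- rbinom(400, 1, 0.3)
  h2 <- ifelse(h1 == 1, rbinom(400, 1, 0.5), 0)  # allele only on h1 background
  g <- toy_geno(cbind(h1[1:200] + h1[201:400], h2[1:200] + h2[201:400]))
  ld <- ld_matrix(g, want_dprime = TRUE)
  expect_equal(ld$dprime[1, 2], 1, tolerance = 1e-6)
  expect_true(ld$r2[1, 2] < 1)   # D' = 1 without r2 = 1
})

test_that("tagset clustering respects the r2 floor and picks max-mean-r2 tags", {
  ## duplicated column pair -> one tagset of two, tie broken by position
  g <- random_panel(n = 100, v = 3, duplicate = 1L, seed = 11)
  ld <- ld_matrix(g)
  tm <- build_tagsets(g, ld)
  ts <- attr(tm, "tagsets")
  expect_equal(sort(lengths(ts), decreasing = TRUE), c(2, 1, 1),
               ignore_attr = TRUE)
  big <- ts[[which(lengths(ts) == 2)]]
  expect_setequal(big, c("v1", "v4"))
  expect_equal(names(ts)[lengths(ts) == 2], "v1")   # earlier position wins tie

  ## no extreme LD -> all singletons
  g2 <- random_panel(n = 300, v = 5, seed = 2)
  tm2 <- build_tagsets(g2, ld_matrix(g2))
  expect_equal(length(tags(tm2)), 5L)
  expect_error(build_tagsets(g2, ld_matrix(g2), r2_threshold = 1.5),
               "r2_threshold")
})

test_that("a planted near-duplicate triple clusters and tags by brute force", {
  set.seed(21)
  n <- 2000
  base <- rbinom(n, 2, 0.4)
  X <- cbind(base, nudge1(base, 1L), nudge1(base, 2L),
             rbinom(n, 2, 0.3), rbinom(n, 2, 0.5), rbinom(n, 2, 0.2))
  g <- toy_geno(X)
  ld <- ld_matrix(g)
  stopifnot(min(ld$r2[1:3, 1:3]) > 0.995)
  tm <- build_tagsets(g, ld)
  ts <- attr(tm, "tagsets")
  expect_equal(sort(lengths(ts), decreasing = TRUE), c(3, 1, 1, 1),
               ignore_attr = TRUE)
  triple <- ts[[which(lengths(ts) == 3)]]
  ## brute-force max-mean-r2 scan over the cluster members
  mean_r2 <- sapply(triple, function(v)
    mean(ld$r2[v, setdiff(triple, v)]))
  expect_equal(names(ts)[lengths(ts) == 3],
               names(which.max(mean_r2)))
  ## every removed variant's index SNP is the max-r2 retained tag
  for (v in setdiff(tm$id, tags(tm))) {
    r <- ld$r2[v, tags(tm)]
    expect_equal(tm$index[tm$id == v], names(which.max(r)))
  }
})

test_that("tagsets partition the panel and duplicate-everything halves tags", {
  for (seed in 1:3) {
    g <- random_panel(n = 150, v = 6, seed = seed)
    g2 <- toy_geno(cbind(g$dosages, g$dosages))   # every variant duplicated
    ld <- ld_matrix(g2)
    tm <- build_tagsets(g2, ld)
    ts <- attr(tm, "tagsets")
    expect_setequal(unlist(ts), g2$variants$id)          # partition: union
    expect_equal(sum(lengths(ts)), ncol(g2$dosages))     # partition: disjoint
    expect_equal(length(tags(tm)), 6L)                   # half as many tags
    for (members in ts[lengths(ts) > 1]) {
      sub <- ld$r2[members, members]
      expect_gt(min(sub[upper.tri(sub)]), attr(tm, "threshold"))
    }
  }
})
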