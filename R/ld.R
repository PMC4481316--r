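#' Pairwise linkage disequilibrium from dosages
#'
#' Computes the squared Pearson correlation r^2 between all pairs of dosage
#' columns (genotype r^2, which is also defined for fractional imputed
#' dosages). Optionally also estimates |D'| from two-locus haplotype
#' frequencies obtained by an EM fit to the 3x3 genotype table (dosages are
#' rounded to hard calls for this step); |D'| is a diagnostic for historical
#' recombination -- in regions without recombination it is close to 1 even
#' between variants with low r^2.
#'
#' @param g a preprocessed [geno_matrix()] (no constant columns, no missing
#'   entries).
#' @param want_dprime also compute the |D'| matrix (quadratic in the number
#'   of variants with an EM per pair; intended for modest panels).
#' @return An object of class `ld_matrix`: list with `ids`, symmetric `r2`
#'   and optionally `dprime` matrices.
#' @export
ld_matrix <- function(g, want_dprime = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  X <- g$dosages
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop("constant dosage column(s): ",
         paste(g$variants$id[sds == 0 | is.na(sds)], collapse = ", "),
         " (run preprocess_genotypes first)")
  r2 <- stats::cor(X)^2
  diag(r2) <- 1
  out <- list(ids = g$variants$id, r2 = r2, dprime = NULL)
  if (want_dprime) {
    V <- ncol(X)
    dp <- matrix(1, V, V, dimnames = dimnames(r2))
    hard <- round(X)
    for (i in seq_len(V - 1L)) {
      for (j in (i + 1L):V) {
        dp[i, j] <- dp[j, i] <- dprime_em(hard[, i], hard[, j])
      }
    }
    out$dprime <- dp
  }
  structure(out, class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("ld_matrix over", length(x$ids), "variants")
  if (!is.null(x$dprime)) cat(" (with |D'|)")
  cat("\n")
  invisible(x)
}

## |D'| between two loci from 0/1/2 hard genotype vectors via the standard
## two-locus EM: only the double-heterozygote class has ambiguous phase.
dprime_em <- function(g1, g2, max_iter = 100L, tol = 1e-10) {
  stopifnot(length(g1) == length(g2))
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  n_hap <- 2 * sum(tab)
  pA <- (2 * sum(tab[3, ]) + sum(tab[2, ])) / n_hap   # alt freq locus 1
  pB <- (2 * sum(tab[, 3]) + sum(tab[, 2])) / n_hap
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  ## unambiguous haplotype counts; h = c(AB, Ab, aB, ab) with A,B = alt
  n_dh <- tab[2, 2]
  base <- c(AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
            Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
            aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
            ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1])
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  for (it in seq_len(max_iter)) {
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5
    h <- base + n_dh * c(w, 1 - w, 1 - w, w)
    p_new <- h / n_hap
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  D <- p[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax == 0) return(NA_real_)
  abs(D) / dmax
}

#' Cluster variants in extreme LD into tagsets
#'
#' Removes cases of extreme LD before model search: variants are clustered by
#' complete-linkage hierarchical clustering on distance 1 - r^2 and the tree
#' is cut so that every within-cluster pair has r^2 > `r2_threshold`. Each
#' cluster is a tagset whose tag is the member in highest mean r^2 with the
#' other members (ties broken by smaller position, then id). For every
#' removed (non-tag) variant its index SNP -- the retained tag with which it
#' has highest r^2 -- is also recorded.
#'
#' @param g a preprocessed [geno_matrix()].
#' @param ld an [ld_matrix()] covering all variants of `g`.
#' @param r2_threshold r^2 cut defining "extreme" LD (default 0.99).
#' @return An object of class `tag_map`: data.frame with columns `id`, `tag`
#'   (tag of the variant's tagset) and `index` (highest-r^2 tag), with
#'   attributes `threshold` and `tagsets` (named list tag -> member ids).
#' @export
build_tagsets <- function(g, ld, r2_threshold = 0.99) {
  stopifnot(inherits(g, "geno_matrix"), inherits(ld, "ld_matrix"))
  if (!(r2_threshold > 0 && r2_threshold <= 1))
    stop("r2_threshold must lie in (0, 1]")
  ids <- g$variants$id
  if (!all(ids %in% ld$ids))
    stop("ld matrix does not cover all variants")
  r2 <- ld$r2[ids, ids, drop = FALSE]
  pos <- g$variants$pos
  names(pos) <- ids
  V <- length(ids)
  if (V == 1L) {
    cl <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - r2), method = "complete")
    ## cut strictly below 1 - threshold: within-cluster pairs need r2 > cut
    cl <- stats::cutree(hc, h = (1 - r2_threshold) - 1e-12)
  }
  tag_of_cluster <- vapply(split(ids, cl), function(members) {
    if (length(members) == 1L) return(members)
    sub <- r2[members, members, drop = FALSE]
    mean_r2 <- (rowSums(sub) - 1) / (length(members) - 1)
    best <- members[mean_r2 == max(mean_r2)]
    best[order_pos_id(best, pos[best])][1L]
  }, character(1))
  tag <- tag_of_cluster[as.character(cl)]
  names(tag) <- ids
  tags <- unname(tag_of_cluster)
  ## index SNP: retained tag with highest r2 (ties by position then id)
  index <- vapply(ids, function(v) {
    if (v %in% tags) return(v)
    r <- r2[v, tags]
    best <- tags[r == max(r)]
    best[order_pos_id(best, pos[best])][1L]
  }, character(1))
  out <- data.frame(id = ids, tag = unname(tag), index = unname(index),
                    stringsAsFactors = FALSE)
  tagsets <- split(out$id, out$tag)
  structure(out, class = c("tag_map", "data.frame"),
            threshold = r2_threshold, tagsets = tagsets)
}

#' @export
print.tag_map <- function(x, ...) {
  ts <- attr(x, "tagsets")
  cat("tag_map:", nrow(x), "variants in", length(ts), "tagsets",
      "(r2 >", attr(x, "threshold"), ")\n")
  cat("  tagset sizes:", paste(sort(table(lengths(ts)), decreasing = TRUE),
                               collapse = " "), "\n")
  invisible(x)
}

#' Tags of a tag map
#' @param tagmap a [build_tagsets()] result.
#' @return Character vector of tag variant ids.
#' @export
tags <- function(tagmap) names(attr(tagmap, "tagsets"))

#' Write a tag map as a two-column TSV
#' @param tagmap a [build_tagsets()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tagmap <- function(tagmap, path) {
  utils::write.table(as.data.frame(tagmap)[, c("id", "tag")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an LD matrix as a square TSV
#' @param ld an [ld_matrix()].
#' @param path output path.
#' @param what `"r2"` or `"dprime"`.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path, what = c("r2", "dprime")) {
  what <- match.arg(what)
  m <- ld[[what]]
  if (is.null(m)) stop("ld matrix has no ", what, " component")
  utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
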