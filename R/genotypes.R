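#' Construct a genotype dosage matrix
#'
#' Container for a samples x variants matrix of alternate-allele dosages in
#' \[0, 2\] (fractional values allowed, e.g. imputed expected dosages) together
#' with per-variant metadata. Missing entries are held as `NA` in `dosages`
#' and flagged in the logical `missing` matrix; [preprocess_genotypes()]
#' replaces them by the per-variant mean before analysis.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#'   Row names are sample ids, column names variant ids.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#'   A `maf` column is computed from the dosages if absent. Variant order must
#'   match the columns of `dosages`.
#' @return An object of class `geno_matrix`: a list with elements `dosages`,
#'   `variants` and `missing`.
#' @export
geno_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(dosages))
  variants$id <- as.character(variants$id)
  if (anyDuplicated(variants$id))
    stop("duplicated variant ids: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (any(!is.na(variants$pos) & variants$pos <= 0))
    stop("variant positions must be strictly positive")
  colnames(dosages) <- variants$id
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]; observed range ",
         rng[1], " .. ", rng[2])
  variants$maf <- compute_maf(dosages)
  rownames(variants) <- NULL
  structure(list(dosages = dosages,
                 variants = variants,
                 missing = is.na(dosages)),
            class = "geno_matrix")
}

## minor allele frequency per column from dosages (missing entries ignored)
compute_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  cat("  MAF range:", sprintf("%.4f", min(x$variants$maf)), "-",
      sprintf("%.4f", max(x$variants$maf)),
      " missing entries:", sum(x$missing), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by variant id
#'
#' @param g a [geno_matrix()].
#' @param ids variant ids to keep, in the requested order.
#' @return A `geno_matrix` restricted to `ids`.
#' @export
subset_variants <- function(g, ids) {
  stopifnot(inherits(g, "geno_matrix"))
  miss <- setdiff(ids, g$variants$id)
  if (length(miss))
    stop("unknown variant ids: ", paste(miss, collapse = ", "))
  idx <- match(ids, g$variants$id)
  out <- g
  out$dosages <- g$dosages[, idx, drop = FALSE]
  out$variants <- g$variants[idx, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$missing <- g$missing[, idx, drop = FALSE]
  out
}

#' Read genotypes from VCF or a dosage table
#'
#' Reads hard-called or imputed genotypes into a [geno_matrix()]. VCF input
#' (plain or bgzipped, VCF 4.x) uses the `DS` FORMAT field when present and
#' otherwise counts alternate alleles in `GT`. Multi-allelic records are
#' rejected and must be split (e.g. `bcftools norm -m-`) beforehand, so that
#' a dosage is unambiguously the count of one alternate allele. Dosage-table
#' input is a TSV whose header row names the variants, whose first column
#' holds sample ids and whose remaining cells are dosages in \[0, 2\]
#' (empty/`NA` cells allowed).
#'
#' @param path path to the input file.
#' @param format `"auto"` (by file extension), `"vcf"` or `"dosage"`.
#' @return A `geno_matrix`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no variant records in VCF: ", path)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multi-allelic VCF records found (ALT contains ','): ",
         "split them first, e.g. with 'bcftools norm -m-'")
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               paste0(fix$CHROM, ":", fix$POS), fix$ID)
  fmt <- v@gt[, 1L]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2L, gt_to_dosage)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(gt))
  }
  dos <- t(ds)                                 # samples x variants
  rownames(dos) <- colnames(v@gt)[-1L]
  variants <- data.frame(id = id,
                         chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF,
                         alt = fix$ALT,
                         stringsAsFactors = FALSE)
  geno_matrix(dos, variants)
}

## "0/1", "0|1", "1/1", "./." etc. -> 0,1,2,NA
gt_to_dosage <- function(gt) {
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    if (length(a) == 0L || any(a == ".") || any(is.na(a))) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L)
    stop("dosage table needs a sample-id column plus >=1 variant column: ",
         path)
  ids <- colnames(tab)[-1L]
  dos <- as.matrix(tab[, -1L, drop = FALSE])
  if (is.character(dos)) {
    suppressWarnings(num <- matrix(as.numeric(dos), nrow = nrow(dos)))
    bad <- which(is.na(num) & !is.na(dos) & dos != "" & dos != "NA",
                 arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf(
        "non-numeric dosage '%s' at line %d, column '%s' of %s",
        dos[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L, ids[bad[1, 2]], path))
    dos <- num
  }
  rownames(dos) <- as.character(tab[[1L]])
  variants <- data.frame(id = ids,
                         chrom = NA_character_,
                         pos = seq_along(ids),   # column order stands in
                         ref = NA_character_,
                         alt = NA_character_,
                         stringsAsFactors = FALSE)
  geno_matrix(dos, variants)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Inverse of the dosage-table reader: header row of variant ids, first
#' column `sample_id`, one row per sample.
#'
#' @param g a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_table <- function(g, path) {
  stopifnot(inherits(g, "geno_matrix"))
  out <- data.frame(sample_id = rownames(g$dosages),
                    g$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter and impute a genotype matrix
#'
#' Drops variants with minor allele frequency at or below `maf_min` or with
#' zero variance among observed dosages, then replaces missing entries with
#' the variant's mean observed dosage so that downstream regression designs
#' are complete. MAF is computed on the analysed samples before imputation.
#'
#' @param g a [geno_matrix()].
#' @param maf_min MAF threshold; variants with `maf <= maf_min` are removed.
#' @return A filtered `geno_matrix`; the attribute `"removed"` is a data.frame
#'   listing dropped variants with the reason (`"maf"` or `"constant"`).
#' @export
preprocess_genotypes <- function(g, maf_min = 0.005) {
  stopifnot(inherits(g, "geno_matrix"))
  if (ncol(g$dosages) == 0L) stop("empty genotype matrix")
  maf <- compute_maf(g$dosages)
  v <- apply(g$dosages, 2L, stats::var, na.rm = TRUE)
  n_obs <- colSums(!g$missing)
  constant <- is.na(v) | v == 0 | n_obs < 2L
  low <- !constant & maf <= maf_min
  drop <- constant | low
  if (all(drop)) stop("no variants survive filtering")
  removed <- data.frame(id = g$variants$id[drop],
                        maf = maf[drop],
                        reason = ifelse(constant[drop], "constant", "maf"),
                        stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  out <- subset_variants(g, g$variants$id[!drop])
  if (any(out$missing)) {
    mu <- colMeans(out$dosages, na.rm = TRUE)
    idx <- which(out$missing, arr.ind = TRUE)
    out$dosages[idx] <- mu[idx[, 2L]]
  }
  ## maf recorded on observed data, pre-imputation
  out$variants$maf <- maf[!drop]
  attr(out, "removed") <- removed
  out
}

#' Read a phenotype/covariate table
#'
#' TSV with columns `sample_id`, `phenotype`, then any covariate columns
#' (categorical covariates such as country of origin are kept as factors and
#' reference-coded at model fitting).
#'
#' @param path path to the TSV.
#' @return A list with `sample_id`, numeric `phenotype`, and `covariates`
#'   (a data.frame or `NULL`).
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2L)
    stop("phenotype table needs sample_id and phenotype columns: ", path)
  ph <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(ph) && !anyNA(tab[[2L]]))
    stop("non-numeric phenotype value at line ",
         which(is.na(ph))[1L] + 1L, " of ", path)
  covs <- if (ncol(tab) > 2L) {
    cv <- tab[, -(1:2), drop = FALSE]
    cv[] <- lapply(cv, function(x) if (is.character(x)) factor(x) else x)
    cv
  } else NULL
  list(sample_id = as.character(tab[[1L]]), phenotype = ph,
       covariates = covs)
}
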