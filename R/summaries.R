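#' Marginal posterior probability of inclusion
#'
#' `MPPI(i)` is the summed posterior probability of all models containing
#' SNP `i`. Summed over SNPs it equals the posterior expected model size.
#'
#' @param post a `posterior_set`.
#' @param panel optional character vector of variant ids defining the
#'   universe (defaults to the posterior's `panel` attribute, else the
#'   variants appearing in any model); SNPs in no model get MPPI 0.
#' @return Named numeric vector of inclusion probabilities.
#' @export
mppi <- function(post, panel = NULL) {
  members <- model_members(post$model)
  panel <- panel %||% attr(post, "panel") %||%
    sort(unique(unlist(members)))
  w <- rep(post$pp, lengths(members))
  v <- unlist(members)
  out <- stats::setNames(numeric(length(panel)), panel)
  if (length(v)) {
    s <- vapply(split(w, v), sum, numeric(1))
    out[names(s)] <- s
  }
  out
}

#' Joint marginal posterior probability of inclusion of a SNP pair
#'
#' Summed posterior probability of models containing both `i` and `j`
#' (equal to `MPPI(i)` when `i == j`).
#'
#' @param post a `posterior_set`.
#' @param i,j variant ids.
#' @return Joint inclusion probability.
#' @export
joint_mppi <- function(post, i, j) {
  members <- model_members(post$model)
  hit <- vapply(members, function(m) (i %in% m) && (j %in% m), logical(1))
  sum(post$pp[hit])
}

#' Group marginal posterior probability of inclusion
#'
#' Summed posterior probability over all models containing at least one
#' member of `group`, each model counted once (never the sum of member
#' MPPIs, which double-counts models with two group members).
#'
#' @param group character vector of variant ids.
#' @param post a `posterior_set`.
#' @return The gMPPI, in `[max member MPPI, min(1, sum of member MPPIs)]`.
#' @export
gmppi <- function(group, post) {
  members <- model_members(post$model)
  hit <- vapply(members, function(m) any(m %in% group), logical(1))
  sum(post$pp[hit])
}

#' Group SNPs sharing diluted posterior support
#'
#' Highly correlated variants split posterior mass across near-equivalent
#' models, so no single SNP need show high MPPI even when the joint support
#' that *one of them* is causal is strong. This routine re-aggregates that
#' support into disjoint SNP groups: (1) seed with the unassigned SNP of
#' maximum MPPI; (2) order the remaining SNPs by decreasing r^2 with the
#' seed; (3) exclude SNPs that co-occur with the seed in models (joint
#' MPPI > `joint_cap`), since co-occurrence marks a distinct signal rather
#' than a substitutable one; (4) walk down the ordering adding SNPs until
#' r^2 with the seed drops below `r2_floor` or until `run_length`
#' consecutive SNPs have MPPI below `mppi_floor` (sub-floor SNPs are never
#' added); (5) remove the group and repeat while any unassigned SNP has
#' MPPI above `seed_floor`. The r^2 stop is evaluated before the MPPI-run
#' stop on each candidate. Ties (equal MPPI or equal r^2) are broken by
#' smaller position, then id.
#'
#' @param post a `posterior_set`.
#' @param ld an [ld_matrix()] over the same panel.
#' @param variants optional variant metadata data.frame (for positional tie
#'   breaks); defaults to the LD matrix order.
#' @param mppi_floor MPPI below which a walked SNP counts toward the stop
#'   run (default 0.001).
#' @param run_length number of consecutive sub-floor SNPs that stops the
#'   walk (default 2).
#' @param r2_floor minimum r^2 with the seed (default 0.5).
#' @param joint_cap joint-MPPI exclusion threshold (default 0.02).
#' @param seed_floor minimum MPPI for starting a new group (default 0.01).
#' @return An object of class `group_set`: list with `groups` (each a list
#'   with `members`, `index_snp`, `mppi`, `gmppi`, `r2_to_index`) and
#'   `leftover` (variants in no group).
#' @export
snp_picker <- function(post, ld, variants = NULL, mppi_floor = 0.001,
                       run_length = 2L, r2_floor = 0.5, joint_cap = 0.02,
                       seed_floor = 0.01) {
  stopifnot(inherits(ld, "ld_matrix"))
  ids <- ld$ids
  m <- mppi(post, panel = ids)
  pos <- if (!is.null(variants)) {
    stats::setNames(variants$pos, variants$id)[ids]
  } else {
    stats::setNames(seq_along(ids), ids)
  }
  members_list <- model_members(post$model)
  unassigned <- ids
  groups <- list()
  repeat {
    eligible <- unassigned[m[unassigned] > seed_floor]
    if (length(eligible) == 0L) break
    top <- eligible[m[eligible] == max(m[eligible])]
    seed <- top[order_pos_id(top, pos[top])][1L]
    others <- setdiff(unassigned, seed)
    r2s <- ld$r2[seed, others]
    ord <- others[order(-r2s, pos[others], others, method = "radix")]
    ## step 3: drop SNPs that co-occur with the seed across models
    joint <- vapply(ord, function(o) {
      hit <- vapply(members_list,
                    function(mm) (seed %in% mm) && (o %in% mm), logical(1))
      sum(post$pp[hit])
    }, numeric(1))
    ord <- ord[joint <= joint_cap]
    grp <- seed
    run <- 0L
    for (o in ord) {
      if (ld$r2[seed, o] < r2_floor) break
      if (m[o] < mppi_floor) {
        run <- run + 1L
        if (run >= run_length) break
      } else {
        run <- 0L
        grp <- c(grp, o)
      }
    }
    groups[[length(groups) + 1L]] <- list(
      members = grp,
      index_snp = seed,
      mppi = m[grp],
      gmppi = gmppi(grp, post),
      r2_to_index = stats::setNames(ld$r2[seed, grp], grp))
    unassigned <- setdiff(unassigned, grp)
  }
  ## label groups A, B, ... in decreasing gMPPI order
  if (length(groups)) {
    ord <- order(-vapply(groups, `[[`, numeric(1), "gmppi"))
    groups <- groups[ord]
    names(groups) <- make.unique(
      c(LETTERS, paste0("G", seq_len(max(0L, length(groups) - 26L))))[
        seq_along(groups)])
  }
  structure(list(groups = groups, leftover = unassigned),
            class = "group_set")
}

#' @export
print.group_set <- function(x, ...) {
  cat("group_set:", length(x$groups), "SNP groups,",
      length(x$leftover), "ungrouped variants\n")
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %s: %d SNPs, index %s, gMPPI %.3f\n",
                nm, length(g$members), g$index_snp, g$gmppi))
  }
  invisible(x)
}

#' @export
as.data.frame.group_set <- function(x, ...) {
  if (length(x$groups) == 0L)
    return(data.frame(group = character(), variant_id = character(),
                      mppi = numeric(), gmppi = numeric(),
                      r2_to_index = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(names(x$groups), function(nm) {
    g <- x$groups[[nm]]
    data.frame(group = nm, variant_id = g$members,
               mppi = unname(g$mppi), gmppi = g$gmppi,
               r2_to_index = unname(g$r2_to_index),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Model-averaged per-SNP effect estimates
#'
#' `beta_i = sum_m I(i in m) beta_i(m) pp_m` on the linear-predictor scale
#' (log odds ratios for the case-control family; `exp(beta)` gives the OR).
#' SNPs in no model get 0.
#'
#' @param post a `posterior_set` carrying per-model coefficients (see
#'   `keep_coef` in [rescore_expanded()]).
#' @param panel optional id universe (defaults as in [mppi()]).
#' @return Named numeric vector of averaged effects.
#' @export
averaged_effects <- function(post, panel = NULL) {
  if (!"coef" %in% names(post))
    stop("posterior set carries no coefficients; rescore with keep_coef = TRUE")
  members <- model_members(post$model)
  panel <- panel %||% attr(post, "panel") %||%
    sort(unique(unlist(members)))
  out <- stats::setNames(numeric(length(panel)), panel)
  for (i in seq_len(nrow(post))) {
    cf <- post$coef[[i]]
    if (length(cf))
      out[names(cf)] <- out[names(cf)] + post$pp[i] * cf
  }
  out
}

#' Posterior distribution over the number of SNPs in the model
#'
#' Aggregates posterior mass by model size; when the posterior carries its
#' [prior_spec()], the binomial prior mass over the same sizes is reported
#' alongside for comparison.
#'
#' @param post a `posterior_set`.
#' @return data.frame with columns `n_snps`, `posterior` and (if available)
#'   `prior`.
#' @export
nsnp_posterior <- function(post) {
  sizes <- 0:max(post$size)
  pp <- vapply(sizes, function(s) sum(post$pp[post$size == s]), numeric(1))
  out <- data.frame(n_snps = sizes, posterior = pp)
  pr <- attr(post, "prior")
  if (!is.null(pr))
    out$prior <- stats::dbinom(sizes, pr$N, pr$q)
  out
}

#' Reweight a posterior under alternative prior expectations
#'
#' Because `pp ~ BF * prior` and the Bayes factors do not depend on the
#' prior, the posterior under a different a priori expected number of
#' causal variants is obtained by recomputing the size prior and
#' renormalising -- no refitting. Optionally reports the support ratio
#' between two declared model families (sets of model keys) at each prior
#' setting, e.g. to ask at which prior expectation a two-SNP explanation
#' overtakes a one-SNP explanation.
#'
#' @param post a `posterior_set` with a `prior` attribute (for `N`).
#' @param n_exp_grid prior expectations to evaluate.
#' @param families optional named list of exactly two character vectors of
#'   model keys.
#' @return List with `sensitivity` (data.frame: `n_exp`, expected posterior
#'   model size, and -- with `families` -- per-family support and their
#'   ratio) and `posteriors` (per-`n_exp` data.frames of model, pp).
#' @export
reweight_prior <- function(post, n_exp_grid, families = NULL) {
  pr <- attr(post, "prior")
  if (is.null(pr)) stop("posterior set carries no prior_spec")
  if (!is.null(families) && length(families) != 2L)
    stop("families must name exactly two model sets")
  n_exp_grid <- n_exp_grid[n_exp_grid < pr$N]   # binomial must stay proper
  if (length(n_exp_grid) == 0L)
    stop("no feasible n_exp below the panel size ", pr$N)
  rows <- list()
  posts <- list()
  for (ne in n_exp_grid) {
    p2 <- prior_spec(pr$N, ne)
    lw <- post$log_abf + model_log_prior(post$size, p2)
    pp <- exp(lw - logsumexp(lw))
    posts[[as.character(ne)]] <- data.frame(model = post$model,
                                            size = post$size, pp = pp,
                                            stringsAsFactors = FALSE)
    row <- data.frame(n_exp = ne, expected_size = sum(post$size * pp))
    if (!is.null(families)) {
      sup <- vapply(families, function(keys) sum(pp[post$model %in% keys]),
                    numeric(1))
      row[[paste0("support_", names(families)[1])]] <- sup[1]
      row[[paste0("support_", names(families)[2])]] <- sup[2]
      row$ratio <- sup[1] / sup[2]
    }
    rows[[length(rows) + 1L]] <- row
  }
  list(sensitivity = do.call(rbind, rows), posteriors = posts)
}

#' Best model of each size
#'
#' For each model size, the model with the largest log Bayes factor, with
#' its BIC on the against-the-null scale (`BIC = -2 log BF`; the null row
#' has BIC 0 by this convention). Mirrors per-size best-model reporting
#' used when comparing search strategies.
#'
#' @param post a `posterior_set` or `visited_set`.
#' @return data.frame with columns `size`, `model`, `log_abf`, `bic`.
#' @export
best_model_per_size <- function(post) {
  df <- as.data.frame(post)
  rows <- lapply(split(df, df$size), function(d) {
    d <- d[order(-d$log_abf, d$model, method = "radix"), , drop = FALSE]
    d[1L, c("model", "size", "log_abf")]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$size), c("size", "model", "log_abf")]
  out$bic <- -2 * out$log_abf
  rownames(out) <- NULL
  out
}
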