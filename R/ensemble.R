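#' ReBoot permutation/bootstrap significance for one taxon pair
#'
#' Compositionality-preserving null: one taxon's values are permuted across
#' samples and every sample is re-closed to sum 1 before the measure is
#' recomputed, so the null distribution carries the spurious (closure-
#' induced) association that relative abundances force on any pair. A
#' bootstrap over samples (with replacement) stabilizes the observed score:
#' by default the bootstrap mean replaces the single observed value in the
#' two-sided empirical p
#' `(1 + #(|null - null_mean| >= |obs - null_mean|)) / (P + 1)`.
#'
#' @param table a relative-mode [abundance_table].
#' @param pair character vector of two taxon identifiers.
#' @param measure one of [MEASURES].
#' @param P number of permutations (>= 100).
#' @param B number of bootstraps (>= 100).
#' @param seed integer seed.
#' @param bootstrap if `FALSE`, the raw observed score is used instead of
#'   the bootstrap mean.
#' @param bins,shrinkage,iterations measure parameters.
#' @return A list: `observed`, `boot_mean`, `null_mean`, `null_sd`, `p`,
#'   `boot_ci` (2.5/97.5 percentiles), `defined`.
#' @export
reboot_pvalue <- function(table, pair, measure = MEASURES, P = 200, B = 100,
                          seed = 1L, bootstrap = TRUE, bins = NULL,
                          shrinkage = 0.1, iterations = 500) {
  stopifnot(inherits(table, "abundance_table"))
  measure <- match.arg(measure)
  if (table$mode != "relative")
    stop("reboot_pvalue expects a relative-mode table", call. = FALSE)
  if (P < 100 || B < 100)
    stop("need at least 100 permutations and bootstraps", call. = FALSE)
  v <- table$values
  if (!all(pair %in% colnames(v))) stop("pair not in table", call. = FALSE)
  n <- nrow(v)
  set.seed(seed)
  perms <- matrix(0L, n, P)
  for (k in seq_len(P)) perms[, k] <- sample.int(n)
  boots <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  out <- reboot_one(v, match(pair[1], colnames(v)),
                    match(pair[2], colnames(v)),
                    measure, perms, boots, bootstrap,
                    bins %||% default_bins(n), shrinkage, iterations)
  out
}

# Shared per-pair machinery; i, j are column indices.
reboot_one <- function(v, i, j, measure, perms, boots, bootstrap, bins,
                       shrinkage, iterations) {
  if (measure == "gblm") {
    observed <- cpp_gblm_pair(v, i, j, shrinkage, as.integer(iterations))
    null <- as.numeric(cpp_gblm_reboot(v, i, j, perms, shrinkage,
                                       as.integer(iterations)))
    boot <- as.numeric(cpp_gblm_boot(v, i, j, boots, shrinkage,
                                     as.integer(iterations)))
  } else {
    code <- measure_codes[[measure]]
    x <- v[, i]; y <- v[, j]
    observed <- cpp_measure(x, y, code, bins)
    null <- as.numeric(cpp_reboot_null(x, y, perms, code, bins))
    boot <- as.numeric(cpp_subset_scores(x, y, boots, code, bins))
  }
  null <- null[is.finite(null)]
  defined <- is.finite(observed) && length(null) >= 10
  if (!defined) {
    return(list(observed = observed, boot_mean = NA_real_,
                null_mean = NA_real_, null_sd = NA_real_, p = NA_real_,
                boot_ci = c(NA_real_, NA_real_), null = numeric(),
                defined = FALSE))
  }
  boot_mean <- mean(boot[is.finite(boot)])
  # The bootstrap mean stabilizes smooth statistics, but resampling ties
  # inflate the binned MI estimator, so MI keeps its raw observed value.
  obs_eff <- if (bootstrap && measure != "mi" && is.finite(boot_mean))
    boot_mean else observed
  null_mean <- mean(null)
  null_sd <- sd(null)
  p <- (1 + sum(abs(null - null_mean) >= abs(obs_eff - null_mean))) /
    (length(null) + 1)
  list(observed = observed, boot_mean = boot_mean, null_mean = null_mean,
       null_sd = null_sd, p = p,
       boot_ci = unname(quantile(boot[is.finite(boot)], c(0.025, 0.975))),
       null = null, obs_eff = obs_eff, defined = TRUE)
}

#' Merge dependent per-measure p-values (Brown's method)
#'
#' Fisher's statistic `-2 * sum(log(p))` referred to a scaled chi-square
#' whose scale and degrees of freedom are estimated from the empirical
#' covariance of `-2 * log(pseudo-p)` across the measures' shared
#' permutation draws. With perfectly dependent measures the merged p equals
#' the single p (no `p^k` inflation); with independent measures it reduces
#' to Fisher's method. Falls back to Fisher when covariance estimation is
#' infeasible (no shared draws, or degenerate covariance).
#'
#' @param pvals numeric vector of per-measure p-values (NAs dropped).
#' @param null_scores optional list of per-measure permutation null draws,
#'   computed from the *same* permutations, used to estimate dependence.
#' @return Merged p-value in (0, 1\].
#' @export
merge_pvalues <- function(pvals, null_scores = NULL) {
  pvals <- pvals[is.finite(pvals)]
  k <- length(pvals)
  if (k == 0) return(NA_real_)
  if (k == 1) return(unname(pvals))
  pvals <- pmax(pvals, .Machine$double.xmin)
  X <- -2 * sum(log(pvals))
  mean_x <- 2 * k
  var_x <- 4 * k
  if (!is.null(null_scores)) {
    null_scores <- Filter(function(u) length(u) >= 10, null_scores)
    lens <- lengths(null_scores)
    if (length(null_scores) >= 2 && length(unique(lens)) == 1) {
      W <- vapply(null_scores, function(u) {
        d <- abs(u - mean(u))
        pk <- vapply(d, function(dk) sum(d >= dk), numeric(1)) / length(d)
        -2 * log(pk)
      }, numeric(lens[1]))
      cv <- stats::cov(W)
      off <- cv[upper.tri(cv)]
      if (all(is.finite(off))) var_x <- 4 * ncol(W) + 2 * sum(off)
    }
  }
  if (!is.finite(var_x) || var_x <= 0) var_x <- 4 * k
  cc <- var_x / (2 * mean_x)
  ff <- 2 * mean_x^2 / var_x
  unname(pchisq(X / cc, df = ff, lower.tail = FALSE))
}

#' Majority-vote sign of an association
#'
#' Pearson, Spearman and GBLM vote with the sign of their score; the
#' Bray-Curtis vote is `sign(null_mean - observed)` (dissimilarity smaller
#' than its compositional null means co-occurrence); mutual information
#' abstains (it is unsigned). An exact tie is reported as `"conflict"`.
#'
#' @param scores named per-measure observed scores.
#' @param null_means named per-measure permutation null means.
#' @return `"+"`, `"-"`, or `"conflict"`.
#' @export
assign_sign <- function(scores, null_means) {
  votes <- c()
  for (m in intersect(c("pearson", "spearman", "gblm"), names(scores))) {
    s <- scores[[m]]
    if (is.finite(s) && s != 0) votes <- c(votes, sign(s))
  }
  if ("bray_curtis" %in% names(scores)) {
    s <- null_means[["bray_curtis"]] - scores[["bray_curtis"]]
    if (is.finite(s) && s != 0) votes <- c(votes, sign(s))
  }
  pos <- sum(votes > 0); neg <- sum(votes < 0)
  if (pos > neg) "+" else if (neg > pos) "-" else "conflict"
}

#' Ensemble association analysis of all taxon pairs
#'
#' For every unordered taxon pair, computes the five-measure observed
#' scores, their ReBoot permutation p-values (shared permutations across
#' measures), the Brown-merged p, the majority-vote sign, and the
#' standardized effect `z = (obs - null_mean) / null_sd` per measure.
#'
#' @param table a relative-mode [abundance_table] (counts tables are closed
#'   automatically).
#' @param measures subset of [MEASURES] to use.
#' @inheritParams reboot_pvalue
#' @return A data frame of class `association_result`, one row per pair,
#'   with per-measure `score_*`, `p_*`, `z_*` columns plus `merged_p` and
#'   `sign`. Taxa are recorded in `attr(, "nodes")`.
#' @export
ensemble_associations <- function(table, measures = MEASURES, P = 200,
                                  B = 100, seed = 1L, bootstrap = TRUE,
                                  bins = NULL, shrinkage = 0.1,
                                  iterations = 500) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative") table <- to_relative(table)
  measures <- match.arg(measures, MEASURES, several.ok = TRUE)
  v <- table$values
  n <- nrow(v); p <- ncol(v)
  taxa <- colnames(v)
  bins <- bins %||% default_bins(n)
  set.seed(child_seed(seed, 11))
  pairs <- combn(p, 2)
  rows <- vector("list", ncol(pairs))
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    perms <- matrix(0L, n, P)
    for (k in seq_len(P)) perms[, k] <- sample.int(n)
    boots <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    per <- lapply(setNames(measures, measures), function(m)
      reboot_one(v, i, j, m, perms, boots, bootstrap, bins,
                 shrinkage, iterations))
    pv <- vapply(per, `[[`, numeric(1), "p")
    merged <- merge_pvalues(pv, lapply(per[is.finite(pv)], `[[`, "null"))
    scores <- vapply(per, function(r)
      if (isTRUE(r$defined)) r$obs_eff else NA_real_, numeric(1))
    nulls <- vapply(per, `[[`, numeric(1), "null_mean")
    sds <- vapply(per, `[[`, numeric(1), "null_sd")
    z <- (scores - nulls) / sds
    row <- data.frame(taxon_a = taxa[i], taxon_b = taxa[j],
                      stringsAsFactors = FALSE)
    for (m in measures) {
      row[[paste0("score_", m)]] <- scores[[m]]
      row[[paste0("p_", m)]] <- pv[[m]]
      row[[paste0("z_", m)]] <- z[[m]]
    }
    row$merged_p <- merged
    row$sign <- assign_sign(scores, nulls)
    rows[[idx]] <- row
  }
  res <- do.call(rbind, rows)
  attr(res, "nodes") <- taxa
  attr(res, "measures") <- measures
  class(res) <- c("association_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment over one family of pairs
#'
#' Adds a `q` column. Call once per generation so each generation's network
#' is corrected within its own family.
#'
#' @param results an `association_result` data frame.
#' @return The data frame with a `q` column.
#' @export
bh_adjust <- function(results) {
  results$q <- p.adjust(results$merged_p, method = "BH")
  results
}

#' Build the signed consortium network from association results
#'
#' Edges are the pairs with BH `q <= q_threshold` and a non-conflicting
#' sign. The edge weight is the mean standardized effect `|z|` over the
#' supporting measures (those whose directional vote agrees with the edge
#' sign; MI, unsigned, always supports). All taxa remain nodes, so isolated
#' taxa are kept with degree zero.
#'
#' @param results an `association_result` data frame (a `q` column is added
#'   via [bh_adjust()] if absent).
#' @param q_threshold BH q-value cutoff (default 0.05).
#' @param nodes node set; defaults to the taxa recorded on `results`.
#' @return A [consortium_network].
#' @export
build_network <- function(results, q_threshold = 0.05, nodes = NULL) {
  nodes <- nodes %||% attr(results, "nodes")
  if (is.null(nodes))
    nodes <- unique(c(results$taxon_a, results$taxon_b))
  if (nrow(results) == 0) return(consortium_network(nodes))
  if (!"q" %in% names(results)) results <- bh_adjust(results)
  measures <- attr(results, "measures") %||%
    sub("^score_", "", grep("^score_", names(results), value = TRUE))
  keep <- which(!is.na(results$q) & results$q <= q_threshold &
                  results$sign %in% c("+", "-"))
  if (length(keep) == 0) return(consortium_network(nodes))
  edges <- lapply(keep, function(r) {
    sgn <- results$sign[r]
    zs <- c(); sup <- c()
    for (m in measures) {
      z <- results[[paste0("z_", m)]][r]
      if (!is.finite(z)) next
      vote <- if (m == "mi") 0 else if (m == "bray_curtis") -sign(z)
              else sign(z)
      agrees <- (m == "mi") || (vote == if (sgn == "+") 1 else -1)
      if (agrees) { zs <- c(zs, abs(z)); sup <- c(sup, m) }
    }
    if (length(zs) == 0) {
      for (m in measures) {
        z <- results[[paste0("z_", m)]][r]
        if (is.finite(z)) zs <- c(zs, abs(z))
      }
    }
    data.frame(taxon_a = results$taxon_a[r], taxon_b = results$taxon_b[r],
               sign = sgn, weight = max(mean(zs), 1e-12), q = results$q[r],
               stringsAsFactors = FALSE)
  })
  consortium_network(nodes, do.call(rbind, edges))
}

#' One-call network inference
#'
#' [ensemble_associations()] + [bh_adjust()] + [build_network()].
#'
#' @inheritParams ensemble_associations
#' @param q_threshold BH q-value cutoff.
#' @return A list with `associations` (q-adjusted) and `network`.
#' @export
infer_network <- function(table, measures = MEASURES, P = 200, B = 100,
                          q_threshold = 0.05, seed = 1L, bootstrap = TRUE,
                          bins = NULL, shrinkage = 0.1, iterations = 500) {
  res <- ensemble_associations(table, measures = measures, P = P, B = B,
                               seed = seed, bootstrap = bootstrap,
                               bins = bins, shrinkage = shrinkage,
                               iterations = iterations)
  res <- bh_adjust(res)
  list(associations = res,
       network = build_network(res, q_threshold = q_threshold))
}
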