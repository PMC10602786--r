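#' Combined taxon-degradation association scores
#'
#' For each taxon, the five ensemble measures are computed between the
#' taxon's relative-abundance vector and the degradation-efficiency vector
#' of one oil fraction, and each is standardized against its own
#' permutation null (efficiencies shuffled `P` times, the same
#' permutations for every measure) into a signed z-statistic:
#' Pearson, Spearman and the GBLM coefficient keep their own sign; the
#' mutual-information z is signed by Spearman's direction; the Bray-Curtis
#' component is the orientation-symmetrized score
#' `(z(e) - z(-e)) / 2` (dissimilarity computed against the min-shifted,
#' unit-sum efficiency profile and against its reflection), which makes the
#' whole combination exactly antisymmetric under response negation. The
#' combined coefficient is the sum of the five signed z's; its p-value
#' comes from the permutation distribution of the combined coefficient
#' itself, with BH correction across taxa within the fraction.
#'
#' The GBLM component fits all taxa jointly (boosting of the standardized
#' efficiency on all standardized taxon abundances), so its coefficient for
#' one taxon is adjusted for the others.
#'
#' @param table an [abundance_table] (closed to relative mode if needed).
#' @param responses a `degradation_record` data frame.
#' @param fraction oil fraction to analyse (one of [OIL_FRACTIONS]).
#' @param P number of permutations (>= 100).
#' @param seed integer seed.
#' @param bins,shrinkage,iterations measure parameters.
#' @return Data frame of class `function_association`: `taxon`, `fraction`,
#'   per-measure signed z columns, `combined`, `p`, `q`, `direction`.
#' @export
taxon_function_scores <- function(table, responses, fraction, P = 1000,
                                  seed = 1L, bins = NULL, shrinkage = 0.1,
                                  iterations = 500) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative") table <- to_relative(table)
  resp <- responses[responses$fraction == fraction, ]
  if (nrow(resp) == 0) stop("no records for fraction ", fraction,
                            call. = FALSE)
  common <- intersect(rownames(table$values), resp$sample_id)
  if (length(common) < 6)
    stop("need at least 6 paired samples", call. = FALSE)
  v <- table$values[common, , drop = FALSE]
  e <- resp$efficiency[match(common, resp$sample_id)]
  if (sd(e) == 0)
    stop("efficiency vector is constant; associations undefined",
         call. = FALSE)
  n <- length(e)
  bins <- bins %||% default_bins(n)
  taxa <- colnames(v)
  keep <- vapply(taxa, function(t) sd(v[, t]) > 0, logical(1))
  for (t in taxa[!keep])
    message("taxon ", t, " is constant across samples; excluded")
  taxa <- taxa[keep]

  set.seed(child_seed(seed, 21))
  perms <- matrix(0L, n, P)
  for (k in seq_len(P)) perms[, k] <- sample.int(n)

  # GBLM: one joint fit per permutation serves every taxon.
  gblm_obs <- setNames(as.numeric(cpp_gblm(v, e, shrinkage,
                                           as.integer(iterations))),
                       colnames(v))
  gblm_null <- matrix(NA_real_, ncol(v), P, dimnames = list(colnames(v)))
  for (k in seq_len(P))
    gblm_null[, k] <- as.numeric(cpp_gblm(v, e[perms[, k]], shrinkage,
                                          as.integer(iterations)))

  # Efficiency profiles for the Bray-Curtis component.
  w_pos <- e - min(e); w_neg <- max(e) - e
  w_pos <- w_pos / sum(w_pos); w_neg <- w_neg / sum(w_neg)

  std_z <- function(obs, null) {
    m <- mean(null); s <- sd(null)
    if (!is.finite(s) || s == 0) return(list(z = 0, zk = rep(0, length(null))))
    list(z = (obs - m) / s, zk = (null - m) / s)
  }

  rows <- lapply(taxa, function(t) {
    x <- v[, t]
    zp <- std_z(cpp_measure(x, e, 1L, bins),
                as.numeric(cpp_permute_y_scores(x, e, perms, 1L, bins)))
    sp_obs <- cpp_measure(x, e, 2L, bins)
    sp_null <- as.numeric(cpp_permute_y_scores(x, e, perms, 2L, bins))
    zs <- std_z(sp_obs, sp_null)
    zm <- std_z(cpp_measure(x, e, 3L, bins),
                as.numeric(cpp_permute_y_scores(x, e, perms, 3L, bins)))
    xn <- x / sum(x)
    bp <- std_z(cpp_measure(xn, w_pos, 0L, bins),
                as.numeric(cpp_permute_y_scores(xn, w_pos, perms, 0L, bins)))
    bn <- std_z(cpp_measure(xn, w_neg, 0L, bins),
                as.numeric(cpp_permute_y_scores(xn, w_neg, perms, 0L, bins)))
    zg <- std_z(gblm_obs[t], gblm_null[t, ])
    # Bray-Curtis association evidence points opposite to dissimilarity.
    z_bc <- ((-bp$z) - (-bn$z)) / 2
    z_bc_k <- ((-bp$zk) - (-bn$zk)) / 2
    z_mi <- sign(sp_obs) * zm$z
    z_mi_k <- sign(sp_null) * zm$zk
    combined <- zp$z + zs$z + z_mi + zg$z + z_bc
    combined_k <- zp$zk + zs$zk + z_mi_k + zg$zk + z_bc_k
    p <- (1 + sum(abs(combined_k) >= abs(combined))) / (P + 1)
    data.frame(taxon = t, fraction = fraction,
               z_pearson = zp$z, z_spearman = zs$z, z_mi = z_mi,
               z_gblm = zg$z, z_bray_curtis = z_bc,
               combined = combined, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$combined >= 0, "+", "-")
  class(out) <- c("function_association", "data.frame")
  out
}

#' Strongest positive and negative taxon-function associations
#'
#' Mirrors the study's report layout: the top-k taxa by combined
#' coefficient, descending for the positive table and ascending for the
#' negative one, with a significance star at BH `q <= 0.05`.
#'
#' @param assocs a `function_association` data frame.
#' @param k rows per table (truncated if fewer taxa).
#' @return A list with `positive` and `negative` data frames (`taxon`,
#'   `fraction`, `combined`, `q`, `star`).
#' @export
top_tables <- function(assocs, k = 10) {
  fmt <- function(df) {
    df <- df[, c("taxon", "fraction", "combined", "q")]
    df$star <- ifelse(!is.na(df$q) & df$q <= 0.05, "*", "")
    rownames(df) <- NULL
    df
  }
  if (nrow(assocs) == 0) {
    empty <- fmt(assocs[0, c("taxon", "fraction", "combined", "q")])
    return(list(positive = empty, negative = empty))
  }
  pos <- assocs[order(-assocs$combined), ]
  neg <- assocs[order(assocs$combined), ]
  list(positive = fmt(utils::head(pos, k)),
       negative = fmt(utils::head(neg, k)))
}

#' Rank-based group comparison (exact for small samples)
#'
#' Wilcoxon-Mann-Whitney rank-sum for two groups and Kruskal-Wallis for two
#' or more, with mid-ranks for ties. For small groups (each `n <= 8` and at
#' most `exact_max` distinct label assignments) the permutation
#' distribution is enumerated exhaustively, which stays valid at the
#' triplicate sample sizes typical of enrichment studies where asymptotic
#' approximations are not; otherwise the usual tie-corrected normal /
#' chi-square approximation is used.
#'
#' @param values a list of numeric vectors, one per group (>= 2 groups,
#'   >= 2 values each).
#' @param test `"wilcoxon"` (2 groups) or `"kruskal"`.
#' @param exact_max enumeration cap on the number of assignments.
#' @return List: `statistic` (rank-sum W, or tie-corrected H), `p_value`
#'   (two-sided), `method`, `exact`.
#' @export
group_compare <- function(values, test = c("wilcoxon", "kruskal"),
                          exact_max = 2e5) {
  test <- match.arg(test)
  if (!is.list(values) || length(values) < 2)
    stop("values must be a list of >= 2 groups", call. = FALSE)
  if (any(lengths(values) < 2))
    stop("each group needs >= 2 values", call. = FALSE)
  pooled <- unlist(values)
  N <- length(pooled)
  r <- rank(pooled)  # mid-ranks
  sizes <- lengths(values)
  idx <- split(seq_len(N), rep(seq_along(values), sizes))
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)

  if (test == "wilcoxon") {
    if (length(values) != 2)
      stop("wilcoxon compares exactly 2 groups", call. = FALSE)
    n1 <- sizes[1]; n2 <- sizes[2]
    W <- sum(r[idx[[1]]])
    E <- n1 * (N + 1) / 2
    if (n1 <= 8 && n2 <= 8 && choose(N, n1) <= exact_max) {
      combs <- combn(N, n1)
      Wk <- colSums(matrix(r[combs], nrow = n1))
      p <- mean(abs(Wk - E) >= abs(W - E) - 1e-12)
      return(list(statistic = W, p_value = p,
                  method = "exact Wilcoxon-Mann-Whitney", exact = TRUE))
    }
    v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z <- (W - E) / sqrt(v)
    return(list(statistic = W, p_value = 2 * stats::pnorm(-abs(z)),
                method = "normal-approximation Wilcoxon-Mann-Whitney",
                exact = FALSE))
  }

  kw_h <- function(group_ranks_sums, sizes) {
    H <- 12 / (N * (N + 1)) * sum(group_ranks_sums^2 / sizes) - 3 * (N + 1)
    corr <- 1 - tie_term / (N^3 - N)
    if (corr > 0) H / corr else 0
  }
  H <- kw_h(vapply(idx, function(i) sum(r[i]), numeric(1)), sizes)
  n_arrange <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
  if (all(sizes <= 8) && n_arrange <= exact_max) {
    assignments <- enumerate_assignments(seq_len(N), sizes)
    Hk <- vapply(assignments, function(a)
      kw_h(vapply(a, function(i) sum(r[i]), numeric(1)), sizes),
      numeric(1))
    p <- mean(Hk >= H - 1e-12)
    return(list(statistic = H, p_value = p,
                method = "exact Kruskal-Wallis", exact = TRUE))
  }
  list(statistic = H,
       p_value = stats::pchisq(H, df = length(values) - 1,
                               lower.tail = FALSE),
       method = "chi-square-approximation Kruskal-Wallis", exact = FALSE)
}

# All ways to split `pool` into ordered groups of the given sizes.
enumerate_assignments <- function(pool, sizes) {
  if (length(sizes) == 1) return(list(list(pool)))
  first <- combn(pool, sizes[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- enumerate_assignments(setdiff(pool, f), sizes[-1])
    out <- c(out, lapply(rest, function(rr) c(list(f), rr)))
  }
  out
}

#' Alpha and beta diversity of a consortium table
#'
#' Shannon diversity in nats, Pielou evenness `H / log(S)` with observed
#' richness `S` per sample (defined as 0 for single-taxon samples), and the
#' pairwise Bray-Curtis distance matrix.
#'
#' @param table an [abundance_table] (closed to relative if needed).
#' @return List: `alpha` (data frame `sample_id`, `generation`, `shannon`,
#'   `evenness`, `richness`), `beta` (symmetric distance matrix).
#' @export
community_metrics <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "relative") table <- to_relative(table)
  v <- table$values
  H <- vegan::diversity(v, index = "shannon")  # natural log
  S <- rowSums(v > 0)
  evenness <- ifelse(S > 1, H / log(S), 0)
  beta <- as.matrix(vegan::vegdist(v, method = "bray"))
  list(alpha = data.frame(sample_id = rownames(v),
                          generation = table$generation,
                          shannon = as.numeric(H),
                          evenness = as.numeric(evenness),
                          richness = as.numeric(S),
                          stringsAsFactors = FALSE),
       beta = beta)
}

#' Core, shared and generation-unique taxa
#'
#' Core taxa are present (relative abundance > 1e-9) in more than
#' `prevalence_min` of all samples pooled across generations *and* have
#' mean relative abundance above `abundance_min` across all samples.
#' Shared taxa occur in every generation; unique taxa in exactly one.
#' Raising either threshold can only shrink the core set.
#'
#' @param tables one [abundance_table] with generation metadata, or a named
#'   list of per-generation tables over a common taxon universe.
#' @param prevalence_min prevalence threshold (default 0.80).
#' @param abundance_min mean relative-abundance threshold (default 0.002,
#'   i.e. 0.2%).
#' @return List: `core`, `shared`, `unique` (named list per generation),
#'   `counts` (Venn-style: per-generation present counts, shared count,
#'   unique counts).
#' @export
core_and_unique <- function(tables, prevalence_min = 0.80,
                            abundance_min = 0.002) {
  if (inherits(tables, "abundance_table")) {
    tab <- to_relative(tables)
    v <- tab$values
    gens <- tab$generation
  } else {
    tabs <- lapply(tables, to_relative)
    taxa <- colnames(tabs[[1]]$values)
    if (!all(vapply(tabs, function(t)
      identical(colnames(t$values), taxa), logical(1))))
      stop("per-generation tables must share one taxon universe",
           call. = FALSE)
    v <- do.call(rbind, lapply(tabs, function(t) t$values))
    gens <- unlist(lapply(seq_along(tabs), function(i) {
      g <- tabs[[i]]$generation
      if (!is.null(names(tables))) rep(names(tables)[i], length(g)) else g
    }))
  }
  present <- v > 1e-9
  prevalence <- colMeans(present)
  mean_ab <- colMeans(v)
  taxa <- colnames(v)
  core <- taxa[prevalence > prevalence_min & mean_ab > abundance_min]
  gen_levels <- unique(gens)
  in_gen <- vapply(gen_levels, function(g)
    colSums(present[gens == g, , drop = FALSE]) > 0,
    logical(length(taxa)))
  rownames(in_gen) <- taxa
  shared <- taxa[rowSums(in_gen) == length(gen_levels)]
  uniq <- lapply(setNames(gen_levels, gen_levels), function(g)
    taxa[in_gen[, g] & rowSums(in_gen) == 1])
  list(core = core, shared = shared, unique = uniq,
       presence_by_generation = in_gen,
       counts = list(per_generation = colSums(in_gen),
                     shared = length(shared),
                     unique = vapply(uniq, length, integer(1))))
}
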