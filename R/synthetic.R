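#' Specification for a synthetic consortium experiment
#'
#' Describes a simulated enrichment-transfer study: a compositional
#' genus-abundance table across successive generations with planted
#' taxon-taxon associations, per-generation abundance drift of designated
#' taxa, and degradation-efficiency responses linearly linked (optionally
#' with pairwise synergy) to keystone latent abundances. Defaults mirror the
#' study design the package targets: 4 generations x 3 replicates = 12
#' samples, 30 genera, 50,000 reads per sample.
#'
#' The latent model is log-normal: log-latents are multivariate normal with
#' a correlation matrix encoding `planted_edges`; counts are multinomial
#' draws from the closed latent composition. This makes planted pairwise
#' correlations interpretable on the log scale, the standard benchmarking
#' construction for compositional association methods.
#'
#' @param n_taxa number of genera.
#' @param n_generations number of transfer generations.
#' @param replicates replicates per generation.
#' @param depth sequencing depth (reads per sample), >= 1000.
#' @param planted_edges data frame (`taxon_a`, `taxon_b`, `rho`) of latent
#'   log-scale correlations in \[-1, 1\].
#' @param keystone_effects data frame (`taxon`, `fraction`, `beta`):
#'   efficiency change per SD of the taxon's log-latent abundance.
#' @param synergy_terms optional data frame (`taxon_a`, `taxon_b`,
#'   `fraction`, `beta`): effect of the standardized log latent product.
#' @param generation_drift named numeric: per-generation multiplicative
#'   trend per taxon (taxon in generation g is scaled by `drift^(g-1)`,
#'   so G1 sits at baseline). Unnamed taxa default to 1.
#' @param noise_sd SD of Gaussian noise added to each efficiency.
#' @param baseline named baseline efficiencies per oil fraction.
#' @param control_mass named control residual masses (g) per fraction;
#'   treatment residuals are back-computed from the simulated efficiencies.
#' @param base_log_mean_sd SD of per-taxon mean log abundances (taxon
#'   dominance spread).
#' @param log_sd per-taxon SD of log-latent abundance across samples.
#' @param seed integer seed; all draws use R's default Mersenne-Twister
#'   generator so a fixed seed reproduces the bit stream exactly.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_taxa = 30, n_generations = 4, replicates = 3,
                           depth = 50000,
                           planted_edges = NULL, keystone_effects = NULL,
                           synergy_terms = NULL, generation_drift = NULL,
                           noise_sd = 0.05,
                           baseline = c(TPH = 0.28, saturates = 0.18,
                                        aromatics = 0.06, resins = 0.01,
                                        asphaltenes = 0.005),
                           control_mass = c(TPH = 1.0, saturates = 0.55,
                                            aromatics = 0.25, resins = 0.15,
                                            asphaltenes = 0.05),
                           base_log_mean_sd = 1.25, log_sd = 1.0,
                           seed = 1L) {
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    if (!all(c(planted_edges$taxon_a, planted_edges$taxon_b) %in% taxa))
      stop("planted edge names an unknown taxon", call. = FALSE)
    if (any(abs(planted_edges$rho) > 1))
      stop("planted correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (!is.null(keystone_effects)) {
    keystone_effects <- as.data.frame(keystone_effects)
    if (!all(keystone_effects$taxon %in% taxa))
      stop("keystone effect names an unknown taxon", call. = FALSE)
    if (any(!is.finite(keystone_effects$beta)))
      stop("effect sizes must be finite", call. = FALSE)
  }
  if (!is.null(synergy_terms)) synergy_terms <- as.data.frame(synergy_terms)
  if (depth < 1000) stop("sequencing depth must be >= 1000", call. = FALSE)
  drift <- setNames(rep(1, n_taxa), taxa)
  if (!is.null(generation_drift))
    drift[names(generation_drift)] <- generation_drift
  structure(list(n_taxa = n_taxa, taxa = taxa,
                 n_generations = n_generations, replicates = replicates,
                 depth = depth, planted_edges = planted_edges,
                 keystone_effects = keystone_effects,
                 synergy_terms = synergy_terms, generation_drift = drift,
                 noise_sd = noise_sd, baseline = baseline,
                 control_mass = control_mass,
                 base_log_mean_sd = base_log_mean_sd, log_sd = log_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Correlation matrix implied by planted edges, repaired by shrinkage toward
# the identity until positive definite.
planted_correlation <- function(spec) {
  C <- diag(spec$n_taxa)
  dimnames(C) <- list(spec$taxa, spec$taxa)
  pe <- spec$planted_edges
  if (!is.null(pe) && nrow(pe) > 0) {
    for (k in seq_len(nrow(pe))) {
      i <- pe$taxon_a[k]; j <- pe$taxon_b[k]
      C[i, j] <- C[j, i] <- pe$rho[k]
    }
  }
  s <- 1
  for (step in 1:40) {
    Cs <- s * C + (1 - s) * diag(spec$n_taxa)
    if (min(eigen(Cs, symmetric = TRUE, only.values = TRUE)$values) > 1e-8)
      return(Cs)
    s <- s * 0.9
  }
  stop("planted correlation matrix cannot be repaired to positive definite",
       call. = FALSE)
}

#' Draw latent (pre-sequencing) abundances
#'
#' Log-latents are multivariate normal with the planted correlation
#' structure; per-taxon mean log abundances are drawn once (seeded) to give
#' a realistic dominance spread; generation drift is applied
#' multiplicatively. Output is strictly positive.
#'
#' @param spec a [synthetic_spec].
#' @param seed optional override of `spec$seed`.
#' @return A samples x taxa matrix of positive latent abundances with
#'   attributes `generation` and `replicate`.
#' @export
generate_latent <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_generations * spec$replicates
  gen <- rep(paste0("G", seq_len(spec$n_generations)),
             each = spec$replicates)
  repl <- rep(seq_len(spec$replicates), times = spec$n_generations)
  mu <- rnorm(spec$n_taxa, 0, spec$base_log_mean_sd)
  C <- planted_correlation(spec)
  Z <- matrix(rnorm(n * spec$n_taxa), n, spec$n_taxa) %*% chol(C)
  L <- sweep(spec$log_sd * Z, 2, mu, `+`)
  gidx <- rep(seq_len(spec$n_generations), each = spec$replicates)
  L <- L + outer(gidx - 1, log(spec$generation_drift[spec$taxa]))
  latent <- exp(L)
  dimnames(latent) <- list(
    sprintf("G%d_r%d", gidx, repl), spec$taxa)
  attr(latent, "generation") <- gen
  attr(latent, "replicate") <- repl
  latent
}

#' Multinomial sequencing of latent abundances
#'
#' Each sample's counts are drawn multinomially with probabilities equal to
#' the sample's closed latent composition and total equal to `depth`.
#'
#' @param latent positive matrix from [generate_latent()].
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return A counts-mode [abundance_table].
#' @export
compose_and_count <- function(latent, depth, seed = 1L) {
  if (any(latent <= 0)) stop("latent abundances must be positive",
                             call. = FALSE)
  set.seed(seed)
  counts <- t(apply(latent, 1, function(row)
    rmultinom(1, size = depth, prob = row / sum(row))[, 1]))
  dimnames(counts) <- dimnames(latent)
  abundance_table(counts,
                  generation = attr(latent, "generation"),
                  replicate = attr(latent, "replicate"),
                  mode = "counts")
}

#' Simulate degradation-efficiency responses
#'
#' For each sample and oil fraction, efficiency is the fraction baseline
#' plus keystone effects `beta * z(log latent)` (z = per-taxon
#' standardization across samples, so beta is in efficiency units per SD),
#' plus optional pairwise synergy terms `beta_ij * z(log(latent_i *
#' latent_j))`, plus Gaussian noise, clipped to \[-0.2, 1\]. The control
#' residual mass is fixed per fraction and the treatment residual is
#' back-computed so that [degradation_efficiency()] recovers the simulated
#' value exactly.
#'
#' @param latent matrix from [generate_latent()].
#' @param spec the [synthetic_spec].
#' @param seed integer seed for the response noise.
#' @return A `degradation_record` data frame covering all fractions in
#'   `spec$baseline`.
#' @export
generate_responses <- function(latent, spec, seed = child_seed(spec$seed, 2)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- nrow(latent)
  z <- scale(log(latent))
  z[is.nan(z)] <- 0  # constant taxon across samples carries no signal
  out <- list()
  for (fr in names(spec$baseline)) {
    eff <- rep(spec$baseline[[fr]], n)
    ke <- spec$keystone_effects
    if (!is.null(ke) && nrow(ke) > 0) {
      for (k in which(ke$fraction == fr))
        eff <- eff + ke$beta[k] * z[, ke$taxon[k]]
    }
    sy <- spec$synergy_terms
    if (!is.null(sy) && nrow(sy) > 0) {
      for (k in which(sy$fraction == fr)) {
        zz <- log(latent[, sy$taxon_a[k]] * latent[, sy$taxon_b[k]])
        zz <- as.numeric(scale(zz))
        zz[is.nan(zz)] <- 0
        eff <- eff + sy$beta[k] * zz
      }
    }
    if (spec$noise_sd > 0) eff <- eff + rnorm(n, 0, spec$noise_sd)
    eff <- pmin(pmax(eff, -0.2), 1)
    ctrl <- spec$control_mass[[fr]]
    out[[fr]] <- degradation_record(
      sample_id = rownames(latent),
      generation = attr(latent, "generation"),
      replicate = attr(latent, "replicate"),
      fraction = fr,
      residual_control = ctrl,
      residual_treatment = ctrl * (1 - eff))
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  class(rec) <- c("degradation_record", "data.frame")
  rec
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: latent draw, multinomial sequencing, degradation
#' responses, and the ground truth needed to score recovery downstream.
#'
#' @param spec a [synthetic_spec].
#' @return A list with `counts` (counts-mode table), `relative`
#'   (closed table), `responses` (degradation records), `latent`, and
#'   `truth` (planted edges and keystone effects).
#' @export
simulate_consortium <- function(spec = synthetic_spec()) {
  latent <- generate_latent(spec)
  counts <- compose_and_count(latent, spec$depth,
                              seed = child_seed(spec$seed, 1))
  responses <- generate_responses(latent, spec)
  list(counts = counts, relative = to_relative(counts),
       responses = responses, latent = latent,
       truth = list(planted_edges = spec$planted_edges,
                    keystone_effects = spec$keystone_effects,
                    synergy_terms = spec$synergy_terms))
}
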