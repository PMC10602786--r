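#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage with validated defaults.
#'
#' @param P permutations for ReBoot and function-link nulls (>= 100).
#' @param B bootstraps for ReBoot (>= 100).
#' @param bins MI bin count (`NULL` = `floor(sqrt(n))` capped at 8).
#' @param q_threshold BH q cutoff for network edges, in (0, 1).
#' @param seed global seed; stage seeds are derived deterministically so
#'   stages are independently re-runnable.
#' @param gblm_shrinkage,gblm_iterations boosting parameters.
#' @param measures measure subset (default all five).
#' @param bootstrap use the bootstrap-stabilized observed score.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(P = 200, B = 100, bins = NULL,
                            q_threshold = 0.05, seed = 1L,
                            gblm_shrinkage = 0.1, gblm_iterations = 500,
                            measures = MEASURES, bootstrap = TRUE) {
  if (P < 100 || B < 100)
    stop("P and B must be >= 100", call. = FALSE)
  if (!is.null(bins) && bins < 2) stop("bins must be >= 2", call. = FALSE)
  if (q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must lie in (0, 1)", call. = FALSE)
  structure(list(P = P, B = B, bins = bins, q_threshold = q_threshold,
                 seed = as.integer(seed), gblm_shrinkage = gblm_shrinkage,
                 gblm_iterations = gblm_iterations,
                 measures = match.arg(measures, MEASURES, several.ok = TRUE),
                 bootstrap = bootstrap),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Reproduces the study's analysis shape end to end: (simulated or
#' user-supplied) abundance table and degradation records; per-generation
#' ensemble association networks with BH correction inside each
#' generation's family; key-score tables; combined taxon-function
#' associations for TPH, saturates and aromatics; alpha/beta diversity;
#' core/shared/unique taxa; and a manifest with the configuration, derived
#' stage seeds, and checksums of every written file. Re-running with the
#' same configuration reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param table an [abundance_table], or `NULL` with `simulate = TRUE`.
#' @param responses a `degradation_record` data frame, or `NULL` with
#'   `simulate = TRUE`.
#' @param simulate generate inputs with [simulate_consortium()].
#' @param spec [synthetic_spec()] used when simulating (its seed is
#'   overridden by the pipeline seed).
#' @param fractions oil fractions for the function-link stage.
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_all <- function(config = pipeline_config(), out_dir,
                    table = NULL, responses = NULL, simulate = FALSE,
                    spec = NULL,
                    fractions = c("TPH", "saturates", "aromatics")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (simulate) {
    spec <- spec %||% synthetic_spec()
    spec$seed <- child_seed(config$seed, 1)
    sim <- simulate_consortium(spec)
    table <- sim$counts
    responses <- sim$responses
    truth <- sim$truth
  }
  if (is.null(table) || is.null(responses))
    stop("provide table and responses, or set simulate = TRUE",
         call. = FALSE)
  rel <- to_relative(table)
  paths <- c(abundance = file.path(out_dir, "abundance.tsv"),
             responses = file.path(out_dir, "responses.csv"))
  write_abundance_table(table, paths[["abundance"]])
  write_degradation_records(responses, paths[["responses"]])

  gens <- unique(rel$generation)
  networks <- list(); keyscores <- list(); associations <- list()
  for (gi in seq_along(gens)) {
    g <- gens[gi]
    sub <- subset_samples(rel, rel$generation == g)
    res <- ensemble_associations(
      sub, measures = config$measures, P = config$P, B = config$B,
      seed = child_seed(config$seed, 100 + gi),
      bootstrap = config$bootstrap, bins = config$bins,
      shrinkage = config$gblm_shrinkage,
      iterations = config$gblm_iterations)
    res <- bh_adjust(res)
    net <- build_network(res, q_threshold = config$q_threshold)
    ks <- key_score_table(net)
    associations[[g]] <- res
    networks[[g]] <- net
    keyscores[[g]] <- ks
    p_net <- file.path(out_dir, paste0("network_", g, ".graphml"))
    p_edge <- file.path(out_dir, paste0("network_", g, ".tsv"))
    p_ks <- file.path(out_dir, paste0("keyscores_", g, ".tsv"))
    p_as <- file.path(out_dir, paste0("associations_", g, ".tsv"))
    write_network(net, p_net, format = "graphml")
    write_network(net, p_edge, format = "edgelist")
    write.table(ks, p_ks, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(res), p_as, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[paste0(c("network_", "edgelist_", "keyscores_", "associations_"),
                 g)] <- c(p_net, p_edge, p_ks, p_as)
  }

  funlink <- list()
  for (fi in seq_along(fractions)) {
    fr <- fractions[fi]
    fa <- taxon_function_scores(
      rel, responses, fr, P = max(config$P, 200),
      seed = child_seed(config$seed, 200 + fi), bins = config$bins,
      shrinkage = config$gblm_shrinkage,
      iterations = config$gblm_iterations)
    funlink[[fr]] <- fa
    p_fa <- file.path(out_dir, paste0("function_link_", fr, ".tsv"))
    write.table(as.data.frame(fa), p_fa, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[paste0("function_link_", fr)] <- p_fa
  }

  div <- community_metrics(rel)
  core <- core_and_unique(rel)
  paths[["alpha"]] <- file.path(out_dir, "alpha_diversity.tsv")
  paths[["beta"]] <- file.path(out_dir, "beta_bray_curtis.tsv")
  paths[["core"]] <- file.path(out_dir, "core_taxa.json")
  write.table(div$alpha, paths[["alpha"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(div$beta, paths[["beta"]], sep = "\t", quote = FALSE)
  jsonlite::write_json(core[c("core", "shared", "unique", "counts")],
                       paths[["core"]], auto_unbox = FALSE, pretty = TRUE)

  recovery <- NULL
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = FALSE,
                         pretty = TRUE)
    recovery <- tryCatch(
      recovery_report(truth, networks[[1]], keyscores[[1]], funlink),
      error = function(e) NULL)
    if (!is.null(recovery)) {
      paths[["recovery"]] <- file.path(out_dir, "recovery.json")
      jsonlite::write_json(recovery, paths[["recovery"]],
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oilcomm")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    stage_seeds = list(
      simulate = child_seed(config$seed, 1),
      networks = setNames(
        lapply(seq_along(gens), function(gi) child_seed(config$seed, 100 + gi)),
        gens),
      function_link = setNames(
        lapply(seq_along(fractions),
               function(fi) child_seed(config$seed, 200 + fi)),
        fractions)),
    checksums = as.list(tools::md5sum(unname(paths[file.exists(paths)]))))
  paths[["manifest"]] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(table = table, responses = responses, truth = truth,
                 networks = networks, keyscores = keyscores,
                 associations = associations, function_link = funlink,
                 diversity = div, core = core, recovery = recovery,
                 paths = paths))
}

#' Score a run against the simulator's ground truth
#'
#' Edge precision and recall of the inferred network against the planted
#' edges, sign accuracy on the recovered planted edges, whether each
#' planted keystone appears in the key-score top-k, and whether the planted
#' keystone with the largest effect tops the combined function-link ranking
#' for its fraction.
#'
#' @param truth list with `planted_edges` and `keystone_effects` (as in
#'   [simulate_consortium()]'s `truth`).
#' @param network a [consortium_network].
#' @param keyscores optional [key_score_table()] result.
#' @param assocs optional named list of `function_association` tables.
#' @param k keystone top-k (default 5).
#' @return A list of metrics; undefined ratios are `NA`.
#' @export
recovery_report <- function(truth, network, keyscores = NULL,
                            assocs = NULL, k = 5) {
  pe <- truth$planted_edges
  key <- function(a, b) ifelse(a < b, paste(a, b), paste(b, a))
  out <- list()
  if (!is.null(pe) && nrow(pe) > 0) {
    if (!all(c(pe$taxon_a, pe$taxon_b) %in% network$nodes))
      stop("truth taxa missing from the network's node set", call. = FALSE)
    truth_keys <- key(pe$taxon_a, pe$taxon_b)
    truth_sign <- ifelse(pe$rho >= 0, "+", "-")
    found_keys <- key(network$edges$taxon_a, network$edges$taxon_b)
    tp <- intersect(found_keys, truth_keys)
    out$edge_precision <- if (length(found_keys) > 0)
      length(tp) / length(found_keys) else NA_real_
    out$edge_recall <- length(tp) / length(truth_keys)
    if (length(tp) > 0) {
      got <- network$edges$sign[match(tp, found_keys)]
      want <- truth_sign[match(tp, truth_keys)]
      out$sign_accuracy <- mean(got == want)
    } else out$sign_accuracy <- NA_real_
  }
  ke <- truth$keystone_effects
  if (!is.null(ke) && nrow(ke) > 0 && !is.null(keyscores)) {
    top <- utils::head(rank_keystones(keyscores), k)
    out$keystone_topk_hit <- mean(unique(ke$taxon) %in% top)
  }
  if (!is.null(ke) && nrow(ke) > 0 && !is.null(assocs)) {
    hits <- c()
    for (fr in intersect(unique(ke$fraction), names(assocs))) {
      fa <- assocs[[fr]]
      kef <- ke[ke$fraction == fr, ]
      best_planted <- kef$taxon[which.max(abs(kef$beta))]
      top1 <- fa$taxon[which.max(abs(fa$combined))]
      hits <- c(hits, top1 == best_planted)
    }
    if (length(hits) > 0) out$function_top1_hit <- mean(hits)
  }
  out
}
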