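measure_codes <- c(bray_curtis = 0L, pearson = 1L, spearman = 2L, mi = 3L)

#' The five ensemble association measures
#' @export
MEASURES <- c("bray_curtis", "pearson", "spearman", "mi", "gblm")

default_bins <- function(n) max(2L, min(8L, floor(sqrt(n))))

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`: 0 for identical vectors,
#' 1 for disjoint supports. Not a metric on raw values; only range and
#' identity properties are relied upon.
#'
#' @param x,y non-negative numeric vectors of equal length (>= 2), not both
#'   all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  if (any(x < 0) || any(y < 0))
    stop("Bray-Curtis requires non-negative vectors", call. = FALSE)
  if (sum(x) + sum(y) == 0)
    stop("both vectors are all-zero: dissimilarity undefined", call. = FALSE)
  cpp_measure(x, y, measure_codes[["bray_curtis"]], 2L)
}

#' Pearson and Spearman correlation between abundance vectors
#'
#' Thin, NA-signalling wrappers: a zero-variance vector yields `NA` (the
#' pair is excluded from that measure's evidence, it is not an error).
#' Spearman is Pearson on mid-ranks (average ranks for ties).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_cor <- function(x, y) {
  check_pair(x, y, min_n = 3)
  cpp_measure(x, y, measure_codes[["pearson"]], 2L)
}

#' @rdname pearson_cor
#' @export
spearman_cor <- function(x, y) {
  check_pair(x, y, min_n = 3)
  cpp_measure(x, y, measure_codes[["spearman"]], 2L)
}

#' Mutual information on equal-frequency bins
#'
#' Each vector is discretized into `bins` equal-frequency bins (mid-rank
#' based, so ties share a bin) and the plug-in mutual information of the
#' resulting contingency table is returned in nats. A constant vector
#' occupies a single bin, giving 0. For `y == x` with no ties and `n`
#' divisible by `bins`, the table is diagonal and MI equals `log(bins)`.
#'
#' @param x,y numeric vectors of equal length.
#' @param bins number of bins (>= 2); default `floor(sqrt(n))` capped at 8.
#' @return Mutual information in nats, >= 0.
#' @export
mutual_information <- function(x, y, bins = NULL) {
  check_pair(x, y)
  bins <- as.integer(bins %||% default_bins(length(x)))
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  if (length(x) < bins)
    stop("need at least as many observations as bins", call. = FALSE)
  cpp_measure(x, y, measure_codes[["mi"]], bins)
}

check_pair <- function(x, y, min_n = 2) {
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop("need at least ", min_n, " observations", call. = FALSE)
  invisible(TRUE)
}

#' Boosted linear model (GBLM) association scores for one target taxon
#'
#' Componentwise L2 boosting of a linear model: at each of `iterations`
#' steps the single standardized predictor most correlated with the current
#' residual of the standardized target is selected and its coefficient
#' updated by `shrinkage` times the least-squares fit. The result is a
#' sparse, signed coefficient per predictor taxon (many exactly zero). With
#' a single true predictor and enough iterations the coefficient converges
#' to the OLS slope on standardized data.
#'
#' @param table a relative-mode [abundance_table].
#' @param target taxon identifier (the regression response).
#' @param shrinkage boosting shrinkage `nu` in (0, 1\].
#' @param iterations number of boosting steps `M` (>= 0).
#' @return Named numeric vector of coefficients over the other taxa.
#' @export
gblm_scores <- function(table, target, shrinkage = 0.1, iterations = 500) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (!target %in% colnames(v)) stop("target taxon not in table",
                                     call. = FALSE)
  if (nrow(v) < 3) stop("need at least 3 samples", call. = FALSE)
  if (ncol(v) < 3) stop("need at least 2 predictor taxa", call. = FALSE)
  X <- v[, setdiff(colnames(v), target), drop = FALSE]
  beta <- cpp_gblm(X, v[, target], shrinkage, as.integer(iterations))
  setNames(as.numeric(beta), colnames(X))
}

#' Pairwise association score matrix under one measure
#'
#' Scores every unordered taxon pair of a relative-mode table. The diagonal
#' holds the measure's self-value (0 for Bray-Curtis, 1 for correlations
#' and GBLM, `MI(x, x)` for mutual information). For `gblm` the pairwise
#' score is the mean of the two directed boosting coefficients. Pairs
#' undefined under the measure (zero variance) are `NA`, not an error.
#'
#' @param table a relative-mode [abundance_table].
#' @param measure one of [MEASURES].
#' @param bins MI bin count (see [mutual_information()]).
#' @param shrinkage,iterations GBLM parameters (see [gblm_scores()]).
#' @return A symmetric taxa x taxa matrix.
#' @export
score_matrix <- function(table, measure = MEASURES, bins = NULL,
                         shrinkage = 0.1, iterations = 500) {
  stopifnot(inherits(table, "abundance_table"))
  measure <- match.arg(measure)
  if (table$mode != "relative")
    stop("score_matrix expects a relative-mode table; see to_relative()",
         call. = FALSE)
  v <- table$values
  p <- ncol(v)
  taxa <- colnames(v)
  S <- matrix(NA_real_, p, p, dimnames = list(taxa, taxa))
  if (measure == "gblm") {
    C <- cpp_gblm_all(v, shrinkage, as.integer(iterations))
    S <- (C + t(C)) / 2
    diag(S) <- 1
    dimnames(S) <- list(taxa, taxa)
    return(S)
  }
  code <- measure_codes[[measure]]
  bins <- as.integer(bins %||% default_bins(nrow(v)))
  for (i in seq_len(p)) {
    S[i, i] <- switch(measure,
                      bray_curtis = 0,
                      pearson = 1, spearman = 1,
                      mi = cpp_measure(v[, i], v[, i], code, bins))
    if (i < p) for (j in (i + 1):p) {
      S[i, j] <- S[j, i] <- cpp_measure(v[, i], v[, j], code, bins)
    }
  }
  S
}
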