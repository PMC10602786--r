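#' Construct a genus abundance table
#'
#' The central data container: a samples x taxa matrix of read counts or
#' relative abundances, with a generation label (e.g. "G1".."G4") and a
#' replicate index per sample. In `relative` mode every row is a composition
#' summing to one; in `counts` mode rows are non-negative integers.
#'
#' @param values numeric matrix, samples in rows, taxa in columns; row names
#'   are sample identifiers, column names taxon identifiers.
#' @param generation character vector of per-sample generation labels.
#' @param replicate integer vector of per-sample replicate indices.
#' @param mode `"counts"` or `"relative"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, generation, replicate = NULL,
                            mode = c("relative", "counts")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stop("taxon identifiers (column names) are required", call. = FALSE)
  if (is.null(replicate)) replicate <- seq_len(nrow(values))
  x <- structure(
    list(values = values,
         generation = as.character(generation),
         replicate = as.integer(replicate),
         mode = mode),
    class = "abundance_table")
  validate_abundance_table(x)
}

validate_abundance_table <- function(x) {
  v <- x$values
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("abundance table needs at least 2 samples and 2 taxa", call. = FALSE)
  if (anyNA(v) || any(v < 0))
    stop("abundance values must be non-negative and non-missing",
         call. = FALSE)
  if (anyDuplicated(colnames(v)))
    stop("duplicate taxon identifiers", call. = FALSE)
  if (anyDuplicated(rownames(v)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (length(x$generation) != nrow(v) || length(x$replicate) != nrow(v))
    stop("per-sample metadata length must match the number of samples",
         call. = FALSE)
  if (x$mode == "relative") {
    rs <- rowSums(v)
    if (any(abs(rs - 1) > 1e-9))
      stop("relative-mode rows must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  x
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  cat("generations:", paste(unique(x$generation), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Convert a counts table to relative abundances (row closure)
#'
#' Divides each sample row by its total so rows sum to one. Idempotent:
#' applying it to a relative-mode table returns the table unchanged.
#'
#' @param x an [abundance_table].
#' @return An `abundance_table` in relative mode.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$mode == "relative") return(x)
  rs <- rowSums(x$values)
  if (any(rs == 0))
    stop("degenerate sample: row sums to 0, cannot close", call. = FALSE)
  abundance_table(x$values / rs, x$generation, x$replicate, mode = "relative")
}

#' Subset an abundance table by sample
#'
#' @param x an [abundance_table].
#' @param samples logical or integer index over samples.
#' @return An `abundance_table` over the selected samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "abundance_table"))
  abundance_table(x$values[samples, , drop = FALSE],
                  x$generation[samples], x$replicate[samples], mode = x$mode)
}

#' Read an abundance table from disk
#'
#' The TSV dialect expects a header row, a `sample_id` first column, a
#' `generation` second column, an optional `replicate` column, and one column
#' per taxon. The `biom` dialect accepts a minimal BIOM-format JSON file
#' (dense or sparse `data`, taxa as rows, samples as columns, with a
#' `generation` entry in each column's metadata).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"biom"`.
#' @param mode `"counts"` or `"relative"`; how to interpret stored values.
#' @return An [abundance_table].
#' @export
read_abundance_table <- function(path, dialect = c("tsv", "biom"),
                                 mode = c("counts", "relative")) {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!all(c("sample_id", "generation") %in% names(df)[1:3]))
      stop("TSV table must start with sample_id and generation columns",
           call. = FALSE)
    rep_col <- if ("replicate" %in% names(df)) df$replicate else NULL
    meta <- c("sample_id", "generation", "replicate")
    taxa <- setdiff(names(df), meta)
    v <- as.matrix(df[, taxa, drop = FALSE])
    rownames(v) <- df$sample_id
    abundance_table(v, df$generation, rep_col, mode = mode)
  } else {
    b <- jsonlite::read_json(path, simplifyVector = FALSE)
    taxa <- vapply(b$rows, function(r) r$id, character(1))
    samp <- vapply(b$columns, function(cc) cc$id, character(1))
    gen <- vapply(b$columns, function(cc) {
      g <- cc$metadata$generation
      if (is.null(g)) NA_character_ else as.character(g)
    }, character(1))
    v <- matrix(0, nrow = length(samp), ncol = length(taxa),
                dimnames = list(samp, taxa))
    if (identical(b$matrix_type, "dense")) {
      for (i in seq_along(b$data))
        v[, i] <- unlist(b$data[[i]])  # row i of BIOM = taxon i
    } else {
      for (trip in b$data) {
        trip <- unlist(trip)
        v[trip[2] + 1, trip[1] + 1] <- trip[3]  # BIOM triples are 0-based
      }
    }
    abundance_table(v, gen, mode = mode)
  }
}

#' Write an abundance table as TSV
#'
#' Emits the dialect read back by [read_abundance_table()]: `sample_id`,
#' `generation`, `replicate`, then one column per taxon, at full double
#' precision so a round trip reproduces the table exactly.
#'
#' @param x an [abundance_table].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(sample_id = rownames(x$values),
                   generation = x$generation,
                   replicate = x$replicate,
                   check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.data.frame(x$values, check.names = FALSE)
  for (j in seq_along(vals)) vals[[j]] <- sprintf("%.17g", vals[[j]])
  out <- cbind(df, vals)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
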