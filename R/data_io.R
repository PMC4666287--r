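#' Read a gene-by-sample count matrix
#'
#' Reads a delimited table with gene identifiers in the first column and one
#' header row of sample identifiers, and validates it as an RNA-seq read
#' count matrix: all entries must be non-negative integers and gene/sample
#' identifiers must be unique.
#'
#' @param path Path to the counts file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return An integer matrix (genes in rows) with gene ids as row names and
#'   sample ids as column names, in file order.
#' @export
read_counts <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("counts file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("counts file needs a gene-id column plus >= 1 sample")
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "counts must be non-negative integers; first offending entry '%s' at gene '%s', sample '%s'",
      vals[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
      sample_ids[bad[1L, 2L]]))
  }
  counts <- matrix(as.integer(num), nrow = nrow(num),
                   dimnames = list(gene_ids, sample_ids))
  validate_counts(counts)
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: writes the matrix with a `gene_id` first
#' column and a sample-id header row.
#'
#' @param counts Integer count matrix with row and column names.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_counts <- function(counts, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  counts <- validate_counts(counts)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- data.frame(gene_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a count matrix
#'
#' @param counts Matrix of read counts, genes in rows.
#' @return The matrix with integer storage, invisibly checked.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix (genes x samples)")
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    stop("need at least 1 gene and 2 samples")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"
  counts
}

#' Construct a covariate table
#'
#' Bundles per-sample explanatory variables with their declared types and,
#' for categorical variables, level orderings (first level = reference).
#' Variable 1 is always the factor of primary scientific interest; the
#' constructor reorders columns so the primary factor comes first.
#'
#' @param data A data.frame, one row per sample, with sample ids as row names.
#' @param primary Name of the factor of primary interest (categorical,
#'   at least 2 levels).
#' @param types Optional named character vector mapping variable names to
#'   `"categorical"` or `"continuous"`. Undeclared variables default to
#'   continuous for numeric columns (with a warning) and categorical for
#'   character/factor columns.
#' @param levels Optional named list of level orderings for categorical
#'   variables; default is lexicographic.
#' @return An object of class `covariate_table` with elements `data`
#'   (typed data.frame, primary factor first), `var_names`, `var_types`,
#'   `primary` (always 1), and `sample_ids`.
#' @export
covariate_table <- function(data, primary, types = NULL, levels = NULL) {
  if (!is.data.frame(data)) stop("data must be a data.frame")
  if (anyNA(data)) stop("covariate table contains missing values")
  if (is.null(rownames(data)) ||
      identical(rownames(data), as.character(seq_len(nrow(data)))))
    stop("data must have sample ids as row names")
  if (!primary %in% colnames(data))
    stop("primary factor '", primary, "' not found")

  nm <- colnames(data)
  vt <- character(length(nm))
  names(vt) <- nm
  for (v in nm) {
    if (!is.null(types) && v %in% names(types)) {
      vt[v] <- match.arg(types[[v]], c("categorical", "continuous"))
    } else if (is.numeric(data[[v]])) {
      vt[v] <- "continuous"
      if (v != primary && (is.null(types) || !v %in% names(types)))
        message("variable '", v, "' has no declared type; treating as continuous")
    } else {
      vt[v] <- "categorical"
    }
  }
  vt[primary] <- "categorical"

  for (v in nm) {
    if (vt[v] == "categorical") {
      lev <- if (!is.null(levels) && v %in% names(levels)) levels[[v]]
             else sort(unique(as.character(data[[v]])))
      obs <- unique(as.character(data[[v]]))
      if (!all(obs %in% lev))
        stop("variable '", v, "' has values outside declared levels")
      f <- factor(as.character(data[[v]]), levels = lev)
      f <- droplevels(f)
      if (nlevels(f) < 2L)
        stop("categorical variable '", v, "' has fewer than 2 observed levels")
      data[[v]] <- f
    } else {
      x <- data[[v]]
      if (!is.numeric(x)) {
        x <- suppressWarnings(as.numeric(as.character(x)))
        if (anyNA(x)) stop("variable '", v, "' is not numeric")
      }
      if (length(unique(x)) < 2L)
        stop("continuous variable '", v, "' is constant")
      data[[v]] <- x
    }
  }

  data <- data[, c(primary, setdiff(nm, primary)), drop = FALSE]
  structure(list(
    data = data,
    var_names = colnames(data),
    var_types = unname(vt[colnames(data)]),
    primary = 1L,
    sample_ids = rownames(data)
  ), class = "covariate_table")
}

#' @export
print.covariate_table <- function(x, ...) {
  cat("covariate_table:", nrow(x$data), "samples,", length(x$var_names),
      "variables\n")
  cat("  primary factor:", x$var_names[1L], "(",
      nlevels(x$data[[1L]]), "levels )\n")
  for (j in seq_along(x$var_names)[-1L])
    cat("  ", x$var_names[j], ":", x$var_types[j], "\n")
  invisible(x)
}

#' Read a covariate table from CSV
#'
#' The file must have sample ids in its first column. Variable typing comes
#' from a config: either a YAML/JSON file path or a list with elements
#' `primary` (variable name) and optionally `variables`, a list of
#' `{name, type, levels}` records.
#'
#' @param path CSV file, column 1 = sample id.
#' @param config Config list or path to a YAML/JSON file.
#' @param sample_ids Optional character vector (e.g. `colnames` of a count
#'   matrix); rows are realigned to this order and all ids must be present.
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path, config, sample_ids = NULL) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  if (is.null(config$primary)) stop("config must name the primary factor")
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in covariate file")
  df <- tab[, -1L, drop = FALSE]
  rownames(df) <- ids
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, ids)
    if (length(miss) > 0L)
      stop("covariate file is missing samples: ", paste(miss, collapse = ", "))
    df <- df[sample_ids, , drop = FALSE]
  }
  types <- NULL; lev <- NULL
  for (v in config$variables) {
    if (!is.null(v$type)) types[[v$name]] <- v$type
    if (!is.null(v$levels)) lev[[v$name]] <- v$levels
  }
  covariate_table(df, primary = config$primary, types = types, levels = lev)
}

#' Filter genes on mean count and zero-count proportion
#'
#' Keeps the genes with mean read count at least `min_mean` and a proportion
#' of zero counts no greater than `max_zero_frac`. The defaults encode the
#' common rule of requiring an average count of at least 8 and, for an
#' n = 31 design, no more than 27 zero counts.
#'
#' @param counts Count matrix (genes in rows).
#' @param min_mean Minimum mean count per gene.
#' @param max_zero_frac Maximum allowed proportion of zero counts per gene.
#' @return The filtered count matrix, gene order preserved.
#' @export
filter_genes <- function(counts, min_mean = 8, max_zero_frac = 27 / 31) {
  counts <- validate_counts(counts)
  stopifnot(min_mean >= 0, max_zero_frac >= 0, max_zero_frac <= 1)
  keep <- rowMeans(counts) >= min_mean &
    rowMeans(counts == 0) <= max_zero_frac
  if (!any(keep))
    stop("all genes removed by filtering; lower min_mean or raise max_zero_frac")
  counts[keep, , drop = FALSE]
}

#' Upper-quantile normalization offsets
#'
#' The offset for sample i is the natural log of the `q` quantile
#' (default 0.75) of that sample's read counts, computed with the
#' interpolation-based type-7 quantile estimator unless another type is
#' requested. Offsets enter the gene-wise log-linear models additively on
#' the log-mean scale.
#'
#' @param counts Count matrix (genes in rows); filter first so that the
#'   quantile is positive.
#' @param q Quantile in (0, 1); default 0.75.
#' @param type Quantile algorithm passed to [stats::quantile()]; default 7.
#' @return Numeric vector of per-sample offsets, named by sample id.
#' @export
compute_offsets <- function(counts, q = 0.75, type = 7) {
  counts <- validate_counts(counts)
  stopifnot(q > 0, q < 1)
  qs <- apply(counts, 2L, stats::quantile, probs = q, type = type,
              names = FALSE)
  if (any(qs <= 0))
    stop("zero ", q, "-quantile for sample(s) ",
         paste(colnames(counts)[qs <= 0], collapse = ", "),
         "; apply stronger gene filtering first")
  stats::setNames(log(qs), colnames(counts))
}

#' Build a design matrix for a set of model variables
#'
#' Builds the n x p model matrix for the variables whose indices are in `S`:
#' an intercept column plus, for each variable, a reference-coded indicator
#' block (categorical; first level = reference, block width = levels - 1) or
#' a single column taken as given (continuous). Codings for a variable do
#' not depend on which other variables are present.
#'
#' @param ct A [covariate_table()].
#' @param S Integer vector of variable indices; must contain 1 (the primary
#'   factor).
#' @return A list of class `design_matrix` with `matrix`, `blocks` (named
#'   list mapping each variable index to its column indices), and `S`.
#' @export
design_matrix <- function(ct, S) {
  stopifnot(inherits(ct, "covariate_table"))
  S <- sort(unique(as.integer(S)))
  k <- length(ct$var_names)
  if (!1L %in% S) stop("S must contain the primary factor (index 1)")
  if (any(S < 1L | S > k)) stop("variable index out of range")

  cols <- list(`(Intercept)` = rep(1, nrow(ct$data)))
  blocks <- list()
  nxt <- 2L
  for (j in S) {
    v <- ct$var_names[j]
    x <- ct$data[[j]]
    if (ct$var_types[j] == "categorical") {
      lev <- levels(x)
      blk <- vapply(lev[-1L], function(l) as.numeric(x == l),
                    numeric(length(x)))
      colnames(blk) <- paste0(v, lev[-1L])
      for (cn in colnames(blk)) cols[[cn]] <- blk[, cn]
      w <- length(lev) - 1L
    } else {
      cols[[v]] <- x
      w <- 1L
    }
    blocks[[as.character(j)]] <- seq.int(nxt, length.out = w)
    nxt <- nxt + w
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ct$sample_ids

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    depvars <- unique(unlist(lapply(names(blocks), function(j) {
      if (any(blocks[[j]] %in% match(dropped, colnames(X))))
        ct$var_names[as.integer(j)] else NULL
    })))
    stop("design matrix is rank deficient; linearly dependent columns: ",
         paste(dropped, collapse = ", "),
         if (length(depvars)) paste0(" (variables: ",
                                     paste(depvars, collapse = ", "), ")"))
  }
  structure(list(matrix = X, blocks = blocks, S = S),
            class = "design_matrix")
}

# columns of a design after dropping variable j's block
drop_block <- function(dm, j) {
  key <- as.character(j)
  if (!key %in% names(dm$blocks)) stop("variable ", j, " not in design")
  drop_cols <- dm$blocks[[key]]
  X <- dm$matrix[, -drop_cols, drop = FALSE]
  list(matrix = X, df1 = length(drop_cols))
}
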