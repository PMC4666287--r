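#' Per-iteration p-value histogram report
#'
#' Summarizes a selection trace as, for each iteration, the 20-bin
#' histogram counts of every remaining variable's p-values (right-closed
#' bins, p = 0 in bin 1), the relevance scores, the removed variable, and
#' the number of discoveries. Bin counts sum to the number of non-missing
#' p-values. When plotted, each histogram should be scaled to its own
#' tallest bar: relevant and irrelevant covariates differ by orders of
#' magnitude in the first bin, and a common vertical axis hides the shape
#' of the flat ones.
#'
#' @param trace A `selection_trace`.
#' @param bins Number of histogram bins (default 20).
#' @return A list of per-iteration records, class `iteration_report`.
#' @export
pvalue_histograms <- function(trace, bins = 20L) {
  stopifnot(inherits(trace, "selection_trace"))
  reports <- lapply(trace$iterations, function(it) {
    H <- apply(it$pvalues, 2L, function(p) {
      p <- p[!is.na(p)]
      tabulate(pmax(ceiling(p * bins), 1L), nbins = bins)
    })
    list(ell = it$ell, counts = H, relevance = it$relevance,
         removed = if (is.na(it$removed)) NA_character_
                   else trace$var_names[it$removed],
         R = it$R)
  })
  structure(list(iterations = reports, bins = bins,
                 var_names = trace$var_names, alpha = trace$alpha),
            class = "iteration_report")
}

#' Render a selection trace as a table
#'
#' Produces the variables-by-iterations relevance grid: one row per
#' variable with its relevance score at each iteration it was still in the
#' model (blank afterwards), plus a final row with the discovery counts
#' R_l(alpha). Formats: `"tsv"` or `"markdown"` (returned as a character
#' vector of lines).
#'
#' @param trace A `selection_trace`.
#' @param format `"tsv"` or `"markdown"`.
#' @param digits Digits for relevance values (GKS measure).
#' @return Character vector of lines, invisibly also printed if
#'   interactive. The grid is a pure function of the persisted trace.
#' @export
render_trace <- function(trace, format = c("tsv", "markdown"), digits = 3) {
  stopifnot(inherits(trace, "selection_trace"))
  format <- match.arg(format)
  L <- trace$L
  vars <- trace$var_names
  grid <- matrix("", nrow = length(vars) + 1L, ncol = L + 1L)
  grid[, 1L] <- c(vars, sprintf("R(%g)", trace$alpha))
  fmt <- function(x) {
    if (trace$measure == "p05") as.character(x)
    else formatC(x, digits = digits, format = "g")
  }
  for (it in trace$iterations) {
    col <- it$ell + 1L
    for (idx in seq_along(it$S))
      grid[it$S[idx], col] <- fmt(it$relevance[idx])
    grid[length(vars) + 1L, col] <- as.character(it$R)
  }
  header <- c("variable", paste0("iter", seq_len(L)))
  if (format == "tsv") {
    lines <- c(paste(header, collapse = "\t"),
               apply(grid, 1L, paste, collapse = "\t"))
  } else {
    lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
               paste0("|", paste(rep("---", L + 1L), collapse = "|"), "|"),
               apply(grid, 1L, function(r)
                 paste0("| ", paste(r, collapse = " | "), " |")))
  }
  lines
}

#' Write selection outputs to a directory
#'
#' Persists a trace the way the command-line interface does: `trace.tsv`
#' (the [render_trace()] grid), `pvalues_iter<l>.tsv` per iteration, and
#' `selected_model.json` with the chosen variable set.
#'
#' @param trace A `selection_trace`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(render_trace(trace, "tsv"), file.path(dir, "trace.tsv"))
  for (it in trace$iterations) {
    ids <- rownames(it$pvalues)
    if (is.null(ids)) ids <- paste0("g", seq_len(nrow(it$pvalues)))
    utils::write.table(
      data.frame(gene = ids, it$pvalues, check.names = FALSE),
      file.path(dir, sprintf("pvalues_iter%d.tsv", it$ell)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(S_hat = trace$S_hat, variables = trace$var_names[trace$S_hat],
         ell_star = trace$ell_star, alpha = trace$alpha,
         measure = trace$measure, R = trace$R),
    file.path(dir, "selected_model.json"), auto_unbox = TRUE)
  invisible(dir)
}
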