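#' Read a two-column association table
#'
#' Reads one binary association layer (e.g. miRNA-disease) from a delimited
#' text file. The first two fields of every non-empty, non-comment line are
#' taken as an associated pair of entity names; duplicate pairs are dropped
#' with a message. Files ending in `.csv` are split on commas, everything
#' else on runs of tabs/spaces.
#'
#' @param path Path to the file.
#' @param col_names Length-2 character vector naming the output columns,
#'   typically the two entity roles (e.g. `c("mirna", "disease")`).
#' @param delim Field delimiter; `NULL` (default) autodetects from the file
#'   extension.
#' @param header If `TRUE`, the first retained line is discarded as a header.
#' @param comment Lines starting with this prefix are skipped.
#'
#' @return A tibble with two character columns, one row per unique pair.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("m1\td1", "m1\td1", "m2\td1"), f)
#' read_associations(f, c("mirna", "disease"))
#' @export
read_associations <- function(path, col_names = c("from", "to"), delim = NULL,
                              header = FALSE, comment = "#") {
  if (!file.exists(path)) {
    stop_io(sprintf("Association file not found: '%s'.", path))
  }
  stopifnot(length(col_names) == 2L)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "[\t ]+"
  }

  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment)
  lineno <- which(keep)
  lines <- lines[keep]
  if (header && length(lines) > 0L) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (length(lines) == 0L) {
    stop_io(sprintf("'%s': no associations (file is empty).", path))
  }

  fields <- strsplit(trimws(lines), delim)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop_io(sprintf("'%s': line %d has fewer than 2 fields.",
                    path, lineno[bad[1L]]))
  }
  left <- trimws(vapply(fields, `[[`, "", 1L))
  right <- trimws(vapply(fields, `[[`, "", 2L))
  empty <- which(!nzchar(left) | !nzchar(right))
  if (length(empty) > 0L) {
    stop_io(sprintf("'%s': line %d has an empty entity name.",
                    path, lineno[empty[1L]]))
  }

  tab <- tibble(!!col_names[1L] := left, !!col_names[2L] := right)
  n0 <- nrow(tab)
  tab <- dplyr::distinct(tab)
  if (nrow(tab) < n0) {
    inform(sprintf("Removed %d duplicate pair(s) from '%s'.",
                   n0 - nrow(tab), path))
  }
  tab
}

# Clean a user-supplied edge data frame down to unique trimmed string pairs.
as_pairs <- function(df, what) {
  if (!is.data.frame(df) || ncol(df) < 2L) {
    stop_param(sprintf("`%s` must be a data frame with at least 2 columns.", what))
  }
  left <- trimws(as.character(df[[1L]]))
  right <- trimws(as.character(df[[2L]]))
  if (any(!nzchar(left)) || any(!nzchar(right)) ||
      anyNA(left) || anyNA(right)) {
    stop_param(sprintf("`%s` contains empty or missing entity names.", what))
  }
  unique(data.frame(left = left, right = right, stringsAsFactors = FALSE))
}

binary_layer <- function(pairs, rows, cols) {
  A <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  A[cbind(match(pairs$left, rows), match(pairs$right, cols))] <- 1
  A
}

new_tripartite_graph <- function(A_md, A_ml, A_dl, stage, A_md0 = NULL,
                                 A_ml0 = NULL, recommendations = NULL) {
  structure(
    list(
      A_md = A_md, A_ml = A_ml, A_dl = A_dl,
      A_md0 = A_md0 %||% A_md, A_ml0 = A_ml0 %||% A_ml,
      stage = stage, recommendations = recommendations
    ),
    class = "tripartite_graph"
  )
}

#' Build a miRNA-disease-lncRNA tripartite graph from three edge tables
#'
#' Joins the three binary association layers into one object holding aligned
#' adjacency matrices. Entity indexes are the union of names per role across
#' all tables, so an entity appearing in only one layer keeps an all-zero
#' row/column in the others (this is what allows scoring diseases with no
#' known miRNA at all).
#'
#' @param md Data frame of miRNA-disease pairs (columns: miRNA, disease).
#' @param ml Data frame of miRNA-lncRNA pairs (columns: miRNA, lncRNA).
#' @param dl Data frame of disease-lncRNA pairs (columns: disease, lncRNA).
#' @param ordering `"lexicographic"` (default; locale-independent, so runs
#'   are reproducible across machines) or `"input"` (first-appearance order).
#'
#' @return A `tripartite_graph`: list with binary matrices `A_md`
#'   (miRNA x disease), `A_ml` (miRNA x lncRNA), `A_dl` (disease x lncRNA),
#'   and a `stage` flag (`"initial"` until [update_graph()] adds
#'   recommended edges).
#' @examples
#' g <- tripartite_graph(
#'   md = data.frame(mirna = "m1", disease = "d1"),
#'   ml = data.frame(mirna = c("m1", "m2"), lncrna = "l1"),
#'   dl = data.frame(disease = "d1", lncrna = "l1")
#' )
#' g
#' @export
tripartite_graph <- function(md, ml, dl,
                             ordering = c("lexicographic", "input")) {
  ordering <- match.arg(ordering)
  md <- as_pairs(md, "md")
  ml <- as_pairs(ml, "ml")
  dl <- as_pairs(dl, "dl")

  order_names <- function(x) {
    x <- unique(x)
    if (ordering == "lexicographic") sort_c(x) else x
  }
  mirnas <- order_names(c(md$left, ml$left))
  diseases <- order_names(c(md$right, dl$left))
  lncrnas <- order_names(c(ml$right, dl$right))

  new_tripartite_graph(
    A_md = binary_layer(md, mirnas, diseases),
    A_ml = binary_layer(ml, mirnas, lncrnas),
    A_dl = binary_layer(dl, diseases, lncrnas),
    stage = "initial"
  )
}

#' @export
print.tripartite_graph <- function(x, ...) {
  cat(sprintf(
    "<tripartite_graph> stage: %s\n  %d miRNAs, %d diseases, %d lncRNAs\n",
    x$stage, nrow(x$A_md), ncol(x$A_md), ncol(x$A_ml)
  ))
  cat(sprintf("  edges: %d miRNA-disease, %d miRNA-lncRNA, %d disease-lncRNA\n",
              sum(x$A_md), sum(x$A_ml), sum(x$A_dl)))
  if (!is.null(x$recommendations)) {
    cat(sprintf("  recommended edges added: %d\n", nrow(x$recommendations)))
  }
  invisible(x)
}

#' Splice the miRNA-lncRNA and miRNA-disease layers into one matrix
#'
#' Row k of the result is the concatenated neighbourhood indicator of miRNA
#' k over lncRNAs (first `n_l` columns) then diseases (last `n_d` columns);
#' its row sum is the total neighbour count used by the co-occurrence
#' similarity.
#'
#' @param g A [tripartite_graph()].
#' @param stage Which layers to splice: the initial matrices (`"initial"`,
#'   default — similarity is always computed on the graph before any edges
#'   are recommended) or the current ones (`"current"`).
#' @return Binary matrix of dimension `n_m x (n_l + n_d)`.
#' @export
splice_mld <- function(g, stage = c("initial", "current")) {
  stopifnot(inherits(g, "tripartite_graph"))
  stage <- match.arg(stage)
  if (stage == "initial") cbind(g$A_ml0, g$A_md0) else cbind(g$A_ml, g$A_md)
}

#' Recover the three edge tables from a tripartite graph
#'
#' Inverse of [tripartite_graph()]: lists the nonzero entries of each layer.
#'
#' @param g A [tripartite_graph()].
#' @return Named list of three tibbles (`md`, `ml`, `dl`).
#' @export
as_association_tables <- function(g) {
  stopifnot(inherits(g, "tripartite_graph"))
  melt <- function(A, names) {
    idx <- which(A == 1, arr.ind = TRUE)
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    tibble(!!names[1L] := rownames(A)[idx[, 1L]],
           !!names[2L] := colnames(A)[idx[, 2L]])
  }
  list(md = melt(g$A_md, c("mirna", "disease")),
       ml = melt(g$A_ml, c("mirna", "lncrna")),
       dl = melt(g$A_dl, c("disease", "lncrna")))
}

#' Write the three edge tables of a graph as TSV files
#'
#' @param g A [tripartite_graph()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix; files are `<prefix>_md.tsv`, `_ml.tsv`,
#'   `_dl.tsv`.
#' @return Invisibly, the three file paths.
#' @export
write_tripartite <- function(g, dir, prefix = "graph") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- as_association_tables(g)
  paths <- file.path(dir, paste0(prefix, "_", names(tabs), ".tsv"))
  purrr::walk2(tabs, paths, ~ readr::write_tsv(.x, .y, col_names = FALSE))
  invisible(stats::setNames(paths, names(tabs)))
}

match_disease <- function(scores, disease) {
  diseases <- colnames(scores$final)
  j <- match(disease, diseases)
  if (is.na(j)) {
    near <- utils::head(agrep(disease, diseases, value = TRUE,
                              ignore.case = TRUE, max.distance = 0.3), 5L)
    hint <- if (length(near)) paste0(" Did you mean: ",
                                     paste(near, collapse = ", "), "?") else ""
    stop_param(sprintf("Disease '%s' is not in the score matrix.%s",
                       disease, hint))
  }
  j
}

#' Rank all candidate miRNAs for one disease
#'
#' Sorts the final resource scores of one disease in descending order, tied
#' scores broken by miRNA index order. Known associations (1-entries of the
#' original, pre-recommendation miRNA-disease layer) are kept in the list
#' and flagged, mirroring how published candidate tables mark "known
#' before" entries. A disease with no known miRNA still gets a full
#' ranking.
#'
#' @param scores A [resource_scores()] result.
#' @param disease Disease name (must be in the index; close matches are
#'   suggested on error).
#' @param top Optionally keep only the first `top` rows.
#' @return Tibble with columns `mirna`, `rank`, `rscore_final`,
#'   `known_before` (0/1).
#' @export
rank_mirnas <- function(scores, disease, top = NULL) {
  stopifnot(inherits(scores, "resource_scores"))
  j <- match_disease(scores, disease)
  s <- scores$final[, j]
  known <- as.integer(scores$known0[, j] == 1)
  ord <- order(-s, seq_along(s))
  out <- tibble(
    mirna = rownames(scores$final)[ord],
    rank = seq_along(ord),
    rscore_final = unname(s[ord]),
    known_before = known[ord]
  )
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Write the ranked miRNA list of one disease to a TSV file
#'
#' @inheritParams rank_mirnas
#' @param path Output file path.
#' @return Invisibly, the ranking tibble.
#' @export
write_ranked_list <- function(scores, disease, path, top = NULL) {
  out <- rank_mirnas(scores, disease, top = top)
  readr::write_tsv(out, path)
  invisible(out)
}
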