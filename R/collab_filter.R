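#' miRNA-miRNA co-occurrence similarity
#'
#' Two miRNAs are similar to the extent that they share neighbours
#' (lncRNAs or diseases) in the initial tripartite graph. The normalized
#' similarity is the shared-neighbour count divided by the geometric mean
#' of the two neighbourhood sizes — i.e. the cosine similarity of the
#' binary rows of the spliced `[A_ml, A_md]` matrix. Pairs where either
#' miRNA has no neighbour at all are defined as 0.
#'
#' @param g A [tripartite_graph()] (the initial layers are used).
#' @return A `mirna_similarity` object: list with the binary co-occurrence
#'   matrix `R` (1 iff the pair shares at least one neighbour) and the
#'   normalized matrix `R_nor` in `[0, 1]`, both `n_m x n_m`.
#' @seealso [recommender_matrix()], [oracle_similarity()]
#' @export
mirna_similarity <- function(g) {
  stopifnot(inherits(g, "tripartite_graph"))
  M <- splice_mld(g, "initial")
  shared <- M %*% t(M)              # |N(m_k) intersect N(m_r)|
  deg <- rowSums(M)                 # |N(m_k)|
  if (all(deg == 0)) {
    warn("All miRNAs are isolated; similarity matrix is all zero.")
  }
  denom <- sqrt(outer(deg, deg))
  R_nor <- ifelse(denom > 0, shared / denom, 0)
  structure(
    list(R = (shared > 0) * 1, R_nor = R_nor),
    class = "mirna_similarity"
  )
}

#' @export
print.mirna_similarity <- function(x, ...) {
  n <- nrow(x$R_nor)
  cat(sprintf("<mirna_similarity> %d x %d; %d co-occurring pairs (off-diagonal)\n",
              n, n, sum(x$R[upper.tri(x$R)])))
  invisible(x)
}

#' @describeIn mirna_similarity Long tibble of the upper-triangular
#'   normalized similarities (`mirna_a`, `mirna_b`, `r_nor`).
#' @param x,... Method arguments.
#' @export
tidy.mirna_similarity <- function(x, ...) {
  idx <- which(upper.tri(x$R_nor, diag = FALSE), arr.ind = TRUE)
  tibble(
    mirna_a = rownames(x$R_nor)[idx[, 1L]],
    mirna_b = colnames(x$R_nor)[idx[, 2L]],
    r_nor = x$R_nor[idx]
  )
}

#' Recommender matrix and per-column thresholds
#'
#' Propagates each column of the spliced initial adjacency through the
#' miRNA similarity: `A_u_mld = R_nor %*% [A_ml, A_md]`. Each column
#' (one lncRNA or disease) also gets its averaged value P, the threshold a
#' miRNA's propagated score must strictly exceed to be recommended.
#'
#' @param sim A [mirna_similarity()] result for the same graph.
#' @param g The [tripartite_graph()].
#' @param p_denominator How the averaged value P of a column is computed:
#'   `"all_rows"` (default) divides the column sum by the number of
#'   miRNAs; `"nonzero_rows"` divides by the number of strictly positive
#'   entries in that column.
#' @return A `recommender_matrix` object: list with `A_u_mld`
#'   (`n_m x (n_l + n_d)`, nonnegative), `column_avgs` (the P values),
#'   `n_l`, and the `p_denominator` used.
#' @export
recommender_matrix <- function(sim, g,
                               p_denominator = c("all_rows", "nonzero_rows")) {
  stopifnot(inherits(sim, "mirna_similarity"), inherits(g, "tripartite_graph"))
  p_denominator <- match.arg(p_denominator)
  A0 <- splice_mld(g, "initial")
  A_u <- sim$R_nor %*% A0
  denom <- switch(p_denominator,
    all_rows = rep(nrow(A_u), ncol(A_u)),
    nonzero_rows = pmax(colSums(A_u > 0), 1L)
  )
  structure(
    list(A_u_mld = A_u, column_avgs = colSums(A_u) / denom,
         n_l = ncol(g$A_ml0), p_denominator = p_denominator),
    class = "recommender_matrix"
  )
}

#' Recommend new miRNA edges from the recommender matrix
#'
#' For every lncRNA/disease column that already has at least one known
#' associated miRNA, every miRNA whose propagated score strictly exceeds
#' the column's averaged value P — and which is not already associated —
#' is recommended as a new edge. Columns with no known association receive
#' no recommendations (they are still scored downstream by the
#' lncRNA-mediated propagation).
#'
#' @param rec A [recommender_matrix()] computed from `g`.
#' @param g The [tripartite_graph()].
#' @return Tibble with one row per recommended edge: `mirna`, `target`,
#'   `role` (`"lncrna"` or `"disease"`), `score` (the propagated value).
#' @export
recommend_edges <- function(rec, g) {
  stopifnot(inherits(rec, "recommender_matrix"), inherits(g, "tripartite_graph"))
  A0 <- splice_mld(g, "initial")
  A_u <- rec$A_u_mld
  P <- rec$column_avgs
  hits <- purrr::map(seq_len(ncol(A0)), function(c) {
    if (!any(A0[, c] == 1)) return(NULL)       # gating: no known miRNA
    theta <- which(A_u[, c] > P[c] & A0[, c] == 0)
    if (length(theta) == 0L) return(NULL)
    tibble(mirna = rownames(A0)[theta], col = c,
           score = unname(A_u[theta, c]))
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(mirna = character(), target = character(),
                  role = character(), score = double()))
  }
  n_l <- rec$n_l
  tibble(
    mirna = out$mirna,
    target = colnames(A0)[out$col],
    role = ifelse(out$col <= n_l, "lncrna", "disease"),
    score = out$score
  )
}

#' Add recommended edges to the graph
#'
#' Writes each recommended edge as a 1 into the miRNA-lncRNA or
#' miRNA-disease layer (the downstream resource allocation consumes binary
#' adjacency and integer degrees, so recommended edges carry no weight).
#' The disease-lncRNA layer and the stored initial layers are untouched;
#' no existing edge is ever removed.
#'
#' @param g A [tripartite_graph()] with `stage = "initial"`.
#' @param recs A recommendation tibble from [recommend_edges()].
#' @param quiet Suppress the per-layer count message.
#' @return The updated graph (`stage = "updated"`), with the
#'   recommendations stored in `$recommendations`.
#' @export
update_graph <- function(g, recs, quiet = FALSE) {
  stopifnot(inherits(g, "tripartite_graph"))
  if (g$stage != "initial") {
    stop_param("`g` has already been updated; recommend edges only once.")
  }
  A_md <- g$A_md
  A_ml <- g$A_ml
  if (nrow(recs) > 0L) {
    d <- recs[recs$role == "disease", , drop = FALSE]
    l <- recs[recs$role == "lncrna", , drop = FALSE]
    A_md[cbind(match(d$mirna, rownames(A_md)),
               match(d$target, colnames(A_md)))] <- 1
    A_ml[cbind(match(l$mirna, rownames(A_ml)),
               match(l$target, colnames(A_ml)))] <- 1
  }
  if (!quiet) {
    inform(sprintf(
      "miRNA-disease layer: %d known + %d recommended = %d edges; miRNA-lncRNA layer: %d known + %d recommended = %d edges.",
      sum(g$A_md), sum(A_md) - sum(g$A_md), sum(A_md),
      sum(g$A_ml), sum(A_ml) - sum(g$A_ml), sum(A_ml)
    ))
  }
  new_tripartite_graph(A_md, A_ml, g$A_dl, stage = "updated",
                       A_md0 = g$A_md0, A_ml0 = g$A_ml0,
                       recommendations = recs)
}

#' Run the full collaborative-filtering stage
#'
#' Convenience wrapper: similarity, recommender matrix, edge
#' recommendation and graph update in one call. This stage runs exactly
#' once on the initial graph (no iteration to a fixpoint).
#'
#' @inheritParams recommender_matrix
#' @inheritParams update_graph
#' @return The updated [tripartite_graph()].
#' @examples
#' sim <- simulate_tripartite(n_m = 20, n_d = 10, n_l = 6, n_blocks = 2,
#'                            seed = 1)
#' gu <- collab_filter(sim$graph, quiet = TRUE)
#' gu
#' @export
collab_filter <- function(g, p_denominator = c("all_rows", "nonzero_rows"),
                          quiet = FALSE) {
  sim <- mirna_similarity(g)
  rec <- recommender_matrix(sim, g, p_denominator)
  update_graph(g, recommend_edges(rec, g), quiet = quiet)
}
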