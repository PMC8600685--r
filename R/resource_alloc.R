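#' Resource-allocation weight matrix between miRNAs
#'
#' Two-step propagation through the miRNA-disease layer: each miRNA
#' spreads one unit of resource evenly over its diseases, and each disease
#' returns what it received evenly over its miRNAs. Entry `W[k, t]` is the
#' fraction of miRNA t's resource that ends up on miRNA k,
#' `W[k,t] = (1/deg(m_k)) * sum_j A[k,j] A[t,j] / deg(d_j)`, with any term
#' involving a zero degree contributing 0. Rows of miRNAs with at least
#' one disease link sum to exactly 1; isolated miRNAs have all-zero rows.
#' The diagonal (self-contribution) is included.
#'
#' @param g A [tripartite_graph()]; its current miRNA-disease layer is
#'   used (the updated layer after [collab_filter()], or the raw layer for
#'   the RA-only baseline).
#' @return Dense `n_m x n_m` nonnegative matrix.
#' @seealso [consistency_correction()], [oracle_weights()]
#' @export
ra_weight_matrix <- function(g) {
  stopifnot(inherits(g, "tripartite_graph"))
  A <- g$A_md
  inv_m <- safe_inv(rowSums(A))     # 1 / deg(m_k), 0 if isolated
  inv_d <- safe_inv(colSums(A))     # 1 / deg(d_j)
  inv_m * (A %*% (inv_d * t(A)))
}

#' Consistence-based correction of the weight matrix
#'
#' Rewards reciprocal resource flow: the transfer from t to k is topped up
#' by the reverse transfer from k to t, normalized by everything flowing
#' into k, `W'[k,t] = W[k,t] + W[t,k] / sum_s W[s,k]`. Columns summing to
#' zero (miRNAs that receive nothing) fall back to `W'` = `W` for the
#' affected entries.
#'
#' @param W Weight matrix from [ra_weight_matrix()].
#' @return Corrected matrix `W'`, elementwise `>= W`.
#' @export
consistency_correction <- function(W) {
  inv_col <- safe_inv(colSums(W))   # 1 / sum_s W[s, k], indexed by k
  W + inv_col * t(W)
}

rscore1_matrix <- function(W_prime, g) W_prime %*% g$A_md

# Two-step propagation through the disease-lncRNA layer: resource on each
# disease spreads evenly over its lncRNAs and returns evenly over each
# lncRNA's diseases. Diseases with no lncRNA (and lncRNAs with no disease)
# pass nothing.
rscore2_matrix <- function(g) {
  A_dl <- g$A_dl
  inv_d <- safe_inv(rowSums(A_dl))  # lncRNAs per disease
  inv_l <- safe_inv(colSums(A_dl))  # diseases per lncRNA
  g$A_md %*% (inv_d * A_dl) %*% (inv_l * t(A_dl))
}

#' Score all miRNA-disease pairs by consistence-based resource allocation
#'
#' Runs the three propagation steps on the graph's current miRNA-disease
#' layer and blends them: `Rscore1 = W' %*% A_md` (disease-mediated
#' spreading between miRNAs) and `Rscore2` (the same resource routed
#' through the disease-lncRNA layer, which is what lets diseases with no
#' known miRNA receive informative scores), combined as
#' `final = gamma * Rscore1 + (1 - gamma) * Rscore2`.
#'
#' @param g A [tripartite_graph()], typically after [collab_filter()].
#' @param gamma Blend weight in `[0, 1]`; `gamma = 1` keeps only the
#'   disease-mediated score, `gamma = 0` only the lncRNA-mediated one.
#'   Default 0.9.
#' @return A `resource_scores` object: list of `n_m x n_d` matrices
#'   `rscore1`, `rscore2`, `final`, plus `gamma`, the scored adjacency
#'   `scored_on`, and `known0` (the original pre-recommendation layer,
#'   used to flag known pairs in rankings).
#' @examples
#' sim <- simulate_tripartite(n_m = 20, n_d = 10, n_l = 6, n_blocks = 2,
#'                            seed = 1)
#' gu <- collab_filter(sim$graph, quiet = TRUE)
#' sc <- resource_scores(gu, gamma = 0.9)
#' rank_mirnas(sc, colnames(gu$A_md)[1], top = 5)
#' @export
resource_scores <- function(g, gamma = 0.9) {
  stopifnot(inherits(g, "tripartite_graph"))
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop_param("`gamma` must be a single number in [0, 1].")
  }
  W <- ra_weight_matrix(g)
  W_prime <- consistency_correction(W)
  r1 <- rscore1_matrix(W_prime, g)
  r2 <- rscore2_matrix(g)
  structure(
    list(
      rscore1 = r1, rscore2 = r2,
      final = gamma * r1 + (1 - gamma) * r2,
      gamma = gamma, scored_on = g$A_md, known0 = g$A_md0
    ),
    class = "resource_scores"
  )
}

#' @export
print.resource_scores <- function(x, ...) {
  cat(sprintf("<resource_scores> %d miRNAs x %d diseases, gamma = %g\n",
              nrow(x$final), ncol(x$final), x$gamma))
  invisible(x)
}

#' @describeIn resource_scores One row per miRNA-disease cell: `mirna`,
#'   `disease`, `rscore1`, `rscore2`, `rscore_final`, `known_before`.
#' @param x,... Method arguments.
#' @export
tidy.resource_scores <- function(x, ...) {
  grid <- expand.grid(mirna = rownames(x$final), disease = colnames(x$final),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble(
    mirna = grid$mirna,
    disease = grid$disease,
    rscore1 = as.vector(x$rscore1),
    rscore2 = as.vector(x$rscore2),
    rscore_final = as.vector(x$final),
    known_before = as.integer(as.vector(x$known0) == 1)
  )
}

#' @describeIn resource_scores One-row summary (dimensions, gamma, edge
#'   counts).
#' @export
glance.resource_scores <- function(x, ...) {
  tibble(
    n_mirnas = nrow(x$final), n_diseases = ncol(x$final),
    gamma = x$gamma,
    n_scored_edges = sum(x$scored_on), n_known_edges = sum(x$known0)
  )
}

#' @describeIn resource_scores Heatmap of the final scores (miRNAs x
#'   diseases); intended for the small graphs where a full tile plot is
#'   readable.
#' @param object A `resource_scores` object.
#' @export
autoplot.resource_scores <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease, y = .data$mirna,
                                   fill = .data$rscore_final)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Rscore_final") +
    ggplot2::labs(x = "disease", y = "miRNA") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
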