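# Literal nested-loop reference implementations of every matrix identity
# in the pipeline. These transcribe the elementwise summations directly
# and deliberately share no code with the vectorized versions; they exist
# so the fast paths can be checked against an independent reading of the
# same definitions. Intended for small graphs only (O(n^3) loops).

#' Nested-loop oracle for the co-occurrence similarity
#'
#' Computes every entry of the normalized similarity by explicit set
#' intersection of the two miRNAs' neighbour sets, one pair at a time.
#'
#' @param g A [tripartite_graph()].
#' @return `n_m x n_m` matrix.
#' @family oracles
#' @export
oracle_similarity <- function(g) {
  M <- splice_mld(g, "initial")
  n_m <- nrow(M)
  neigh <- lapply(seq_len(n_m), function(k) which(M[k, ] == 1))
  R_nor <- matrix(0, n_m, n_m, dimnames = dimnames(g$A_md)[c(1L, 1L)])
  for (k in seq_len(n_m)) {
    for (r in seq_len(n_m)) {
      nk <- length(neigh[[k]])
      nr <- length(neigh[[r]])
      if (nk > 0 && nr > 0) {
        R_nor[k, r] <- length(intersect(neigh[[k]], neigh[[r]])) /
          sqrt(nk * nr)
      }
    }
  }
  R_nor
}

#' Nested-loop oracle for the recommender matrix
#'
#' Triple loop over the matrix product `R_nor %*% [A_ml, A_md]`.
#'
#' @param R_nor Similarity matrix (e.g. from [oracle_similarity()]).
#' @param g A [tripartite_graph()].
#' @return `n_m x (n_l + n_d)` matrix.
#' @family oracles
#' @export
oracle_recommender <- function(R_nor, g) {
  A0 <- splice_mld(g, "initial")
  out <- matrix(0, nrow(A0), ncol(A0), dimnames = dimnames(A0))
  for (k in seq_len(nrow(A0))) {
    for (c in seq_len(ncol(A0))) {
      acc <- 0
      for (r in seq_len(nrow(A0))) acc <- acc + R_nor[k, r] * A0[r, c]
      out[k, c] <- acc
    }
  }
  out
}

#' Nested-loop oracle for the miRNA-miRNA weight matrix
#'
#' Transcribes `w_kt = (1/deg(m_k)) * sum_j A[k,j] A[t,j] / deg(d_j)`
#' term by term, skipping zero-degree terms.
#'
#' @param g A [tripartite_graph()] (current miRNA-disease layer).
#' @return `n_m x n_m` matrix.
#' @family oracles
#' @export
oracle_weights <- function(g) {
  A <- g$A_md
  n_m <- nrow(A)
  n_d <- ncol(A)
  deg_m <- rowSums(A)
  deg_d <- colSums(A)
  W <- matrix(0, n_m, n_m, dimnames = dimnames(A)[c(1L, 1L)])
  for (k in seq_len(n_m)) {
    if (deg_m[k] == 0) next
    for (t in seq_len(n_m)) {
      acc <- 0
      for (j in seq_len(n_d)) {
        if (deg_d[j] > 0) acc <- acc + A[k, j] * A[t, j] / deg_d[j]
      }
      W[k, t] <- acc / deg_m[k]
    }
  }
  W
}

#' Nested-loop oracle for the consistence correction
#'
#' Elementwise `W'[k,t] = W[k,t] + W[t,k] / sum_s W[s,k]`, falling back
#' to `W[k,t]` when the column sum is zero.
#'
#' @param W Weight matrix.
#' @return Corrected matrix.
#' @family oracles
#' @export
oracle_consistency <- function(W) {
  n <- nrow(W)
  Wp <- W
  for (k in seq_len(n)) {
    colsum_k <- 0
    for (s in seq_len(n)) colsum_k <- colsum_k + W[s, k]
    if (colsum_k > 0) {
      for (t in seq_len(n)) Wp[k, t] <- W[k, t] + W[t, k] / colsum_k
    }
  }
  Wp
}

#' Nested-loop oracle for the disease-mediated score
#'
#' Triple loop over `W' %*% A_md`.
#'
#' @param W_prime Corrected weight matrix.
#' @param g A [tripartite_graph()].
#' @return `n_m x n_d` matrix.
#' @family oracles
#' @export
oracle_rscore1 <- function(W_prime, g) {
  A <- g$A_md
  out <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (k in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      acc <- 0
      for (t in seq_len(nrow(A))) acc <- acc + W_prime[k, t] * A[t, j]
      out[k, j] <- acc
    }
  }
  out
}

#' Path-summation oracle for the lncRNA-mediated score
#'
#' Sums the resource over every explicit path m_k -> d_j' -> l_s -> d_j:
#' the resource `A_md[k, j']` splits evenly over disease j's lncRNAs and
#' each lncRNA returns its share evenly over its diseases. Zero-degree
#' nodes pass nothing.
#'
#' @param g A [tripartite_graph()].
#' @return `n_m x n_d` matrix.
#' @family oracles
#' @export
oracle_rscore2 <- function(g) {
  A <- g$A_md
  A_dl <- g$A_dl
  n_m <- nrow(A); n_d <- ncol(A); n_l <- ncol(A_dl)
  deg_d <- rowSums(A_dl)
  deg_l <- colSums(A_dl)
  out <- matrix(0, n_m, n_d, dimnames = dimnames(A))
  for (k in seq_len(n_m)) {
    for (j in seq_len(n_d)) {
      acc <- 0
      for (j2 in seq_len(n_d)) {
        if (A[k, j2] == 0 || deg_d[j2] == 0) next
        for (s in seq_len(n_l)) {
          if (A_dl[j2, s] == 1 && A_dl[j, s] == 1 && deg_l[s] > 0) {
            acc <- acc + A[k, j2] / deg_d[j2] / deg_l[s]
          }
        }
      }
      out[k, j] <- acc
    }
  }
  out
}

#' Concordant-pair oracle for the area under the ROC curve
#'
#' The Mann-Whitney reading of AUC: over all positive-negative pairs, the
#' fraction where the positive outscores the negative, with half credit
#' for ties. Exhaustive O(n_pos * n_neg) enumeration.
#'
#' @param scores,labels As in [roc_pr_curves()].
#' @return AUC in `[0, 1]`.
#' @family oracles
#' @export
oracle_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  stopifnot(length(pos) > 0L, length(neg) > 0L)
  acc <- 0
  for (p in pos) {
    for (n in neg) {
      acc <- acc + (p > n) + 0.5 * (p == n)
    }
  }
  acc / (length(pos) * length(neg))
}
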