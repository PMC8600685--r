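# Fixtures built in code: named binary matrices wrapped into graph objects
# without going through edge tables, so isolated entities can be placed
# deliberately.

name_mat <- function(A, rp, cp) {
  lab <- function(p, n) if (n == 0L) NULL else paste0(p, sprintf("%02d", seq_len(n)))
  dimnames(A) <- list(lab(rp, nrow(A)), lab(cp, ncol(A)))
  A
}

make_graph <- function(A_md, A_ml, A_dl, stage = "initial") {
  A_md <- name_mat(A_md, "m", "d")
  A_ml <- name_mat(A_ml, "m", "l")
  A_dl <- name_mat(A_dl, "d", "l")
  tripred:::new_tripartite_graph(A_md, A_ml, A_dl, stage = stage)
}

# Erdos-Renyi style random graph on all three layers, possibly with
# isolated entities (rows/columns of zeros).
random_graph <- function(n_m = 8, n_d = 6, n_l = 4, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    make_graph(
      matrix(rbinom(n_m * n_d, 1, density), n_m),
      matrix(rbinom(n_m * n_l, 1, density), n_m),
      matrix(rbinom(n_d * n_l, 1, density), n_d)
    )
  })
}

# 2-miRNA hand-computable toy: m1 ~ {l1, d1}, m2 ~ {l1}
toy_graph <- function() {
  make_graph(A_md = matrix(c(1, 0), 2, 1),
             A_ml = matrix(c(1, 1), 2, 1),
             A_dl = matrix(1, 1, 1))
}

# both miRNAs linked to the single disease; no lncRNA edges
toy_ra_graph <- function() {
  make_graph(A_md = matrix(c(1, 1), 2, 1),
             A_ml = matrix(0, 2, 1),
             A_dl = matrix(0, 1, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
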