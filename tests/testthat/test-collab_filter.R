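test_that("co-occurrence similarity matches hand-computed values", {
  g <- toy_graph()  # m1 ~ {l1, d1}, m2 ~ {l1}
  sim <- mirna_similarity(g)
  expect_equal(sim$R_nor["m01", "m02"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(diag(sim$R_nor), c(m01 = 1, m02 = 1))
  expect_equal(sim$R["m01", "m02"], 1)

  # disjoint neighbourhoods: similarity and co-occurrence both zero
  g2 <- make_graph(A_md = matrix(c(1, 0, 0, 1), 2, 2),
                   A_ml = matrix(0, 2, 1),
                   A_dl = matrix(0, 2, 1))
  sim2 <- mirna_similarity(g2)
  expect_equal(sim2$R_nor["m01", "m02"], 0)
  expect_equal(sim2$R["m01", "m02"], 0)

  # all-zero graph warns and yields all-zero matrices
  g3 <- make_graph(matrix(0, 2, 2), matrix(0, 2, 1), matrix(0, 2, 1))
  expect_warning(sim3 <- mirna_similarity(g3), "isolated")
  expect_true(all(sim3$R_nor == 0))
})

test_that("similarity is symmetric, bounded, and implies co-occurrence", {
  for (seed in 1:5) {
    g <- random_graph(n_m = 10, n_d = 7, n_l = 5, density = 0.25, seed = seed)
    sim <- mirna_similarity(g)
    expect_equal(sim$R_nor, t(sim$R_nor))
    expect_true(all(sim$R_nor >= 0 & sim$R_nor <= 1 + 1e-12))
    deg <- rowSums(splice_mld(g))
    expect_equal(unname(diag(sim$R_nor)), as.numeric(deg > 0))
    expect_true(all(sim$R[sim$R_nor > 0] == 1))
  }
})

test_that("recommender matrix is the similarity-propagated adjacency", {
  g <- toy_graph()
  sim <- mirna_similarity(g)
  rec <- recommender_matrix(sim, g)
  s2 <- 1 / sqrt(2)
  expect_matrix_equal(rec$A_u_mld,
                      matrix(c(1 + s2, 1 + s2, 1, s2), 2), tol = 1e-12)
  expect_equal(unname(rec$column_avgs),
               c((2 + 2 * s2) / 2, (1 + s2) / 2), tolerance = 1e-12)

  # identity similarity leaves the adjacency unchanged
  sim_id <- sim
  sim_id$R_nor <- diag(2)
  rec_id <- recommender_matrix(sim_id, g)
  expect_equal(unname(rec_id$A_u_mld), unname(splice_mld(g)))

  # nonzero columns get positive averages, all-zero columns exactly 0
  g2 <- make_graph(A_md = matrix(c(1, 0, 0, 0), 2, 2),
                   A_ml = matrix(c(1, 0), 2, 1),
                   A_dl = matrix(0, 2, 1))
  rec2 <- recommender_matrix(mirna_similarity(g2), g2)
  expect_true(all(rec2$column_avgs >= 0))
  expect_equal(unname(rec2$column_avgs[colSums(rec2$A_u_mld) == 0]), 0)

  # nonzero_rows denominator divides by the positive-entry count instead:
  # disjoint miRNAs give identity similarity, each disease column (1, 0)
  g4 <- make_graph(A_md = matrix(c(1, 0, 0, 1), 2, 2),
                   A_ml = matrix(0, 2, 1),
                   A_dl = matrix(0, 2, 1))
  sim4 <- mirna_similarity(g4)
  expect_equal(unname(recommender_matrix(sim4, g4)$column_avgs),
               c(0, 0.5, 0.5))
  expect_equal(unname(recommender_matrix(sim4, g4,
                                         "nonzero_rows")$column_avgs),
               c(0, 1, 1))
})

fake_rec <- function(A_u, P, n_l = 0L) {
  structure(list(A_u_mld = A_u, column_avgs = P, n_l = n_l,
                 p_denominator = "all_rows"),
            class = "recommender_matrix")
}

test_that("edges are recommended only above P, for new pairs, in gated columns", {
  # one disease column; A0 known edge at row 1
  g <- make_graph(A_md = matrix(c(1, 0), 2, 1),
                  A_ml = matrix(0, 2, 0),
                  A_dl = matrix(0, 1, 0))
  # row 1 already known, row 2 below threshold -> nothing
  rec <- fake_rec(name_mat(matrix(c(0.9, 0.1), 2, 1), "m", "d"), 0.5)
  expect_equal(nrow(recommend_edges(rec, g)), 0L)

  # three miRNAs, known only at row 1, rows 2 above P -> exactly row 2
  g3 <- make_graph(A_md = matrix(c(1, 0, 0), 3, 1),
                   A_ml = matrix(0, 3, 0),
                   A_dl = matrix(0, 1, 0))
  rec3 <- fake_rec(name_mat(matrix(c(0.9, 0.8, 0.1), 3, 1), "m", "d"), 0.6)
  out <- recommend_edges(rec3, g3)
  expect_equal(out$mirna, "m02")
  expect_equal(out$role, "disease")
  expect_equal(out$score, 0.8)

  # a tie at exactly P is not recommended (strict inequality)
  rec_tie <- fake_rec(name_mat(matrix(c(0.9, 0.6, 0.1), 3, 1), "m", "d"), 0.6)
  expect_equal(nrow(recommend_edges(rec_tie, g3)), 0L)

  # column with no known association: gated off regardless of scores
  g0 <- make_graph(A_md = matrix(0, 2, 1),
                   A_ml = matrix(0, 2, 0),
                   A_dl = matrix(0, 1, 0))
  rec0 <- fake_rec(name_mat(matrix(c(5, 5), 2, 1), "m", "d"), 0.1)
  expect_equal(nrow(recommend_edges(rec0, g0)), 0L)
})

test_that("update_graph adds binary edges monotonically and only once", {
  g <- toy_graph()
  empty <- recommend_edges(fake_rec(name_mat(matrix(0, 2, 1), "m", "d"), 1),
                           make_graph(matrix(0, 2, 1), matrix(0, 2, 0),
                                      matrix(0, 1, 0)))
  gu <- update_graph(g, empty, quiet = TRUE)
  expect_equal(gu$A_md, g$A_md)
  expect_equal(gu$A_ml, g$A_ml)
  expect_equal(gu$stage, "updated")
  expect_error(update_graph(gu, empty), "already been updated")

  gu2 <- collab_filter(toy_graph(), quiet = TRUE)
  # never deletes an edge, stays binary, initial layers preserved
  expect_true(all(gu2$A_md >= g$A_md))
  expect_true(all(gu2$A_ml >= g$A_ml))
  expect_true(all(gu2$A_md %in% c(0, 1)))
  expect_equal(gu2$A_md0, g$A_md)
  expect_equal(gu2$A_dl, g$A_dl)
  # cells partition: ones + zeros = n_m * n_d
  expect_equal(sum(gu2$A_md == 1) + sum(gu2$A_md == 0), length(gu2$A_md))
})

test_that("the collaborative-filtering stage is deterministic", {
  g <- random_graph(n_m = 12, n_d = 8, n_l = 6, density = 0.3, seed = 3)
  gu1 <- collab_filter(g, quiet = TRUE)
  gu2 <- collab_filter(g, quiet = TRUE)
  expect_identical(gu1$A_md, gu2$A_md)
  expect_identical(gu1$A_ml, gu2$A_ml)
  expect_identical(gu1$recommendations, gu2$recommendations)
  # recommended edges were new and scored strictly above their column's P
  rec <- recommender_matrix(mirna_similarity(g), g)
  recs <- gu1$recommendations
  if (nrow(recs) > 0L) {
    A0 <- splice_mld(g)
    cols <- match(recs$target, colnames(A0))
    rows <- match(recs$mirna, rownames(A0))
    expect_true(all(A0[cbind(rows, cols)] == 0))
    expect_true(all(recs$score > rec$column_avgs[cols]))
  }
})
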