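#' Simulate a tripartite graph with planted cross-layer signal
#'
#' Block-model generator for testing and benchmarking. Entities of every
#' role are partitioned into `n_blocks` aligned blocks; within-block
#' miRNA-disease cells carry an edge with probability
#' `within_block_prob`, all other cells with `background_prob`. The
#' miRNA-lncRNA and disease-lncRNA layers are coupled to the same blocks:
#' their within-block cells carry an edge with probability
#' `layer_coupling` (background elsewhere), so miRNAs and diseases of a
#' block share lncRNA partners — exactly the shared-neighbour signal the
#' collaborative-filtering stage exploits. A fraction `holdout_frac` of
#' the planted (within-block) miRNA-disease edges is removed from the
#' graph and returned separately, giving a ground-truth recovery task.
#'
#' The defaults are the package's standard benchmark conditions: 60
#' miRNAs x 40 diseases x 20 lncRNAs in 4 blocks, dense signal (0.5)
#' over sparse background (0.02), coupling 0.7, 30% of planted edges held
#' out.
#'
#' @param n_m,n_d,n_l Number of miRNAs, diseases, lncRNAs.
#' @param n_blocks Number of aligned blocks.
#' @param within_block_prob,background_prob Edge probabilities for
#'   within-block and out-of-block miRNA-disease cells; the former must
#'   exceed the latter for a detectable signal.
#' @param layer_coupling Within-block edge probability of the two lncRNA
#'   layers.
#' @param holdout_frac Fraction of planted miRNA-disease edges withheld.
#' @param seed Integer seed; generation is fully reproducible from it and
#'   leaves the global RNG untouched.
#' @return List with `graph` (a [tripartite_graph()], `stage =
#'   "initial"`, holdout already removed), `planted` (tibble of all
#'   within-block edges drawn, including the withheld ones) and `heldout`
#'   (tibble of the withheld pairs, absent from the graph).
#' @examples
#' sim <- simulate_tripartite(n_m = 20, n_d = 10, n_l = 6, n_blocks = 2,
#'                            seed = 42)
#' sim$graph
#' nrow(sim$heldout)
#' @export
simulate_tripartite <- function(n_m = 60, n_d = 40, n_l = 20, n_blocks = 4,
                                within_block_prob = 0.5,
                                background_prob = 0.02,
                                layer_coupling = 0.7,
                                holdout_frac = 0.3,
                                seed = 1) {
  n_m <- check_count(n_m, "n_m"); n_d <- check_count(n_d, "n_d")
  n_l <- check_count(n_l, "n_l"); n_blocks <- check_count(n_blocks, "n_blocks")
  check_prob(within_block_prob, "within_block_prob")
  check_prob(background_prob, "background_prob")
  check_prob(layer_coupling, "layer_coupling")
  check_prob(holdout_frac, "holdout_frac")
  if (within_block_prob <= background_prob) {
    stop_param("`within_block_prob` must exceed `background_prob` for a detectable signal.")
  }

  # zero-padded names so lexicographic index order matches construction order
  mirnas <- sprintf("m%03d", seq_len(n_m))
  diseases <- sprintf("d%03d", seq_len(n_d))
  lncrnas <- sprintf("l%03d", seq_len(n_l))
  blocks_of <- function(n) sort(rep_len(seq_len(n_blocks), n))
  b_m <- blocks_of(n_m); b_d <- blocks_of(n_d); b_l <- blocks_of(n_l)

  draw <- function(b_row, b_col, p_in, p_out, rows, cols) {
    same <- outer(b_row, b_col, `==`)
    p <- ifelse(same, p_in, p_out)
    A <- matrix(rbinom(length(p), 1L, as.vector(p)), nrow(p),
                dimnames = list(rows, cols))
    A
  }

  withr::with_seed(seed, {
    A_md <- draw(b_m, b_d, within_block_prob, background_prob,
                 mirnas, diseases)
    A_ml <- draw(b_m, b_l, layer_coupling, background_prob, mirnas, lncrnas)
    A_dl <- draw(b_d, b_l, layer_coupling, background_prob, diseases, lncrnas)

    within <- outer(b_m, b_d, `==`)
    planted_idx <- which(A_md == 1 & within)
    n_hold <- floor(holdout_frac * length(planted_idx))
    heldout_idx <- if (n_hold > 0L) sort(sample(planted_idx, n_hold))
                   else integer()
  })
  A_md[heldout_idx] <- 0

  cells <- function(idx) {
    tibble(mirna = mirnas[(idx - 1L) %% n_m + 1L],
           disease = diseases[(idx - 1L) %/% n_m + 1L])
  }
  list(
    graph = new_tripartite_graph(A_md, A_ml, A_dl, stage = "initial"),
    planted = cells(planted_idx),
    heldout = cells(heldout_idx)
  )
}

#' Rank held-out planted edges against random non-edges
#'
#' The generator's recovery task: run the full pipeline (collaborative
#' filtering at `p_denominator = "all_rows"`, then resource allocation) on
#' a simulated graph whose held-out planted edges were removed, and
#' measure how well the final scores separate those held-out pairs from
#' an equal number of uniformly sampled non-edges (cells that are zero in
#' the scored layer and not themselves held out).
#'
#' @param sim A [simulate_tripartite()] result.
#' @param gamma Blend weight for [resource_scores()].
#' @param seed Seed for sampling the comparison non-edges.
#' @param mode `"cf_ra"` (default) or `"ra_only"` (skip collaborative
#'   filtering).
#' @return A [roc_pr_curves()] result (fields `auc`, `aupr`, curves).
#' @export
heldout_recovery <- function(sim, gamma = 0.9, seed = 1,
                             mode = c("cf_ra", "ra_only")) {
  mode <- match.arg(mode)
  g <- sim$graph
  if (nrow(sim$heldout) == 0L) {
    stop_param("`sim` has no held-out pairs (holdout_frac was 0).")
  }
  g_scored <- if (mode == "cf_ra") collab_filter(g, quiet = TRUE) else g
  final <- resource_scores(g_scored, gamma = gamma)$final

  hold_cells <- cbind(match(sim$heldout$mirna, rownames(final)),
                      match(sim$heldout$disease, colnames(final)))
  hold_lin <- (hold_cells[, 2L] - 1L) * nrow(final) + hold_cells[, 1L]
  nonedge <- setdiff(which(g_scored$A_md == 0), hold_lin)
  neg_lin <- withr::with_seed(seed,
                              sample(nonedge, min(length(hold_lin),
                                                  length(nonedge))))
  roc_pr_curves(c(final[hold_lin], final[neg_lin]),
                rep(c(1L, 0L), c(length(hold_lin), length(neg_lin))))
}
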