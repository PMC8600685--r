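#' ROC and precision-recall curves for binary scores
#'
#' Threshold sweep over the unique score values, highest first, with tied
#' scores grouped at a single threshold. AUC is the trapezoidal area under
#' the (FPR, TPR) curve — equal to the concordant-pair (Mann-Whitney)
#' statistic with the usual half-credit for ties. AUPR is the area under
#' the precision-recall step curve, `sum (recall_i - recall_{i-1}) *
#' precision_i` over thresholds.
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels 0/1 (or logical) vector of true classes, same length.
#' @return A `roc_pr` object: list with `auc`, `aupr`, and tibbles `roc`
#'   (`threshold`, `fpr`, `tpr`) and `pr` (`threshold`, `recall`,
#'   `precision`).
#' @examples
#' roc_pr_curves(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0))$auc  # 0.75
#' @export
roc_pr_curves <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_param("`labels` must contain both classes to draw ROC/PR curves.")
  }

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative counts at the end of each tie group
  grp_end <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  fp <- grp_end - tp
  thr <- s[grp_end]

  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)

  structure(
    list(
      auc = auc, aupr = aupr,
      roc = tibble(threshold = unname(thr), fpr = fpr[-1L], tpr = tpr[-1L]),
      pr = tibble(threshold = unname(thr), recall = unname(recall),
                  precision = unname(precision))
    ),
    class = "roc_pr"
  )
}

#' @export
print.roc_pr <- function(x, ...) {
  cat(sprintf("<roc_pr> AUC = %.4f, AUPR = %.4f (%d thresholds)\n",
              x$auc, x$aupr, nrow(x$roc)))
  invisible(x)
}

#' Assign fivefold CV labels to the positive and negative cells
#'
#' Positives are the 1-cells of the graph's current miRNA-disease layer
#' (known plus recommended, when called after [collab_filter()]);
#' negatives are all remaining 0-cells — no negative subsampling. Each
#' class is shuffled with the seed and split into `k` near-equal parts
#' (sizes differ by at most 1).
#'
#' @param g A [tripartite_graph()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the assignment is reproducible from it and
#'   the global RNG state is left untouched.
#' @return A `fold_assignment`: list with linear cell indices `pos_idx`,
#'   `neg_idx` and their fold labels `pos_fold`, `neg_fold` in `1..k`.
#' @export
make_folds <- function(g, k = 5, seed = 1) {
  stopifnot(inherits(g, "tripartite_graph"))
  k <- check_count(k, "k", min = 2L)
  pos <- which(g$A_md == 1)
  neg <- which(g$A_md == 0)
  if (length(pos) < k) {
    stop_param(sprintf("Need at least %d positive cells for %d folds, have %d.",
                       k, k, length(pos)))
  }
  withr::with_seed(seed, {
    pos_fold <- sample(rep(seq_len(k), length.out = length(pos)))
    neg_fold <- sample(rep(seq_len(k), length.out = length(neg)))
  })
  structure(
    list(pos_idx = pos, pos_fold = pos_fold,
         neg_idx = neg, neg_fold = neg_fold, k = k, seed = seed),
    class = "fold_assignment"
  )
}

#' Score the test cells of one CV fold
#'
#' Makes a training copy of the miRNA-disease layer with this fold's test
#' positives set to 0, recomputes the full resource allocation on it (the
#' disease-lncRNA layer is untouched), and returns the final scores at
#' every test cell with its true label. A test positive is therefore
#' scored without ever reading its own edge.
#'
#' @param g The [tripartite_graph()] the folds were made from.
#' @param folds A [make_folds()] assignment.
#' @param fold_id Which fold (1..k) is the test part.
#' @param gamma Blend weight passed to [resource_scores()].
#' @return Tibble with columns `cell` (linear index into the score
#'   matrix), `score`, `label`.
#' @export
run_fold <- function(g, folds, fold_id, gamma = 0.9) {
  stopifnot(inherits(folds, "fold_assignment"),
            fold_id %in% seq_len(folds$k))
  test_pos <- folds$pos_idx[folds$pos_fold == fold_id]
  test_neg <- folds$neg_idx[folds$neg_fold == fold_id]

  g_train <- g
  g_train$A_md[test_pos] <- 0
  final <- resource_scores(g_train, gamma = gamma)$final

  cells <- c(test_pos, test_neg)
  tibble(
    cell = cells,
    score = final[cells],
    label = rep(c(1L, 0L), c(length(test_pos), length(test_neg)))
  )
}

#' Fivefold cross-validation of the predictor
#'
#' Repeats a k-fold cross-validation of the resource-allocation scores.
#' In mode `"cf_ra"` the positives are the 1-cells of the updated
#' miRNA-disease layer (known plus collaborative-filtering
#' recommendations, fixed once before splitting); an initial graph is
#' passed through [collab_filter()] first. In mode `"ra_only"` the
#' collaborative-filtering stage is skipped entirely and the original
#' known associations alone are split and scored — the
#' resource-allocation-only baseline. Per fold, [run_fold()] rescores the
#' masked matrix and [roc_pr_curves()] measures AUC/AUPR; a repeat's value
#' is the mean over its k folds.
#'
#' @param g A [tripartite_graph()].
#' @param gamma Blend weight (default 0.9).
#' @param k Folds per repeat (default 5).
#' @param repeats Number of independent repetitions (default 10).
#' @param seed Base seed; repeat r uses `seed + r - 1`.
#' @param mode `"cf_ra"` (full pipeline, default) or `"ra_only"`.
#' @param keep_curves Keep the ROC/PR curve points of the first repeat's
#'   folds (for plotting).
#' @param quiet Suppress the collaborative-filtering count message.
#' @return A `tripred_cv` object with `per_fold` and `per_repeat` tibbles,
#'   an `overall` summary (mean, sd, max over repeats), and the settings.
#' @examples
#' sim <- simulate_tripartite(n_m = 20, n_d = 10, n_l = 6, n_blocks = 2,
#'                            seed = 1)
#' cv <- crossval(sim$graph, repeats = 2, seed = 1, quiet = TRUE)
#' glance(cv)
#' @export
crossval <- function(g, gamma = 0.9, k = 5, repeats = 10, seed = 1,
                     mode = c("cf_ra", "ra_only"), keep_curves = FALSE,
                     quiet = FALSE) {
  stopifnot(inherits(g, "tripartite_graph"))
  mode <- match.arg(mode)
  repeats <- check_count(repeats, "repeats")

  g_eval <- if (mode == "cf_ra") {
    if (g$stage == "initial") collab_filter(g, quiet = quiet) else g
  } else {
    # baseline: score the original known layer, no recommended edges
    new_tripartite_graph(g$A_md0, g$A_ml0, g$A_dl, stage = "initial")
  }

  curves <- list()
  per_fold <- purrr::map_dfr(seq_len(repeats), function(r) {
    folds <- make_folds(g_eval, k = k, seed = seed + r - 1L)
    purrr::map_dfr(seq_len(k), function(f) {
      res <- run_fold(g_eval, folds, f, gamma = gamma)
      curve <- roc_pr_curves(res$score, res$label)
      if (keep_curves && r == 1L) curves[[f]] <<- curve
      tibble(repeat_id = r, fold = f, auc = curve$auc, aupr = curve$aupr)
    })
  })

  per_repeat <- per_fold |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::summarise(auc = mean(.data$auc), aupr = mean(.data$aupr),
                     .groups = "drop")
  overall <- list(
    auc_mean = mean(per_repeat$auc),
    auc_sd = if (repeats > 1L) sd(per_repeat$auc) else NA_real_,
    auc_max = max(per_repeat$auc),
    aupr_mean = mean(per_repeat$aupr),
    aupr_sd = if (repeats > 1L) sd(per_repeat$aupr) else NA_real_,
    aupr_max = max(per_repeat$aupr)
  )

  structure(
    list(per_fold = per_fold, per_repeat = per_repeat, overall = overall,
         gamma = gamma, k = k, repeats = repeats, seed = seed, mode = mode,
         n_pos = sum(g_eval$A_md), n_neg = sum(g_eval$A_md == 0),
         curves = if (keep_curves) curves else NULL),
    class = "tripred_cv"
  )
}

#' @export
print.tripred_cv <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<tripred_cv> mode = %s, gamma = %g, %d-fold x %d repeats (%d pos / %d neg cells)\n",
    x$mode, x$gamma, x$k, x$repeats, x$n_pos, x$n_neg
  ))
  cat(sprintf("  AUC  mean %.4f (sd %.4f, max %.4f)\n",
              o$auc_mean, o$auc_sd, o$auc_max))
  cat(sprintf("  AUPR mean %.4f (sd %.4f, max %.4f)\n",
              o$aupr_mean, o$aupr_sd, o$aupr_max))
  invisible(x)
}

#' @describeIn crossval Per-fold AUC/AUPR tibble.
#' @param x,... Method arguments.
#' @export
tidy.tripred_cv <- function(x, ...) x$per_fold

#' @describeIn crossval One-row summary: mean/sd/max AUC and AUPR over
#'   repeats plus the settings.
#' @export
glance.tripred_cv <- function(x, ...) {
  tibble(
    mode = x$mode, gamma = x$gamma, k = x$k, repeats = x$repeats,
    n_pos = x$n_pos, n_neg = x$n_neg,
    auc_mean = x$overall$auc_mean, auc_sd = x$overall$auc_sd,
    auc_max = x$overall$auc_max,
    aupr_mean = x$overall$aupr_mean, aupr_sd = x$overall$aupr_sd,
    aupr_max = x$overall$aupr_max
  )
}

#' @describeIn crossval Per-fold AUC and AUPR as points over repeats; if
#'   the object was built with `keep_curves = TRUE`, the first repeat's
#'   ROC curves are drawn instead.
#' @param object A `tripred_cv` object.
#' @export
autoplot.tripred_cv <- function(object, ...) {
  if (!is.null(object$curves)) {
    df <- purrr::imap_dfr(object$curves, function(curve, f) {
      dplyr::mutate(rbind(tibble(threshold = Inf, fpr = 0, tpr = 0),
                          curve$roc),
                    fold = factor(f))
    })
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$fold)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                             colour = "grey60") +
        ggplot2::geom_step() +
        ggplot2::coord_equal() +
        ggplot2::labs(x = "false positive rate", y = "true positive rate",
                      title = sprintf("ROC by fold (repeat 1, gamma = %g)",
                                      object$gamma)) +
        ggplot2::theme_minimal()
    )
  }
  df <- tidyr::pivot_longer(object$per_fold, c("auc", "aupr"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$repeat_id),
                                   y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red3", linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "repeat", y = NULL) +
    ggplot2::theme_minimal()
}
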