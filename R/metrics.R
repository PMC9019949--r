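#' Ranking loss of a target pool
#'
#' The absolute difference between the true GDT-TS score of the target's best
#' model and the true score of the model ranked first by the predicted
#' scores. A loss of 0 means the best model was selected. Ties in the
#' predicted score are broken by lexicographic `model_id` (deterministic).
#'
#' @param true numeric vector of true scores in \[0,1\].
#' @param predicted numeric vector of predicted scores (no missing values).
#' @param model_id optional identifiers used for tie-breaking (and error
#'   messages); defaults to `"model_1"`, ... in input order.
#' @return the ranking loss, a number in \[0,1\].
#' @export
ranking_loss <- function(true, predicted, model_id = NULL) {
  n <- length(true)
  if (n == 0) stop("empty pool")
  if (length(predicted) != n) stop("true and predicted lengths differ")
  if (is.null(model_id)) model_id <- paste0("model_", seq_len(n))
  if (anyNA(predicted))
    stop(sprintf("missing prediction for model %s",
                 model_id[which(is.na(predicted))[1]]))
  if (anyNA(true) || any(true < 0 | true > 1))
    stop("true scores must lie in [0,1]")
  top <- which(predicted == max(predicted))
  if (length(top) > 1) top <- top[order(model_id[top])][1]
  abs(max(true) - true[top])
}

#' Per-target Pearson correlation
#'
#' Pearson correlation between predicted and true scores of one target's
#' models. When either sequence is constant (zero variance) or the pool has
#' fewer than 2 models the correlation is undefined and `NA` is returned;
#' such targets are excluded from the averaged correlation in
#' [evaluate_pools()].
#'
#' @inheritParams ranking_loss
#' @return correlation in \[-1,1\], or `NA` when undefined.
#' @export
per_target_pcc <- function(true, predicted) {
  if (length(true) < 2 || length(predicted) != length(true)) return(NA_real_)
  if (stats::sd(true) == 0 || stats::sd(predicted) == 0) return(NA_real_)
  stats::cor(predicted, true)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D(n,m) = sup_x |F1_n(x) - F2_m(x)|` exactly by evaluating both
#' empirical distribution functions at every pooled data point (both ECDFs
#' are right-continuous step functions jumping only at data points, so the
#' supremum is attained there). The p-value comes from the standard
#' asymptotic two-sample Kolmogorov distribution
#' `Q(lambda) = 2 * sum_k (-1)^(k-1) exp(-2 k^2 lambda^2)` with
#' `lambda = sqrt(n*m/(n+m)) * D`.
#'
#' @param sample1,sample2 non-empty numeric vectors.
#' @return `list(statistic = D, p.value = p)`.
#' @export
ks_two_sample <- function(sample1, sample2) {
  if (length(sample1) == 0 || length(sample2) == 0)
    stop("KS test requires two non-empty samples")
  if (anyNA(sample1) || anyNA(sample2)) stop("samples contain NA")
  n <- length(sample1)
  m <- length(sample2)
  pts <- sort(unique(c(sample1, sample2)))
  f1 <- vapply(pts, function(z) sum(sample1 <= z), numeric(1)) / n
  f2 <- vapply(pts, function(z) sum(sample2 <= z), numeric(1)) / m
  d <- max(abs(f1 - f2))
  lambda <- sqrt(n * m / (n + m)) * d
  k <- seq_len(100)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  p <- min(max(p, 0), 1)
  list(statistic = d, p.value = p)
}

#' Sample skewness (population form)
#'
#' `(1/n * sum((x - mean)^3)) / (1/n * sum((x - mean)^2))^(3/2)` — the biased
#' population estimator, with no small-sample correction.
#'
#' @param x numeric vector, `n >= 2`, non-zero variance.
#' @return the skewness.
#' @export
sample_skewness <- function(x) {
  if (length(x) < 2) stop("skewness requires n >= 2")
  if (anyNA(x)) stop("sample contains NA")
  d <- x - mean(x)
  v <- mean(d^2)
  if (v == 0) stop("domain error: zero variance sample")
  mean(d^3) / v^1.5
}

# expected ranking loss of a uniform-random selector on one pool: the mean,
# over models, of (best true score - true score)
random_selector_loss <- function(true) {
  mean(max(true) - true)
}

#' Evaluate prediction quality over target pools
#'
#' Computes the full evaluation suite: per-target ranking loss and Pearson
#' correlation, their means (the PCC mean over targets where it is defined,
#' with a logged count of excluded targets), the skewness of the ranking-loss
#' sample, and two Kolmogorov-Smirnov comparisons — (1) all true scores vs
#' all predicted scores pooled over models, and (2) the per-target best true
#' score vs the true score of the per-target selected model. Because Pearson
#' correlation can be averaged per target, pooled over all models, or taken
#' between best and selected scores, all three are reported, labeled.
#'
#' @param pools a `data.frame` with columns `target_id`, `model_id`,
#'   `true_gdtts`, `predicted_gdtts`.
#' @return object of class `dmqa_eval_report`: `per_target` data.frame
#'   (`target_id`, `n_models`, `ranking_loss`, `pcc`, `random_loss`),
#'   `mean_ranking_loss`, `mean_pcc`, `pooled_pcc`, `best_vs_selected_pcc`,
#'   `mean_random_loss`, `loss_skewness`, and `ks_results` data.frame
#'   (`label`, `d_statistic`, `p_value`).
#' @export
evaluate_pools <- function(pools) {
  req <- c("target_id", "model_id", "true_gdtts", "predicted_gdtts")
  if (!is.data.frame(pools) || !all(req %in% names(pools)))
    stop("pools must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(pools) == 0) stop("empty pool list")
  targets <- unique(pools$target_id)
  per <- lapply(targets, function(tid) {
    sub <- pools[pools$target_id == tid, , drop = FALSE]
    best_true <- max(sub$true_gdtts)
    top <- which(sub$predicted_gdtts == max(sub$predicted_gdtts))
    if (length(top) > 1) top <- top[order(sub$model_id[top])][1]
    data.frame(target_id = tid, n_models = nrow(sub),
               ranking_loss = ranking_loss(sub$true_gdtts,
                                           sub$predicted_gdtts,
                                           sub$model_id),
               pcc = per_target_pcc(sub$true_gdtts, sub$predicted_gdtts),
               random_loss = random_selector_loss(sub$true_gdtts),
               best_true = best_true,
               selected_true = sub$true_gdtts[top],
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  n_undef <- sum(is.na(per$pcc))
  if (n_undef > 0)
    dmqa_log(sprintf("%d target(s) with undefined PCC excluded from mean_pcc",
                     n_undef), level = "NOTE", verbose = FALSE)
  ks1 <- ks_two_sample(pools$true_gdtts, pools$predicted_gdtts)
  ks2 <- ks_two_sample(per$best_true, per$selected_true)
  losses <- per$ranking_loss
  skew <- if (length(losses) >= 2 && stats::sd(losses) > 0)
    sample_skewness(losses) else NA_real_
  structure(list(
    per_target = per[, c("target_id", "n_models", "ranking_loss", "pcc",
                         "random_loss")],
    mean_ranking_loss = mean(per$ranking_loss),
    mean_pcc = if (all(is.na(per$pcc))) NA_real_
               else mean(per$pcc, na.rm = TRUE),
    n_undefined_pcc = n_undef,
    pooled_pcc = per_target_pcc(pools$true_gdtts, pools$predicted_gdtts),
    best_vs_selected_pcc = per_target_pcc(per$best_true, per$selected_true),
    mean_random_loss = mean(per$random_loss),
    loss_skewness = skew,
    ks_results = data.frame(
      label = c("all_true_vs_all_predicted", "best_true_vs_selected_true"),
      d_statistic = c(ks1$statistic, ks2$statistic),
      p_value = c(ks1$p.value, ks2$p.value),
      stringsAsFactors = FALSE)),
    class = "dmqa_eval_report")
}

#' @export
print.dmqa_eval_report <- function(x, ...) {
  cat(sprintf("<evaluation over %d targets>\n", nrow(x$per_target)))
  cat(sprintf("  mean ranking loss : %.4f (random selector: %.4f)\n",
              x$mean_ranking_loss, x$mean_random_loss))
  cat(sprintf("  mean per-target PCC: %s (%d undefined excluded)\n",
              ifelse(is.na(x$mean_pcc), "NA", sprintf("%.4f", x$mean_pcc)),
              x$n_undefined_pcc))
  cat(sprintf("  pooled PCC: %s; best-vs-selected PCC: %s\n",
              ifelse(is.na(x$pooled_pcc), "NA",
                     sprintf("%.4f", x$pooled_pcc)),
              ifelse(is.na(x$best_vs_selected_pcc), "NA",
                     sprintf("%.4f", x$best_vs_selected_pcc))))
  cat(sprintf("  ranking-loss skewness: %s\n",
              ifelse(is.na(x$loss_skewness), "NA",
                     sprintf("%.4f", x$loss_skewness))))
  for (i in seq_len(nrow(x$ks_results)))
    cat(sprintf("  KS %s: D = %.5f, p = %.4g\n", x$ks_results$label[i],
                x$ks_results$d_statistic[i], x$ks_results$p_value[i]))
  invisible(x)
}

#' Read a predictions table
#'
#' TSV with columns `target_id`, `model_id`, `true_gdtts`,
#' `predicted_gdtts` (the joined input of [evaluate_pools()]), or the
#' three-column prediction output of the CLI.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_predictions_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("predictions file not found: '%s'", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(target_id = "character",
                                         model_id = "character"))
  df
}

#' Write an evaluation report
#'
#' Emits the per-target table as TSV and the aggregate statistics as JSON.
#'
#' @param report a `dmqa_eval_report`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "dmqa_eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(report$per_target, file.path(dir, "per_target.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    mean_ranking_loss = report$mean_ranking_loss,
    mean_pcc = report$mean_pcc,
    n_undefined_pcc = report$n_undefined_pcc,
    pooled_pcc = report$pooled_pcc,
    best_vs_selected_pcc = report$best_vs_selected_pcc,
    mean_random_loss = report$mean_random_loss,
    loss_skewness = report$loss_skewness,
    ks = report$ks_results)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Diagnostic plots of an evaluation
#'
#' `plot_selection_scatter`: true GDT-TS of each target's best model against
#' the true GDT-TS of the model selected by the predictions (points on the
#' 45-degree line have zero ranking loss). `plot_loss_histogram`: histogram
#' of the per-target ranking losses with the mean marked.
#'
#' @param pools data.frame as in [evaluate_pools()].
#' @param report a `dmqa_eval_report`.
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the plotted data.
#' @export
plot_selection_scatter <- function(pools, file = NULL) {
  rep <- evaluate_pools(pools)
  per <- lapply(split(pools, pools$target_id), function(sub) {
    top <- which(sub$predicted_gdtts == max(sub$predicted_gdtts))
    if (length(top) > 1) top <- top[order(sub$model_id[top])][1]
    c(best = max(sub$true_gdtts), selected = sub$true_gdtts[top])
  })
  per <- do.call(rbind, per)
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  plot(per[, "selected"], per[, "best"], xlim = c(0, 1), ylim = c(0, 1),
       xlab = "true GDT-TS of selected model",
       ylab = "true GDT-TS of best model",
       main = "Best vs selected model quality", pch = 19,
       col = grDevices::rgb(0, 0, 0.6, 0.6))
  graphics::abline(0, 1, col = "goldenrod", lwd = 2)
  if (stats::sd(per[, "selected"]) > 0)
    graphics::abline(stats::lm(per[, "best"] ~ per[, "selected"]),
                     col = "red")
  invisible(per)
}

#' @rdname plot_selection_scatter
#' @export
plot_loss_histogram <- function(report, file = NULL) {
  stopifnot(inherits(report, "dmqa_eval_report"))
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  losses <- report$per_target$ranking_loss
  graphics::hist(losses, breaks = 20, xlab = "ranking loss",
                 main = "Distribution of per-target ranking loss",
                 col = "grey80")
  graphics::abline(v = mean(losses), lty = 2, lwd = 2)
  invisible(losses)
}
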