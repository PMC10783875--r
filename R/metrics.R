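# Affinity-regression metrics and the ablation harnesses.

#' Compute the four affinity-prediction metrics
#'
#' RMSE and MAE of the predictions, Pearson's correlation R, and SD: the
#' standard deviation of the residuals about the least-squares regression of
#' the true values on the predictions (denominator N - 1), the scatter a
#' linear recalibration of the predictor cannot remove.
#'
#' @param y true values (pAff).
#' @param y_hat predicted values.
#' @return a `metric_report` with fields rmse, mae, sd, r and n.
#' @export
compute_metrics <- function(y, y_hat) {
  .assert(length(y) == length(y_hat) && length(y) >= 2L,
          "need equal-length vectors with at least 2 values")
  .assert(all(is.finite(y)) && all(is.finite(y_hat)), "values must be finite")
  rmse <- sqrt(mean((y - y_hat)^2))
  mae <- mean(abs(y - y_hat))
  if (stats::sd(y_hat) == 0) {
    warning("predictions have zero variance; R and SD undefined", call. = FALSE)
    r <- NaN
    sdv <- NaN
  } else {
    r <- stats::cor(y, y_hat)
    fit <- stats::lm.fit(cbind(1, y_hat), y)
    sdv <- sqrt(sum(fit$residuals^2) / (length(y) - 1L))
  }
  structure(list(rmse = rmse, mae = mae, sd = sdv, r = r, n = length(y)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n = %d | RMSE %.4f | MAE %.4f | SD %.4f | R %.4f\n",
              x$n, x$rmse, x$mae, x$sd, x$r))
  invisible(x)
}

# Rebuild a model with the same architecture but a different lambda /
# task set / initialization seed (fresh parameters).
.respawn_model <- function(model, lambda = NULL, enabled_tasks = NULL, seed = 1L) {
  cfg <- model$config
  mbp_model(encoder = cfg$encoder, d_interaction = cfg$d_interaction,
            head_hidden = cfg$head_hidden,
            lambda = lambda %||% cfg$lambda,
            enabled_tasks = enabled_tasks %||% cfg$enabled_tasks,
            cutoffs = cfg$cutoffs, full_protein = cfg$full_protein,
            schema = cfg$schema, seed = seed)
}

.one_ablation_run <- function(model, data, pre_cfg, fine_cfg, seed) {
  pre_cfg$seed <- seed
  fine_cfg$seed <- seed
  fit_pre <- pretrain(model, data$assays, data$complexes, pre_cfg)
  fit <- finetune(fit_pre$best_model, data$train, data$val, data$complexes,
                  fine_cfg)
  pred <- vapply(seq_len(nrow(data$test)), function(i) {
    .predict_bundle(fit$model, data$complexes[[data$test$complex_id[i]]],
                    data$test$task_type[i])
  }, numeric(1))
  m <- compute_metrics(data$test$y_paff, pred)
  data.frame(seed = seed, rmse = m$rmse, mae = m$mae, sd = m$sd, r = m$r,
             final_rank_loss = utils::tail(fit_pre$history$loss_rank, 1L))
}

#' Ablation over the regression-loss weight lambda
#'
#' Runs one full pretrain + finetune cycle per (lambda, seed) combination on
#' the supplied data and reports test metrics; the canonical grid is
#' `c(0, 0.01, 0.1, 0.3, 1.0)` (lambda = 0 is the pure-ranking objective).
#'
#' @param model template [mbp_model()] (architecture reused; parameters are
#'   re-initialized per run with the run's seed).
#' @param data list with `assays`, `complexes` (prepared bundles keyed by
#'   ligand/complex id), and `train`/`val`/`test` data frames
#'   (`complex_id`, `y_paff`, `task_type`).
#' @param lambdas numeric grid of regression weights.
#' @param seeds integer seeds; each (lambda, seed) is one run.
#' @param pretrain_config,finetune_config [train_config()] objects.
#' @return data frame with one row per run: lambda, seed, rmse, mae, sd, r
#'   and the final pre-training ranking loss.
#' @export
run_lambda_ablation <- function(model, data, lambdas = c(0, 0.01, 0.1, 0.3, 1.0),
                                seeds = 1L,
                                pretrain_config = train_config("pretrain"),
                                finetune_config = train_config("finetune")) {
  .assert(length(lambdas) >= 1L, "lambda grid must be non-empty")
  out <- list()
  for (lam in lambdas) {
    for (sd in seeds) {
      m <- .respawn_model(model, lambda = lam, seed = sd)
      row <- .one_ablation_run(m, data, pretrain_config, finetune_config, sd)
      row$lambda <- lam
      out[[length(out) + 1L]] <- row
    }
  }
  df <- do.call(rbind, out)
  df[, c("lambda", setdiff(names(df), "lambda"))]
}

#' Ablation over enabled pre-training tasks
#'
#' @param model template [mbp_model()].
#' @param data as in [run_lambda_ablation()].
#' @param task_sets list of task subsets (character vectors over
#'   `c("ic50_reg", "ic50_rank", "k_reg", "k_rank")`).
#' @param seeds integer seeds.
#' @param pretrain_config,finetune_config [train_config()] objects.
#' @return data frame with one row per run and a `tasks` label column.
#' @export
run_task_ablation <- function(model, data, task_sets, seeds = 1L,
                              pretrain_config = train_config("pretrain"),
                              finetune_config = train_config("finetune")) {
  .assert(length(task_sets) >= 1L, "need at least one task subset")
  out <- list()
  for (ts in task_sets) {
    for (sd in seeds) {
      m <- .respawn_model(model, enabled_tasks = ts, seed = sd)
      row <- .one_ablation_run(m, data, pretrain_config, finetune_config, sd)
      row$tasks <- paste(sort(ts), collapse = "+")
      out[[length(out) + 1L]] <- row
    }
  }
  df <- do.call(rbind, out)
  df[, c("tasks", setdiff(names(df), "tasks"))]
}

#' Summarize ablation runs as mean (sd) per condition
#'
#' @param df output of an ablation runner.
#' @param by grouping column, e.g. `"lambda"` or `"tasks"`.
#' @return data frame of per-condition means and standard deviations of the
#'   four metrics.
#' @export
summarize_ablation <- function(df, by) {
  .assert(by %in% names(df), "grouping column not found")
  agg <- function(fun) stats::aggregate(df[, c("rmse", "mae", "sd", "r")],
                                        by = df[by], FUN = fun)
  m <- agg(mean)
  s <- agg(stats::sd)
  names(s)[-1L] <- paste0(names(s)[-1L], "_sd")
  merge(m, s, by = by)
}
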