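#' Rank-based ROC AUC
#'
#' The Mann-Whitney form of the area under the ROC curve: the probability
#' that a random positive scores above a random negative, with ties counting
#' one half. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric score (probability) vector.
#' @param labels binary 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Running maximum of a performance series
#'
#' The monotone "best-so-far" presentation of a test-AUC-versus-round curve:
#' each point is the highest value achieved over all previous rounds.
#' Idempotent; same length as the input.
#'
#' @param series numeric vector.
#' @return monotone non-decreasing vector of the same length.
#' @export
best_so_far <- function(series) {
  if (length(series) == 0L) stop("series must be non-empty", call. = FALSE)
  cummax(series)
}

#' Average epochs per participating client over a run
#'
#' The computational-complexity metric: the expected total number of training
#' epochs a single participating client runs across the whole federated
#' process, `sum_t sum_{k in round t} epochs(k, t) / m`. For FedAvg this is
#' exactly `T * E`; under loss-adaptive boosting it varies with the data.
#'
#' @param history a `run_history`, or a data.frame like [history_table()]'s
#'   output with columns `round` and `epochs_trained`.
#' @return the average-epochs value.
#' @export
average_epochs <- function(history) {
  tab <- if (inherits(history, "run_history")) history_table(history) else history
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("history is empty", call. = FALSE)
  }
  per_round <- tapply(tab$epochs_trained, tab$round, mean)
  sum(per_round)
}

#' Cross-validation plan over clients
#'
#' Folds partition the client set (not the examples): with 90 clients and 10
#' folds, each fold holds 9 whole clients. Repeats re-randomize the fold
#' assignment; fold assignment depends only on the plan seed and repeat index,
#' so two methods evaluated under the same plan see identical folds (a paired
#' design).
#'
#' @param n_folds number of folds (must divide the client count).
#' @param n_repeats number of repeats.
#' @param seed plan seed.
#' @return an object of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10L, n_repeats = 5L, seed = 1L) {
  stop_if_not_count(n_folds, "n_folds")
  stop_if_not_count(n_repeats, "n_repeats")
  structure(
    list(
      n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
      seed = as.integer(seed)
    ),
    class = "cv_plan"
  )
}

#' Fold assignment for one repeat
#'
#' @param K number of clients.
#' @param plan a [cv_plan()].
#' @param repeat_index which repeat.
#' @return integer vector of length `K`: fold index of each client.
#' @export
fold_assignment <- function(K, plan, repeat_index) {
  if (K %% plan$n_folds != 0L) {
    stop(sprintf("%d clients cannot be split into %d equal folds", K, plan$n_folds),
      call. = FALSE
    )
  }
  set.seed(derive_seed(plan$seed, 555L, repeat_index))
  perm <- sample.int(K)
  assign <- integer(K)
  assign[perm] <- rep(seq_len(plan$n_folds), each = K %/% plan$n_folds)
  assign
}

pool_shards <- function(shards) {
  n <- sum(vapply(shards, function(s) length(s$labels), integer(1)))
  new_patient_cohort(
    features = do.call(rbind, lapply(shards, `[[`, "features")),
    age_group = rep(0L, n), gender = rep(0L, n),
    mortality = unlist(lapply(shards, `[[`, "labels")),
    ids = unlist(lapply(shards, `[[`, "ids"))
  )
}

#' Client-level k-fold cross-validation of a federated method
#'
#' For each repeat: shuffle the clients into folds; treat each fold in turn as
#' the test set, train the configured method on the remaining folds' clients,
#' and record the final global model's predictions on the held-out fold's
#' pooled examples. One AUC per repeat is computed from the pooled
#' cross-fold predictions against the true labels, alongside the run's
#' average-epochs metric. When `holdout` is supplied and `config` carries
#' `alpha`/`beta`, the data-sharing pool is built from the holdout and
#' distributed to the training clients of every fold at initialization.
#'
#' @param shards list of `K` `client_shard`s (partition the cohort before
#'   calling; apply non-IID sorting at partition time if wanted).
#' @param plan a [cv_plan()].
#' @param config a [fed_config()]; the per-fold client count `K` is derived
#'   internally from the training folds, so `config$K` is ignored here.
#' @param holdout optional `patient_cohort` backing the data-sharing pool.
#' @return list with `auc` (one pooled AUC per repeat), `avg_epochs` (mean
#'   average-epochs per repeat), and `per_fold` (data.frame of repeat, fold,
#'   average epochs).
#' @export
cross_validate <- function(shards, plan, config, holdout = NULL) {
  K <- length(shards)
  n_folds <- plan$n_folds
  auc <- numeric(plan$n_repeats)
  ae <- numeric(plan$n_repeats)
  per_fold <- list()
  sharing <- !is.null(config$alpha) && !is.null(config$beta)
  if (sharing && is.null(holdout)) {
    stop("data-sharing requested but no holdout supplied", call. = FALSE)
  }
  for (rep_i in seq_len(plan$n_repeats)) {
    assign <- fold_assignment(K, plan, rep_i)
    preds <- numeric(0)
    labs <- integer(0)
    fold_epochs <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      train_shards <- shards[assign != f]
      test_pool <- pool_shards(shards[assign == f])
      cfg <- config
      cfg$K <- length(train_shards)
      cfg$seed <- derive_seed(config$seed, 7000L + rep_i, f)
      if (sharing) {
        total <- sum(vapply(train_shards, function(s) s$n_local, integer(1)))
        pool <- build_shared_pool(holdout, cfg$beta, total,
          seed = derive_seed(cfg$seed, 31L)
        )
        train_shards <- distribute_shared_data(pool, cfg$alpha, train_shards,
          seed = derive_seed(cfg$seed, 32L)
        )
      }
      hist <- run_experiment(cfg, train_shards, test_set = NULL)
      preds <- c(preds, fed_predict(hist$final_weights, test_pool$features))
      labs <- c(labs, test_pool$mortality)
      fold_epochs[f] <- average_epochs(hist)
    }
    auc[rep_i] <- roc_auc(preds, labs)
    ae[rep_i] <- mean(fold_epochs)
    per_fold[[rep_i]] <- data.frame(
      repeat_index = rep_i, fold = seq_len(n_folds), avg_epochs = fold_epochs
    )
  }
  list(auc = auc, avg_epochs = ae, per_fold = do.call(rbind, per_fold))
}

#' Exact one-sided Wilcoxon signed-rank test
#'
#' Tests whether paired differences (method B minus method A) are
#' systematically positive, by exact enumeration of all `2^n` sign
#' assignments of the absolute-difference ranks (tied ranks handled by
#' midranks). With five repeats all favouring one method the one-sided p is
#' `1/32 = 0.03125`. Zero differences are dropped before ranking (the
#' standard reduction); an all-zero input is an error.
#'
#' @param paired_differences numeric vector (`n <= 20` after dropping zeros).
#' @param alternative `"greater"` (default: B > A) or `"two.sided"`.
#' @return the exact p-value.
#' @export
signed_rank_test <- function(paired_differences,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- paired_differences[paired_differences != 0]
  if (length(d) == 0L) stop("all paired differences are zero", call. = FALSE)
  n <- length(d)
  if (n > 20L) stop("exact enumeration supports n <= 20", call. = FALSE)
  r2 <- as.integer(round(2 * rank(abs(d)))) # doubled ranks: integers even with ties
  W2 <- sum(r2[d > 0])
  # distribution of the doubled positive-rank sum over all 2^n sign choices,
  # by convolution (equivalent to full enumeration)
  counts <- 1
  offset <- 0L
  for (r in r2) {
    new_counts <- numeric(length(counts) + r)
    new_counts[seq_along(counts)] <- counts
    new_counts[r + seq_along(counts)] <- new_counts[r + seq_along(counts)] + counts
    counts <- new_counts
  }
  total <- 2^n
  sums <- seq_along(counts) - 1L
  p_greater <- sum(counts[sums >= W2]) / total
  if (alternative == "greater") {
    p_greater
  } else {
    p_less <- sum(counts[sums <= W2]) / total
    min(1, 2 * min(p_greater, p_less))
  }
}

#' Paired comparison of two federated methods under cross-validation
#'
#' Runs [cross_validate()] for both configurations under the same plan (hence
#' identical fold assignments and training seeds — a paired design), and
#' summarizes per-repeat AUCs, average epochs, and the exact one-sided
#' signed-rank p-value for "B beats A".
#'
#' @param shards list of `client_shard`s.
#' @param plan a [cv_plan()].
#' @param config_a,config_b the two [fed_config()]s (e.g. FedAvg vs
#'   LoAdaBoost); they should share the seed for pairing.
#' @param holdout optional holdout for data-sharing.
#' @return an object of class `comparison_result`: per-repeat AUC pairs,
#'   mean/sd per method, average epochs per method, and the p-value.
#' @export
compare_methods <- function(shards, plan, config_a, config_b, holdout = NULL) {
  res_a <- cross_validate(shards, plan, config_a, holdout = holdout)
  res_b <- cross_validate(shards, plan, config_b, holdout = holdout)
  structure(
    list(
      method_a = config_a$method, method_b = config_b$method,
      auc_a = res_a$auc, auc_b = res_b$auc,
      mean_a = mean(res_a$auc), sd_a = stats::sd(res_a$auc),
      mean_b = mean(res_b$auc), sd_b = stats::sd(res_b$auc),
      avg_epochs_a = mean(res_a$avg_epochs),
      avg_epochs_b = mean(res_b$avg_epochs),
      p_value = signed_rank_test(res_b$auc - res_a$auc)
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<comparison_result>\n  %s: AUC %.4f +- %.4f, avg epochs %.1f\n",
      "  %s: AUC %.4f +- %.4f, avg epochs %.1f\n  one-sided p = %.5f\n"
    ),
    x$method_a, x$mean_a, x$sd_a, x$avg_epochs_a,
    x$method_b, x$mean_b, x$sd_b, x$avg_epochs_b, x$p_value
  ))
  invisible(x)
}
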