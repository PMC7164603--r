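#' Federated run configuration
#'
#' Bundles the protocol parameters: `K` clients, participating fraction `C`
#' (`m = max(floor(C * K), 1)` clients are sampled each round), local epochs
#' `E`, minibatch size `B`, maximum global rounds `T_max`, the method
#' (`"fedavg"` or `"loadaboost"`), optional data-sharing parameters `alpha`
#' (fraction of the shared pool delivered to each client) and `beta` (pool
#' size as a fraction of the total client examples), and the run seed from
#' which all round-, client- and sampling-level seeds are derived.
#'
#' @param K total number of clients.
#' @param C fraction of clients participating per round, in `[0, 1]`.
#' @param E local epochs per round.
#' @param B minibatch size.
#' @param T_max maximum number of global rounds.
#' @param method `"fedavg"` or `"loadaboost"`.
#' @param alpha,beta optional data-sharing fractions (both or neither).
#' @param learning_rate,beta1,beta2 Adam hyperparameters.
#' @param seed run seed.
#' @return an object of class `fed_config`.
#' @export
fed_config <- function(K, C = 0.1, E = 5L, B = 30L, T_max = 20L,
                       method = c("fedavg", "loadaboost"),
                       alpha = NULL, beta = NULL,
                       learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                       seed = 1L) {
  method <- match.arg(method)
  stop_if_not_count(K, "K")
  stop_if_not_count(E, "E")
  stop_if_not_count(T_max, "T_max")
  if (C < 0 || C > 1) stop("C must lie in [0, 1]", call. = FALSE)
  if (xor(is.null(alpha), is.null(beta))) {
    stop("alpha and beta must be supplied together", call. = FALSE)
  }
  if (!is.null(alpha) && (alpha < 0 || alpha > 1)) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      K = as.integer(K), C = C, E = as.integer(E), B = as.integer(B),
      T_max = as.integer(T_max), method = method,
      alpha = alpha, beta = beta,
      learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
      seed = as.integer(seed)
    ),
    class = "fed_config"
  )
}

fed_train_config <- function(config, E, seed) {
  train_config(
    E = E, B = config$B, learning_rate = config$learning_rate,
    beta1 = config$beta1, beta2 = config$beta2, seed = seed
  )
}

#' Number of clients participating per round
#' @param K total clients.
#' @param C participating fraction in `[0, 1]`.
#' @return `max(floor(C * K), 1)`: at least one client trains every round.
#' @export
n_participating <- function(K, C) {
  max(floor(C * K), 1L)
}

#' Sample the participating clients for one round
#'
#' Uniform sample without replacement of size `max(floor(C * K), 1)`,
#' re-drawn independently each round.
#'
#' @param K total clients (`>= 1`).
#' @param C participating fraction in `[0, 1]`.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return integer vector of client ids.
#' @export
sample_clients <- function(K, C, seed = NULL) {
  stop_if_not_count(K, "K")
  if (C < 0 || C > 1) stop("C must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- n_participating(K, C)
  sort(sample.int(K, m))
}

#' Build the globally shared data pool
#'
#' A uniform subsample `G` of the server-held IID holdout, of size
#' `round(beta * total_client_examples)` — e.g. 27,000 client examples at
#' `beta = 1%` give a 270-example pool.
#'
#' @param holdout a `patient_cohort` (the IID holdout).
#' @param beta pool size as a fraction of the total client examples.
#' @param total_client_examples total number of examples across all clients.
#' @param seed optional seed.
#' @return a `patient_cohort` of the pool.
#' @export
build_shared_pool <- function(holdout, beta, total_client_examples, seed = NULL) {
  size <- round(beta * total_client_examples)
  if (size > n_patients(holdout)) {
    stop("shared pool larger than the holdout set", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- if (size > 0) sort(sample.int(n_patients(holdout), size)) else integer()
  cohort_subset(holdout, idx)
}

#' Distribute shared data to the clients at initialization
#'
#' Each client independently receives a uniform random fraction `alpha` of the
#' pool (`round(alpha * |G|)` examples), appended once to its local shard
#' before round 1. Different clients may receive overlapping subsets.
#'
#' @param pool a `patient_cohort` from [build_shared_pool()].
#' @param alpha per-client fraction of the pool, in `[0, 1]`.
#' @param shards list of `client_shard`s.
#' @param seed optional seed.
#' @return the shards with shared examples appended (`n_shared` set).
#' @export
distribute_shared_data <- function(pool, alpha, shards, seed = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  npool <- n_patients(pool)
  take <- round(alpha * npool)
  if (take == 0L) {
    return(shards)
  }
  lapply(shards, function(sh) {
    idx <- sort(sample.int(npool, take))
    new_client_shard(
      client_id = sh$client_id,
      ids = c(sh$ids, pool$ids[idx]),
      features = rbind(sh$features, pool$features[idx, , drop = FALSE]),
      labels = c(sh$labels, pool$mortality[idx]),
      n_local = sh$n_local,
      n_shared = take
    )
  })
}

#' Initialize the server state
#'
#' Round index 0, globally shared initial weights `w_0` (Glorot-uniform from
#' the run seed, identical for every method at the same seed), and the
#' previous-round median client loss initialized to 1.0 — the round-1
#' retraining criterion.
#'
#' @param spec a [network_spec()].
#' @param config a [fed_config()].
#' @return an object of class `server_state`.
#' @export
init_server <- function(spec, config) {
  structure(
    list(
      t = 0L,
      average_weights = init_weights(spec, seed = derive_seed(config$seed, 0L)),
      median_loss_prev = 1.0
    ),
    class = "server_state"
  )
}

# Seeds: client sampling uses tag 9001 + round; client training uses
# (seed, round, client) so updates are order-independent and a LoAdaBoost
# round with no retraining is bit-identical to a FedAvg round at the same
# initial epoch count.
round_sampling_seed <- function(config, t) derive_seed(config$seed, 9001L, t)
client_seed <- function(config, t, k) derive_seed(config$seed, t, k)
retrain_seed <- function(config, t, k, r) derive_seed(config$seed, t, k, 1000L + r)

#' One FedAvg global round
#'
#' Samples `m` clients, trains each for exactly `E` epochs from the current
#' average weights, and replaces the server weights with the unweighted mean
#' of the returned client weights.
#'
#' @param state a `server_state`.
#' @param shards list of `client_shard`s (length `K`).
#' @param config a [fed_config()].
#' @return list with the advanced `state` and the list of client `updates`
#'   (each: `client_id`, `weights`, `reported_loss`, `epochs_trained`,
#'   `retrain_rounds`).
#' @export
run_fedavg_round <- function(state, shards, config) {
  t <- state$t + 1L
  ids <- sample_clients(config$K, config$C, seed = round_sampling_seed(config, t))
  updates <- lapply(ids, function(k) {
    res <- train_local(
      state$average_weights, shards[[k]], config$E,
      fed_train_config(config, config$E, client_seed(config, t, k))
    )
    list(
      client_id = k, weights = res$weights, reported_loss = res$loss,
      epochs_trained = res$epochs, retrain_rounds = 0L
    )
  })
  state$average_weights <- average_weights(lapply(updates, `[[`, "weights"))
  state$t <- t
  list(state = state, updates = updates)
}

#' Retraining epoch schedule for a loss-boosted client
#'
#' Initial training lasts `ceiling(E / 2)` epochs (E/2 rounded up for odd E);
#' retraining round `r` grants `max(ceiling(E / 2) - r + 1, 1)` epochs; the
#' cumulative budget over initial training plus retraining is
#' `floor(3 * E / 2)` epochs, and the final retraining round is truncated so
#' the budget is never exceeded. A client therefore trains at least `E/2` and
#' at most `3E/2` epochs in a round.
#'
#' @param E local epochs per round (`>= 1`).
#' @return list with `initial` (epochs before the loss check), `grants`
#'   (epoch allowance of each retraining round, already truncated to the
#'   budget) and `budget` (total epoch cap `floor(3E/2)`).
#' @examples
#' retrain_schedule(10) # initial 5; grants 5, 4, 1; budget 15
#' retrain_schedule(5)  # initial 3; grants 3, 1; budget 7
#' retrain_schedule(1)  # initial 1; no retraining possible
#' @export
retrain_schedule <- function(E) {
  stop_if_not_count(E, "E")
  half_up <- ceiling(E / 2)
  budget <- floor(3 * E / 2)
  grants <- integer()
  cum <- half_up
  r <- 1L
  repeat {
    g <- max(half_up - r + 1L, 1L)
    g <- min(g, budget - cum)
    if (g <= 0L) break
    grants <- c(grants, g)
    cum <- cum + g
    r <- r + 1L
  }
  list(initial = as.integer(half_up), grants = grants, budget = as.integer(budget))
}

#' One client's loss-adaptive update (LoAdaBoost)
#'
#' Trains `ceiling(E / 2)` epochs from the server's average weights to obtain
#' `(w0, L0)`. If `L0` does not exceed the previous round's median client loss
#' the update is finished. Otherwise the client is retrained on the decaying
#' schedule of [retrain_schedule()], re-evaluating the training loss after
#' each retraining round and stopping as soon as the loss drops to the median
#' or the `3E/2` epoch budget is exhausted. The loss reported to the server is
#' always the pre-retraining loss `L0`; the weights are the final ones.
#'
#' @param state a `server_state` carrying `median_loss_prev`.
#' @param shard the client's `client_shard`.
#' @param config a [fed_config()].
#' @param client_id client index (used for seed derivation).
#' @param t global round index (defaults to the next round of `state`).
#' @return a client update list: `client_id`, `weights`, `reported_loss`,
#'   `epochs_trained`, `retrain_rounds`.
#' @export
loadaboost_client_update <- function(state, shard, config, client_id,
                                     t = state$t + 1L) {
  sched <- retrain_schedule(config$E)
  res <- train_local(
    state$average_weights, shard, sched$initial,
    fed_train_config(config, config$E, client_seed(config, t, client_id))
  )
  L0 <- res$loss
  weights <- res$weights
  epochs <- sched$initial
  retrains <- 0L
  if (L0 > state$median_loss_prev) {
    for (r in seq_along(sched$grants)) {
      res <- train_local(
        weights, shard, sched$grants[r],
        fed_train_config(config, config$E, retrain_seed(config, t, client_id, r))
      )
      weights <- res$weights
      epochs <- epochs + sched$grants[r]
      retrains <- r
      if (res$loss <= state$median_loss_prev) break
    }
  }
  list(
    client_id = client_id, weights = weights, reported_loss = L0,
    epochs_trained = as.integer(epochs), retrain_rounds = retrains
  )
}

#' Median of reported client losses
#'
#' The server's robustness criterion: the sample median (mean of the central
#' order-statistic pair for even counts) of the losses reported this round,
#' used as the retraining threshold next round.
#'
#' @param reported_losses non-empty numeric vector of nonnegative losses.
#' @return the median.
#' @export
median_loss <- function(reported_losses) {
  if (length(reported_losses) == 0L) {
    stop("cannot take the median of zero losses", call. = FALSE)
  }
  stats::median(reported_losses)
}

#' One LoAdaBoost global round
#'
#' Samples clients exactly as FedAvg does, runs [loadaboost_client_update()]
#' for each (updates are seed-isolated, so order has no effect), averages the
#' final client weights, and sets the next round's median-loss criterion from
#' the reported pre-retraining losses.
#'
#' @inheritParams run_fedavg_round
#' @return list with the advanced `state` and the client `updates`.
#' @export
run_loadaboost_round <- function(state, shards, config) {
  t <- state$t + 1L
  ids <- sample_clients(config$K, config$C, seed = round_sampling_seed(config, t))
  updates <- lapply(ids, function(k) {
    loadaboost_client_update(state, shards[[k]], config, k, t = t)
  })
  state$average_weights <- average_weights(lapply(updates, `[[`, "weights"))
  state$median_loss_prev <- median_loss(
    vapply(updates, `[[`, numeric(1), "reported_loss")
  )
  state$t <- t
  list(state = state, updates = updates)
}

#' Run a full federated experiment
#'
#' Initializes the server from the run seed (identical initial weights for
#' every method at the same seed), iterates global rounds to `T_max`, and
#' evaluates the global model on `test_set` after every round. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [fed_config()].
#' @param shards list of `K` `client_shard`s.
#' @param test_set optional `patient_cohort` evaluated each round (rank-based
#'   ROC AUC of the global model).
#' @return an object of class `run_history`: per-round records (participating
#'   ids; per-client epochs, reported loss and retrain count; server median
#'   loss; test AUC), the AUC series with its running maximum, and the final
#'   global weights.
#' @export
run_experiment <- function(config, shards, test_set = NULL) {
  if (length(shards) != config$K) {
    stop("length(shards) must equal config$K", call. = FALSE)
  }
  spec <- network_spec(
    input_dim = ncol(shards[[1]]$features),
    hidden = c(20L, 10L, 5L)
  )
  state <- init_server(spec, config)
  step <- switch(config$method,
    fedavg = run_fedavg_round,
    loadaboost = run_loadaboost_round
  )
  rounds <- vector("list", config$T_max)
  auc <- rep(NA_real_, config$T_max)
  for (t in seq_len(config$T_max)) {
    out <- step(state, shards, config)
    state <- out$state
    if (!is.null(test_set)) {
      auc[t] <- roc_auc(
        fed_predict(state$average_weights, test_set$features),
        test_set$mortality
      )
    }
    rounds[[t]] <- list(
      round = t,
      client_ids = vapply(out$updates, `[[`, integer(1), "client_id"),
      epochs_trained = vapply(out$updates, `[[`, integer(1), "epochs_trained"),
      reported_loss = vapply(out$updates, `[[`, numeric(1), "reported_loss"),
      retrain_rounds = vapply(out$updates, `[[`, integer(1), "retrain_rounds"),
      median_loss = state$median_loss_prev,
      test_auc = auc[t]
    )
  }
  structure(
    list(
      config = config, rounds = rounds, auc = auc,
      best_auc = if (!is.null(test_set)) best_so_far(auc) else auc,
      final_weights = state$average_weights
    ),
    class = "run_history"
  )
}

#' @export
print.run_history <- function(x, ...) {
  cat(sprintf(
    "<run_history> method=%s, %d rounds, avg epochs/client = %.2f%s\n",
    x$config$method, length(x$rounds), average_epochs(x),
    if (!all(is.na(x$auc))) sprintf(", final best AUC = %.4f", max(x$best_auc)) else ""
  ))
  invisible(x)
}

#' Per-round history as a data frame
#'
#' One row per (round, client): round, client id, epochs trained, reported
#' loss, retraining rounds.
#'
#' @param history a `run_history`.
#' @return a data.frame.
#' @export
history_table <- function(history) {
  do.call(rbind, lapply(history$rounds, function(rd) {
    data.frame(
      round = rd$round, client_id = rd$client_ids,
      epochs_trained = rd$epochs_trained,
      reported_loss = rd$reported_loss,
      retrain_rounds = rd$retrain_rounds
    )
  }))
}
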