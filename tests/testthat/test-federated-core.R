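test_that("client sampling draws max(floor(C*K), 1) clients without replacement", {
  expect_length(sample_clients(90, 0.1, seed = 1), 9)
  expect_length(sample_clients(90, 0, seed = 1), 1) # at least one client trains
  expect_length(sample_clients(90, 1, seed = 1), 90)
  s <- sample_clients(40, 0.5, seed = 2)
  expect_false(any(duplicated(s)))
  expect_true(all(s %in% 1:40))
  expect_error(sample_clients(0, 0.5), ">= 1")
})

test_that("shared-pool and per-client share sizes follow the alpha/beta arithmetic", {
  holdout <- small_cohort(n = 3000, d = 3, seed = 2)
  pool <- build_shared_pool(holdout, beta = 0.01, total_client_examples = 27000, seed = 1)
  expect_equal(n_patients(pool), 270)
  expect_false(any(duplicated(pool$ids))) # sampled without replacement

  train <- small_cohort(n = 900, d = 3, seed = 3)
  shards <- partition_iid(train, 9, seed = 1)
  with10 <- distribute_shared_data(pool, 0.10, shards, seed = 4)
  expect_true(all(vapply(with10, function(s) s$n_shared, integer(1)) == 27L))
  expect_true(all(vapply(with10, function(s) nrow(s$features), integer(1)) == 127L))
  with20 <- distribute_shared_data(pool, 0.20, shards, seed = 4)
  expect_true(all(vapply(with20, function(s) s$n_shared, integer(1)) == 54L))
  # alpha = 0 and beta = 0 are no-ops
  expect_identical(distribute_shared_data(pool, 0, shards, seed = 4), shards)
  expect_equal(n_patients(build_shared_pool(holdout, 0, 27000)), 0)
  expect_error(build_shared_pool(holdout, 0.5, 27000), "larger than the holdout")
  expect_error(distribute_shared_data(pool, 1.2, shards), "alpha")
})

test_that("the retraining schedule matches an epoch-by-epoch replay of the rules", {
  for (E in 1:16) {
    sched <- retrain_schedule(E)
    oracle <- oracle_retrain_grants(E)
    expect_equal(sched$initial, oracle$initial, info = paste("E =", E))
    expect_equal(sched$grants, oracle$grants, info = paste("E =", E))
    expect_equal(sched$budget, oracle$budget, info = paste("E =", E))
    # cumulative epochs never exceed the 3E/2 budget and reach it exactly
    # when every grant is used
    expect_equal(sched$initial + sum(sched$grants), oracle$budget)
  }
  # the worked examples
  s10 <- retrain_schedule(10)
  expect_equal(s10$initial, 5)
  expect_equal(s10$budget, 15)
  expect_equal(cumsum(c(s10$initial, s10$grants)), c(5, 10, 14, 15))
  s5 <- retrain_schedule(5)
  expect_equal(s5$initial, 3)
  expect_equal(s5$grants, c(3, 1))
  s1 <- retrain_schedule(1)
  expect_length(s1$grants, 0) # budget 1: no retraining possible
  expect_error(retrain_schedule(0), ">= 1")
})

make_state <- function(spec, cfg, median = 1.0) {
  st <- init_server(spec, cfg)
  st$median_loss_prev <- median
  st
}

test_that("a client below the median trains ceiling(E/2) epochs and never retrains", {
  shard <- separable_shard(n = 120, d = 8, seed = 3)
  cfg <- fed_config(K = 1, C = 1, E = 5, T_max = 1, method = "loadaboost", seed = 4)
  spec <- network_spec(8, c(6, 3))
  st <- make_state(spec, cfg, median = Inf)
  up <- loadaboost_client_update(st, shard, cfg, client_id = 1L)
  expect_equal(up$epochs_trained, 3)
  expect_equal(up$retrain_rounds, 0)
})

test_that("a client that cannot reach the median exhausts the full 3E/2 budget", {
  # no-signal shard: labels independent of features, so the training loss
  # cannot drop to an unattainably small median
  co <- generate_cohort(cohort_config(
    n_patients = 100, n_drugs = 8, effect_scale = 0,
    covariate_effects = c(age_group = 0, gender = 0), seed = 6
  ))
  shard <- partition_iid(co, 1, seed = 1)[[1]]
  cfg <- fed_config(K = 1, C = 1, E = 4, T_max = 1, method = "loadaboost", seed = 5)
  spec <- network_spec(8, c(6, 3))
  st <- make_state(spec, cfg, median = 1e-9)
  up <- loadaboost_client_update(st, shard, cfg, client_id = 1L)
  expect_equal(up$epochs_trained, 6) # floor(3 * 4 / 2)
  expect_gt(up$retrain_rounds, 0)
  # the reported loss is the pre-retraining loss, necessarily above the median
  expect_gt(up$reported_loss, st$median_loss_prev)
})

test_that("epoch counts always stay within [ceiling(E/2), floor(3E/2)] and retraining
           triggers exactly when the reported loss exceeds the median", {
  co <- generate_cohort(cohort_config(n_patients = 300, n_drugs = 10, seed = 7))
  shards <- partition_iid(co, 6, seed = 2)
  spec <- network_spec(10, c(6, 3))
  for (E in c(1, 2, 5, 7)) {
    cfg <- fed_config(K = 6, C = 1, E = E, T_max = 1, method = "loadaboost", seed = E)
    for (med in c(0.3, 0.69, 2)) {
      st <- make_state(spec, cfg, median = med)
      for (k in c(1L, 4L)) {
        up <- loadaboost_client_update(st, shards[[k]], cfg, client_id = k)
        expect_gte(up$epochs_trained, ceiling(E / 2))
        expect_lte(up$epochs_trained, floor(3 * E / 2))
        if (length(retrain_schedule(E)$grants) > 0) {
          expect_equal(up$retrain_rounds > 0, up$reported_loss > med)
        } else {
          expect_equal(up$retrain_rounds, 0) # E = 1: budget leaves no room
        }
      }
    }
  }
})

test_that("a LoAdaBoost round with no retraining is bit-identical to FedAvg at ceiling(E/2) epochs", {
  co <- generate_cohort(cohort_config(n_patients = 450, n_drugs = 12, seed = 8))
  shards <- partition_iid(co, 9, seed = 3)
  spec <- network_spec(12, c(8, 4))
  cfg_lo <- fed_config(K = 9, C = 1 / 3, E = 6, T_max = 1, method = "loadaboost", seed = 21)
  cfg_fa <- fed_config(K = 9, C = 1 / 3, E = 3, T_max = 1, method = "fedavg", seed = 21)
  st_lo <- make_state(spec, cfg_lo, median = Inf) # criterion cannot trigger
  st_fa <- init_server(spec, cfg_fa)
  out_lo <- run_loadaboost_round(st_lo, shards, cfg_lo)
  out_fa <- run_fedavg_round(st_fa, shards, cfg_fa)
  expect_identical(
    vapply(out_lo$updates, `[[`, integer(1), "client_id"),
    vapply(out_fa$updates, `[[`, integer(1), "client_id")
  )
  expect_identical(
    flatten_weights(out_lo$state$average_weights),
    flatten_weights(out_fa$state$average_weights)
  )
})

test_that("the server's next-round median is the median of the reported pre-retraining losses", {
  expect_equal(median_loss(0.3), 0.3)
  expect_equal(median_loss(c(0.2, 0.4, 0.9)), 0.4)
  expect_equal(median_loss(c(0.1, 0.2, 0.6, 1.0)), 0.4) # midpoint of the central pair
  expect_error(median_loss(numeric()), "zero losses")

  co <- generate_cohort(cohort_config(n_patients = 200, n_drugs = 10, seed = 9))
  shards <- partition_iid(co, 4, seed = 4)
  cfg <- fed_config(K = 4, C = 1, E = 3, T_max = 1, method = "loadaboost", seed = 31)
  st <- init_server(network_spec(10, c(6, 3)), cfg)
  expect_equal(st$median_loss_prev, 1.0) # round-1 criterion
  out <- run_loadaboost_round(st, shards, cfg)
  expect_equal(
    out$state$median_loss_prev,
    median(vapply(out$updates, `[[`, numeric(1), "reported_loss"))
  )
})

test_that("run_experiment produces T_max rounds of m updates, reproducibly", {
  co <- generate_cohort(cohort_config(n_patients = 360, n_drugs = 10, seed = 10))
  shards <- partition_iid(co, 6, seed = 5)
  test_co <- small_cohort(n = 120, d = 10, seed = 12)
  cfg <- fed_config(K = 6, C = 0.5, E = 2, T_max = 4, method = "fedavg", seed = 41)
  h <- run_experiment(cfg, shards, test_set = test_co)
  expect_length(h$rounds, 4)
  expect_true(all(vapply(h$rounds, function(r) length(r$client_ids), integer(1)) == 3L))
  # FedAvg cumulative epochs per participating client: T * E exactly
  expect_equal(average_epochs(h), 4 * 2)
  # same config -> identical history; both methods share round-0 weights
  h2 <- run_experiment(cfg, shards, test_set = test_co)
  expect_identical(h$auc, h2$auc)
  expect_identical(flatten_weights(h$final_weights), flatten_weights(h2$final_weights))
  cfg_lo <- cfg
  cfg_lo$method <- "loadaboost"
  spec <- network_spec(10, c(20, 10, 5))
  expect_identical(
    flatten_weights(init_server(spec, cfg)$average_weights),
    flatten_weights(init_server(spec, cfg_lo)$average_weights)
  )
})
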