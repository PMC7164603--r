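#' Configuration for the synthetic ICU-style cohort generator
#'
#' The generator emulates the statistical shape of an ICU drug-exposure
#' extract: a binary patient-by-drug indicator matrix, binary AGE_GROUP
#' (1 = older than 65) and GENDER (1 = male) covariates, and a binary
#' MORTALITY label at roughly 30% prevalence. Labels follow a sparse logistic
#' model on the drug indicators plus the covariates, and a fraction of drugs
#' have covariate-shifted prevalence so that sorting patients by
#' (AGE_GROUP, GENDER) induces genuine covariate shift across clients.
#'
#' @param n_patients number of patients.
#' @param n_drugs number of binary drug features.
#' @param mortality_prevalence target label prevalence in `(0, 1)`.
#' @param drug_prevalence_range range of per-drug marginal frequencies; each
#'   drug's baseline prevalence is drawn uniformly from it.
#' @param effect_sparsity fraction of drugs with a nonzero log-odds effect on
#'   mortality.
#' @param effect_scale standard deviation of the nonzero drug effects
#'   (log-odds units).
#' @param covariate_effects named log-odds coefficients for `age_group` and
#'   `gender` in the mortality model.
#' @param covariate_coupling log-odds shift applied to the prevalence of the
#'   covariate-linked drugs (strength of the feature/covariate correlation).
#' @param coupled_fraction fraction of drugs linked to each covariate.
#' @param age_prevalence,gender_prevalence marginal rates of AGE_GROUP = 1 and
#'   GENDER = 1 (defaults match the published MIMIC-III extract summary:
#'   16,053/30,000 and 12,716/30,000).
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 30000L,
                          n_drugs = 2814L,
                          mortality_prevalence = 0.30,
                          drug_prevalence_range = c(0.02, 0.30),
                          effect_sparsity = 0.10,
                          effect_scale = 1.0,
                          covariate_effects = c(age_group = 0.9, gender = 0.3),
                          covariate_coupling = 1.0,
                          coupled_fraction = 0.2,
                          age_prevalence = 16053 / 30000,
                          gender_prevalence = 12716 / 30000,
                          seed = 1L) {
  stop_if_not_count(n_patients, "n_patients")
  stop_if_not_count(n_drugs, "n_drugs")
  if (mortality_prevalence <= 0 || mortality_prevalence >= 1) {
    stop("mortality_prevalence must lie strictly in (0, 1)", call. = FALSE)
  }
  if (length(drug_prevalence_range) != 2L ||
    any(drug_prevalence_range <= 0) || any(drug_prevalence_range >= 1) ||
    drug_prevalence_range[1] > drug_prevalence_range[2]) {
    stop("drug_prevalence_range must be an increasing pair inside (0, 1)", call. = FALSE)
  }
  ce <- c(
    age_group = unname(covariate_effects["age_group"] %||% covariate_effects[1]),
    gender = unname(covariate_effects["gender"] %||% covariate_effects[2])
  )
  structure(
    list(
      n_patients = as.integer(n_patients),
      n_drugs = as.integer(n_drugs),
      mortality_prevalence = mortality_prevalence,
      drug_prevalence_range = drug_prevalence_range,
      effect_sparsity = effect_sparsity,
      effect_scale = effect_scale,
      covariate_effects = ce,
      covariate_coupling = covariate_coupling,
      coupled_fraction = coupled_fraction,
      age_prevalence = age_prevalence,
      gender_prevalence = gender_prevalence,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

new_patient_cohort <- function(features, age_group, gender, mortality, ids,
                               config = NULL) {
  structure(
    list(
      features = features, age_group = as.integer(age_group),
      gender = as.integer(gender), mortality = as.integer(mortality),
      ids = as.integer(ids), config = config
    ),
    class = "patient_cohort"
  )
}

#' @export
print.patient_cohort <- function(x, ...) {
  cat(sprintf(
    "<patient_cohort> %d patients x %d drug features; mortality prevalence %.3f\n",
    nrow(x$features), ncol(x$features), mean(x$mortality)
  ))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort a `patient_cohort`.
#' @return integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$features)

#' Subset a cohort by row index
#' @param cohort a `patient_cohort`.
#' @param idx integer row indices.
#' @return a `patient_cohort` restricted to `idx`.
#' @export
cohort_subset <- function(cohort, idx) {
  new_patient_cohort(
    features = cohort$features[idx, , drop = FALSE],
    age_group = cohort$age_group[idx],
    gender = cohort$gender[idx],
    mortality = cohort$mortality[idx],
    ids = cohort$ids[idx],
    config = cohort$config
  )
}

# Calibrate the logistic intercept by bisection so that the expected
# prevalence mean(plogis(c + eta)) hits the target. Monotone in c, so the
# bisection is exact up to tolerance; an unreachable target raises an error.
calibrate_intercept <- function(eta, target, lower = -40, upper = 40,
                                tol = 1e-6) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  if (f(lower) > 0 || f(upper) < 0) {
    stop("intercept calibration failed: target prevalence unreachable given the effect scales",
      call. = FALSE
    )
  }
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

#' Generate a synthetic patient cohort
#'
#' Draws covariates, a binary drug matrix whose covariate-linked columns have
#' prevalence shifted by AGE_GROUP/GENDER, and mortality labels from a sparse
#' logistic model `logit(p) = intercept + w.x + a*age + g*gender`. The
#' intercept is auto-calibrated by bisection so the empirical prevalence lands
#' within about two percentage points of the configured target (exactly on
#' target in expectation; the residual gap is binomial noise).
#'
#' @param config a [cohort_config()].
#' @return a `patient_cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  d <- config$n_drugs
  age <- stats::rbinom(n, 1L, config$age_prevalence)
  gender <- stats::rbinom(n, 1L, config$gender_prevalence)

  base_prev <- stats::runif(
    d, config$drug_prevalence_range[1], config$drug_prevalence_range[2]
  )
  n_coupled <- min(d, round(config$coupled_fraction * d))
  coupled_age <- if (n_coupled > 0) sample.int(d, n_coupled) else integer()
  coupled_gender <- if (n_coupled > 0) sample.int(d, n_coupled) else integer()

  X <- matrix(0L, n, d)
  base_logit <- stats::qlogis(base_prev)
  for (j in seq_len(d)) {
    lj <- base_logit[j]
    pj <- if (j %in% coupled_age || j %in% coupled_gender) {
      shift <- config$covariate_coupling *
        ((j %in% coupled_age) * age + (j %in% coupled_gender) * gender)
      stats::plogis(lj + shift)
    } else {
      base_prev[j]
    }
    X[, j] <- stats::rbinom(n, 1L, pj)
  }

  n_effects <- round(config$effect_sparsity * d)
  w <- numeric(d)
  if (n_effects > 0 && config$effect_scale > 0) {
    nz <- sample.int(d, n_effects)
    w[nz] <- stats::rnorm(n_effects, 0, config$effect_scale)
  }
  eta <- as.numeric(X %*% w) +
    config$covariate_effects[["age_group"]] * age +
    config$covariate_effects[["gender"]] * gender
  intercept <- calibrate_intercept(eta, config$mortality_prevalence)
  mortality <- stats::rbinom(n, 1L, stats::plogis(intercept + eta))

  new_patient_cohort(X, age, gender, mortality, ids = seq_len(n), config = config)
}

new_client_shard <- function(client_id, ids, features, labels,
                             n_local, n_shared = 0L) {
  structure(
    list(
      client_id = as.integer(client_id), ids = as.integer(ids),
      features = features, labels = as.integer(labels),
      n_local = as.integer(n_local), n_shared = as.integer(n_shared)
    ),
    class = "client_shard"
  )
}

shards_from_slices <- function(cohort, ord, n_clients) {
  size <- length(ord) %/% n_clients
  lapply(seq_len(n_clients), function(k) {
    idx <- ord[((k - 1L) * size + 1L):(k * size)]
    new_client_shard(
      client_id = k, ids = cohort$ids[idx],
      features = cohort$features[idx, , drop = FALSE],
      labels = cohort$mortality[idx],
      n_local = size, n_shared = 0L
    )
  })
}

check_divisible <- function(n, n_clients) {
  stop_if_not_count(n_clients, "n_clients")
  if (n %% n_clients != 0L) {
    stop(sprintf(
      "%d examples cannot be split into %d equal clients", n, n_clients
    ), call. = FALSE)
  }
}

#' Partition a cohort into IID client shards
#'
#' A uniform random permutation followed by contiguous equal slices: every
#' client's data is an IID sample of the cohort. The number of patients must
#' divide exactly (all reference configurations do, e.g. 27,000 over 90
#' clients of 300).
#'
#' @param cohort a `patient_cohort`.
#' @param n_clients number of clients.
#' @param seed integer seed for the permutation.
#' @return list of `client_shard` objects.
#' @export
partition_iid <- function(cohort, n_clients, seed = 1L) {
  n <- n_patients(cohort)
  check_divisible(n, n_clients)
  set.seed(seed)
  shards_from_slices(cohort, sample.int(n), n_clients)
}

#' Partition a cohort into covariate-sorted non-IID client shards
#'
#' Stable sort by (AGE_GROUP, GENDER), then contiguous equal slices: each
#' shard is near-homogeneous in the sort keys, so client label and feature
#' distributions differ systematically. Deterministic (no randomness).
#'
#' @inheritParams partition_iid
#' @return list of `client_shard` objects.
#' @export
partition_noniid <- function(cohort, n_clients) {
  n <- n_patients(cohort)
  check_divisible(n, n_clients)
  ord <- order(cohort$age_group, cohort$gender) # radix sort: stable
  shards_from_slices(cohort, ord, n_clients)
}

#' Split a cohort into a training set and an IID holdout
#'
#' The holdout is a uniform random sample (IID by construction), the substrate
#' for both test evaluation and the data-sharing pool.
#'
#' @param cohort a `patient_cohort`.
#' @param holdout_n holdout size, strictly less than the cohort size.
#' @param seed integer seed.
#' @return list with elements `training` and `holdout`, two disjoint
#'   `patient_cohort`s whose union of ids is the input's.
#' @export
split_holdout <- function(cohort, holdout_n, seed = 1L) {
  n <- n_patients(cohort)
  if (holdout_n >= n) stop("holdout_n must be smaller than the cohort", call. = FALSE)
  if (holdout_n < 0L) stop("holdout_n must be >= 0", call. = FALSE)
  set.seed(seed)
  hold <- if (holdout_n > 0L) sort(sample.int(n, holdout_n)) else integer()
  train <- setdiff(seq_len(n), hold)
  list(
    training = cohort_subset(cohort, train),
    holdout = cohort_subset(cohort, hold)
  )
}

#' Write a cohort to a wide CSV with a JSON config sidecar
#'
#' Columns: `ids, age_group, gender, mortality, drug_0 ... drug_{d-1}`. The
#' generating configuration (when present) is written to `<path>.json`. The
#' round-trip through [read_cohort()] is bit-exact.
#'
#' @param cohort a `patient_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  d <- ncol(cohort$features)
  feat <- cohort$features
  colnames(feat) <- paste0("drug_", seq_len(d) - 1L)
  dt <- data.table::data.table(
    ids = cohort$ids, age_group = cohort$age_group,
    gender = cohort$gender, mortality = cohort$mortality
  )
  dt <- cbind(dt, data.table::as.data.table(feat))
  data.table::fwrite(dt, path)
  if (!is.null(cohort$config)) {
    jsonlite::write_json(unclass(cohort$config), paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV path.
#' @return a `patient_cohort`.
#' @export
read_cohort <- function(path) {
  dt <- data.table::fread(path)
  drug_cols <- grep("^drug_", names(dt), value = TRUE)
  feat <- as.matrix(dt[, drug_cols, with = FALSE])
  storage.mode(feat) <- "integer"
  cfg_path <- paste0(path, ".json")
  config <- NULL
  if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    raw$covariate_effects <- unlist(raw$covariate_effects)
    raw$drug_prevalence_range <- unlist(raw$drug_prevalence_range)
    config <- do.call(cohort_config, raw)
  }
  new_patient_cohort(
    feat, dt$age_group, dt$gender, dt$mortality, dt$ids,
    config = config
  )
}
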