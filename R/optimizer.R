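#' Protocol configuration
#'
#' Study-design constants for the sequential optimization protocol: 50
#' subjects, 3 stimulation blocks each, with the first 20 subjects (60
#' assignments) forming the random burn-in phase; extreme raw scores at or
#' above `exclusion_threshold` are logged but excluded from model fitting.
#'
#' @param n_subjects stopping criterion: total subjects (default 50).
#' @param blocks_per_subject stimulation blocks per subject (default 3).
#' @param burn_in_subjects subjects covered by the random burn-in (default
#'   20); the burn-in spans `burn_in_subjects * blocks_per_subject`
#'   assignments.
#' @param exclusion_threshold raw normalized-performance scores `>=` this
#'   value are flagged and excluded from fitting (default 3.6); `NULL`
#'   disables exclusion.
#' @param acquisition `"ei"` (default) or `"ucb"`.
#' @param kappa UCB exploration weight (only used with `"ucb"`).
#' @param baseline_bounds raw drift range mapped to the unit interval for
#'   the personalization covariate.
#' @param restarts hyperparameter-fit restarts per refit.
#' @param seed master seed; every randomized step derives its own stream
#'   from it.
#' @return object of class `persbo_config`.
#' @export
protocol_config <- function(n_subjects = 50, blocks_per_subject = 3,
                            burn_in_subjects = 20, exclusion_threshold = 3.6,
                            acquisition = c("ei", "ucb"), kappa = NULL,
                            baseline_bounds = c(0, 0.2), restarts = 5,
                            seed = 1) {
  acquisition <- match.arg(acquisition)
  if (n_subjects < burn_in_subjects) {
    abort_persbo("`n_subjects` must be >= `burn_in_subjects`.", "configuration_error")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      blocks_per_subject = as.integer(blocks_per_subject),
      burn_in_subjects = as.integer(burn_in_subjects),
      burn_in_assignments = as.integer(burn_in_subjects * blocks_per_subject),
      exclusion_threshold = exclusion_threshold,
      acquisition = acquisition,
      kappa = kappa,
      baseline_bounds = baseline_bounds,
      restarts = as.integer(restarts),
      seed = as.integer(seed),
      burn_space = search_space("burn_in", baseline_bounds),
      opt_space = search_space("optimization", baseline_bounds)
    ),
    class = "persbo_config"
  )
}

empty_history <- function() {
  tibble(iter = integer(), subject_id = character(), block_id = character(),
         phase = character(), frequency = double(), current = double(),
         p_raw = double(), y_raw = double(), excluded = logical())
}

#' Start a fresh protocol state
#'
#' @param config a [protocol_config()].
#' @return object of class `persbo_protocol` holding the (empty) observation
#'   history.
#' @export
new_protocol <- function(config = protocol_config()) {
  stopifnot(inherits(config, "persbo_config"))
  structure(list(config = config, history = empty_history(),
                 cache = new.env(parent = emptyenv())),
            class = "persbo_protocol")
}

#' @export
print.persbo_protocol <- function(x, ...) {
  cat(sprintf("<persbo_protocol: %d/%d observations (%d excluded), %d burn-in>\n",
              nrow(x$history),
              x$config$n_subjects * x$config$blocks_per_subject,
              sum(x$history$excluded),
              sum(x$history$phase == "burn_in")))
  invisible(x)
}

normalize_p <- function(p_raw, space) {
  normalize_coords(tibble(frequency = 5, current = 0.1, p_raw = p_raw),
                   space)$p
}

#' Surrogate refit from the current protocol history
#'
#' Refits the GP (standardization and hyperparameters) over all included
#' observations; with fewer than three usable points, or no output variance,
#' a default-hyperparameter surrogate is used. Fits are cached per state so
#' that a proposal and the predicted-best trace of the same iteration share
#' one refit; rebuilding from the full log always reproduces the same model.
#'
#' @param state a `persbo_protocol`.
#' @param mode `"pbo"` (personalized) or `"standard_bo"` (ignores `p`).
#' @return a `persbo_gp`.
#' @export
protocol_model <- function(state, mode = c("pbo", "standard_bo")) {
  mode <- match.arg(mode)
  cfg <- state$config
  key <- paste(mode, nrow(state$history), sum(state$history$y_raw))
  hit <- state$cache$model
  if (!is.null(hit) && identical(state$cache$key, key)) return(hit)

  inc <- filter(state$history, !.data$excluded)
  if (!nrow(inc)) abort_persbo("no included observations to model.", "protocol_error")
  data <- normalize_coords(inc, cfg$opt_space)
  data$y <- data$y_raw
  personalized <- mode == "pbo"
  fit_seed <- derive_seed(cfg$seed, nrow(state$history), 90L)
  model <- if (nrow(data) < 3L || sd(data$y) == 0) {
    gp_fit(data, personalized = personalized,
           hyper = list(sigma_l = 0.2, sigma_p = 0.3, sigma_n2 = 0.1),
           seed = fit_seed)
  } else {
    gp_fit(data, personalized = personalized, restarts = cfg$restarts,
           seed = fit_seed)
  }
  state$cache$key <- key
  state$cache$model <- model
  model
}

#' Propose the next stimulation parameters
#'
#' During the burn-in phase (the first `burn_in_assignments` observations)
#' parameters are drawn uniformly from the burn-in grid (active currents
#' only, no sham). Afterwards, `"pbo"` maximizes the acquisition function at
#' the subject's baseline coordinate over the optimization grid (sham
#' included), `"standard_bo"` does the same with a surrogate that ignores
#' the baseline, and `"random"` keeps drawing uniformly from the
#' phase-appropriate grid.
#'
#' @param state a `persbo_protocol`.
#' @param p_raw the subject's raw baseline ability (drift rate).
#' @param mode `"pbo"`, `"standard_bo"`, or `"random"`.
#' @param codebook optional codebook; when given, the blinded `code` is
#'   attached to the recommendation.
#' @return one-row tibble: `iter`, `phase`, `frequency`, `current`, and for
#'   model-driven proposals `acq`, `f_plus` (plus `code` when blinded).
#' @export
propose_next <- function(state, p_raw, mode = c("pbo", "standard_bo", "random"),
                         codebook = NULL) {
  mode <- match.arg(mode)
  cfg <- state$config
  done <- nrow(state$history)
  if (done >= cfg$n_subjects * cfg$blocks_per_subject) {
    abort_persbo("stopping criterion reached: protocol complete.",
                 "protocol_complete")
  }
  iter <- done + 1L
  burn <- done < cfg$burn_in_assignments
  phase <- if (burn) "burn_in" else "pbo"
  seed_i <- derive_seed(cfg$seed, iter, match(mode, c("pbo", "standard_bo", "random")))

  if (burn || mode == "random") {
    grid <- stim_grid(if (burn) cfg$burn_space else cfg$opt_space)
    pick <- withr::with_seed(seed_i, sample.int(nrow(grid), 1L))
    rec <- tibble(iter = iter, phase = phase,
                  frequency = grid$frequency[pick], current = grid$current[pick])
  } else {
    model <- protocol_model(state, mode)
    p_unit <- if (mode == "pbo") normalize_p(p_raw, cfg$opt_space) else 0
    a <- acquire_next(model, p_unit, cfg$opt_space,
                      acquisition = cfg$acquisition, kappa = cfg$kappa,
                      seed = seed_i)
    rec <- tibble(iter = iter, phase = phase, frequency = a$frequency,
                  current = a$current, acq = a$acq, f_plus = a$f_plus)
  }
  if (!is.null(codebook)) {
    rec$code <- encode_params(rec, codebook)
  }
  rec
}

#' Record an observation and refresh the protocol state
#'
#' Appends one scored stimulation block to the history. Raw scores at or
#' above the exclusion threshold are flagged and never enter covariance
#' matrices, but stay in the log. The surrogate is refit from the full
#' included history on next use, so the state carries no information beyond
#' the log itself.
#'
#' @param object a `persbo_protocol`.
#' @param observation one-row data frame with `subject_id`, `block_id`,
#'   `frequency`, `current`, `p_raw`, `y_raw`.
#' @param ... unused.
#' @return the updated `persbo_protocol`.
#' @export
update.persbo_protocol <- function(object, observation, ...) {
  cfg <- object$config
  req <- c("subject_id", "block_id", "frequency", "current", "p_raw", "y_raw")
  if (!all(req %in% names(observation)) || nrow(observation) != 1L) {
    abort_persbo(sprintf("observation must be one row with columns %s.",
                         paste(req, collapse = ", ")), "invalid_input")
  }
  key <- paste(observation$subject_id, observation$block_id)
  if (key %in% paste(object$history$subject_id, object$history$block_id)) {
    abort_persbo("duplicate (subject, block) observation.", "protocol_error")
  }
  iter <- nrow(object$history) + 1L
  thr <- cfg$exclusion_threshold
  row <- tibble(
    iter = iter,
    subject_id = as.character(observation$subject_id),
    block_id = as.character(observation$block_id),
    phase = if (iter <= cfg$burn_in_assignments) "burn_in" else "pbo",
    frequency = observation$frequency, current = observation$current,
    p_raw = observation$p_raw, y_raw = observation$y_raw,
    excluded = !is.null(thr) && observation$y_raw >= thr
  )
  object$history <- bind_rows(object$history, row)
  object$cache <- new.env(parent = emptyenv())
  object
}

#' Best-inferred stimulation parameters at a baseline value
#'
#' The argmax of the posterior-mean surface over the optimization grid at a
#' fixed baseline coordinate — the model's recommendation after (or during)
#' a study.
#'
#' @param model a fitted `persbo_gp`.
#' @param p unit-scale baseline coordinate.
#' @param space the optimization [search_space()].
#' @return one-row tibble: `frequency`, `current`, `mu` (raw-score scale).
#' @export
best_inferred <- function(model, p, space = search_space()) {
  stopifnot(inherits(model, "persbo_gp"))
  grid <- stim_grid(space)
  cand <- normalize_coords(grid, space)
  if (model$personalized) cand$p <- p
  post <- predict(model, cand, scale = "raw")
  i <- which.max(post$mu)
  tibble(frequency = grid$frequency[i], current = grid$current[i],
         mu = post$mu[i])
}

#' Run the closed-loop protocol against a synthetic cohort
#'
#' Drives the full sequential experiment: for each subject in turn (three
#' blocks each), propose parameters, observe a score from the synthetic
#' response surface, and update the state. Scores come either from the
#' additive-noise fast path (`observe = "fast"`: surface value plus Gaussian
#' noise of the surface's `noise_sd`) or through the full diffusion pipeline
#' (`observe = "diffusion"`: finite-trial simulation scored by EZ
#' estimation).
#'
#' @param cohort a [generate_cohort()] tibble with at least `n_subjects`
#'   rows.
#' @param config a [protocol_config()].
#' @param surface a [make_surface()] ground truth.
#' @param mode `"pbo"`, `"standard_bo"`, or `"random"`.
#' @param observe `"fast"` or `"diffusion"`.
#' @param trace record the per-iteration best performance predicted by the
#'   GP at any parameter combination (at the current subject's baseline)?
#' @return object of class `persbo_run`: list with `state`, `history`,
#'   `trace`, `config`, `mode`, `surface`.
#' @export
run_protocol <- function(cohort, config = protocol_config(), surface,
                         mode = c("pbo", "standard_bo", "random"),
                         observe = c("fast", "diffusion"), trace = TRUE) {
  mode <- match.arg(mode)
  observe <- match.arg(observe)
  stopifnot(inherits(surface, "persbo_surface"))
  if (nrow(cohort) < config$n_subjects) {
    abort_persbo("cohort smaller than the configured number of subjects.",
                 "protocol_error")
  }
  state <- new_protocol(config)
  space <- config$opt_space
  trace_rows <- vector("list", config$n_subjects * config$blocks_per_subject)
  iter <- 0L
  for (s in seq_len(config$n_subjects)) {
    subj <- cohort[s, ]
    p_unit <- normalize_p(subj$p_raw, space)
    for (b in seq_len(config$blocks_per_subject)) {
      iter <- iter + 1L
      rec <- propose_next(state, subj$p_raw, mode)
      xy <- normalize_coords(rec, space)
      if (observe == "fast") {
        mu <- surface_value(surface, xy$x1, xy$x2, p_unit)
        y <- mu + withr::with_seed(derive_seed(config$seed, 7L, iter),
                                   rnorm(1, 0, surface$noise_sd))
      } else {
        samp <- sample_subject(surface, p_unit, subj$v_true, rec, space,
                               v_base = subj$v_base,
                               seed = derive_seed(config$seed, 8L, iter))
        y <- samp$score
      }
      state <- update(state, tibble(
        subject_id = subj$subject_id, block_id = paste0("stim", b),
        frequency = rec$frequency, current = rec$current,
        p_raw = subj$p_raw, y_raw = y
      ))
      if (trace) {
        model <- protocol_model(state,
                                if (mode == "standard_bo") "standard_bo" else "pbo")
        bi <- best_inferred(model, p_unit, space)
        cand <- normalize_coords(bi, space)
        if (model$personalized) cand$p <- p_unit
        post <- predict(model, cand, scale = "raw")
        trace_rows[[iter]] <- tibble(iter = iter, subject_id = subj$subject_id,
                                     pred_best = post$mu, pred_sigma = post$sigma)
      }
    }
  }
  structure(
    list(state = state, history = state$history,
         trace = if (trace) bind_rows(trace_rows) else NULL,
         config = config, mode = mode, surface = surface),
    class = "persbo_run"
  )
}

#' @export
print.persbo_run <- function(x, ...) {
  cat(sprintf("<persbo_run: mode = %s, %d observations (%d burn-in, %d excluded)>\n",
              x$mode, nrow(x$history), sum(x$history$phase == "burn_in"),
              sum(x$history$excluded)))
  invisible(x)
}

#' Participant-level cross-validation of the surrogate
#'
#' Randomly splits participants (all blocks of a subject stay together) into
#' a training and a testing group, fits the personalized GP regression of
#' the raw score on (frequency, current, baseline), and reports the mean
#' squared error of the raw-scale predictions on the held-out group.
#'
#' @param history an observation log with `subject_id`, `frequency`,
#'   `current`, `p_raw`, `y_raw` (and optionally `excluded`).
#' @param train_fraction fraction of participants in the training group.
#' @param seed integer seed for the split.
#' @param space the [search_space()] used for normalization.
#' @param restarts hyperparameter-fit restarts.
#' @return one-row tibble: `mse`, `n_train_subjects`, `n_test_subjects`,
#'   `n_train_obs`, `n_test_obs`.
#' @export
cross_validate <- function(history, train_fraction = 0.8, seed = 1,
                           space = search_space(), restarts = 5) {
  if ("excluded" %in% names(history)) history <- filter(history, !.data$excluded)
  subjects <- unique(history$subject_id)
  if (length(subjects) < 5L) {
    abort_persbo("need at least 5 distinct subjects.", "split_error")
  }
  shuffled <- withr::with_seed(seed, sample(subjects))
  n_train <- round(train_fraction * length(subjects))
  if (n_train < 2L || length(subjects) - n_train < 2L) {
    abort_persbo("fewer than 2 subjects in one of the splits.", "split_error")
  }
  train_ids <- shuffled[seq_len(n_train)]
  train <- filter(history, .data$subject_id %in% train_ids)
  test <- filter(history, !.data$subject_id %in% train_ids)
  prep <- function(df) {
    out <- normalize_coords(df, space)
    out$y <- out$y_raw
    out
  }
  model <- gp_fit(prep(train), personalized = TRUE, restarts = restarts,
                  seed = derive_seed(seed, 17L))
  pred <- predict(model, prep(test), scale = "raw")
  tibble(mse = mean((test$y_raw - pred$mu)^2),
         n_train_subjects = length(train_ids),
         n_test_subjects = length(subjects) - length(train_ids),
         n_train_obs = nrow(train), n_test_obs = nrow(test))
}

#' Save / load a protocol state as JSON
#'
#' @param state a `persbo_protocol`.
#' @param path JSON file path.
#' @export
write_state <- function(state, path) {
  cfg <- state$config
  jsonlite::write_json(
    list(
      config = cfg[c("n_subjects", "blocks_per_subject", "burn_in_subjects",
                     "exclusion_threshold", "acquisition", "kappa",
                     "baseline_bounds", "restarts", "seed")],
      history = state$history
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- s$config
  config <- protocol_config(
    n_subjects = cfg$n_subjects, blocks_per_subject = cfg$blocks_per_subject,
    burn_in_subjects = cfg$burn_in_subjects,
    exclusion_threshold = cfg$exclusion_threshold,
    acquisition = cfg$acquisition, kappa = cfg$kappa,
    baseline_bounds = unlist(cfg$baseline_bounds), restarts = cfg$restarts,
    seed = cfg$seed
  )
  state <- new_protocol(config)
  if (length(s$history)) {
    h <- as_tibble(s$history)
    h$iter <- as.integer(h$iter)
    state$history <- h
  }
  state
}
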