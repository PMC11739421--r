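#' Campaign configuration
#'
#' Defaults mirror a standard simulated campaign on a 4-site landscape: a
#' random initial batch of 96 variants followed by four rounds of 96
#' proposals each, a 5-member DNN ensemble on one-hot encodings, and
#' Thompson sampling.
#'
#' @param encoder encoder name or `alde_encoder` (see [get_encoder()]).
#' @param model named list: `kind` is one of `"gp"`, `"dkl"`,
#'   `"dnn_ensemble"`, `"boosting_ensemble"`; remaining entries are passed
#'   to the corresponding fit function.
#' @param acquisition named list: `rule` (`"greedy"`, `"ucb"`,
#'   `"thompson"`) and optionally `beta` (default 4).
#' @param n0 initial random batch size (default 96).
#' @param rounds number of learning/proposal rounds R (default 4).
#' @param q proposal batch size per round (default 96).
#' @param replicates default replicate count for [run_replicates()]
#'   (default 70).
#' @param seed master seed; all campaign randomness derives sub-seeds from
#'   it.
#' @param missing policy for unmeasured combos, `"zero"` or `"skip"` (see
#'   [observe_fitness()]).
#' @return An object of class `alde_campaign_config`.
#' @export
campaign_config <- function(encoder = "onehot",
                            model = list(kind = "dnn_ensemble"),
                            acquisition = list(rule = "thompson", beta = 4),
                            n0 = 96, rounds = 4, q = 96, replicates = 70,
                            seed = 1, missing = c("zero", "skip")) {
  missing <- match.arg(missing)
  stopifnot(n0 >= 1, rounds >= 0, q >= 1, replicates >= 1)
  structure(list(encoder = encoder, model = model,
                 acquisition = acquisition, n0 = as.integer(n0),
                 rounds = as.integer(rounds), q = as.integer(q),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 missing = missing),
            class = "alde_campaign_config")
}

fit_surrogate <- function(model, x, y, seed) {
  kind <- model$kind %||% "dnn_ensemble"
  args <- model[setdiff(names(model), "kind")]
  switch(kind,
         gp = do.call(fit_gp, c(list(x = x, y = y), args)),
         dkl = do.call(fit_dkl, c(list(x = x, y = y, seed = seed), args)),
         dnn_ensemble = do.call(fit_ensemble,
                                c(list(x = x, y = y, base_learner = "dnn",
                                       seed = seed), args)),
         boosting_ensemble = do.call(fit_ensemble,
                                     c(list(x = x, y = y,
                                            base_learner = "boosting",
                                            seed = seed), args)),
         stop_alde("unknown model kind '%s'", kind,
                   class = "alde_contract_error"))
}

landscape_digest <- function(l) {
  sprintf("%d:%d:%.10g:%.10g", l$k, length(l$fitness),
          sum(l$fitness), max(l$fitness))
}

#' Run an active-learning campaign on a landscape
#'
#' Round 0 observes a uniform random sample of `n0` distinct variants.
#' Each subsequent round refits the surrogate from scratch on all
#' observations so far, proposes `q` new variants through the acquisition
#' rule with every observed variant excluded, and observes their landscape
#' fitnesses. No variant is ever observed twice; the total budget is
#' `n0 + rounds * q` distinct variants.
#'
#' @param l an [landscape()] object, normally max-normalized so that the
#'   trajectory is on the 0-1 scale.
#' @param config an [campaign_config()].
#' @return An `alde_campaign`: list with `method`, `config`, `rounds`
#'   (per-round records with proposed variants, scores and observed
#'   fitnesses), `observed` (data.frame variant/fitness/round),
#'   `trajectory` (running maximum after each round, length `rounds + 1`),
#'   and `final_max`.
#' @export
run_alde <- function(l, config) {
  stopifnot(inherits(l, "alde_landscape"),
            inherits(config, "alde_campaign_config"))
  combos_all <- enumerate_design_space(l$k, l$alphabet)
  budget <- config$n0 + config$rounds * config$q
  if (budget > length(combos_all)) {
    stop_alde("budget %d exceeds the design space (%d variants)", budget,
              length(combos_all), class = "alde_capacity_error")
  }
  encoder <- get_encoder(config$encoder)

  init <- with_seed(derive_seed(config$seed, 1L),
                    sample(combos_all, config$n0))
  obs_fit <- observe_fitness(l, init, missing = config$missing)
  observed <- data.frame(variant = names(obs_fit),
                         fitness = unname(obs_fit),
                         round = 0L, stringsAsFactors = FALSE)
  trajectory <- max(observed$fitness)
  round_log <- list()

  for (r in seq_len(config$rounds)) {
    res <- tryCatch({
      xtr <- build_design_matrix(observed$variant, encoder)
      p <- fit_surrogate(config$model, xtr, observed$fitness,
                         seed = derive_seed(config$seed, 2L, r))
      spec <- acquisition_spec(
        rule = config$acquisition$rule %||% "thompson",
        beta = config$acquisition$beta %||% 4,
        batch_size = config$q,
        exclude = observed$variant,
        seed = derive_seed(config$seed, 3L, r))
      prop <- propose_batch(p, combos_all, encoder, spec)
      list(p = p, prop = prop, spec = spec)
    }, alde_error = function(e) {
      stop_alde("round %d: %s", r, conditionMessage(e),
                class = class(e)[1])
    })
    fit_r <- observe_fitness(l, res$prop$variants, missing = config$missing)
    observed <- rbind(observed,
                      data.frame(variant = names(fit_r),
                                 fitness = unname(fit_r),
                                 round = r, stringsAsFactors = FALSE))
    trajectory <- c(trajectory, max(observed$fitness))
    round_log[[r]] <- list(round = r,
                           proposed = res$prop$variants,
                           scores = res$prop$scores,
                           observed = unname(fit_r),
                           model_kind = res$p$model_kind,
                           rule = res$prop$provenance$rule)
  }
  if (anyDuplicated(observed$variant)) {
    stop_alde("internal error: a variant was observed twice",
              class = "alde_contract_error")
  }
  structure(list(method = "alde", config = config, rounds = round_log,
                 observed = observed, trajectory = trajectory,
                 final_max = trajectory[length(trajectory)],
                 landscape_digest = landscape_digest(l)),
            class = "alde_campaign")
}

#' @export
print.alde_campaign <- function(x, ...) {
  cat(sprintf("<alde_campaign> %s: %d variants observed, final max %.4f\n",
              x$method, nrow(x$observed), x$final_max))
  cat("  trajectory:", paste(sprintf("%.4f", x$trajectory), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Random-sampling baseline
#'
#' Observes a uniform sample of `budget` distinct variants in one shot.
#'
#' @param l an [landscape()] object.
#' @param budget number of distinct variants to observe.
#' @param seed integer seed.
#' @param missing missing-variant policy (see [observe_fitness()]).
#' @return An `alde_campaign` with `method = "random"`.
#' @export
run_random_baseline <- function(l, budget, seed, missing = "zero") {
  combos_all <- enumerate_design_space(l$k, l$alphabet)
  if (budget > length(combos_all)) {
    stop_alde("budget %d exceeds the design space (%d variants)", budget,
              length(combos_all), class = "alde_capacity_error")
  }
  picks <- with_seed(derive_seed(seed, 1L), sample(combos_all, budget))
  fit <- observe_fitness(l, picks, missing = missing)
  observed <- data.frame(variant = names(fit), fitness = unname(fit),
                         round = 0L, stringsAsFactors = FALSE)
  structure(list(method = "random", config = list(budget = budget, seed = seed),
                 rounds = list(), observed = observed,
                 trajectory = max(observed$fitness),
                 final_max = max(observed$fitness),
                 landscape_digest = landscape_digest(l)),
            class = "alde_campaign")
}

#' Single-round MLDE baseline
#'
#' One round of supervised learning on a random initial sample followed by
#' greedy selection of the top predictions: exactly [run_alde()] with
#' `rounds = 1` and the acquisition rule forced to greedy, at total budget
#' `n0 + q`.
#'
#' @inheritParams run_alde
#' @return An `alde_campaign` with `method = "mlde"`.
#' @export
run_mlde <- function(l, config) {
  config$rounds <- 1L
  config$acquisition$rule <- "greedy"
  out <- run_alde(l, config)
  out$method <- "mlde"
  out
}

#' All site orders of a k-site design
#'
#' @param k number of sites.
#' @return List of all `factorial(k)` permutations of `1:k`, in
#'   lexicographic order.
#' @export
site_orders <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- site_orders(k - 1L)
    for (p in rest) {
      tail <- seq_len(k)[-i][p]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

#' Simulate one directed-evolution greedy single-step walk
#'
#' Visits the sites in the given order; at each site every alphabet symbol
#' (including the incumbent, so the walk may stay put) is substituted into
#' the current variant and evaluated, and the best is fixed before moving
#' on. Ties go to the lexicographically smallest variant.
#'
#' @param l an [landscape()] object.
#' @param start starting combo (must be present in the landscape).
#' @param order permutation of `1:k` giving the site visitation order.
#' @param missing missing-variant policy; `"zero"` treats unmeasured
#'   substitutions as fitness 0, `"skip"` removes them from the choice set.
#' @return An `alde_walk`: list with `start`, `order`, `path` (length
#'   `k + 1`: start plus one accepted state per site), `evaluated` (all
#'   distinct variants queried), `end_variant`, `end_fitness`.
#' @export
run_de_greedy_walk <- function(l, start, order = seq_len(l$k),
                               missing = c("zero", "skip")) {
  missing <- match.arg(missing)
  start <- toupper(start)
  if (!start %in% names(l$fitness)) {
    stop_alde("start variant '%s' is not in the landscape", start,
              class = "alde_contract_error")
  }
  stopifnot(length(order) == l$k, setequal(order, seq_len(l$k)))
  current <- start
  path <- start
  evaluated <- start
  for (site in order) {
    chars <- strsplit(current, "")[[1]]
    cands <- vapply(l$alphabet, function(a) {
      ch <- chars; ch[site] <- a; paste(ch, collapse = "")
    }, character(1))
    fit <- observe_fitness(l, cands, missing = missing)
    if (length(fit) == 0L) next
    evaluated <- union(evaluated, names(fit))
    best <- names(fit)[order_by_score(unname(fit), names(fit))[1]]
    current <- best
    path <- c(path, current)
  }
  end_fit <- unname(observe_fitness(l, current, missing = "zero"))
  structure(list(start = start, order = order, path = path,
                 evaluated = evaluated, end_variant = current,
                 end_fitness = end_fit),
            class = "alde_walk")
}

#' Exhaustive directed-evolution simulation
#'
#' Runs one greedy walk from every active variant under every one of the
#' `k!` site orders (24 orders for a 4-site design) and summarizes the end
#' fitnesses.
#'
#' @param l an [landscape()] object.
#' @param threshold activity threshold for starting points (strictly
#'   greater; default 0).
#' @param missing missing-variant policy.
#' @return A list with `walks` (data.frame: start, order id, end variant,
#'   end fitness), `end_fitnesses`, `n_starts`, `n_orders`, and `summary`
#'   (mean, median, sd, max).
#' @export
run_de_all <- function(l, threshold = 0, missing = "zero") {
  starts <- active_variants(l, threshold)
  if (length(starts) == 0L) {
    stop_alde("no active variants above threshold %.4g", threshold,
              class = "alde_configuration_error")
  }
  orders <- site_orders(l$k)
  rows <- vector("list", length(starts) * length(orders))
  i <- 0L
  for (s in starts) {
    for (oi in seq_along(orders)) {
      w <- run_de_greedy_walk(l, s, orders[[oi]], missing = missing)
      i <- i + 1L
      rows[[i]] <- data.frame(start = s, order_id = oi,
                              end_variant = w$end_variant,
                              end_fitness = w$end_fitness,
                              stringsAsFactors = FALSE)
    }
  }
  walks <- do.call(rbind, rows)
  ef <- walks$end_fitness
  list(walks = walks, end_fitnesses = ef,
       n_starts = length(starts), n_orders = length(orders),
       summary = c(mean = mean(ef), median = stats::median(ef),
                   sd = stats::sd(ef), max = max(ef)),
       landscape_digest = landscape_digest(l))
}

#' Run replicate campaigns
#'
#' Repeats a campaign under independent derived seeds, e.g. to report the
#' mean and standard deviation of the final normalized maximum fitness
#' across random initializations.
#'
#' @param l an [landscape()] object.
#' @param config an [campaign_config()].
#' @param replicates number of replicates (default from the config).
#' @param method `"alde"`, `"mlde"` or `"random"` (random uses the matched
#'   total budget `n0 + rounds * q`).
#' @return List of `alde_campaign` objects.
#' @export
run_replicates <- function(l, config, replicates = config$replicates,
                           method = c("alde", "mlde", "random")) {
  method <- match.arg(method)
  lapply(seq_len(replicates), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 7L, i)
    switch(method,
           alde = run_alde(l, cfg),
           mlde = run_mlde(l, cfg),
           random = run_random_baseline(l, config$n0 + config$rounds * config$q,
                                        seed = cfg$seed,
                                        missing = config$missing))
  })
}

#' Summarize campaign results
#'
#' @param results list of `alde_campaign` objects, all on the same
#'   landscape.
#' @return A data.frame with one row per method: replicate count, mean and
#'   standard deviation of the final normalized maximum fitness
#'   (`sd = 0` and `single_replicate = TRUE` when only one replicate is
#'   present), plus a `trajectories` attribute holding the per-replicate
#'   running maxima.
#' @export
summarize_campaigns <- function(results) {
  stopifnot(length(results) > 0,
            all(vapply(results, inherits, logical(1), "alde_campaign")))
  digests <- vapply(results, `[[`, character(1), "landscape_digest")
  if (length(unique(digests)) != 1L) {
    stop_alde("results reference different landscapes",
              class = "alde_aggregation_error")
  }
  methods <- vapply(results, `[[`, character(1), "method")
  fm <- vapply(results, `[[`, numeric(1), "final_max")
  out <- do.call(rbind, lapply(unique(methods), function(m) {
    v <- fm[methods == m]
    data.frame(method = m, n = length(v), mean_final_max = mean(v),
               sd_final_max = if (length(v) > 1L) stats::sd(v) else 0,
               single_replicate = length(v) == 1L,
               stringsAsFactors = FALSE)
  }))
  attr(out, "trajectories") <- lapply(results, `[[`, "trajectory")
  out
}

#' Write campaign logs to a directory
#'
#' Emits `proposals.csv` (round, variant, score), `observations.csv`
#' (variant, fitness, round), `trajectory.csv`, and `provenance.json`
#' (config and seeds). Identical campaigns write byte-identical files.
#'
#' @param result an `alde_campaign`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(result, dir) {
  stopifnot(inherits(result, "alde_campaign"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  props <- if (length(result$rounds) > 0) {
    do.call(rbind, lapply(result$rounds, function(r) {
      data.frame(round = r$round, variant = r$proposed, score = r$scores,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(round = integer(0), variant = character(0),
               score = numeric(0))
  }
  data.table::fwrite(props, file.path(dir, "proposals.csv"))
  data.table::fwrite(result$observed, file.path(dir, "observations.csv"))
  data.table::fwrite(data.frame(round = seq_along(result$trajectory) - 1L,
                                running_max = result$trajectory),
                     file.path(dir, "trajectory.csv"))
  jsonlite::write_json(
    list(method = result$method,
         config = unclass(result$config),
         landscape = result$landscape_digest,
         final_max = result$final_max),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Load a campaign configuration from a YAML file
#'
#' Expects top-level blocks `encoder`, `model`, `acquisition` and
#' `campaign` (n0, rounds, q, replicates, seed, missing); absent fields
#' fall back to [campaign_config()] defaults.
#'
#' @param path YAML file path.
#' @return An `alde_campaign_config`.
#' @export
load_campaign_config <- function(path) {
  y <- yaml::read_yaml(path)
  cc <- y$campaign %||% list()
  campaign_config(
    encoder = y$encoder %||% "onehot",
    model = y$model %||% list(kind = "dnn_ensemble"),
    acquisition = y$acquisition %||% list(rule = "thompson", beta = 4),
    n0 = cc$n0 %||% 96, rounds = cc$rounds %||% 4, q = cc$q %||% 96,
    replicates = cc$replicates %||% 70, seed = cc$seed %||% 1,
    missing = cc$missing %||% "zero")
}
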