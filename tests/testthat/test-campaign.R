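small_config <- function(seed = 3, rounds = 2, rule = "thompson") {
  campaign_config(
    encoder = "onehot",
    model = list(kind = "boosting_ensemble"),
    acquisition = list(rule = rule, beta = 4),
    n0 = 16, rounds = rounds, q = 8, seed = seed)
}

test_that("campaign budget accounting and trajectory invariants hold", {
  l <- epistatic_landscape()
  res <- run_alde(l, small_config())
  expect_equal(nrow(res$observed), 16 + 2 * 8)
  expect_false(anyDuplicated(res$observed$variant) > 0)
  expect_length(res$trajectory, 3)
  expect_true(all(diff(res$trajectory) >= 0))
  expect_gte(res$final_max, max(res$observed$fitness[res$observed$round == 0]))
  expect_true(res$final_max >= 0 && res$final_max <= 1)
})

test_that("a campaign larger than the design space is refused", {
  l <- sign_epistasis_landscape()
  cfg <- campaign_config(n0 = 3, rounds = 1, q = 2, seed = 1)
  expect_error(run_alde(l, cfg), class = "alde_capacity_error")
})

test_that("greedy walks climb and stop at local optima", {
  l <- sign_epistasis_landscape()
  for (ord in site_orders(2)) {
    w <- run_de_greedy_walk(l, "AA", ord)
    expect_equal(w$end_variant, "AA")
    expect_equal(w$end_fitness, 0.1)
    expect_length(w$path, 3)  # k + 1
  }
  # ... while a walk from a mutant neighbour of the optimum reaches it
  w2 <- run_de_greedy_walk(l, "CA", c(2L, 1L))
  expect_equal(w2$end_variant, "CC")
})

test_that("on an additive landscape every walk reaches the global optimum", {
  l <- additive_landscape()
  best <- names(l$fitness)[which.max(l$fitness)]
  res <- run_de_all(l, threshold = -Inf)
  expect_equal(res$n_orders, 6)
  expect_equal(nrow(res$walks), 64 * 6)
  expect_true(all(res$walks$end_variant == best))
  expect_true(all(abs(res$end_fitnesses - 1) < 1e-12))
})

test_that("walk end fitness never falls below the start fitness", {
  l <- epistatic_landscape()
  starts <- with_seed(41, sample(names(l$fitness), 10))
  for (s in starts) {
    w <- run_de_greedy_walk(l, s, c(2L, 3L, 1L))
    expect_gte(w$end_fitness, l$fitness[[s]])
    expect_lte(length(w$evaluated), 1 + 3 * (4 - 1) + 3)
  }
})

test_that("exhaustive DE enumerates starts times site orders", {
  expect_length(site_orders(4), 24)
  expect_length(site_orders(3), 6)
  expect_length(site_orders(1), 1)
  l <- sign_epistasis_landscape()
  res <- run_de_all(l, threshold = 0.05)  # only AA and CC are above
  expect_equal(res$n_starts, 2)
  expect_equal(nrow(res$walks), 2 * 2)
  expect_error(run_de_all(l, threshold = 2),
               class = "alde_configuration_error")
  # the global optimum is reached by some walk, so the max end fitness is 1
  expect_equal(max(res$end_fitnesses), 1)
})

test_that("random baseline is seeded and saturates at full budget", {
  l <- epistatic_landscape()
  r1 <- run_random_baseline(l, 10, seed = 5)
  r2 <- run_random_baseline(l, 10, seed = 5)
  expect_identical(r1$observed, r2$observed)
  full <- run_random_baseline(l, 64, seed = 1)
  expect_equal(full$final_max, 1.0)
  # expected final max is non-decreasing in budget (Monte Carlo)
  m_small <- mean(vapply(1:200, function(s)
    run_random_baseline(l, 5, seed = s)$final_max, numeric(1)))
  m_large <- mean(vapply(1:200, function(s)
    run_random_baseline(l, 20, seed = s)$final_max, numeric(1)))
  expect_gte(m_large, m_small)
})

test_that("MLDE is the one-round greedy reduction of the campaign loop", {
  l <- epistatic_landscape()
  cfg <- small_config(seed = 6, rounds = 1, rule = "greedy")
  a <- run_alde(l, cfg)
  m <- run_mlde(l, small_config(seed = 6, rounds = 5, rule = "thompson"))
  expect_identical(a$observed, m$observed)
  expect_identical(a$trajectory, m$trajectory)
  expect_equal(nrow(m$observed), 16 + 8)
})

test_that("campaigns are fully deterministic and logs byte-identical", {
  l <- epistatic_landscape()
  cfg <- small_config(seed = 9)
  r1 <- run_alde(l, cfg)
  r2 <- run_alde(l, cfg)
  expect_identical(r1, r2)
  d1 <- file.path(tempdir(), "camp1")
  d2 <- file.path(tempdir(), "camp2")
  write_campaign(r1, d1)
  write_campaign(r2, d2)
  for (f in c("proposals.csv", "observations.csv", "trajectory.csv",
              "provenance.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("replicate summaries report mean and spread per method", {
  l <- epistatic_landscape()
  cfg <- small_config(seed = 2)
  reps <- run_replicates(l, cfg, replicates = 3, method = "random")
  s <- summarize_campaigns(reps)
  expect_equal(s$n, 3)
  expect_equal(s$method, "random")
  fm <- vapply(reps, `[[`, numeric(1), "final_max")
  expect_equal(s$mean_final_max, mean(fm))
  expect_equal(s$sd_final_max, sd(fm))
  one <- summarize_campaigns(reps[1])
  expect_true(one$single_replicate)
  expect_equal(one$sd_final_max, 0)
  other <- run_random_baseline(additive_landscape(), 5, seed = 1)
  expect_error(summarize_campaigns(c(reps, list(other))),
               class = "alde_aggregation_error")
})

test_that("campaign configs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "encoder: onehot",
    "model:",
    "  kind: boosting_ensemble",
    "acquisition:",
    "  rule: ucb",
    "  beta: 4",
    "campaign:",
    "  n0: 16",
    "  rounds: 2",
    "  q: 8",
    "  seed: 5"), path)
  cfg <- load_campaign_config(path)
  expect_equal(cfg$acquisition$rule, "ucb")
  expect_equal(cfg$n0, 16)
  expect_equal(cfg$rounds, 2)
  l <- epistatic_landscape()
  res <- run_alde(l, cfg)
  expect_equal(nrow(res$observed), 32)
})
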