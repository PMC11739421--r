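test_that("loading reads, filters stop codons, and averages replicates", {
  path <- write_landscape_csv(data.frame(
    variant = c("AC", "AD", "CC"), fitness = c(1, 2, 3)))
  l <- load_landscape(path)
  expect_equal(length(l$fitness), 3)
  expect_equal(l$k, 2)
  expect_equal(unname(l$fitness[c("AC", "AD", "CC")]), c(1, 2, 3))

  # replicate rows for the same combination are mean-averaged
  path2 <- write_landscape_csv(data.frame(
    variant = c("AC", "AC"), fitness = c(1, 3)))
  l2 <- load_landscape(path2)
  expect_equal(unname(l2$fitness), 2)
  expect_equal(l2$metadata$load_report$rows_averaged, 1)

  # stop-codon rows are dropped but counted
  path3 <- write_landscape_csv(data.frame(
    variant = c("AC", "A*", "CC"), fitness = c(1, 9, 3)))
  l3 <- load_landscape(path3)
  expect_equal(sort(names(l3$fitness)), c("AC", "CC"))
  expect_equal(l3$metadata$load_report$rows_dropped_stop, 1)

  # lower-case combos are folded to upper case
  path4 <- write_landscape_csv(data.frame(
    variant = c("ac", "cc"), fitness = c(1, 2)))
  expect_equal(sort(names(load_landscape(path4)$fitness)), c("AC", "CC"))
})

test_that("loading rejects malformed inputs", {
  expect_error(
    load_landscape(write_landscape_csv(data.frame(
      variant = c("AC", "ACD"), fitness = c(1, 2)))),
    class = "alde_structural_error")
  expect_error(
    load_landscape(write_landscape_csv(data.frame(
      variant = c("AC", "AD"), fitness = c("1.0", "oops")))),
    class = "alde_parse_error")
  expect_error(
    load_landscape(write_landscape_csv(data.frame(
      variant = c("A*", "C*"), fitness = c(1, 2)))),
    class = "alde_empty_landscape_error")
})

test_that("normalization divides by max or reference and records provenance", {
  l <- landscape(c("A", "C"), c(2, 4), alphabet = c("A", "C"))
  lm <- normalize_landscape(l, "max")
  expect_equal(unname(lm$fitness[c("A", "C")]), c(0.5, 1.0))
  expect_identical(max(lm$fitness), 1)
  expect_equal(lm$metadata$normalization$denominator, 4)

  lr <- normalize_landscape(l, "reference", reference = "A")
  expect_equal(unname(lr$fitness[c("A", "C")]), c(1.0, 2.0))

  lz <- landscape(c("A", "C"), c(0, 0), alphabet = c("A", "C"))
  expect_error(normalize_landscape(lz, "max"),
               class = "alde_normalization_error")
  expect_error(normalize_landscape(l, "reference", reference = "W"),
               class = "alde_normalization_error")
})

test_that("load then max-normalize leaves a maximum of exactly 1", {
  path <- write_landscape_csv(data.frame(
    variant = c("AC", "AD", "CC", "CD"), fitness = c(0.3, 1.7, 0.9, 0.2)))
  l <- normalize_landscape(load_landscape(path), "max")
  expect_identical(max(l$fitness), 1)
  expect_true(all(l$fitness <= 1))
})

test_that("design-space size and enumeration agree", {
  expect_identical(design_space_size(4, 20), 160000)
  expect_identical(design_space_size(1, 20), 20)
  expect_identical(design_space_size(5, 20), 3200000)
  for (k in 1:4) {
    for (a in 2:6) {
      alpha <- LETTERS[seq_len(a)]
      combos <- enumerate_design_space(k, alpha)
      expect_equal(length(combos), design_space_size(k, a))
      expect_false(anyDuplicated(combos) > 0)
    }
  }
  expect_equal(enumerate_design_space(2, c("A", "C")),
               c("AA", "AC", "CA", "CC"))
  expect_equal(enumerate_design_space(1, c("A", "C", "D")), c("A", "C", "D"))
  expect_error(enumerate_design_space(6, AA20),
               class = "alde_capacity_error")
})

test_that("active variants use a strict threshold", {
  l <- landscape(c("A", "C", "D"), c(0, 0.5, 1))
  expect_equal(sort(active_variants(l, 0)), c("C", "D"))
  expect_equal(active_variants(l, 1), character(0))
  expect_equal(sort(active_variants(l, -Inf)), c("A", "C", "D"))
})

test_that("missing-variant lookup honours the zero/skip policy", {
  l <- landscape(c("AA", "AC"), c(0.4, 0.8), alphabet = c("A", "C"))
  z <- observe_fitness(l, c("AA", "CC"), missing = "zero")
  expect_equal(unname(z), c(0.4, 0))
  s <- observe_fitness(l, c("AA", "CC"), missing = "skip")
  expect_equal(names(s), "AA")
})

test_that("synthetic generation is complete, seeded, and scaled to [0,1]", {
  sp <- synthetic_spec(k = 3, alphabet_size = 4, seed = 9)
  l1 <- generate_synthetic_landscape(sp)
  l2 <- generate_synthetic_landscape(sp)
  expect_identical(l1$fitness, l2$fitness)
  expect_equal(length(l1$fitness), 64)
  expect_equal(range(l1$fitness), c(0, 1))
  expect_error(synthetic_spec(k = 2, interaction_order = 3))
  expect_error(synthetic_spec(epistasis_weight = 1.2))
})

test_that("zero epistasis yields background-independent mutation effects", {
  l <- additive_landscape()
  combos <- names(l$fitness)
  alpha <- l$alphabet
  # the fitness change of a substitution at site s must not depend on the
  # residues at the other sites
  for (s in 1:3) {
    for (from_to in list(c(1, 2), c(2, 4))) {
      deltas <- c()
      for (cb in combos) {
        ch <- strsplit(cb, "")[[1]]
        if (ch[s] != alpha[from_to[1]]) next
        ch2 <- ch
        ch2[s] <- alpha[from_to[2]]
        deltas <- c(deltas, l$fitness[[paste(ch2, collapse = "")]] -
                      l$fitness[[cb]])
      }
      expect_lt(diff(range(deltas)), 1e-12)
    }
  }
})

test_that("landscape round-trips through CSV with a provenance sidecar", {
  l <- normalize_landscape(additive_landscape(), "max")
  path <- tempfile(fileext = ".csv")
  write_landscape(l, path)
  l2 <- load_landscape(path)
  expect_equal(sort(names(l2$fitness)), sort(names(l$fitness)))
  expect_equal(l2$fitness[names(l$fitness)], l$fitness, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$normalization$mode, "max")
})
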