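# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Noiseless additive landscape, k=3 over 4 amino acids (64 variants).
additive_landscape <- function(seed = 5) {
  generate_synthetic_landscape(
    synthetic_spec(k = 3, alphabet_size = 4, interaction_order = 1,
                   epistasis_weight = 0, noise_sd = 0, seed = seed))
}

# Strongly epistatic landscape, k=3 over 4 amino acids.
epistatic_landscape <- function(seed = 7, w = 0.8) {
  generate_synthetic_landscape(
    synthetic_spec(k = 3, alphabet_size = 4, interaction_order = 2,
                   epistasis_weight = w, noise_sd = 0, seed = seed))
}

# Two-site sign-epistasis trap over {A, C}: the single best variant CC is
# unreachable by a greedy walk from AA because both single mutants are
# deleterious.
sign_epistasis_landscape <- function() {
  landscape(c("AA", "AC", "CA", "CC"), c(0.1, 0.05, 0.05, 1.0),
            alphabet = c("A", "C"))
}

# Ensemble posterior whose members return fixed constant predictions
# (exercises the posterior contract without training).
constant_member_posterior <- function(values) {
  members <- lapply(values, function(v) {
    force(v)
    list(kind = "fixed", predict = function(x) rep(v, nrow(x)))
  })
  structure(list(kind = "ensemble", model_kind = "dnn_ensemble",
                 members = members, member_rows = list(),
                 bootstrap_fraction = 1, ym = 0, ys = 1,
                 n_train = 0L, input_dim = NULL, seed = 0L),
            class = "alde_posterior")
}

# Ensemble posterior with arbitrary fixed per-candidate prediction vectors
# (one numeric vector per member, aligned with the candidate rows).
vector_member_posterior <- function(pred_list) {
  members <- lapply(pred_list, function(v) {
    force(v)
    list(kind = "fixed", predict = function(x) v[seq_len(nrow(x))])
  })
  structure(list(kind = "ensemble", model_kind = "dnn_ensemble",
                 members = members, member_rows = list(),
                 bootstrap_fraction = 1, ym = 0, ys = 1,
                 n_train = 0L, input_dim = NULL, seed = 0L),
            class = "alde_posterior")
}

write_landscape_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
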