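#' Acquisition specification
#'
#' @param rule `"greedy"`, `"ucb"` or `"thompson"`. Greedy is UCB with
#'   `beta = 0`: it scores candidates by the posterior mean alone.
#' @param beta UCB exploration parameter, on the scale under the square
#'   root: scores are `mu + sqrt(beta) * sigma`. Default 4 (exploration
#'   coefficient 2).
#' @param batch_size number of variants per proposed batch (q).
#' @param exclude combos that are already measured; they are never proposed.
#' @param seed integer seed (Thompson sampling only); per-draw sub-seeds are
#'   derived from it by a counter scheme so batches are reproducible and
#'   order-stable.
#' @return An object of class `alde_acquisition_spec`.
#' @export
acquisition_spec <- function(rule = c("greedy", "ucb", "thompson"), beta = 4,
                             batch_size = 96, exclude = character(0),
                             seed = 1) {
  rule <- match.arg(rule)
  stopifnot(beta >= 0, batch_size >= 1)
  structure(list(rule = rule, beta = beta,
                 batch_size = as.integer(batch_size),
                 exclude = toupper(as.character(exclude)),
                 seed = as.integer(seed)),
            class = "alde_acquisition_spec")
}

#' Upper-confidence-bound scores
#'
#' `alpha(x) = mu(x) + sqrt(beta) * sigma(x)`; `beta = 0` reduces to the
#' greedy rule (scores equal the posterior mean).
#'
#' @param mean,std aligned numeric vectors of posterior means and standard
#'   deviations.
#' @param beta exploration parameter (>= 0).
#' @return Numeric score vector.
#' @export
score_ucb <- function(mean, std, beta = 4) {
  if (length(mean) != length(std)) {
    stop_alde("mean and std lengths differ", class = "alde_contract_error")
  }
  if (any(std < 0)) {
    stop_alde("negative standard deviations", class = "alde_contract_error")
  }
  stopifnot(beta >= 0)
  mean + sqrt(beta) * std
}

#' Select the top-scoring batch
#'
#' Picks the `q` highest-scoring candidates not in the exclusion set,
#' ordered by descending score with ties broken lexicographically by combo
#' string (C collation).
#'
#' @param scores numeric acquisition values, one per candidate.
#' @param combos candidate combo strings aligned with `scores`.
#' @param q batch size.
#' @param exclude combos that must not be proposed.
#' @param provenance free-form list recorded on the proposal.
#' @return An `alde_proposal`: list with `variants` (length-q character),
#'   `scores` (aligned), and `provenance`.
#' @export
select_batch <- function(scores, combos, q, exclude = character(0),
                         provenance = list(rule = "greedy")) {
  stopifnot(length(scores) == length(combos), q >= 1)
  eligible <- !(combos %in% exclude)
  if (sum(eligible) < q) {
    stop_alde("batch size %d exceeds the %d eligible candidates", q,
              sum(eligible), class = "alde_capacity_error")
  }
  ord <- order_by_score(scores[eligible], combos[eligible])[seq_len(q)]
  structure(list(variants = combos[eligible][ord],
                 scores = unname(scores[eligible][ord]),
                 provenance = provenance),
            class = "alde_proposal")
}

#' @export
print.alde_proposal <- function(x, ...) {
  cat(sprintf("<alde_proposal> %d variants via %s\n", length(x$variants),
              x$provenance$rule %||% "?"))
  print(utils::head(data.frame(variant = x$variants, score = x$scores), 10))
  invisible(x)
}

#' Thompson-sampling batch proposal
#'
#' Each batch position is an independent posterior function draw (see
#' [sample_function()]): the draw's argmax over the still-eligible
#' candidates joins the batch, and within-batch picks are excluded from
#' later draws so a batch never contains duplicates. Batch order is draw
#' order; per-draw seeds derive from `spec$seed`.
#'
#' @param p an `alde_posterior`.
#' @param x candidate design matrix.
#' @param combos candidate combo strings aligned with the rows of `x`.
#' @param spec an [acquisition_spec()] with `rule = "thompson"`.
#' @return An `alde_proposal`.
#' @export
thompson_batch <- function(p, x, combos, spec) {
  stopifnot(inherits(spec, "alde_acquisition_spec"))
  q <- spec$batch_size
  eligible <- !(combos %in% spec$exclude)
  if (sum(eligible) < q) {
    stop_alde("batch size %d exceeds the %d eligible candidates", q,
              sum(eligible), class = "alde_capacity_error")
  }
  chosen <- character(0)
  scores <- numeric(0)
  for (j in seq_len(q)) {
    s <- sample_function(p, x, seed = derive_seed(spec$seed, 11L, j))
    ok <- eligible & !(combos %in% chosen)
    i <- order_by_score(s[ok], combos[ok])[1]
    chosen <- c(chosen, combos[ok][i])
    scores <- c(scores, s[ok][i])
  }
  structure(list(variants = chosen, scores = scores,
                 provenance = list(rule = "thompson", seed = spec$seed,
                                   batch_size = q)),
            class = "alde_proposal")
}

#' Rank the whole design space and propose a batch
#'
#' Annotates every candidate with its acquisition score, rank and
#' eligibility (excluded candidates stay in the ranking but are flagged),
#' and returns the batch proposal: the top q eligible candidates for
#' greedy/UCB, or the Thompson batch (with the ranking reported from a
#' single reference posterior draw).
#'
#' @param p an `alde_posterior`.
#' @param combos candidate combo strings (the enumerated design space).
#' @param encoder an `alde_encoder` matching the one used for training.
#' @param spec an [acquisition_spec()].
#' @return A list with `ranking` (data.frame: rank, variant, score,
#'   eligible) and `proposal` (an `alde_proposal`).
#' @export
rank_design_space <- function(p, combos, encoder, spec) {
  stopifnot(inherits(spec, "alde_acquisition_spec"))
  x <- build_design_matrix(combos, encoder)
  if (spec$rule == "thompson") {
    ref <- sample_function(p, x, seed = derive_seed(spec$seed, 11L, 0L))
    proposal <- thompson_batch(p, x, combos, spec)
    score <- ref
  } else {
    st <- posterior_stats(p, x)
    beta <- if (spec$rule == "greedy") 0 else spec$beta
    score <- score_ucb(st$mean, st$sd, beta)
    proposal <- select_batch(score, combos, spec$batch_size,
                             exclude = spec$exclude,
                             provenance = list(rule = spec$rule, beta = beta))
  }
  ord <- order_by_score(score, combos)
  ranking <- data.frame(rank = seq_along(combos),
                        variant = combos[ord],
                        score = unname(score[ord]),
                        eligible = !(combos[ord] %in% spec$exclude),
                        stringsAsFactors = FALSE)
  list(ranking = ranking, proposal = proposal)
}

#' Propose the next batch from a fitted posterior
#'
#' Thin dispatcher used by the campaign loop and the command-line
#' interface: greedy/UCB batches come from [select_batch()] on posterior
#' statistics, Thompson batches from [thompson_batch()].
#'
#' @inheritParams rank_design_space
#' @return An `alde_proposal`.
#' @export
propose_batch <- function(p, combos, encoder, spec) {
  x <- build_design_matrix(combos, encoder)
  if (spec$rule == "thompson") {
    thompson_batch(p, x, combos, spec)
  } else {
    st <- posterior_stats(p, x)
    beta <- if (spec$rule == "greedy") 0 else spec$beta
    select_batch(score_ucb(st$mean, st$sd, beta), combos, spec$batch_size,
                 exclude = spec$exclude,
                 provenance = list(rule = spec$rule, beta = beta))
  }
}
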