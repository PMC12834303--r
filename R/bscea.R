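# BeamStar contraction-expansion search (BSCEA): extend a seed base-by-base
# under f = g + h, where g accumulates |ln p| over chosen bases and h combines
# sequence entropy, normalised remaining length and GC disparity; the beam
# width widens linearly to a peak, then shrinks towards termination.

#' Accumulated path cost
#'
#' Adds `sum(|ln p_i|)` over a vector of chosen-base probabilities to the
#' current accumulated cost. Probabilities are floored at `p_min` before the
#' logarithm so a zero-probability step yields a large finite cost.
#'
#' @param current_g accumulated cost so far (>= 0).
#' @param probabilities chosen-base probabilities in `(0, 1]`.
#' @param p_min floor applied before `log`.
#' @return new accumulated cost (non-negative).
#' @export
#' @examples
#' path_cost_g(0, c(0.5))           # |ln 0.5|
#' path_cost_g(1, c(0.25, 0.25))    # 1 + 2 ln 4
path_cost_g <- function(current_g, probabilities, p_min = 1e-9) {
  stopifnot(is.numeric(current_g), length(current_g) == 1L, current_g >= 0,
            is.numeric(probabilities))
  p <- pmax(probabilities, p_min)
  if (any(p > 1 + 1e-9)) stop("probability > 1 in path cost", call. = FALSE)
  current_g + sum(abs(log(pmin(p, 1))))
}

#' Normalised sequence entropy of a probability trace
#'
#' `H(S) / maxEntropy`, where `H(S)` sums the full 4-way entropy of each
#' step's predictive distribution and `maxEntropy = n log 4` for an `n`-step
#' trace. The ratio lies in `[0, 1]` and is invariant to the logarithm base
#' (numerator and denominator rescale together); `log_base` is accepted for
#' completeness.
#'
#' @param prob_trace matrix (steps x 4) of per-step distributions, or a list
#'   of 4-vectors.
#' @param log_base base of the logarithm.
#' @return value in `[0, 1]`; 0 for an empty trace.
#' @export
entropy_term <- function(prob_trace, log_base = exp(1)) {
  if (is.list(prob_trace)) prob_trace <- do.call(rbind, prob_trace)
  if (is.null(prob_trace) || length(prob_trace) == 0L) return(0)
  stopifnot(is.matrix(prob_trace), ncol(prob_trace) == 4L)
  n <- nrow(prob_trace)
  p <- prob_trace
  lp <- ifelse(p > 0, log(p, base = log_base), 0)
  h <- -sum(p * lp)
  h / (n * log(4, base = log_base))
}

#' Normalised logarithm of the remaining sequence length
#'
#' `ln(total - predicted) / ln(total)`; by convention 0 once nothing (or one
#' base, whose log is 0) remains, and 0 for `total_length < 2`.
#'
#' @param total_length total number of bases to predict.
#' @param seed_length number already predicted.
#' @return value in `[0, 1]`.
#' @export
norm_rem_len <- function(total_length, seed_length) {
  stopifnot(total_length >= 1L, seed_length >= 0L)
  if (total_length < 2L) return(0)
  rem <- total_length - seed_length
  if (rem <= 1L) return(0)
  log(rem) / log(total_length)
}

#' GC-content disparity between a sequence and its extension
#'
#' `|GC(next)/len(next) - GC(current)/len(current)|` with GC counting `C + G`.
#'
#' @param current_seq current sequence (non-empty).
#' @param next_seq candidate extended sequence (non-empty).
#' @return value in `[0, 1]`.
#' @export
#' @examples
#' gc_ratio_impact("ATAT", "ATATG")  # 0.2
gc_ratio_impact <- function(current_seq, next_seq) {
  if (!nzchar(current_seq) || !nzchar(next_seq)) {
    stop("gc_ratio_impact requires non-empty sequences", call. = FALSE)
  }
  gc <- function(s) {
    n <- nchar(s)
    (n - nchar(gsub("[GC]", "", s))) / n
  }
  abs(gc(next_seq) - gc(current_seq))
}

#' Heuristic weights for the search cost
#'
#' @param alpha entropy weight (enters with a leading minus sign: complex,
#'   high-entropy paths are *rewarded* relative to degenerate ones).
#' @param beta remaining-length weight.
#' @param gamma GC-disparity weight.
#' @param log_base logarithm base for the entropy term.
#' @return a `heuristic_weights` list.
#' @export
heuristic_weights <- function(alpha = 1, beta = 1, gamma = 1,
                              log_base = exp(1)) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, log_base > 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 log_base = log_base), class = "heuristic_weights")
}

#' Heuristic cost of a candidate extension
#'
#' `-alpha * entropy_term + beta * norm_rem_len + gamma * gc_ratio_impact`,
#' evaluated for the extension `next_seq = current_seq + proposed base` whose
#' per-step distributions (including the proposal step) are `prob_trace`.
#'
#' @param prob_trace matrix/list of per-step 4-vectors including the
#'   candidate step.
#' @param current_seq sequence before the extension (seed included).
#' @param next_seq sequence after the extension.
#' @param n_predicted predicted bases after the extension (seed excluded).
#' @param total_length target number of predicted bases.
#' @param weights a [heuristic_weights()].
#' @return heuristic cost (may be negative through the entropy reward).
#' @export
heuristic_cost <- function(prob_trace, current_seq, next_seq, n_predicted,
                           total_length, weights = heuristic_weights()) {
  stopifnot(inherits(weights, "heuristic_weights"))
  -weights$alpha * entropy_term(prob_trace, weights$log_base) +
    weights$beta * norm_rem_len(total_length, n_predicted) +
    weights$gamma * gc_ratio_impact(current_seq, next_seq)
}

#' Contraction-expansion beam schedule
#'
#' The width is interpolated linearly from `w_init` at step 0 up to `w_max`
#' at the contraction point `contract_at * target_length`, then back down to
#' `w_final` at the last step.
#'
#' @param w_init starting width.
#' @param w_max peak width.
#' @param w_final width at the final step.
#' @param contract_at fraction of the target length at which contraction
#'   begins, in `(0, 1]`.
#' @return a `beam_schedule` list.
#' @export
beam_schedule <- function(w_init = 8L, w_max = 16L, w_final = 8L,
                          contract_at = 0.75) {
  stopifnot(w_init >= 1L, w_final >= 1L, w_max >= w_init, w_max >= w_final,
            contract_at > 0, contract_at <= 1)
  structure(list(w_init = as.integer(w_init), w_max = as.integer(w_max),
                 w_final = as.integer(w_final), contract_at = contract_at),
            class = "beam_schedule")
}

#' Constant-width beam schedule
#' @param w the width.
#' @return a [beam_schedule()] with all widths equal to `w`.
#' @export
constant_schedule <- function(w) beam_schedule(w, w, w, contract_at = 1)

#' Beam width at a given search step
#'
#' @param step 0-based step index in `[0, target_length)`.
#' @param target_length number of bases to predict.
#' @param schedule a [beam_schedule()].
#' @return positive integer width.
#' @export
beam_width_at <- function(step, target_length, schedule) {
  stopifnot(inherits(schedule, "beam_schedule"),
            step >= 0L, step < target_length)
  tc <- schedule$contract_at * target_length
  w <- if (step < tc) {
    if (tc <= 0) schedule$w_max
    else schedule$w_init + (schedule$w_max - schedule$w_init) * step / tc
  } else {
    last <- target_length - 1
    if (last - tc <= 0) schedule$w_final
    else schedule$w_max + (schedule$w_final - schedule$w_max) * (step - tc) / (last - tc)
  }
  max(1L, as.integer(round(w)))
}

.validate_probs <- function(P, n) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  if (!is.matrix(P) || ncol(P) != 4L || nrow(P) != n) {
    stop("oracle must return an n x 4 probability matrix", call. = FALSE)
  }
  if (any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-6)) {
    stop("oracle returned a non-simplex probability row", call. = FALSE)
  }
  pmax(P, 0)
}

#' Contraction-expansion beam search over next-base predictions
#'
#' Starting from a seed, every surviving node is extended by all four bases
#' at each step; children are scored `f = g + h` and the
#' [beam_width_at()] lowest-f children survive. Ties break by lower `f`,
#' then earlier channel order of the appended base, then lexicographic
#' sequence, which makes the search fully deterministic. After
#' `target_length` steps the lowest-f candidate is returned.
#'
#' @param oracle function mapping a character vector of contexts (seed plus
#'   predicted bases so far) to an `n x 4` matrix of next-base probabilities
#'   in channel order.
#' @param seed non-empty N-free seed sequence (context only; not part of the
#'   returned fill).
#' @param target_length number of bases to predict.
#' @param weights a [heuristic_weights()].
#' @param schedule a [beam_schedule()].
#' @param p_min probability floor for the path cost.
#' @return a `search_result` list: `$best` (node with `$sequence` including
#'   the seed, `$fill`, `$g`, `$h`, `$f`, `$prob_trace`, `$chosen_probs`),
#'   `$candidates` (final beam as a data.frame), `$stats`.
#' @export
bscea_search <- function(oracle, seed, target_length,
                         weights = heuristic_weights(),
                         schedule = beam_schedule(), p_min = 1e-9) {
  stopifnot(is.function(oracle), is.character(seed), length(seed) == 1L,
            nzchar(seed), target_length >= 1L)
  if (grepl("N", seed, fixed = TRUE)) stop("seed must be N-free", call. = FALSE)
  .check_alphabet(seed, "seed")
  L <- as.integer(target_length)
  seed_len <- nchar(seed)
  seed_gc <- seed_len - nchar(gsub("[GC]", "", seed))

  # beam state as parallel vectors; traces as a list of (steps x 4) matrices
  seqs <- seed; g <- 0; hsum <- 0; gc_cnt <- seed_gc
  traces <- list(matrix(numeric(0), ncol = 4L))
  chosen <- list(numeric(0))
  h_cur <- 0
  nodes_expanded <- 0L; peak <- 1L
  log4 <- log(4)

  for (step in 0:(L - 1L)) {
    n <- length(seqs)
    nodes_expanded <- nodes_expanded + n
    P <- .validate_probs(oracle(seqs), n)
    h_step <- -rowSums(ifelse(P > 0, P * log(P), 0))   # nats
    len_cur <- seed_len + step

    # children: node i extended by base j
    ii <- rep(seq_len(n), times = 4L)
    jj <- rep(1:4, each = n)
    pj <- P[cbind(ii, jj)]
    child_g <- g[ii] + abs(log(pmin(pmax(pj, p_min), 1)))
    child_hsum <- hsum[ii] + h_step[ii]
    ent <- child_hsum / ((step + 1) * log4)
    nrl <- {
      rem <- L - (step + 1L)
      if (L < 2L || rem <= 1L) 0 else log(rem) / log(L)
    }
    is_gc <- jj == 2L | jj == 3L
    child_gc <- gc_cnt[ii] + as.integer(is_gc)
    gc_imp <- abs(child_gc / (len_cur + 1) - gc_cnt[ii] / len_cur)
    child_h <- -weights$alpha * ent + weights$beta * nrl + weights$gamma * gc_imp
    child_f <- child_g + child_h
    child_seq <- paste0(seqs[ii], CHANNEL_ORDER[jj])

    w <- beam_width_at(step, L, schedule)
    ord <- order(child_f, jj, child_seq, method = "radix")
    keep <- ord[seq_len(min(w, length(ord)))]

    ki <- ii[keep]
    seqs <- child_seq[keep]
    g <- child_g[keep]
    hsum <- child_hsum[keep]
    gc_cnt <- child_gc[keep]
    h_cur <- child_h[keep]
    traces <- lapply(seq_along(keep), function(t) {
      rbind(traces[[ki[[t]]]], P[ki[[t]], ])
    })
    chosen <- lapply(seq_along(keep), function(t) {
      c(chosen[[ki[[t]]]], pj[[keep[[t]]]])
    })
    peak <- max(peak, length(seqs))
  }

  f <- g + h_cur
  last_base <- match(substr(seqs, nchar(seqs), nchar(seqs)), CHANNEL_ORDER)
  best_i <- order(f, last_base, seqs, method = "radix")[[1L]]
  best <- list(sequence = seqs[[best_i]],
               fill = substr(seqs[[best_i]], seed_len + 1L, nchar(seqs[[best_i]])),
               g = g[[best_i]], h = h_cur[[best_i]], f = f[[best_i]],
               prob_trace = traces[[best_i]], chosen_probs = chosen[[best_i]])
  structure(list(
    best = best,
    candidates = data.frame(sequence = seqs, g = g, h = h_cur, f = f,
                            stringsAsFactors = FALSE),
    stats = list(nodes_expanded = nodes_expanded, peak_beam = peak),
    seed = seed, target_length = L
  ), class = "search_result")
}

#' Predict a fill for one gap
#'
#' `mode = "left"` seeds the search from the left flank; `"right"` runs on
#' the reverse complement of the right flank and reverse-complements the
#' result, reusing the single trained model via strand symmetry;
#' `"bidirectional"` runs both and reconciles: when the two candidates agree
#' at `>= min_identity` over the gap, the merged fill takes its left half
#' from the leftward candidate and its right half from the rightward one
#' (each direction is most reliable near its own seed); otherwise the
#' lower-f candidate wins.
#'
#' @param model a trained model (see [train_model()]) or an oracle function
#'   as accepted by [bscea_search()].
#' @param gap one row of a [detect_gaps()] data.frame.
#' @param weights a [heuristic_weights()].
#' @param schedule a [beam_schedule()].
#' @param mode `"bidirectional"`, `"left"` or `"right"`.
#' @param target_length bases to predict; defaults to the gap's N-run length.
#' @param min_flank shortest usable flank; gaps with no usable flank are
#'   skipped with a warning (returns `NULL`).
#' @param min_identity agreement needed to merge the two directions.
#' @param p_min probability floor for the path cost.
#' @return list with `$fill`, `$direction`, `$f`, `$per_direction` (each a
#'   `search_result`-derived summary), or `NULL` when skipped.
#' @export
fill_gap <- function(model, gap, weights = heuristic_weights(),
                     schedule = beam_schedule(),
                     mode = c("bidirectional", "left", "right"),
                     target_length = NULL, min_flank = 50L,
                     min_identity = 0.8, p_min = 1e-9) {
  mode <- match.arg(mode)
  gap <- as.list(gap)
  oracle <- if (is.function(model)) model else model_oracle(model)
  L <- if (is.null(target_length)) gap$end - gap$start else as.integer(target_length)
  left_ok <- nchar(gap$left_flank) >= min_flank
  right_ok <- nchar(gap$right_flank) >= min_flank
  if (mode == "left" && !left_ok || mode == "right" && !right_ok ||
      mode == "bidirectional" && !left_ok && !right_ok) {
    warning(sprintf("gap %s skipped: no usable flank (min %d bp)",
                    gap$gap_id %||% "?", min_flank))
    return(NULL)
  }
  run_left <- function() {
    r <- bscea_search(oracle, gap$left_flank, L, weights, schedule, p_min)
    list(fill = r$best$fill, f = r$best$f, result = r)
  }
  run_right <- function() {
    r <- bscea_search(oracle, reverse_complement(gap$right_flank), L,
                      weights, schedule, p_min)
    list(fill = reverse_complement(r$best$fill), f = r$best$f, result = r)
  }
  if (mode == "left" || (mode == "bidirectional" && !right_ok)) {
    lr <- run_left()
    return(list(fill = lr$fill, direction = "left", f = lr$f,
                per_direction = list(left = lr)))
  }
  if (mode == "right" || (mode == "bidirectional" && !left_ok)) {
    rr <- run_right()
    return(list(fill = rr$fill, direction = "right", f = rr$f,
                per_direction = list(right = rr)))
  }
  lr <- run_left(); rr <- run_right()
  lc <- strsplit(lr$fill, "")[[1L]]; rc <- strsplit(rr$fill, "")[[1L]]
  identity <- mean(lc == rc)
  if (identity >= min_identity) {
    half <- ceiling(L / 2)
    fill <- paste0(substr(lr$fill, 1L, half), substr(rr$fill, half + 1L, L))
    list(fill = fill, direction = "merged", f = min(lr$f, rr$f),
         identity_between = identity,
         per_direction = list(left = lr, right = rr))
  } else {
    pick <- if (lr$f <= rr$f) lr else rr
    list(fill = pick$fill,
         direction = if (lr$f <= rr$f) "left" else "right", f = pick$f,
         identity_between = identity,
         per_direction = list(left = lr, right = rr))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
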