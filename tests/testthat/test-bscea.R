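test_that("path cost accumulates |ln p| and floors zero probabilities", {
  expect_equal(path_cost_g(0, c(1, 1)), 0)
  expect_equal(path_cost_g(0, 0.5), abs(log(0.5)))
  expect_equal(path_cost_g(1, c(0.25, 0.25)), 1 + 2 * log(4))
  expect_equal(path_cost_g(0, 0), abs(log(1e-9)))
  expect_error(path_cost_g(0, 1.5), "probability > 1")
  # additive along paths
  expect_equal(path_cost_g(path_cost_g(0, 0.3), 0.7),
               path_cost_g(0, c(0.3, 0.7)))
})

test_that("entropy term is the normalised trace entropy in [0, 1]", {
  uni <- matrix(0.25, 5, 4)
  expect_equal(entropy_term(uni), 1)
  hot <- matrix(rep(c(1, 0, 0, 0), 3), 3, 4, byrow = TRUE)
  expect_equal(entropy_term(hot), 0)
  expect_equal(entropy_term(matrix(c(0.5, 0.5, 0, 0), 1)), log(2) / log(4))
  expect_equal(entropy_term(list()), 0)
  # base-invariance of the normalised ratio
  tr <- matrix(c(0.7, 0.1, 0.1, 0.1, 0.4, 0.3, 0.2, 0.1), 2, 4, byrow = TRUE)
  expect_equal(entropy_term(tr, log_base = 2), entropy_term(tr))
  set.seed(3)
  for (i in 1:20) {
    p <- matrix(rgamma(4 * 8, 1), 8)
    p <- p / rowSums(p)
    e <- entropy_term(p)
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("normalised remaining length matches its closed form", {
  expect_equal(norm_rem_len(100, 99), 0)
  expect_equal(norm_rem_len(100, 0), 1)
  expect_equal(norm_rem_len(100, 50), log(50) / log(100))
  expect_equal(norm_rem_len(100, 100), 0)
  expect_equal(norm_rem_len(1, 0), 0)
})

test_that("GC disparity is the absolute GC-fraction difference", {
  expect_equal(gc_ratio_impact("ATAT", "ATATG"), abs(1 / 5 - 0))
  expect_equal(gc_ratio_impact("GGCC", "GGCCA"), abs(4 / 5 - 1))
  expect_equal(gc_ratio_impact("ACGT", "ACGT"), 0)
  expect_error(gc_ratio_impact("", "A"), "non-empty")
})

test_that("heuristic combines the three terms with signed weights", {
  tr <- matrix(0.25, 50, 4)   # entropy term 1 after 50 steps
  w0 <- heuristic_weights(0, 0, 0)
  expect_equal(heuristic_cost(tr, "x", "y", 50, 100, w0), 0)
  # worked composition: entropy 1, remaining ln50/ln100, gc 0.2
  w1 <- heuristic_weights(1, 1, 1)
  h <- heuristic_cost(tr, "ATAT", "ATATG", 50, 100, w1)
  expect_equal(h, -1 + log(50) / log(100) + 0.2)
  # raising gamma never lowers h when the GC impact is positive
  h2 <- heuristic_cost(tr, "ATAT", "ATATG", 50, 100,
                       heuristic_weights(1, 1, 2))
  expect_gte(h2, h)
})

test_that("beam width follows the expand-then-contract schedule", {
  sch <- beam_schedule(4, 16, 4, contract_at = 0.5)
  expect_equal(beam_width_at(0, 100, sch), 4)
  expect_equal(beam_width_at(99, 100, sch), 4)
  expect_equal(beam_width_at(25, 100, sch), 10)
  expect_equal(beam_width_at(50, 100, sch), 16)
  widths <- vapply(0:99, beam_width_at, 1L, target_length = 100,
                   schedule = sch)
  expect_true(all(diff(widths[1:51]) >= 0))
  expect_true(all(diff(widths[51:100]) <= 0))
  expect_true(all(widths >= 1))
  const <- constant_schedule(7)
  expect_true(all(vapply(0:9, beam_width_at, 1L, 10, const) == 7))
  expect_error(beam_schedule(8, 4, 8), ">=")
})

test_that("a near-deterministic oracle forces its sequence at g ~ 0", {
  forced <- function(contexts) {
    # always continue with the base after the context's last base in ACGT order
    last <- substr(contexts, nchar(contexts), nchar(contexts))
    nxt <- (match(last, c("A", "C", "G", "T")) %% 4) + 1
    P <- matrix(1e-9 / 3, length(contexts), 4)
    P[cbind(seq_along(contexts), nxt)] <- 1 - 1e-9
    P
  }
  res <- bscea_search(forced, "A", 5, schedule = constant_schedule(4))
  expect_equal(res$best$fill, "CGTAC")
  expect_lt(res$best$g, 1e-6)
  expect_equal(nrow(res$best$prob_trace), 5)
})

test_that("reported costs are recomputable from the probability trace", {
  orc <- markov_oracle(2, rng_seed = 5)
  res <- bscea_search(orc, "ACG", 8, schedule = beam_schedule(2, 8, 2, 0.75))
  b <- res$best
  expect_equal(nchar(b$fill), 8)
  expect_equal(b$g, path_cost_g(0, b$chosen_probs), tolerance = 1e-9)
  expect_equal(b$f, b$g + b$h)
  # chosen probabilities are rows of the trace at the chosen bases
  fill_idx <- match(strsplit(b$fill, "")[[1]], c("A", "C", "G", "T"))
  expect_equal(b$prob_trace[cbind(seq_len(8), fill_idx)], b$chosen_probs)
})

test_that("full-width search equals brute-force enumeration", {
  w <- heuristic_weights(1, 1, 1)
  orc <- markov_oracle(2, rng_seed = 17)
  res <- bscea_search(orc, "ACGT", 6, weights = w,
                      schedule = constant_schedule(4096))
  bf <- brute_force_best(orc, "ACGT", 6, w)
  expect_identical(res$best$fill, bf$fill)
  expect_equal(res$best$f, bf$f, tolerance = 1e-9)
})

test_that("zero-weight search reduces to plain beam search", {
  orc <- markov_oracle(3, rng_seed = 23)
  w0 <- heuristic_weights(0, 0, 0)
  for (width in c(2, 8)) {
    res <- bscea_search(orc, "GAT", 10, weights = w0,
                        schedule = constant_schedule(width))
    ref <- plain_beam_search(orc, "GAT", 10, width)
    expect_identical(res$best$sequence, ref$sequence)
    expect_equal(res$best$g, ref$g, tolerance = 1e-9)
  }
})

test_that("oracle contract violations are caught", {
  bad <- function(contexts) matrix(0.3, length(contexts), 4)
  expect_error(bscea_search(bad, "A", 3), "non-simplex")
  expect_error(bscea_search(markov_oracle(1, 1), "NN", 3), "N-free")
})

test_that("fill_gap is strand-symmetric and reconciles directions", {
  orc <- markov_oracle(2, rng_seed = 9)
  gap_l <- list(gap_id = "g1", scaffold_id = "s", start = 100, end = 110,
                left_flank = "ACGTACGTAC", right_flank = "")
  res_l <- fill_gap(orc, gap_l, mode = "left", min_flank = 5,
                    schedule = constant_schedule(8))
  expect_equal(nchar(res_l$fill), 10)
  expect_equal(res_l$direction, "left")
  # right mode on the mirrored gap gives the reverse-complement fill
  gap_r <- list(gap_id = "g2", scaffold_id = "s", start = 100, end = 110,
                left_flank = "", right_flank = reverse_complement("ACGTACGTAC"))
  res_r <- fill_gap(orc, gap_r, mode = "right", min_flank = 5,
                    schedule = constant_schedule(8))
  expect_identical(res_r$fill, reverse_complement(res_l$fill))

  # bidirectional with two identical candidates returns that candidate:
  # the forced continuation is the RC-palindrome ATATATAT, so the leftward
  # search (seed CCCCC) and the rightward search (seed revcomp(GGGGG) =
  # CCCCC) both yield it
  forced <- function(contexts) {
    last <- substr(contexts, nchar(contexts), nchar(contexts))
    nxt <- ifelse(last == "A", 4L, 1L)   # A -> T, anything else -> A
    P <- matrix(1e-9 / 3, length(contexts), 4)
    P[cbind(seq_along(contexts), nxt)] <- 1 - 1e-9
    P
  }
  gap_b <- list(gap_id = "g3", scaffold_id = "s", start = 100, end = 108,
                left_flank = "CCCCC", right_flank = "GGGGG")
  res_b <- fill_gap(forced, gap_b, mode = "bidirectional", min_flank = 3,
                    schedule = constant_schedule(4))
  expect_equal(res_b$fill, "ATATATAT")
  expect_equal(res_b$direction, "merged")
  expect_equal(res_b$identity_between, 1)

  # unusable flanks -> skipped with a warning
  gap_s <- list(gap_id = "g4", scaffold_id = "s", start = 5, end = 10,
                left_flank = "AC", right_flank = "GT")
  expect_warning(out <- fill_gap(orc, gap_s, min_flank = 50), "skipped")
  expect_null(out)
})
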