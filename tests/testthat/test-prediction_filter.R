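test_that("alignment rate is matches over candidate length", {
  hom <- paste0("AAAACCCC", "ACGTACGTGG", "TTTTGGGG")
  expect_equal(align_candidate("ACGTACGTGG", hom)$rate, 1)
  # all-N candidates never match
  expect_equal(align_candidate("NNNNNNNN", hom)$rate, 0)
})

test_that("k mismatches give rate (L - k)/L, agreeing with edit distance", {
  set.seed(5)
  base <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  hom <- paste0("GGGGGGGG", base, "CCCCCCCC")
  for (k in c(1, 3, 5)) {
    cand <- base
    pos <- seq(10, 50, length.out = k)
    for (p in pos) {
      old <- substr(cand, p, p)
      substr(cand, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    rep_ <- align_candidate(cand, hom)
    expect_equal(rep_$rate, (60 - k) / 60)
    # independent check: Levenshtein distance to the best-matching window
    expect_equal(rep_$edit_distance, as.integer(utils::adist(cand, base)))
  }
})

make_filter_fixture <- function() {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  truth <- scaffold_record("t", seq)
  gapped <- truth
  substr(gapped$sequence, 181, 220) <- strrep("N", 40)
  scaf <- scaffold_record("t", gapped$sequence)
  gaps <- detect_gaps(scaf)
  truth_fill <- substr(seq, 181, 220)
  list(truth = truth, scaf = scaf, gaps = gaps, truth_fill = truth_fill)
}

test_that("filter partitions candidates by framed rate vs threshold and baseline", {
  fx <- make_filter_fixture()
  corrupt <- paste(rev(strsplit(fx$truth_fill, "")[[1]]), collapse = "")
  candidates <- data.frame(
    gap_id = fx$gaps$gap_id[c(1, 1)],
    candidate_id = c("good", "bad"),
    fill = c(fx$truth_fill, corrupt),
    stringsAsFactors = FALSE)
  provider <- truth_homolog_provider(fx$truth, fx$gaps)
  out <- filter_predictions(candidates, fx$gaps, provider, tau = 0.9)
  expect_equal(out$verdicts$label, c("available", "disposable"))
  expect_equal(out$available$candidate_id, "good")
  expect_equal(out$disposable$candidate_id, "bad")
  expect_equal(out$verdicts$rate[1], 1)
  expect_lt(out$verdicts$baseline_rate[1], out$verdicts$rate[1])
  # partition is exhaustive and disjoint
  expect_equal(sort(c(out$available$candidate_id, out$disposable$candidate_id)),
               sort(candidates$candidate_id))
})

test_that("raising tau never moves a candidate from disposable to available", {
  fx <- make_filter_fixture()
  set.seed(21)
  fills <- vapply(1:10, function(i) {
    f <- fx$truth_fill
    nmut <- sample(0:20, 1)
    if (nmut > 0) {
      for (p in sample(40, nmut)) {
        substr(f, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(f, p, p)), 1)
      }
    }
    f
  }, character(1))
  candidates <- data.frame(gap_id = fx$gaps$gap_id[1],
                           candidate_id = sprintf("c%02d", 1:10),
                           fill = fills, stringsAsFactors = FALSE)
  provider <- truth_homolog_provider(fx$truth, fx$gaps)
  labels <- sapply(c(0.5, 0.7, 0.9, 0.99), function(tau) {
    filter_predictions(candidates, fx$gaps, provider, tau = tau)$verdicts$label
  })
  for (j in 2:ncol(labels)) {
    expect_true(all(labels[, j] == "disposable" |
                      labels[, j - 1] == "available"))
  }
  # the available set's mean rate is at least the pool's mean rate
  out <- filter_predictions(candidates, fx$gaps, provider, tau = 0.9)
  if (nrow(out$available) > 0) {
    avail_rates <- out$verdicts$rate[out$verdicts$label == "available"]
    expect_gte(mean(avail_rates), mean(out$verdicts$rate))
  }
})

test_that("missing homologs pass through as disposable, or error in strict mode", {
  fx <- make_filter_fixture()
  candidates <- data.frame(gap_id = fx$gaps$gap_id[1], candidate_id = "c1",
                           fill = fx$truth_fill, stringsAsFactors = FALSE)
  none <- function(gap_id) NA_character_
  out <- filter_predictions(candidates, fx$gaps, none)
  expect_equal(out$verdicts$label, "disposable")
  expect_error(filter_predictions(candidates, fx$gaps, none, strict = TRUE),
               "no homolog region")
})

test_that("filtering a corrupted candidate lowers mismatches against truth", {
  fx <- make_filter_fixture()
  corrupt <- chartr("ACGT", "TGCA", fx$truth_fill)
  unfiltered <- patch_scaffold(fx$scaf, fx$gaps[1, ], corrupt)
  filtered <- fx$scaf   # corrupt candidate was disposed of; gap left open
  cmp <- compare_assemblies(unfiltered, filtered, fx$truth)
  expect_lte(cmp$filtered$mismatches_per_100kb,
             cmp$unfiltered$mismatches_per_100kb)
  expect_gt(cmp$mismatch_reduction_per_100kb, 0)
})

test_that("no-op filtering leaves identical scaffolds; rejecting all reverts", {
  fx <- make_filter_fixture()
  patched <- patch_scaffold(fx$scaf, fx$gaps[1, ], fx$truth_fill)
  cmp <- compare_assemblies(patched, patched, fx$truth)
  expect_equal(cmp$mismatch_reduction_per_100kb, 0)
  cmp2 <- compare_assemblies(fx$scaf, fx$scaf, fx$truth)
  expect_equal(cmp2$filtered$n_count, 40)
})

test_that("FASTA homolog providers key regions by gap id", {
  fx <- make_filter_fixture()
  f <- withr::local_tempfile(fileext = ".fasta")
  region <- truth_homolog_provider(fx$truth, fx$gaps)(fx$gaps$gap_id[1])
  write_fasta(list(scaffold_record(fx$gaps$gap_id[1], region)), f)
  provider <- fasta_homolog_provider(f)
  expect_equal(provider(fx$gaps$gap_id[1]), region)
  expect_true(is.na(provider("nope")))
})
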