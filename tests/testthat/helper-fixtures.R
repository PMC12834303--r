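# Shared fixtures, built once per test run and cached. The heavy ones (a
# trained periodic-genome model, the 50 kb end-to-end fixture) are reused by
# several files.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# ---- periodic-genome fixtures ----------------------------------------------

periodic_genome <- function() fx_cached("periodic_genome", function() {
  generate_genome(genome_spec(4000, gc_content = 0.5, repeat_motif_len = 21,
                              repeat_fraction = 1, rng_seed = 11))
})

periodic_training_set <- function() fx_cached("periodic_ts", function() {
  make_training_set(periodic_genome(), window_len = 64, step = 1, rng_seed = 5)
})

# window 64 >= motif period 21: the next base is a deterministic function of
# the context, so a trained model should approach perfect accuracy
periodic_model <- function() fx_cached("periodic_model", function() {
  cfg <- model_config(window_len = 64, conv_channels = 16, lstm_hidden = 32,
                      dropout_rate = 0.1)
  tc <- training_config(learning_rate = 2e-3, batch_size = 128,
                        max_epochs = 6, early_stop_patience = 3,
                        validation_fraction = 0.1, rng_seed = 42)
  train_model(build_model(cfg, init_seed = 2), periodic_training_set(), tc)
})

# ---- 50 kb end-to-end fixture ----------------------------------------------

e2e_fixture <- function() fx_cached("e2e", function() {
  spec <- genome_spec(50000, gc_content = 0.45, repeat_motif_len = 21,
                      repeat_fraction = 0.5, rng_seed = 101)
  genome <- generate_genome(spec)
  sim <- introduce_gaps(genome, n_gaps = 20, gap_len_range = c(20, 100),
                        min_spacing = 200, rng_seed = 202,
                        block_types = c("repeat", "unique"))
  ts <- make_training_set(sim$scaffold, window_len = 32, step = 3,
                          rng_seed = 7)
  cfg <- model_config(window_len = 32, conv_channels = 16, lstm_hidden = 24,
                      dropout_rate = 0.1)
  tc <- training_config(learning_rate = 2e-3, batch_size = 256,
                        max_epochs = 15, early_stop_patience = 3,
                        validation_fraction = 0.05, rng_seed = 42)
  model <- train_model(build_model(cfg, init_seed = 2), ts, tc)
  list(spec = spec, genome = genome, scaffold = sim$scaffold,
       truth = sim$truth, model = model)
})

e2e_run <- function(out_dir, apply_filter = TRUE, seed = 1L) {
  fx <- e2e_fixture()
  cfg <- run_config(scaffold = list(fx$scaffold), model = fx$model,
                    out_dir = out_dir, truth = list(fx$genome),
                    schedule = beam_schedule(8, 16, 8, 0.75),
                    apply_filter = apply_filter, rng_seed = seed)
  run_pipeline(cfg)
}

e2e_pipeline <- function() fx_cached("e2e_pipeline", function() {
  dir <- file.path(tempdir(), "gapfillr-e2e")
  e2e_run(dir)
})

# ---- exact periodic oracle + small pipeline fixture ------------------------

# A deterministic strand-aware oracle that continues a periodic genome: the
# last motif-period bases pin the phase (on either strand), so the next base
# is exact. Lets the pipeline be exercised end-to-end without training.
periodic_oracle <- function(motif) {
  k <- nchar(motif)
  cycle <- strrep(motif, 3)
  rc_cycle <- reverse_complement(cycle)
  function(contexts) {
    P <- matrix(1e-7 / 3, length(contexts), 4)
    for (i in seq_along(contexts)) {
      s <- contexts[[i]]
      tailk <- substr(s, nchar(s) - k + 1, nchar(s))
      pos <- regexpr(tailk, cycle, fixed = TRUE)
      src <- cycle
      if (pos < 0) {
        pos <- regexpr(tailk, rc_cycle, fixed = TRUE)
        src <- rc_cycle
      }
      nxt <- if (pos > 0) substr(src, pos + k, pos + k) else "A"
      P[i, match(nxt, c("A", "C", "G", "T"))] <- 1 - 1e-7
    }
    P
  }
}

pipeline_fixture <- function() fx_cached("pipeline_fixture", function() {
  genome <- generate_genome(genome_spec(20000, gc_content = 0.45,
                                        repeat_motif_len = 21,
                                        repeat_fraction = 1, rng_seed = 61))
  sim <- introduce_gaps(genome, n_gaps = 8, gap_len_range = c(20, 60),
                        min_spacing = 300, rng_seed = 62)
  motif <- substr(genome$sequence, 1, 21)
  list(genome = genome, sim = sim, oracle = periodic_oracle(motif))
})

# ---- independent search oracles --------------------------------------------

# Exhaustive minimum-f completion, written directly from the cost
# definitions (no shared code with bscea_search beyond the closed-form
# component functions it is meant to check).
brute_force_best <- function(oracle, seed, target_length, weights, p_min = 1e-9) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), target_length),
                    list(stringsAsFactors = FALSE)))
  fills <- do.call(paste0, grid[, rev(seq_len(target_length)), drop = FALSE])
  gc_frac <- function(s) {
    (nchar(s) - nchar(gsub("[GC]", "", s))) / nchar(s)
  }
  best <- NULL
  for (fill in fills) {
    seqs <- seed
    g <- 0; hsum <- 0; h <- 0
    for (k in seq_len(target_length)) {
      p <- drop(oracle(seqs))
      b <- substr(fill, k, k)
      j <- match(b, bases)
      g <- g + abs(log(max(p[[j]], p_min)))
      hsum <- hsum + -sum(ifelse(p > 0, p * log(p), 0))
      nxt <- paste0(seqs, b)
      ent <- hsum / (k * log(4))
      rem <- target_length - k
      nrl <- if (rem <= 1) 0 else log(rem) / log(target_length)
      gci <- abs(gc_frac(nxt) - gc_frac(seqs))
      h <- -weights$alpha * ent + weights$beta * nrl + weights$gamma * gci
      seqs <- nxt
    }
    f <- g + h
    cand <- list(fill = fill, f = f,
                 last = match(substr(fill, target_length, target_length), bases))
    if (is.null(best) || f < best$f - 1e-12 ||
        (abs(f - best$f) <= 1e-12 &&
         (cand$last < best$last ||
          (cand$last == best$last && fill < best$fill)))) {
      best <- cand
    }
  }
  best
}

# Textbook beam search: keep the w lowest cumulative -log p prefixes.
plain_beam_search <- function(oracle, seed, target_length, width,
                              p_min = 1e-9) {
  bases <- c("A", "C", "G", "T")
  seqs <- seed; g <- 0
  for (step in seq_len(target_length)) {
    P <- oracle(seqs)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1)
    ii <- rep(seq_along(seqs), times = 4)
    jj <- rep(1:4, each = length(seqs))
    child_g <- g[ii] + abs(log(pmax(P[cbind(ii, jj)], p_min)))
    child_seq <- paste0(seqs[ii], bases[jj])
    ord <- order(child_g, jj, child_seq, method = "radix")
    keep <- ord[seq_len(min(width, length(ord)))]
    seqs <- child_seq[keep]; g <- child_g[keep]
  }
  i <- which.min(g)
  list(sequence = seqs[[i]], g = g[[i]])
}

fill_identity <- function(fill, truth_seq) {
  mean(strsplit(fill, "")[[1]] == strsplit(truth_seq, "")[[1]])
}
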