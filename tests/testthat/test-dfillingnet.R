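tiny_config <- function(...) {
  args <- utils::modifyList(list(window_len = 8, conv_channels = 3,
                                 lstm_hidden = 2, pool_size = 2,
                                 dropout_rate = 0), list(...))
  do.call(model_config, args)
}

test_that("forward pass returns a probability simplex per example", {
  m <- build_model(tiny_config(), init_seed = 3)
  probs <- predict_probs(m, c("ACGTACGT", "GGGGCCCC", "AT"))
  expect_equal(dim(probs), c(3, 4))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_error(predict_next_probs(m, ""), "empty context")
})

test_that("inference is deterministic and dropout-free", {
  m <- build_model(tiny_config(dropout_rate = 0.5), init_seed = 3)
  p1 <- predict_next_probs(m, "ACGTAC")
  p2 <- predict_next_probs(m, "ACGTAC")
  expect_identical(p1, p2)
})

test_that("zeroing the second BiLSTM reduces the BL-Res output to the conv projection", {
  m <- build_model(tiny_config(), init_seed = 4)
  for (nm in c("l2f_W", "l2f_b", "l2b_W", "l2b_b")) {
    m$params[[nm]][] <- 0
  }
  X <- gapfillr:::.encode_batch("ACGTACGT", 8)
  fwd <- gapfillr:::.net_forward(m, X, training = FALSE)
  ch <- fwd$cache
  for (t in seq_len(ch$T)) {
    proj_t <- sweep(ch$Xs[[t]] %*% m$params$W_proj, 2, m$params$b_proj, "+")
    expect_equal(ch$Ys[[t]], proj_t, tolerance = 1e-12)
  }
})

test_that("parameter count matches the closed-form shape arithmetic", {
  cfg <- tiny_config()
  # by hand: conv 3*4*3+3 = 39; bn 2*3 = 6; proj 3*4+4 = 16;
  # lstm1 2*((3+2)*8+8) = 96; lstm2 2*((3*2)*8+8) = 112; out 4*4+4 = 20
  expect_equal(n_parameters(cfg), 39 + 6 + 16 + 96 + 112 + 20)
  m <- build_model(cfg)
  expect_equal(sum(vapply(m$params, length, 1L)), n_parameters(cfg))
})

test_that("analytic gradients match finite differences", {
  set.seed(1)
  m <- build_model(tiny_config(), init_seed = 3)
  ctxs <- c("ACGTACGT", "GGCATTAC", "TTTTACGC", "CAGCAGTA")
  y <- c(1L, 2L, 3L, 4L)
  X <- gapfillr:::.encode_batch(ctxs, 8)
  fwd <- gapfillr:::.net_forward(m, X, training = TRUE)
  gr <- gapfillr:::.net_backward(m, fwd, y)
  lossfn <- function(mm) {
    f <- gapfillr:::.net_forward(mm, X, training = TRUE)
    gapfillr:::.ce_loss(f$probs, y)
  }
  eps <- 1e-5
  for (nm in names(gr)) {
    p <- m$params[[nm]]
    for (k in sample(length(p), min(4, length(p)))) {
      m2 <- m
      m2$params[[nm]][k] <- p[k] + eps
      l1 <- lossfn(m2)
      m2$params[[nm]][k] <- p[k] - eps
      l0 <- lossfn(m2)
      num <- (l1 - l0) / (2 * eps)
      expect_equal(gr[[nm]][k], num, tolerance = 1e-3,
                   label = sprintf("d%s[%d]", nm, k))
    }
  }
})

test_that("training-set windows enumerate N-free stretches with next-base targets", {
  ts <- make_training_set(scaffold_record("g", "ACGTAC"), window_len = 4)
  expect_setequal(ts$contexts, c("ACGT", "CGTA"))
  expect_equal(ts$targets[match(c("ACGT", "CGTA"), ts$contexts)], c("A", "C"))

  expect_warning(short <- make_training_set(scaffold_record("g", "ACG"),
                                            window_len = 4), "empty")
  expect_length(short$contexts, 0)

  # N-runs split stretches; count = sum(usable - window_len)
  r <- scaffold_record("g", paste0(strrep("ACGT", 5), "NN", strrep("GGCA", 4)))
  ts <- make_training_set(r, window_len = 6, step = 1)
  expect_length(ts$contexts, (20 - 6) + (16 - 6))
  expect_false(any(grepl("N", ts$contexts)))
})

test_that("zero-epoch training returns the initialised weights unchanged", {
  m <- build_model(tiny_config(), init_seed = 9)
  ts <- make_training_set(scaffold_record("g", strrep("ACGTT", 20)),
                          window_len = 8)
  m2 <- train_model(m, ts, training_config(max_epochs = 0))
  expect_identical(m2$params, m$params)
  expect_false(is.null(m2$fingerprint))
})

test_that("training is deterministic under a fixed seed", {
  ts <- make_training_set(scaffold_record("g", strrep("ACGGTCA", 30)),
                          window_len = 8, rng_seed = 3)
  tc <- training_config(max_epochs = 2, batch_size = 32, rng_seed = 77)
  m1 <- train_model(build_model(tiny_config(), init_seed = 5), ts, tc)
  m2 <- train_model(build_model(tiny_config(), init_seed = 5), ts, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$fingerprint, m2$fingerprint)
})

test_that("model files round-trip bit-identically and validate on load", {
  m <- periodic_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  ctxs <- periodic_training_set()$contexts[1:100]
  expect_identical(predict_probs(m2, ctxs), predict_probs(m, ctxs))

  # tampered channel order is refused
  obj <- readRDS(f)
  obj$config$channel_order <- "TGCA"
  saveRDS(obj, f)
  expect_error(load_model(f), "channel order")

  # missing config field is named
  obj$config$channel_order <- "ACGT"
  obj$config$window_len <- NULL
  saveRDS(obj, f)
  expect_error(load_model(f), "window_len")

  saveRDS(list(a = 1), f)
  expect_error(load_model(f), "not a gapfillr model")
})

test_that("a window spanning the motif period learns the periodic genome", {
  acc <- next_base_accuracy(periodic_model(), periodic_training_set())
  expect_gte(acc, 0.99)
})

test_that("a window shorter than the period cannot beat the motif's frequency ceiling", {
  g <- periodic_genome()
  motif <- substr(g$sequence, 1, 21)
  w <- 8
  # closed-form ceiling: per phase, the length-w context determines a set of
  # possible next bases; best achievable accuracy is the modal frequency
  ctxs <- vapply(1:21, function(ph) {
    s <- substr(strrep(motif, 3), ph, ph + w - 1)
    s
  }, character(1))
  nxt <- vapply(1:21, function(ph) substr(strrep(motif, 3), ph + w, ph + w),
                character(1))
  ceiling_acc <- mean(vapply(seq_along(ctxs), function(i) {
    same <- nxt[ctxs == ctxs[[i]]]
    max(table(same)) / length(same)
  }, numeric(1)))
  cfg <- model_config(window_len = w, conv_channels = 8, lstm_hidden = 8,
                      pool_size = 2, dropout_rate = 0)
  ts <- make_training_set(g, window_len = w, step = 1, rng_seed = 2)
  tc <- training_config(learning_rate = 3e-3, batch_size = 256,
                        max_epochs = 4, early_stop_patience = 2,
                        rng_seed = 21)
  m <- train_model(build_model(cfg, init_seed = 6), ts, tc)
  acc <- next_base_accuracy(m, ts)
  expect_lte(acc, ceiling_acc + 0.02)
})
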