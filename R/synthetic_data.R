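# Seeded synthetic genomes, gapped scaffolds with truth tables, and Markov
# probability oracles. Everything here is bit-deterministic under its seed
# (the caller's RNG state is saved and restored).

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Specify a synthetic genome
#'
#' The genome is a concatenation of blocks: *unique* blocks of i.i.d. bases
#' with `P(G) = P(C) = gc_content/2`, and *repeat* blocks that are tandem
#' copies of a single seeded random motif (the motif phase runs continuously
#' across adjacent repeat blocks, so `repeat_fraction = 1` yields an exactly
#' periodic genome).
#'
#' @param length genome length in bases (>= 1000).
#' @param gc_content target GC fraction in (0,1).
#' @param repeat_motif_len motif length for repeat blocks.
#' @param repeat_fraction expected fraction of the genome in repeat blocks.
#' @param rng_seed integer seed.
#' @param block_len nominal block size in bases.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(length, gc_content = 0.45, repeat_motif_len = 21L,
                        repeat_fraction = 0.5, rng_seed = 1L,
                        block_len = 2000L) {
  stopifnot(length >= 1000L, gc_content > 0, gc_content < 1,
            repeat_motif_len >= 1L, repeat_fraction >= 0, repeat_fraction <= 1,
            block_len >= repeat_motif_len)
  structure(list(length = as.integer(length), gc_content = gc_content,
                 repeat_motif_len = as.integer(repeat_motif_len),
                 repeat_fraction = repeat_fraction,
                 rng_seed = as.integer(rng_seed),
                 block_len = as.integer(block_len)),
            class = "genome_spec")
}

.sample_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic genome
#'
#' @param spec a [genome_spec()].
#' @return a [scaffold_record()] (id `"synthetic_genome"`) carrying the block
#'   map as `attr(, "blocks")` (data.frame of 0-based half-open `start`,
#'   `end`, `type` in `{"unique","repeat"}`) and the spec as
#'   `attr(, "spec")`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  .with_seed(spec$rng_seed, {
    # motif composition pinned to the target GC (rounded), so repeat blocks
    # do not drag the genome-wide GC off specification
    k <- round(spec$gc_content * spec$repeat_motif_len)
    motif <- paste(sample(c(sample(c("G", "C"), k, replace = TRUE),
                            sample(c("A", "T"), spec$repeat_motif_len - k,
                                   replace = TRUE))), collapse = "")
    n_blocks <- ceiling(spec$length / spec$block_len)
    types <- ifelse(stats::runif(n_blocks) < spec$repeat_fraction,
                    "repeat", "unique")
    if (spec$repeat_fraction >= 1) types[] <- "repeat"
    if (spec$repeat_fraction <= 0) types[] <- "unique"
    sizes <- rep(spec$block_len, n_blocks)
    sizes[n_blocks] <- spec$length - (n_blocks - 1L) * spec$block_len
    pieces <- character(n_blocks)
    i <- 1L
    while (i <= n_blocks) {
      if (types[[i]] == "repeat") {
        # extend phase continuously across adjacent repeat blocks
        j <- i
        while (j < n_blocks && types[[j + 1L]] == "repeat") j <- j + 1L
        run_len <- sum(sizes[i:j])
        tandem <- substr(strrep(motif, ceiling(run_len / nchar(motif))), 1L, run_len)
        off <- 0L
        for (k in i:j) {
          pieces[[k]] <- substr(tandem, off + 1L, off + sizes[[k]])
          off <- off + sizes[[k]]
        }
        i <- j + 1L
      } else {
        pieces[[i]] <- .sample_bases(sizes[[i]], spec$gc_content)
        i <- i + 1L
      }
    }
    ends <- cumsum(sizes)
    blocks <- data.frame(start = c(0L, ends[-n_blocks]), end = ends,
                         type = types, stringsAsFactors = FALSE)
    g <- scaffold_record("synthetic_genome", paste(pieces, collapse = ""))
    attr(g, "blocks") <- blocks
    attr(g, "spec") <- spec
    g
  })
}

#' Mask random intervals of a genome with N-runs
#'
#' Places `n_gaps` non-overlapping intervals, each at least `min_spacing`
#' bases from its neighbours and `edge_margin` bases from the scaffold ends,
#' replaces them with `N`, and records the masked bases in a truth table.
#' When the genome carries a block map (from [generate_genome()]) and
#' `block_types` is given, gap *i* is placed wholly inside a block of
#' `block_types[i]`, at least `block_margin` bases from the block edges.
#'
#' @param genome a [scaffold_record()] (optionally with a block map).
#' @param n_gaps number of gaps.
#' @param gap_len_range integer `c(min, max)` gap lengths.
#' @param min_spacing minimum distance between gaps.
#' @param rng_seed integer seed.
#' @param edge_margin keep-out zone at the scaffold ends (guarantees full
#'   flanks for the predictor).
#' @param block_types optional character vector recycled to `n_gaps`
#'   (`"repeat"` / `"unique"`); requires a block map.
#' @param block_margin distance kept from block boundaries when targeting
#'   block types.
#' @param max_tries placement attempts before giving up.
#' @return list with `$scaffold` (gapped [scaffold_record()]) and `$truth`
#'   (data.frame `scaffold_id`, `start`, `end`, `truth_seq`, `block_type`).
#' @export
introduce_gaps <- function(genome, n_gaps, gap_len_range = c(20L, 100L),
                           min_spacing = 200L, rng_seed = 1L,
                           edge_margin = 500L, block_types = NULL,
                           block_margin = 150L, max_tries = 20000L) {
  stopifnot(inherits(genome, "scaffold_record"), n_gaps >= 1L,
            length(gap_len_range) == 2L, gap_len_range[[1L]] >= 1L,
            gap_len_range[[2L]] >= gap_len_range[[1L]])
  blocks <- attr(genome, "blocks")
  if (!is.null(block_types)) {
    if (is.null(blocks)) stop("block_types given but genome has no block map",
                              call. = FALSE)
    block_types <- rep_len(block_types, n_gaps)
  }
  n <- nchar(genome$sequence)
  .with_seed(rng_seed, {
    placed_s <- integer(0); placed_e <- integer(0); placed_type <- character(0)
    tries <- 0L
    while (length(placed_s) < n_gaps) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf("could not place %d gaps after %d tries; relax spacing",
                     n_gaps, max_tries), call. = FALSE)
      }
      i <- length(placed_s) + 1L
      lens <- gap_len_range[[1L]]:gap_len_range[[2L]]
      len <- lens[[sample.int(length(lens), 1L)]]
      if (!is.null(block_types)) {
        want <- block_types[[i]]
        cand <- blocks[blocks$type == want &
                         (blocks$end - blocks$start) >= len + 2L * block_margin, ,
                       drop = FALSE]
        if (nrow(cand) == 0L) {
          stop(sprintf("no '%s' block can hold a %d bp gap", want, len),
               call. = FALSE)
        }
        b <- cand[sample.int(nrow(cand), 1L), ]
        lo <- b$start + block_margin
        hi <- b$end - block_margin - len
      } else {
        lo <- edge_margin
        hi <- n - edge_margin - len
      }
      if (hi < lo) next
      s <- lo + sample.int(hi - lo + 1L, 1L) - 1L   # 0-based start
      e <- s + len
      if (s < edge_margin || e > n - edge_margin) next
      if (length(placed_s) &&
          any(pmax(placed_s, s) - pmin(placed_e, e) < min_spacing)) next
      placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
      placed_type <- c(placed_type,
                       if (is.null(block_types)) .block_type_at(blocks, s, e)
                       else block_types[[i]])
    }
    ord <- order(placed_s)
    placed_s <- placed_s[ord]; placed_e <- placed_e[ord]
    placed_type <- placed_type[ord]
    seq <- genome$sequence
    truth <- substring(seq, placed_s + 1L, placed_e)
    for (i in seq_along(placed_s)) {
      substr(seq, placed_s[[i]] + 1L, placed_e[[i]]) <-
        strrep("N", placed_e[[i]] - placed_s[[i]])
    }
    sc <- scaffold_record(genome$id, seq)
    attr(sc, "blocks") <- blocks
    list(scaffold = sc,
         truth = data.frame(scaffold_id = genome$id, start = placed_s,
                            end = placed_e, truth_seq = truth,
                            block_type = placed_type,
                            stringsAsFactors = FALSE))
  })
}

.block_type_at <- function(blocks, s, e) {
  if (is.null(blocks)) return(NA_character_)
  hit <- blocks$start <= s & blocks$end >= e
  if (any(hit)) blocks$type[[which(hit)[[1L]]]] else "mixed"
}

#' Write a truth table as TSV
#'
#' First three columns are BED-compatible (`scaffold_id`, `start`, `end`,
#' 0-based half-open), followed by the masked sequence and block type.
#'
#' @param truth data.frame from [introduce_gaps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' A seeded random Markov next-base oracle
#'
#' Builds a transition table over all `4^order` contexts with Dirichlet(1)
#' rows and returns a vectorised oracle: a function mapping a character
#' vector of contexts to a matrix of next-base probabilities (columns in
#' channel order A,C,G,T). Contexts use their last `order` bases and are
#' left-padded with `A` when shorter. Stands in for a trained model in
#' search tests, where completions can be enumerated exhaustively.
#'
#' @param order Markov order (>= 0).
#' @param rng_seed integer seed.
#' @return a function `character vector -> matrix (n x 4)`, with the
#'   transition table attached as `attr(, "table")`.
#' @export
markov_oracle <- function(order, rng_seed = 1L) {
  stopifnot(order >= 0L)
  order <- as.integer(order)
  n_ctx <- 4L^order
  tab <- .with_seed(rng_seed, {
    m <- matrix(stats::rgamma(n_ctx * 4L, shape = 1), nrow = n_ctx)
    m / rowSums(m)
  })
  colnames(tab) <- CHANNEL_ORDER
  ctx_names <- if (order == 0L) "" else {
    grid <- do.call(expand.grid, rep(list(CHANNEL_ORDER), order))
    # first factor varies fastest; reverse so names read left-to-right
    apply(grid[, rev(seq_len(order)), drop = FALSE], 1L, paste, collapse = "")
  }
  rownames(tab) <- ctx_names
  f <- function(contexts) {
    stopifnot(is.character(contexts))
    if (order == 0L) {
      out <- tab[rep(1L, length(contexts)), , drop = FALSE]
      rownames(out) <- NULL
      return(out)
    }
    key <- vapply(contexts, function(s) {
      if (nchar(s) >= order) substr(s, nchar(s) - order + 1L, nchar(s))
      else paste0(strrep("A", order - nchar(s)), s)
    }, character(1), USE.NAMES = FALSE)
    idx <- match(key, ctx_names)
    if (anyNA(idx)) stop("oracle context outside {A,C,G,T}: ",
                         key[which(is.na(idx))[1L]], call. = FALSE)
    out <- tab[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  attr(f, "table") <- tab
  attr(f, "order") <- order
  f
}
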