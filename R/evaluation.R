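# Assembly-quality metrics: fill counts/rates, N's per 100 kb, truth-based
# mismatches per 100 kb, and GC profiles.

.count_n <- function(seq) nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))

.as_record_list <- function(x) {
  if (inherits(x, "scaffold_record")) list(x) else x
}

#' Gap filling rate
#'
#' `100 * gaps_filled / gaps_total`, reported to two decimals. `NA` when no
#' gaps were detected.
#'
#' @param gaps_filled,gaps_total counts.
#' @return percentage.
#' @export
#' @examples
#' fill_rate(73, 141)  # 51.77
fill_rate <- function(gaps_filled, gaps_total) {
  stopifnot(gaps_filled >= 0, gaps_filled <= gaps_total)
  if (gaps_total == 0) return(NA_real_)
  round(100 * gaps_filled / gaps_total, 2)
}

#' Undetermined bases per 100 kb
#' @param x a [scaffold_record()] or list of them.
#' @return total N count / total length * 100000.
#' @export
ns_per_100kb <- function(x) {
  recs <- .as_record_list(x)
  stopifnot(length(recs) >= 1L)
  n <- sum(vapply(recs, function(r) .count_n(r$sequence), numeric(1)))
  len <- sum(vapply(recs, function(r) nchar(r$sequence), numeric(1)))
  n / len * 1e5
}

#' Truth-based mismatches per 100 kb
#'
#' For length-matched pairs (the simulator's coordinate bookkeeping),
#' mismatches are counted positionally over positions where the assembly is
#' not `N`, divided by the full length. Otherwise the pair is globally
#' aligned with the filter module's aligner and mismatches are counted over
#' aligned non-N columns, divided by the alignment length.
#'
#' @param assembly,truth [scaffold_record()]s.
#' @return mismatches per 100 kb.
#' @export
mismatches_per_100kb <- function(assembly, truth) {
  a <- assembly$sequence; t_ <- truth$sequence
  if (nchar(a) == nchar(t_)) {
    av <- utf8ToInt(a); tv <- utf8ToInt(t_)
    nn <- utf8ToInt("N")
    mism <- sum(av != tv & av != nn & tv != nn)
    return(mism / nchar(a) * 1e5)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = t_, type = "global",
    substitutionMatrix = .gapfillr_submat(), gapOpening = 2, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  aligned <- pa != "-" & sa != "-"
  mism <- sum(aligned & pa != sa & pa != "N" & sa != "N")
  mism / length(pa) * 1e5
}

#' GC profile over fixed windows
#'
#' GC fraction per non-overlapping window (windows containing any `N` are
#' excluded), a histogram of window GC binned at 1% resolution, and the
#' global GC percentage over non-N bases.
#'
#' @param record a [scaffold_record()].
#' @param window window size in bases (>= 100).
#' @return list `$window_gc` (fractions), `$histogram` (named counts per 1%
#'   bin), `$global_gc_percent`, `$windows_used`, `$windows_total`.
#' @export
gc_profile <- function(record, window = 1000L) {
  stopifnot(inherits(record, "scaffold_record"), window >= 100L)
  seq <- record$sequence
  n <- nchar(seq)
  n_win <- n %/% window
  starts <- (seq_len(n_win) - 1L) * window + 1L
  subs <- substring(seq, starts, starts + window - 1L)
  has_n <- grepl("N", subs, fixed = TRUE)
  gc <- function(s) (nchar(s) - nchar(gsub("[GC]", "", s))) / nchar(s)
  wgc <- vapply(subs[!has_n], gc, numeric(1), USE.NAMES = FALSE)
  bins <- cut(wgc * 100, breaks = seq(0, 100, by = 1), include.lowest = TRUE,
              right = FALSE)
  den <- gsub("N", "", seq, fixed = TRUE)
  list(window_gc = wgc,
       histogram = table(bins),
       global_gc_percent = 100 * gc(den),
       windows_used = sum(!has_n), windows_total = n_win)
}

#' Before/after metrics for a gap-filling run
#'
#' A gap counts as *filled* when its interval in the `after` scaffold
#' contains no `N`; partially cleared gaps are reported separately. Requires
#' length-preserving patching (fills of exactly the gap length), so gap
#' coordinates remain valid on both scaffold sets.
#'
#' @param before,after id-matched [scaffold_record()]s or lists of them.
#' @param gaps [detect_gaps()] data.frame on the `before` scaffolds.
#' @param truth optional truth [scaffold_record()] list for mismatch
#'   metrics.
#' @return list `$before`, `$after` (metric lists), `$delta`, and
#'   `$per_gap` (data.frame with `filled` / `partial` flags).
#' @export
evaluate_run <- function(before, after, gaps, truth = NULL) {
  bl <- .as_record_list(before); al <- .as_record_list(after)
  bid <- vapply(bl, function(r) r$id, character(1))
  aid <- vapply(al, function(r) r$id, character(1))
  if (!identical(sort(bid), sort(aid))) {
    stop("before/after scaffold ids do not match", call. = FALSE)
  }
  al <- al[match(bid, aid)]
  for (i in seq_along(bl)) {
    if (nchar(bl[[i]]$sequence) != nchar(al[[i]]$sequence)) {
      stop("scaffold '", bid[[i]], "' changed length; evaluate_run needs ",
           "length-preserving patching", call. = FALSE)
    }
  }
  if (!is.null(truth)) truth <- .as_record_list(truth)
  n_total <- nrow(gaps)
  filled <- logical(n_total); partial <- logical(n_total)
  for (i in seq_len(n_total)) {
    rec <- al[[match(gaps$scaffold_id[[i]], bid)]]
    region <- substr(rec$sequence, gaps$start[[i]] + 1L, gaps$end[[i]])
    nn <- .count_n(region)
    filled[[i]] <- nn == 0L
    partial[[i]] <- nn > 0L && nn < nchar(region)
  }
  metrics <- function(recs) {
    m <- list(gaps_total = n_total, n_count = sum(vapply(
      recs, function(r) .count_n(r$sequence), numeric(1))),
      ns_per_100kb = ns_per_100kb(recs),
      gc_percent = gc_profile(recs[[1L]], window = 100L)$global_gc_percent)
    if (!is.null(truth)) {
      tid <- vapply(truth, function(r) r$id, character(1))
      m$mismatches_per_100kb <- mean(vapply(seq_along(recs), function(i) {
        mismatches_per_100kb(recs[[i]], truth[[match(bid[[i]], tid)]])
      }, numeric(1)))
    }
    m
  }
  mb <- metrics(bl); ma <- metrics(al)
  mb$gaps_filled <- 0L; mb$fill_rate <- fill_rate(0L, n_total)
  ma$gaps_filled <- sum(filled); ma$fill_rate <- fill_rate(sum(filled), n_total)
  delta <- list(gaps_filled = ma$gaps_filled,
                gaps_partial = sum(partial),
                n_count = ma$n_count - mb$n_count,
                ns_per_100kb = ma$ns_per_100kb - mb$ns_per_100kb)
  list(before = mb, after = ma, delta = delta,
       per_gap = data.frame(gap_id = gaps$gap_id, filled = filled,
                            partial = partial, stringsAsFactors = FALSE))
}

#' Write an evaluation as TSV
#' @param ev an [evaluate_run()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(ev, path) {
  keys <- union(names(ev$before), names(ev$after))
  df <- data.frame(
    metric = keys,
    before = vapply(keys, function(k) as.numeric(ev$before[[k]] %||% NA),
                    numeric(1)),
    after = vapply(keys, function(k) as.numeric(ev$after[[k]] %||% NA),
                   numeric(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
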