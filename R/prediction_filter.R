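# PredictionFilter: score candidate fills by local alignment against a
# homologous (or simulator-truth) region, compare with the unfilled N-run
# baseline, and partition candidates into Available / Disposable.

.gapfillr_submat <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch   # N never counts as a match, even against N
  m
}

#' Align a candidate fill against a homologous region
#'
#' Best local alignment under unit match/mismatch scoring with affine gaps
#' (defaults +1 / -1, gap open -2, gap extend -1). The alignment rate is
#' identical aligned bases divided by the candidate length, so 1 means the
#' candidate matches a substring of the homolog exactly over its full length.
#'
#' @param candidate nucleotide string (may contain `N`; `N` never matches).
#' @param homolog_region nucleotide string spanning the gap plus margin.
#' @param match,mismatch,gap_open,gap_extend scoring parameters (penalties
#'   given as positive numbers).
#' @return list with `rate`, `matches`, `edit_distance` (mismatches plus
#'   indel bases within the aligned span), `aligned_span` (`c(start, end)`
#'   on the homolog, 1-based), `score`.
#' @export
align_candidate <- function(candidate, homolog_region, match = 1,
                            mismatch = -1, gap_open = 2, gap_extend = 1) {
  stopifnot(nzchar(candidate), nzchar(homolog_region))
  aln <- Biostrings::pairwiseAlignment(
    pattern = candidate, subject = homolog_region, type = "local",
    substitutionMatrix = .gapfillr_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  matches <- Biostrings::nmatch(aln)
  # nmatch() counts positions scored as matches; N/N pairs score as
  # mismatches in our matrix but compare equal as characters -- exclude them.
  if (grepl("N", candidate, fixed = TRUE)) {
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    matches <- sum(pa == sa & pa != "N" & pa != "-")
  }
  nmis <- Biostrings::nmismatch(aln)
  indel_bases <- sum(Biostrings::nindel(aln)@insertion[, "WidthSum"],
                     Biostrings::nindel(aln)@deletion[, "WidthSum"])
  span <- c(Biostrings::start(Biostrings::subject(aln)),
            Biostrings::end(Biostrings::subject(aln)))
  rate <- matches / nchar(candidate)
  list(rate = min(max(rate, 0), 1), matches = matches,
       edit_distance = nmis + indel_bases,
       aligned_span = span, score = Biostrings::score(aln))
}

# frame a fill with flank margins so candidate and baseline rates are
# computed over sequences of identical length
.framed <- function(gap, inner, margin) {
  lf <- gap$left_flank; rf <- gap$right_flank
  lm <- substr(lf, max(1L, nchar(lf) - margin + 1L), nchar(lf))
  rm_ <- substr(rf, 1L, min(margin, nchar(rf)))
  paste0(lm, inner, rm_)
}

#' Partition candidate fills into Available and Disposable
#'
#' Each candidate is framed with up to `frame_margin` flank bases per side
#' and locally aligned against its gap's homolog region; the unfilled
#' baseline (the same frame around the original N-run) is aligned the same
#' way. A candidate is *available* iff its rate reaches `tau` **and**
#' exceeds the baseline rate; everything else is *disposable*.
#'
#' @param candidates data.frame with columns `gap_id`, `candidate_id`,
#'   `fill`.
#' @param gaps the [detect_gaps()] data.frame the candidates refer to.
#' @param homolog_provider function `gap_id -> region string` (or `NA` when
#'   no homolog exists); see [truth_homolog_provider()].
#' @param tau availability threshold on the framed alignment rate.
#' @param frame_margin flank bases included per side in the framed rate.
#' @param strict error (listing gap ids) instead of labelling candidates
#'   without a homolog disposable.
#' @return list with `$available`, `$disposable` (row subsets of
#'   `candidates`) and `$verdicts` (one row per candidate: rates, baseline,
#'   label).
#' @export
filter_predictions <- function(candidates, gaps, homolog_provider, tau = 0.9,
                               frame_margin = 50L, strict = FALSE) {
  stopifnot(is.data.frame(candidates),
            all(c("gap_id", "candidate_id", "fill") %in% names(candidates)))
  n <- nrow(candidates)
  verdicts <- data.frame(gap_id = candidates$gap_id,
                         candidate_id = candidates$candidate_id,
                         rate = NA_real_, baseline_rate = NA_real_,
                         edit_distance = NA_integer_,
                         label = "disposable", stringsAsFactors = FALSE)
  missing_ids <- character(0)
  baseline_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    gid <- candidates$gap_id[[i]]
    gap <- gaps[gaps$gap_id == gid, , drop = FALSE]
    if (nrow(gap) != 1L) stop("candidate refers to unknown gap ", gid,
                              call. = FALSE)
    gap <- as.list(gap[1L, ])
    region <- homolog_provider(gid)
    if (is.null(region) || (length(region) == 1L && is.na(region))) {
      missing_ids <- c(missing_ids, gid)
      next
    }
    framed <- .framed(gap, candidates$fill[[i]], frame_margin)
    rep_ <- align_candidate(framed, region)
    base_rate <- if (exists(gid, envir = baseline_cache)) {
      get(gid, envir = baseline_cache)
    } else {
      baseline <- .framed(gap, strrep("N", gap$end - gap$start), frame_margin)
      br <- align_candidate(baseline, region)$rate
      assign(gid, br, envir = baseline_cache)
      br
    }
    verdicts$rate[[i]] <- rep_$rate
    verdicts$baseline_rate[[i]] <- base_rate
    verdicts$edit_distance[[i]] <- rep_$edit_distance
    if (rep_$rate >= tau && rep_$rate > base_rate) {
      verdicts$label[[i]] <- "available"
    }
  }
  if (strict && length(missing_ids)) {
    stop("no homolog region for gap(s): ",
         paste(unique(missing_ids), collapse = ", "), call. = FALSE)
  }
  keep <- verdicts$label == "available"
  list(available = candidates[keep, , drop = FALSE],
       disposable = candidates[!keep, , drop = FALSE],
       verdicts = verdicts)
}

#' Homolog provider backed by a simulator truth genome
#'
#' Returns the truth sequence spanning each gap plus `margin` bases per
#' side — the simulator's stand-in for the homologous-region lookup.
#'
#' @param truth_genome ungapped truth [scaffold_record()].
#' @param gaps [detect_gaps()] data.frame (coordinates valid on the truth).
#' @param margin extra truth bases per side.
#' @return function `gap_id -> region string` for [filter_predictions()].
#' @export
truth_homolog_provider <- function(truth_genome, gaps, margin = 100L) {
  force(truth_genome); force(gaps); force(margin)
  function(gap_id) {
    gap <- gaps[gaps$gap_id == gap_id, , drop = FALSE]
    if (nrow(gap) != 1L) return(NA_character_)
    lo <- max(0L, gap$start[[1L]] - margin)
    hi <- min(nchar(truth_genome$sequence), gap$end[[1L]] + margin)
    substr(truth_genome$sequence, lo + 1L, hi)
  }
}

#' Homolog provider backed by a FASTA of regions keyed by gap id
#' @param path FASTA whose record ids are gap ids.
#' @return function `gap_id -> region string` for [filter_predictions()].
#' @export
fasta_homolog_provider <- function(path) {
  recs <- read_fasta(path)
  ids <- vapply(recs, function(r) r$id, character(1))
  function(gap_id) {
    i <- match(gap_id, ids)
    if (is.na(i)) NA_character_ else recs[[i]]$sequence
  }
}

#' Contrast an unfiltered and a filtered patched scaffold against truth
#'
#' Desk-scale realisation of the Assembly-1 (all predictions applied) versus
#' Assembly-2 (available predictions only) comparison: both patched
#' scaffolds are scored with the evaluation metrics against the truth
#' genome.
#'
#' @param unfiltered_patch,filtered_patch patched [scaffold_record()]s.
#' @param truth truth [scaffold_record()].
#' @return list `$unfiltered`, `$filtered` (each with `n_count`,
#'   `ns_per_100kb`, `mismatches_per_100kb`), plus
#'   `$mismatch_reduction_per_100kb`.
#' @export
compare_assemblies <- function(unfiltered_patch, filtered_patch, truth) {
  score <- function(rec) {
    list(n_count = .count_n(rec$sequence),
         ns_per_100kb = ns_per_100kb(rec),
         mismatches_per_100kb = mismatches_per_100kb(rec, truth))
  }
  u <- score(unfiltered_patch); f <- score(filtered_patch)
  list(unfiltered = u, filtered = f,
       mismatch_reduction_per_100kb =
         u$mismatches_per_100kb - f$mismatches_per_100kb)
}
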