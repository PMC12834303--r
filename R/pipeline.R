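# End-to-end orchestration: detect -> classify -> predict (search) ->
# filter -> patch -> evaluate, with a manifest that records every resolved
# parameter so a run is reproducible bit-for-bit.

#' Assemble a pipeline run configuration
#'
#' Any argument left `NULL` keeps its built-in default; the fully resolved
#' set is echoed into the run manifest.
#'
#' @param scaffold path to the gapped scaffold FASTA, or a list of
#'   [scaffold_record()]s.
#' @param model path to a saved model, a `dfillingnet`, or an oracle
#'   function.
#' @param out_dir output directory (created if absent).
#' @param truth optional truth genome (path or [scaffold_record()]) used as
#'   the homolog provider and for truth-based metrics.
#' @param homolog_fasta optional FASTA of homolog regions keyed by gap id
#'   (used when no truth is given).
#' @param flank_len,min_gap_len gap detection parameters.
#' @param min_flank shortest usable flank for prediction.
#' @param weights a [heuristic_weights()].
#' @param schedule a [beam_schedule()].
#' @param tau availability threshold of the prediction filter.
#' @param frame_margin flank margin used by the filter's framed rates.
#' @param mode fill direction: `"bidirectional"`, `"left"` or `"right"`.
#' @param fixed_gap_list gap ids routed away from the prediction path.
#' @param rng_seed run seed (echoed to the manifest; prediction itself is
#'   deterministic).
#' @param apply_filter apply the prediction filter before patching (`FALSE`
#'   patches every candidate — the unfiltered contrast).
#' @return a `run_config` list.
#' @export
run_config <- function(scaffold, model, out_dir, truth = NULL,
                       homolog_fasta = NULL, flank_len = 500L,
                       min_gap_len = 1L, min_flank = 50L,
                       weights = heuristic_weights(),
                       schedule = beam_schedule(), tau = 0.9,
                       frame_margin = 50L,
                       mode = c("bidirectional", "left", "right"),
                       fixed_gap_list = character(), rng_seed = 1L,
                       apply_filter = TRUE) {
  mode <- match.arg(mode)
  structure(list(scaffold = scaffold, model = model, out_dir = out_dir,
                 truth = truth, homolog_fasta = homolog_fasta,
                 flank_len = as.integer(flank_len),
                 min_gap_len = as.integer(min_gap_len),
                 min_flank = as.integer(min_flank), weights = weights,
                 schedule = schedule, tau = tau,
                 frame_margin = as.integer(frame_margin), mode = mode,
                 fixed_gap_list = fixed_gap_list,
                 rng_seed = as.integer(rng_seed),
                 apply_filter = isTRUE(apply_filter)),
            class = "run_config")
}

#' Route gaps between the fixed and prediction paths
#'
#' Gaps named in `fixed_gap_list` get status `"fixed"` (left to external
#' tools); all others become `"unfixed"` and enter the prediction path.
#'
#' @param gaps [detect_gaps()] data.frame.
#' @param fixed_gap_list character vector of gap ids (duplicates are
#'   dropped with a warning; unknown ids are an error).
#' @return `gaps` with `status` set.
#' @export
classify_gaps <- function(gaps, fixed_gap_list = character()) {
  stopifnot(is.data.frame(gaps))
  if (anyDuplicated(fixed_gap_list)) {
    warning("duplicate ids in fixed_gap_list; deduplicated")
    fixed_gap_list <- unique(fixed_gap_list)
  }
  unknown <- setdiff(fixed_gap_list, gaps$gap_id)
  if (length(unknown)) {
    stop("fixed_gap_list names unknown gap(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gaps$status <- ifelse(gaps$gap_id %in% fixed_gap_list, "fixed", "unfixed")
  gaps
}

.load_scaffolds <- function(x) {
  if (is.character(x)) read_fasta(x)
  else if (inherits(x, "scaffold_record")) list(x)
  else x
}

.load_pipeline_model <- function(x) {
  if (is.function(x)) x
  else if (inherits(x, "dfillingnet")) model_oracle(x)
  else if (is.character(x)) model_oracle(load_model(x))
  else stop("model must be a path, dfillingnet or oracle function",
            call. = FALSE)
}

#' Run the full gap-filling pipeline
#'
#' Detects gaps, classifies them, predicts a fill for every unfixed gap with
#' a usable flank, filters the candidates against the homolog/truth regions,
#' patches the accepted fills and evaluates before vs after. Writes
#' `patched.fasta`, `gaps.bed`, `candidates.tsv`, `verdicts.tsv`,
#' `metrics.tsv` and `manifest.yaml` under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-gap progress messages.
#' @return (invisibly) list with `$scaffolds` (patched), `$gaps`,
#'   `$candidates`, `$verdicts`, `$evaluation`, `$manifest`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)
  scaffolds <- .load_scaffolds(config$scaffold)
  oracle <- .load_pipeline_model(config$model)
  truth <- if (!is.null(config$truth)) .load_scaffolds(config$truth) else NULL

  gaps <- do.call(rbind, lapply(scaffolds, detect_gaps,
                                min_gap_len = config$min_gap_len,
                                flank_len = config$flank_len))
  if (is.null(gaps)) gaps <- detect_gaps(scaffolds[[1L]])[0L, ]
  gaps <- classify_gaps(gaps, config$fixed_gap_list)

  candidates <- data.frame(gap_id = character(), candidate_id = character(),
                           fill = character(), direction = character(),
                           f = numeric(), stringsAsFactors = FALSE)
  todo <- gaps[gaps$status == "unfixed", , drop = FALSE]
  for (i in seq_len(nrow(todo))) {
    gap <- todo[i, ]
    res <- withCallingHandlers(
      fill_gap(oracle, gap, weights = config$weights,
               schedule = config$schedule, mode = config$mode,
               min_flank = config$min_flank),
      warning = function(w) {
        if (!quiet) message(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (is.null(res)) next
    if (!quiet) {
      message(sprintf("gap %s: direction %s, f = %.3f", gap$gap_id,
                      res$direction, res$f))
    }
    candidates <- rbind(candidates, data.frame(
      gap_id = gap$gap_id, candidate_id = paste0(gap$gap_id, "/1"),
      fill = res$fill, direction = res$direction, f = res$f,
      stringsAsFactors = FALSE))
  }

  provider <- if (!is.null(truth)) {
    truth_homolog_provider(truth[[1L]], gaps, margin = config$frame_margin + 50L)
  } else if (!is.null(config$homolog_fasta)) {
    fasta_homolog_provider(config$homolog_fasta)
  } else NULL

  if (config$apply_filter && !is.null(provider) && nrow(candidates) > 0L) {
    flt <- filter_predictions(candidates, gaps, provider, tau = config$tau,
                              frame_margin = config$frame_margin)
    accepted <- flt$available
    verdicts <- flt$verdicts
  } else {
    accepted <- candidates
    verdicts <- if (nrow(candidates)) {
      data.frame(gap_id = candidates$gap_id,
                 candidate_id = candidates$candidate_id,
                 rate = NA_real_, baseline_rate = NA_real_,
                 edit_distance = NA_integer_, label = "available",
                 stringsAsFactors = FALSE)
    } else NULL
  }

  patched <- scaffolds
  ids <- vapply(patched, function(r) r$id, character(1))
  for (i in seq_len(nrow(accepted))) {
    gap <- gaps[gaps$gap_id == accepted$gap_id[[i]], ][1L, ]
    j <- match(gap$scaffold_id, ids)
    patched[[j]] <- patch_scaffold(patched[[j]], gap, accepted$fill[[i]])
  }

  evaluation <- evaluate_run(scaffolds, patched, gaps, truth = truth)

  write_fasta(patched, file.path(config$out_dir, "patched.fasta"))
  write_gap_bed(gaps, file.path(config$out_dir, "gaps.bed"))
  utils::write.table(candidates, file.path(config$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(verdicts)) {
    utils::write.table(verdicts, file.path(config$out_dir, "verdicts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_metrics_tsv(evaluation, file.path(config$out_dir, "metrics.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gapfillr")),
    rng_seed = config$rng_seed, flank_len = config$flank_len,
    min_gap_len = config$min_gap_len, min_flank = config$min_flank,
    weights = unclass(config$weights),
    schedule = unclass(config$schedule), tau = config$tau,
    frame_margin = config$frame_margin, mode = config$mode,
    apply_filter = config$apply_filter,
    fixed_gap_list = as.list(config$fixed_gap_list),
    n_gaps = nrow(gaps), n_candidates = nrow(candidates),
    n_accepted = nrow(accepted))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(scaffolds = patched, gaps = gaps, candidates = candidates,
                 verdicts = verdicts, evaluation = evaluation,
                 manifest = manifest))
}
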