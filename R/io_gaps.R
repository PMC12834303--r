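# Scaffold / gap IO: FASTA in/out, N-run detection, flank extraction,
# patching, BED inventories. Coordinates are 0-based half-open throughout
# (BED convention); R's 1-based substr() is confined to this file's internals.

#' Construct a scaffold record
#'
#' A scaffold record is a named nucleotide sequence over `{A,C,G,T,N}`,
#' the unit all other modules operate on.
#'
#' @param id character identifier.
#' @param sequence nucleotide string (uppercase `A,C,G,T,N`).
#' @return an object of class `scaffold_record` (a list with `$id`,
#'   `$sequence`).
#' @export
scaffold_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("scaffold sequence must be non-empty", call. = FALSE)
  .check_alphabet(sequence, what = sprintf("scaffold '%s'", id))
  structure(list(id = id, sequence = sequence), class = "scaffold_record")
}

#' @export
print.scaffold_record <- function(x, ...) {
  n <- nchar(x$sequence)
  nn <- n - nchar(gsub("N", "", x$sequence, fixed = TRUE))
  cat(sprintf("<scaffold_record> %s: %d bp, %d N (%.2f%%)\n",
              x$id, n, nn, 100 * nn / n))
  invisible(x)
}

#' Read scaffolds from a FASTA file
#'
#' Sequences are uppercased; IUPAC ambiguity codes other than `N` are mapped
#' to `N` (or rejected with `strict = TRUE`). Any other character is a parse
#' error reported with its line number.
#'
#' @param path FASTA file (multi-record, wrapping allowed).
#' @param strict reject ambiguity codes instead of mapping them to `N`.
#' @return list of [scaffold_record()] in file order.
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) return(list())
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  ambiguity <- "RYSWKMBDHV"
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    bad <- regexpr("[^ACGTN]", s)
    if (bad > 0L) {
      ch <- substr(s, bad, bad)
      if (grepl(ch, ambiguity, fixed = TRUE) && !strict) {
        s <- chartr(ambiguity, strrep("N", nchar(ambiguity)), s)
      } else {
        stop(sprintf("illegal character '%s' in record '%s' near line %d of %s",
                     ch, ids[[i]], .fasta_line_of(path, ids[[i]], as.integer(bad)),
                     path), call. = FALSE)
      }
    }
    out[[i]] <- scaffold_record(ids[[i]], s)
  }
  out
}

# best-effort line number of sequence offset `off` (1-based) within a record
.fasta_line_of <- function(path, id, off) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  start <- hdr[match(id, sub("\\s.*$", "", sub("^>", "", lines[hdr])))]
  if (is.na(start)) return(NA_integer_)
  i <- start + 1L
  seen <- 0L
  while (i <= length(lines) && !startsWith(lines[[i]], ">")) {
    seen <- seen + nchar(lines[[i]])
    if (seen >= off) return(i)
    i <- i + 1L
  }
  NA_integer_
}

#' Write scaffolds to FASTA
#'
#' @param records list of [scaffold_record()].
#' @param path output path.
#' @param line_width bases per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  stopifnot(is.list(records), line_width >= 1L)
  if (inherits(records, "scaffold_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  ids <- vapply(records, function(r) r$id, character(1))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(line_width))
  invisible(path)
}

#' Locate N-gaps in a scaffold and extract their flanks
#'
#' Every maximal run of `N` of length at least `min_gap_len` becomes one gap,
#' reported with 0-based half-open coordinates. Flanks are the up-to
#' `flank_len` non-N bases immediately adjacent on each side, truncated at the
#' scaffold ends and at neighbouring N-runs (a flank never crosses another
#' N-run, of any length).
#'
#' @param record a [scaffold_record()].
#' @param min_gap_len smallest N-run reported as a gap.
#' @param flank_len maximum flank length extracted per side.
#' @return data.frame with columns `gap_id`, `scaffold_id`, `start`, `end`
#'   (0-based half-open), `left_flank`, `right_flank`, `status`
#'   (`"unclassified"`), sorted by `start`. Zero rows when no gap qualifies.
#' @export
detect_gaps <- function(record, min_gap_len = 1L, flank_len = 500L) {
  stopifnot(inherits(record, "scaffold_record"),
            min_gap_len >= 1L, flank_len >= 1L)
  seq <- record$sequence
  runs <- gregexpr("N+", seq)[[1L]]
  empty <- data.frame(gap_id = character(), scaffold_id = character(),
                      start = integer(), end = integer(),
                      left_flank = character(), right_flank = character(),
                      status = character(), stringsAsFactors = FALSE)
  if (runs[[1L]] == -1L) return(empty)
  len <- attr(runs, "match.length")
  starts1 <- as.integer(runs)            # 1-based inclusive
  keep <- len >= min_gap_len
  if (!any(keep)) return(empty)
  starts1 <- starts1[keep]; len <- len[keep]
  nseq <- nchar(seq)
  left <- character(length(starts1)); right <- character(length(starts1))
  for (i in seq_along(starts1)) {
    s <- starts1[[i]]; e <- s + len[[i]] - 1L
    lo <- max(1L, s - flank_len)
    lf <- substr(seq, lo, s - 1L)
    # truncate at the nearest N to the left
    nhit <- gregexpr("N", lf, fixed = TRUE)[[1L]]
    if (nhit[[1L]] != -1L) lf <- substr(lf, max(nhit) + 1L, nchar(lf))
    hi <- min(nseq, e + flank_len)
    rf <- substr(seq, e + 1L, hi)
    nhit <- regexpr("N", rf, fixed = TRUE)
    if (nhit > 0L) rf <- substr(rf, 1L, nhit - 1L)
    left[[i]] <- lf; right[[i]] <- rf
  }
  start0 <- starts1 - 1L
  end0 <- start0 + len
  data.frame(
    gap_id = sprintf("%s:%d-%d", record$id, start0, end0),
    scaffold_id = record$id,
    start = start0, end = end0,
    left_flank = left, right_flank = right,
    status = "unclassified",
    stringsAsFactors = FALSE
  )
}

#' Replace a gap's N-run with a fill sequence
#'
#' Bases outside `[start, end)` are untouched; the returned scaffold has
#' length `original - (end - start) + nchar(fill)`.
#'
#' @param record a [scaffold_record()].
#' @param gap one row of a [detect_gaps()] data.frame (or a list with
#'   `scaffold_id`, `start`, `end`).
#' @param fill replacement sequence (no `N`).
#' @return a new [scaffold_record()].
#' @export
patch_scaffold <- function(record, gap, fill) {
  stopifnot(inherits(record, "scaffold_record"), is.character(fill),
            length(fill) == 1L)
  gap <- as.list(gap)
  if (!identical(gap$scaffold_id, record$id)) {
    stop(sprintf("gap belongs to scaffold '%s', not '%s'",
                 gap$scaffold_id, record$id), call. = FALSE)
  }
  s0 <- as.integer(gap$start); e0 <- as.integer(gap$end)
  n <- nchar(record$sequence)
  if (!(e0 > s0 && s0 >= 0L && e0 <= n)) {
    stop("gap coordinates inconsistent with scaffold length", call. = FALSE)
  }
  region <- substr(record$sequence, s0 + 1L, e0)
  if (gsub("N", "", region, fixed = TRUE) != "") {
    stop("gap interval is not an N-run in this scaffold", call. = FALSE)
  }
  if (grepl("N", fill, fixed = TRUE)) stop("fill must contain no N", call. = FALSE)
  .check_alphabet(fill, "fill")
  scaffold_record(record$id, paste0(substr(record$sequence, 1L, s0), fill,
                                    substr(record$sequence, e0 + 1L, n)))
}

#' Write a gap inventory as BED3+1
#'
#' One line per gap: `scaffold_id`, `start`, `end` (0-based half-open) and the
#' gap status, tab-separated — readable by standard interval tools.
#'
#' @param gaps data.frame from [detect_gaps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gap_bed <- function(gaps, path) {
  stopifnot(is.data.frame(gaps))
  if (nrow(gaps) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s", gaps$scaffold_id, gaps$start, gaps$end,
                   gaps$status)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+1 gap inventory written by [write_gap_bed()]
#'
#' @param path BED file.
#' @return data.frame with `scaffold_id`, `start`, `end`, `status`.
#' @export
read_gap_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), status = character(),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("scaffold_id", "start", "end", "status"),
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  df
}
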