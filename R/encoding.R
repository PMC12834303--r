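# Fixed channel order for one-hot encoding. Serialised into every model file;
# a trained model is never decoded under a different convention.
CHANNEL_ORDER <- c("A", "C", "G", "T")
GAPFILLR_ALPHABET <- c(CHANNEL_ORDER, "N")

.check_alphabet <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' in %s at offset %d (alphabet is A,C,G,T,N)",
                 substr(seq, bad, bad), what, as.integer(bad)), call. = FALSE)
  }
  invisible(TRUE)
}

#' One-hot encode a nucleotide sequence
#'
#' Converts a string over the alphabet `A,C,G,T,N` into a numeric matrix of
#' shape `length x 4` with channel order A,C,G,T. Definite bases become unit
#' basis vectors; `N` rows follow the chosen policy: all-zero (`"zero"`, the
#' default -- an undetermined base carries no evidence) or all `0.25`
#' (`"uniform"`).
#'
#' @param seq character scalar over `{A,C,G,T,N}` (uppercase).
#' @param n_policy how to encode `N`: `"zero"` or `"uniform"`.
#' @return numeric matrix `(nchar(seq), 4)` with column names `A,C,G,T`.
#' @export
#' @examples
#' one_hot_encode("ACGT")
#' one_hot_encode("N", n_policy = "uniform")
one_hot_encode <- function(seq, n_policy = c("zero", "uniform")) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n_policy <- match.arg(n_policy)
  .check_alphabet(seq)
  n <- nchar(seq)
  m <- matrix(0, nrow = n, ncol = 4L, dimnames = list(NULL, CHANNEL_ORDER))
  if (n == 0L) return(m)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, CHANNEL_ORDER)
  def <- !is.na(idx)
  m[cbind(which(def), idx[def])] <- 1
  if (n_policy == "uniform" && any(!def)) m[!def, ] <- 0.25
  m
}

#' Decode a one-hot (or probability) matrix back to bases
#'
#' Takes the per-row argmax over the four channels; ties resolve to the
#' earliest channel in A,C,G,T order. Inverse of [one_hot_encode()] on
#' N-free sequences.
#'
#' @param m numeric matrix with 4 columns.
#' @return character scalar (empty string for a 0-row matrix).
#' @export
one_hot_decode <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  if (nrow(m) == 0L) return("")
  paste(CHANNEL_ORDER[max.col(m, ties.method = "first")], collapse = "")
}

#' Reverse complement
#'
#' Reverses the sequence and complements each base (`A<->T`, `C<->G`,
#' `N -> N`). An involution that preserves length and GC count.
#'
#' @param seq character scalar over `{A,C,G,T,N}`.
#' @return character scalar.
#' @export
#' @examples
#' reverse_complement("AAN")  # "NTT"
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .check_alphabet(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  intToUtf8(rev(utf8ToInt(comp)))
}
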