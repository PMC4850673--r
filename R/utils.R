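# Small shared helpers: sequence manipulation and Phred encoding.

DNA_BASES <- c("A", "C", "G", "T")
OVERLAP_LEVELS <- c("NOT_OVERLAP", "MATCH", "CONFLICT", "UNKNOWN")

revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan", vapply(strsplit(x, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""), character(1)))
}

#' Decode and encode Phred+33 quality strings
#'
#' @param x A character vector of FASTQ quality strings (`phred_decode`) or a
#'   list/vector of integer Phred scores (`phred_encode`).
#' @return `phred_decode` returns a list of integer vectors; `phred_encode`
#'   returns a character vector.
#' @examples
#' phred_decode("!I")        # 0, 40
#' phred_encode(list(c(0L, 40L)))
#' @export
phred_decode <- function(x) {
  lapply(x, function(s) utf8ToInt(s) - 33L)
}

#' @rdname phred_decode
#' @export
phred_encode <- function(x) {
  if (!is.list(x)) x <- list(x)
  vapply(x, function(q) {
    stopifnot(all(q >= 0 & q <= 93))
    intToUtf8(as.integer(q) + 33L)
  }, character(1))
}

# split a sequence into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

check_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != as.integer(x))
    abort(sprintf("`%s` must be a single integer", name))
  if (!is.null(min) && x < min)
    abort(sprintf("`%s` must be >= %d", name, min))
  invisible(as.integer(x))
}
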