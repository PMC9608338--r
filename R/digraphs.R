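#' The keyboard alphabet
#'
#' Default: the 26 English letters followed by space (27 characters), space
#' being a first-class key.
#'
#' @param chars Character vector of unique single characters.
#' @return The validated character vector.
#' @export
keyboard_alphabet <- function(chars = c(LETTERS, " ")) {
  stopifnot(all(nchar(chars) == 1), !anyDuplicated(chars))
  if (length(chars) < 2) stop("alphabet must have at least 2 characters",
                              call. = FALSE)
  chars
}

#' Normalize text for digraph counting and transcription
#'
#' Uppercases, converts every run of whitespace (spaces, tabs, newlines) to
#' a single space, and trims leading/trailing space. Shared by digraph
#' counting and the transcription simulator so both see the same character
#' stream.
#'
#' @param text Character vector; elements are joined by single spaces.
#' @return One normalized string.
#' @export
normalize_text <- function(text) {
  s <- paste(text, collapse = " ")
  s <- toupper(s)
  s <- gsub("[[:space:]]+", " ", s)
  trimws(s)
}

#' Count digraph transitions in a corpus
#'
#' Counts ordered adjacent character pairs (including same-character pairs
#' such as the "LL" in "HELLO") after normalization. Characters outside the
#' alphabet are dropped and act as separators: the pair straddling a dropped
#' character is not counted.
#'
#' @param corpus Character vector of text (e.g. one phrase per element).
#' @param alphabet A [keyboard_alphabet()].
#' @return An `N x N` integer matrix of counts, rows = from-character,
#'   columns = to-character, dimnames = the alphabet.
#' @examples
#' count_digraphs("AB A")["A", "B"]
#' @export
count_digraphs <- function(corpus, alphabet = keyboard_alphabet()) {
  alphabet <- keyboard_alphabet(alphabet)
  n <- length(alphabet)
  f <- matrix(0L, n, n, dimnames = list(alphabet, alphabet))
  chars <- strsplit(normalize_text(corpus), "")[[1]]
  if (length(chars) < 2) return(f)
  idx <- match(chars, alphabet)  # NA marks a dropped character
  from <- idx[-length(idx)]
  to <- idx[-1]
  keep <- !is.na(from) & !is.na(to)
  if (any(keep)) {
    lin <- (to[keep] - 1L) * n + from[keep]  # column-major cell index
    f <- matrix(tabulate(lin, nbins = n * n), n, n,
                dimnames = list(alphabet, alphabet))
  }
  f
}

#' Default phrase corpus bundled with the package
#'
#' A small synthetic set of short English phrases (one per line) with
#' letter/space content only, standing in for a text-entry evaluation
#' phrase set. Used as the default digraph source in examples and tests.
#'
#' @return Character vector of phrases.
#' @export
default_corpus <- function() {
  readLines(system.file("extdata", "phrases_synthetic.txt",
                        package = "abilikey"),
            encoding = "UTF-8")
}
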