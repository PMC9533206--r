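#' Tokenize text into lowercase alphanumeric tokens
#'
#' The single tokenizer shared by the keyword matcher, the lexicon loader,
#' the word-frequency tables and the bag-of-words builder, so that lexicon
#' entries and post text are normalized identically. Every maximal run of
#' Unicode letters/digits is one token; hyphens, apostrophes and all other
#' punctuation act as boundaries ("laid-off" -> "laid", "off").
#'
#' @param text A character scalar (any Unicode text; `NA` is treated as "").
#' @return Character vector of lowercase tokens; `character(0)` for empty text.
#' @examples
#' tokenize("I was laid-off; SO unemployed!")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  text <- tolower(enc2utf8(as.character(text)))
  m <- gregexpr("[\\p{L}\\p{N}]+", text, perl = TRUE)
  toks <- regmatches(text, m)[[1L]]
  if (length(toks) == 1L && is.na(toks)) character(0) else toks
}

# vectorized form used internally: list of token vectors, one per text
tokenize_all <- function(texts) {
  texts <- as.character(texts)
  texts[is.na(texts)] <- ""
  texts <- tolower(enc2utf8(texts))
  m <- gregexpr("[\\p{L}\\p{N}]+", texts, perl = TRUE)
  out <- regmatches(texts, m)
  lapply(out, function(t) t[nzchar(t)])
}
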