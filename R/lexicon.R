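#' @title The theme keyword lexicon
#'
#' @description A `theme_lexicon` is an ordered list of themes, each carrying
#' a list of keyword patterns. A pattern is either a *root* (one lowercase
#' token, matched as a prefix of post tokens, so "unemploy" captures
#' "unemployment", "unemployed", "unemployable") or a *phrase* (an ordered
#' token list matched against a consecutive token run, each phrase token as a
#' prefix). The built-in default covers the 29 psychosocial-survivorship
#' themes of the Quality of Cancer Survivorship Care Framework's
#' psychosocial-effects domain.
#'
#' @name theme_lexicon
NULL

new_pattern <- function(tokens) {
  stopifnot(length(tokens) >= 1L, all(nzchar(tokens)))
  list(kind = if (length(tokens) >= 2L) "phrase" else "root",
       tokens = as.character(tokens))
}

new_lexicon <- function(themes, patterns, id = "custom") {
  stopifnot(length(themes) == length(patterns))
  if (anyDuplicated(themes)) {
    stop("duplicate theme name: ",
         paste(unique(themes[duplicated(themes)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(themes = as.character(themes), patterns = patterns, id = id),
            class = "theme_lexicon")
}

pattern_key <- function(p) {
  paste0(if (p$kind == "phrase") "phrase:" else "root:",
         paste(p$tokens, collapse = " "))
}

#' @describeIn theme_lexicon Number of themes.
#' @param x,object A `theme_lexicon`.
#' @param ... Unused.
#' @export
length.theme_lexicon <- function(x) length(x$themes)

#' @export
print.theme_lexicon <- function(x, ...) {
  cat(sprintf("<theme_lexicon '%s': %d themes, %d patterns>\n", x$id,
              length(x$themes), sum(lengths(x$patterns))))
  invisible(x)
}

.lexicon_cache <- new.env(parent = emptyenv())

#' Built-in psychosocial theme lexicon
#'
#' Returns the shipped 29-theme keyword lexicon in its canonical order, each
#' keyword lowercased; multi-word entries are phrase patterns, single words
#' are root patterns.
#'
#' @return A `theme_lexicon` with 29 themes.
#' @examples
#' lex <- builtin_lexicon()
#' lex$themes[1:3]
#' @export
builtin_lexicon <- function() {
  if (!is.null(.lexicon_cache$builtin)) return(.lexicon_cache$builtin)
  path <- system.file("extdata", "box1_lexicon.txt", package = "themescan",
                      mustWork = TRUE)
  lex <- load_lexicon(path)
  lex$id <- "builtin"
  .lexicon_cache$builtin <- lex
  lex
}

#' Load a lexicon from its plain-text config format
#'
#' The format is UTF-8 text: a `[Theme Name]` line opens a theme block and
#' every following non-empty, non-comment (`#`) line is one keyword. Keywords
#' are normalized with the shared tokenizer ([tokenize()]), so punctuation
#' inside an entry ("full-time") yields a phrase pattern.
#'
#' @param lexicon_file Path to the lexicon file.
#' @return A `theme_lexicon` preserving file order.
#' @export
load_lexicon <- function(lexicon_file) {
  lines <- readLines(lexicon_file, encoding = "UTF-8", warn = FALSE)
  themes <- character(0)
  patterns <- list()
  current <- NA_character_
  bucket <- list()
  flush <- function() {
    if (!is.na(current)) {
      if (length(bucket) == 0L) {
        stop("empty theme (no keywords): ", current, call. = FALSE)
      }
      themes[[length(themes) + 1L]] <<- current
      patterns[[length(patterns) + 1L]] <<- bucket
    }
  }
  for (raw in lines) {
    line <- trimws(raw)
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "[")) {
      if (!endsWith(line, "]")) stop("malformed theme header: ", line,
                                     call. = FALSE)
      flush()
      current <- substr(line, 2L, nchar(line) - 1L)
      bucket <- list()
    } else {
      if (is.na(current)) stop("keyword before any theme header: ", line,
                               call. = FALSE)
      toks <- tokenize(line)
      if (length(toks) == 0L) {
        stop("empty keyword entry in theme: ", current, call. = FALSE)
      }
      pat <- new_pattern(toks)
      if (pattern_key(pat) %in% vapply(bucket, pattern_key, "")) {
        stop("duplicate keyword '", paste(toks, collapse = " "),
             "' in theme: ", current, call. = FALSE)
      }
      bucket[[length(bucket) + 1L]] <- pat
    }
  }
  flush()
  if (length(themes) == 0L) stop("lexicon file defines no themes",
                                 call. = FALSE)
  new_lexicon(themes, patterns,
              id = tools::file_path_sans_ext(basename(lexicon_file)))
}

#' Serialize a lexicon to the plain-text config format
#'
#' @param lexicon A `theme_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "theme_lexicon"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(lexicon$themes)) {
    writeLines(sprintf("[%s]", lexicon$themes[i]), con)
    writeLines(vapply(lexicon$patterns[[i]],
                      function(p) paste(p$tokens, collapse = " "), ""), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Validate a lexicon and report pattern overlaps
#'
#' Report-only diagnostics: within-theme duplicate patterns (an error when
#' loading, but constructed lexicons may carry them), cross-theme shared
#' patterns (informational; the built-in lexicon deliberately repeats e.g.
#' "spouse" under two themes), and short roots that are likely to over-match
#' (e.g. "rest" matching "restaurant").
#'
#' @param lexicon A `theme_lexicon`.
#' @param min_root_length Roots shorter than this are flagged (default 5).
#' @return A list of three data frames: `within_theme_duplicates`
#'   (`theme`, `pattern`), `cross_theme_shared` (`pattern`, `themes`,
#'   semicolon-joined), `short_roots` (`theme`, `root`).
#' @export
validate_lexicon <- function(lexicon, min_root_length = 5L) {
  stopifnot(inherits(lexicon, "theme_lexicon"))
  dup_theme <- character(0); dup_pat <- character(0)
  short_theme <- character(0); short_root <- character(0)
  key_theme <- list()
  for (i in seq_along(lexicon$themes)) {
    keys <- vapply(lexicon$patterns[[i]], pattern_key, "")
    dups <- unique(keys[duplicated(keys)])
    if (length(dups) > 0L) {
      dup_theme <- c(dup_theme, rep(lexicon$themes[i], length(dups)))
      dup_pat <- c(dup_pat, dups)
    }
    for (p in lexicon$patterns[[i]]) {
      if (p$kind == "root" && nchar(p$tokens) < min_root_length) {
        short_theme <- c(short_theme, lexicon$themes[i])
        short_root <- c(short_root, p$tokens)
      }
    }
    for (k in unique(keys)) {
      key_theme[[k]] <- c(key_theme[[k]], lexicon$themes[i])
    }
  }
  shared <- Filter(function(v) length(v) > 1L, key_theme)
  list(
    within_theme_duplicates = data.frame(theme = dup_theme, pattern = dup_pat,
                                         stringsAsFactors = FALSE),
    cross_theme_shared = data.frame(
      pattern = names(shared),
      themes = vapply(shared, paste, "", collapse = "; "),
      row.names = NULL, stringsAsFactors = FALSE),
    short_roots = data.frame(theme = short_theme, root = short_root,
                             stringsAsFactors = FALSE)
  )
}
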