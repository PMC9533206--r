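lex <- builtin_lexicon()

test_that("tokenize lowercases and splits on punctuation", {
  expect_equal(tokenize("I was laid-off; SO unemployed!"),
               c("i", "was", "laid", "off", "so", "unemployed"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("in vitro (IVF)"), c("in", "vitro", "ivf"))
})

test_that("match_count applies prefix and phrase semantics with dedup", {
  unemp <- lex$patterns[[match("Underemployment, unemployment, and return to work",
                               lex$themes)]]
  expect_equal(match_count(tokenize("unemployment looms"), unemp), 1L)

  fatigue <- lex$patterns[[match("Fatigue", lex$themes)]]
  expect_equal(match_count(tokenize("tired, so tired, utterly exhausted"),
                           fatigue), 3L)
  expect_equal(match_count(character(0), fatigue), 0L)

  # a token matched by two roots of one theme counts once
  pats <- list(themescan:::new_pattern("sleep"),
               themescan:::new_pattern("slee"))
  expect_equal(match_count(c("sleeping"), pats), 1L)
  # two phrases matching the same span count once
  pats2 <- list(themescan:::new_pattern(c("sleep", "dist")),
                themescan:::new_pattern(c("slee", "disturb")))
  expect_equal(match_count(c("sleep", "disturbance"), pats2), 1L)
  # overlapping spans of a repeated-word phrase all count
  pats3 <- list(themescan:::new_pattern(c("ha", "ha")))
  expect_equal(match_count(c("ha", "ha", "ha"), pats3), 2L)
})

test_that("score_post scores every theme of the lexicon", {
  s <- score_post("nap nap nap", lex)
  expect_equal(unname(s[["Fatigue"]]), 3L)
  expect_equal(sum(s), 3L)

  expect_true(all(score_post("", lex) == 0L))

  s2 <- score_post("my husband cried", lex)
  expect_gte(s2[["Interpersonal"]], 1L)
  expect_gte(s2[["Family and caregiver relationships"]], 1L)
  expect_gte(s2[["Distress"]], 1L)
})

test_that("score_corpus is deterministic, complete and permutation safe", {
  gen <- generate_corpus(synthetic_config(n_posts = 60L, seed = 3L))
  m1 <- score_corpus(gen$corpus, lex)
  m2 <- score_corpus(gen$corpus, lex)
  expect_identical(m1$scores, m2$scores)
  expect_equal(nrow(m1$scores), 60L)
  expect_equal(colnames(m1$scores), lex$themes)

  shuffled <- gen$corpus[sample(nrow(gen$corpus)), ]
  m3 <- score_corpus(post_corpus(shuffled), lex)
  expect_identical(m3$scores[rownames(m1$scores), ], m1$scores)

  empty <- score_corpus(make_corpus(character(0)), lex)
  expect_equal(nrow(empty$scores), 0L)
})

test_that("classification applies the minimum theme score", {
  row <- stats::setNames(rep(0L, length(lex$themes)), lex$themes)
  row[c("Fatigue", "Stress")] <- c(3L, 2L)
  expect_equal(classify_post(row, 3L), "Fatigue")

  row2 <- stats::setNames(rep(0L, length(lex$themes)), lex$themes)
  row2[["Underemployment, unemployment, and return to work"]] <- 1L
  expect_equal(classify_post(row2, 3L), character(0))
  expect_equal(classify_post(row2 * 0L, 3L), character(0))
})

test_that("raising the threshold never enlarges a related-theme set", {
  gen <- generate_corpus(synthetic_config(n_posts = 100L, seed = 5L,
                                          noise_keyword_rate = 0.5))
  m <- score_corpus(gen$corpus, lex)
  for (i in seq_len(nrow(m$scores))) {
    prev <- classify_post(m$scores[i, ], 1L)
    for (tau in 2:5) {
      cur <- classify_post(m$scores[i, ], tau)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
  counts <- vapply(1:5, function(tau) sum(related_posts(m, tau)), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("top_theme breaks ties by lexicon order", {
  row <- stats::setNames(rep(0L, length(lex$themes)), lex$themes)
  row[c("Fatigue", "Worry")] <- c(5L, 2L)
  expect_equal(top_theme(row), "Fatigue")

  row2 <- stats::setNames(rep(0L, length(lex$themes)), lex$themes)
  row2[c("Stress", "Worry")] <- 2L
  expect_equal(top_theme(row2), "Stress")  # Stress precedes Worry
  expect_true(is.na(top_theme(row2 * 0L)))
})

test_that("total_theme_score sums across themes", {
  row <- stats::setNames(rep(0L, length(lex$themes)), lex$themes)
  row[c("Fatigue", "Stress")] <- c(3L, 2L)
  expect_equal(total_theme_score(row), 5L)
  expect_equal(total_theme_score(row * 0L), 0L)
  expect_equal(total_theme_score(score_post("nap nap nap", lex)), 3L)
})

test_that("qualitative sample enforces ordering and the per-user cap", {
  # one user owns the 7 highest-scoring posts
  texts <- c(sprintf("%s", vapply(9:3, function(k)
    paste(rep("nap", k + 10), collapse = " "), "")),
    "nap nap nap", "cope cope", "worry")
  corpus <- make_corpus(texts,
                        users = c(rep("prolific", 7), "u1", "u2", "u3"))
  m <- score_corpus(corpus, lex)
  sel <- select_qualitative_sample(m, corpus, k = 20L, max_per_user = 5L)
  expect_equal(sum(corpus$username[match(sel, corpus$post_id)] == "prolific"),
               5L)
  expect_equal(length(sel), 8L)  # exhaustion: only 10 posts, cap drops 2
  # the sixth (and seventh) post of the prolific poster is skipped in favor
  # of the next users posts
  expect_true(all(c("p008", "p009", "p010") %in% sel))

  small <- make_corpus(c("nap", "cope", "worry"))
  ms <- score_corpus(small, lex)
  expect_equal(sort(select_qualitative_sample(ms, small, k = 20L)),
               c("p001", "p002", "p003"))

  abc <- make_corpus(c(paste(rep("nap", 10), collapse = " "),
                       paste(rep("nap", 9), collapse = " "),
                       paste(rep("nap", 8), collapse = " ")),
                     users = c("ua", "ub", "uc"))
  mabc <- score_corpus(abc, lex)
  expect_equal(select_qualitative_sample(mabc, abc, k = 2L),
               c("p001", "p002"))

  # ties broken by post_id ascending
  tie <- make_corpus(c("nap nap", "nap nap", "nap nap"),
                     users = c("ua", "ub", "uc"),
                     ids = c("z9", "a1", "m5"))
  mtie <- score_corpus(tie, lex)
  expect_equal(select_qualitative_sample(mtie, tie, k = 3L),
               c("a1", "m5", "z9"))
})

test_that("agreement is the share of concordant designations", {
  a <- stats::setNames(rep("Fatigue", 20), sprintf("p%02d", 1:20))
  expect_equal(agreement(a, a), 1.0)
  b <- stats::setNames(rep("Worry", 20), names(a))
  expect_equal(agreement(a, b), 0.0)
  c2 <- a; c2[c("p03", "p17")] <- "Stress"
  expect_equal(agreement(a, c2), 0.9)
  expect_equal(agreement(stats::setNames(c("Fatigue", NA), c("x", "y")),
                         stats::setNames(c("Fatigue", NA), c("x", "y"))), 1.0)
  expect_error(agreement(a, b[1:10]), "different post sets")
})

test_that("score matrix round-trips through CSV with total/related columns", {
  gen <- generate_corpus(synthetic_config(n_posts = 40L, seed = 9L))
  m <- score_corpus(gen$corpus, lex)
  path <- withr::local_tempfile(fileext = ".csv")
  write_score_matrix(m, path)
  df <- utils::read.csv(path, check.names = FALSE)
  expect_equal(df$total, unname(rowSums(m$scores)))
  expect_equal(df$related, unname(as.integer(related_posts(m))))
  back <- read_score_matrix(path, min_score = 3L)
  expect_equal(back$scores, m$scores)
})

test_that("match_count agrees with the brute-force regex oracle", {
  gen <- generate_corpus(synthetic_config(n_posts = 150L, seed = 21L,
                                          noise_keyword_rate = 0.5))
  m <- score_corpus(gen$corpus, lex)
  for (i in seq_len(nrow(gen$corpus))) {
    expect_equal(unname(m$scores[i, ]),
                 unname(oracle_score_post(gen$corpus$text[i], lex)),
                 info = gen$corpus$post_id[i])
  }
})

test_that("concatenation is superadditive, equal without boundary phrases", {
  set.seed(77)
  gen <- generate_corpus(synthetic_config(n_posts = 40L, seed = 23L))
  texts <- gen$corpus$text
  for (i in seq_len(20)) {
    a <- texts[2 * i - 1]; b <- texts[2 * i]
    sa <- score_post(a, lex); sb <- score_post(b, lex)
    sc <- score_post(paste(a, b), lex)
    expect_true(all(sc >= sa + sb))
  }
})
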