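# exhaustive best path: the oracle Viterbi is checked against
brute_force_path <- function(E, Tm) {
  n <- nrow(E)
  k <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  scores <- apply(paths, 1, function(p) {
    s <- sum(E[cbind(seq_len(n), p)])
    if (n > 1) s <- s + sum(Tm[cbind(p[-n], p[-1])])
    s
  })
  list(score = max(scores), path = paths[which.max(scores), ])
}

viterbi_score <- function(path, E, Tm) {
  n <- length(path)
  s <- sum(E[cbind(seq_len(n), path)])
  if (n > 1) s <- s + sum(Tm[cbind(path[-n], path[-1])])
  s
}

test_that("the alphabet collects observed labels plus class O", {
  a <- build_alphabet(list(c(0, 0, 0)))
  expect_equal(a$labels, 0)
  labs <- encode_sentence(abdomen_tokens, abdomen_mentions)
  a6 <- build_alphabet(list(labs))
  expect_equal(a6$size, 5L)  # 4 distinct non-O labels + O
  expect_equal(a6$labels[1], 0)
  expect_error(build_alphabet(list()), "empty")
})

test_that("Viterbi matches exhaustive path enumeration", {
  # single position: argmax of the emission column
  E1 <- matrix(c(0.3, 1.2, -0.5), 1)
  expect_equal(viterbi(E1, matrix(0, 3, 3)), 2L)

  # hand-set 2x2: transitions flip the greedy choice
  E <- rbind(c(2, 1.9), c(0, 0))
  Tm <- rbind(c(-5, -5), c(0, 0))
  expect_equal(viterbi(E, Tm), c(2L, 1L))
  expect_equal(brute_force_path(E, Tm)$path, c(2, 1), ignore_attr = TRUE)

  set.seed(31)
  for (trial in 1:40) {
    n <- sample(1:6, 1)
    k <- sample(2:6, 1)
    E <- matrix(stats::rnorm(n * k), n, k)
    Tm <- matrix(stats::rnorm(k * k), k, k)
    got <- viterbi(E, Tm)
    ref <- brute_force_path(E, Tm)
    expect_equal(viterbi_score(got, E, Tm), ref$score)
    expect_equal(got, as.integer(ref$path), ignore_attr = TRUE)
  }
})

test_that("a single sentence is memorized exactly", {
  labs <- encode_sentence(abdomen_tokens, abdomen_mentions)
  corpus <- list(list(tokens = abdomen_tokens, labels = labs))
  model <- train_tagger(corpus, tconf = train_config(epochs = 20, seed = 2))
  expect_true(model$converged)
  expect_equal(predict_tagger(model, abdomen_tokens), labs)
})

test_that("training is deterministic and predictions stay in the alphabet", {
  corpus <- generate_corpus(generator_config(n_sentences = 60, seed = 19))
  m1 <- train_tagger(corpus$sentences, tconf = train_config(epochs = 10, seed = 4))
  m2 <- train_tagger(corpus$sentences, tconf = train_config(epochs = 10, seed = 4))
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$transitions, m2$transitions)

  other <- generate_corpus(generator_config(n_sentences = 20, seed = 99))
  for (s in other$sentences) {
    p <- predict_tagger(m1, s$tokens, pos = s$pos)
    expect_true(all(p %in% m1$alphabet$labels))
  }
})

test_that("a separable corpus is fit to perfect training F1", {
  corpus <- generate_corpus(generator_config(n_sentences = 150, seed = 29))
  lex <- generate_cluster_lexicon(
    c(corpus$vocabulary$background, corpus$vocabulary$disorder), 300,
    seed = 29, disorder_words = corpus$vocabulary$disorder)
  model <- train_tagger(corpus$sentences, lex,
                        tconf = train_config(epochs = 30, seed = 8))
  preds <- lapply(corpus$sentences, function(s) {
    decode_labels(predict_tagger(model, s$tokens, lex, s$pos))
  })
  golds <- lapply(corpus$sentences, `[[`, "mentions")
  expect_equal(evaluate_mentions(preds, golds, "strict")$f1, 1)
})

test_that("a degenerate single-label corpus trains with a warning", {
  corpus <- list(list(tokens = c("a", "b"), labels = c(0, 0)),
                 list(tokens = c("c", "d"), labels = c(0, 0)))
  expect_warning(model <- train_tagger(corpus, tconf = train_config(epochs = 2)),
                 "single distinct label")
  expect_equal(predict_tagger(model, c("a", "d")), c(0, 0))
})

test_that("models survive a save/load round trip", {
  corpus <- generate_corpus(generator_config(n_sentences = 40, seed = 3))
  model <- train_tagger(corpus$sentences,
                        tconf = train_config(epochs = 5, seed = 6))
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$alphabet$labels, model$alphabet$labels)
  expect_equal(back$weights, model$weights, tolerance = 1e-12)
  s <- corpus$sentences[[1]]
  expect_equal(predict_tagger(back, s$tokens, pos = s$pos),
               predict_tagger(model, s$tokens, pos = s$pos))
  expect_error(load_model(extdata("clinical_example-lexicon.tsv")))
})
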