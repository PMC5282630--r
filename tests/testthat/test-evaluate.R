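test_that("boundary matching distinguishes strict, left and right modes", {
  gold <- c(0L, 1L, 2L)       # Multiple renal cysts
  pred <- c(1L, 2L)           # renal cysts
  expect_false(mention_matches(pred, gold, "strict"))
  expect_false(mention_matches(pred, gold, "left"))
  expect_true(mention_matches(pred, gold, "right"))
  expect_true(all(vapply(c("strict", "left", "right"),
                         function(m) mention_matches(gold, gold, m),
                         logical(1))))
  expect_false(any(vapply(c("strict", "left", "right"),
                          function(m) mention_matches(c(5L, 6L), gold, m),
                          logical(1))))
})

test_that("precision, recall and F1 follow their defining ratios", {
  # TP=2 FP=1 FN=2 arranged in one sentence
  golds <- list(list(0L, 2L, c(4L, 5L), 8L))
  preds <- list(list(0L, 2L, 6L))
  r <- evaluate_mentions(preds, golds, "strict")
  expect_equal(c(r$tp, r$fp, r$fn), c(2L, 1L, 2L))
  expect_equal(r$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 2 * (2 / 3) * 0.5 / ((2 / 3) + 0.5), tolerance = 1e-12)

  perfect <- evaluate_mentions(golds, golds, "strict")
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  empty <- evaluate_mentions(list(list()), golds, "strict")
  expect_equal(c(empty$precision, empty$recall, empty$f1), c(0, 0, 0))
})

test_that("matching is one-to-one: a prediction consumes one gold at most", {
  # one gold, two distinct left-matching predictions: only one can score
  golds <- list(list(c(0L, 1L)))
  preds <- list(list(c(0L, 2L), c(0L, 3L)))
  r <- evaluate_mentions(preds, golds, "left")
  expect_equal(c(r$tp, r$fp, r$fn), c(1L, 1L, 0L))
  # and the leftmost unmatched gold is consumed first
  golds2 <- list(list(c(5L, 6L), c(0L, 1L)))
  preds2 <- list(list(0L))
  r2 <- evaluate_mentions(preds2, golds2, "left")
  expect_equal(r2$tp, 1L)
})

test_that("evaluation is invariant to sentence order and duplicate predictions", {
  golds <- list(list(0L, c(2L, 3L)), list(c(1L, 4L)))
  preds <- list(list(0L), list(c(1L, 4L), c(1L, 4L)))
  r1 <- evaluate_mentions(preds, golds, "strict")
  r2 <- evaluate_mentions(rev(preds), rev(golds), "strict")
  expect_equal(r1$tp, r2$tp)
  expect_equal(r1$fp, r2$fp)
  expect_equal(r1$f1, r2$f1)
  expect_equal(r1$tp, 2L)
  expect_equal(r1$fp, 0L)  # duplicate prediction collapsed
})

test_that("strict F1 never exceeds left or right F1", {
  set.seed(53)
  for (trial in 1:25) {
    n_sent <- sample(3:6, 1)
    golds <- preds <- vector("list", n_sent)
    for (s in seq_len(n_sent)) {
      n_g <- sample(0:3, 1)
      golds[[s]] <- lapply(seq_len(n_g), function(i) {
        start <- 5L * (i - 1L)
        sort(unique(start + sample(0:4, sample(1:3, 1))))
      })
      preds[[s]] <- lapply(golds[[s]], function(g) {
        if (stats::runif(1) < 0.5) g else
          sort(unique(c(min(g) + sample(-1:1, 1), max(g) + sample(-1:1, 1))))
      })
      preds[[s]] <- Filter(function(p) all(p >= 0), preds[[s]])
    }
    fs <- vapply(c("strict", "left", "right"), function(m) {
      evaluate_mentions(preds, golds, m)$f1
    }, numeric(1))
    expect_lte(fs[["strict"]], fs[["left"]] + 1e-12)
    expect_lte(fs[["strict"]], fs[["right"]] + 1e-12)
  }
})

test_that("mention categories follow overlap > discontiguous > contiguous", {
  expect_equal(categorize_mention(c(1L, 3L)), "discontiguous")
  expect_equal(categorize_mention(1:3), "contiguous")
  for (i in 1:3) {
    expect_equal(categorize_mention(abdomen_mentions[[i]],
                                    abdomen_mentions[-i]), "overlapping")
  }
  # nesting without token sharing is still overlapping
  expect_equal(categorize_mention(4L, list(c(2L, 6L))), "overlapping")
})

test_that("per-category evaluation splits counts by mention type", {
  golds <- list(list(0:1, c(3L, 5L)), list(c(0L, 2L), 1L))
  preds <- list(list(0:1, c(3L, 5L)), list(c(0L, 2L), 1L))
  r <- evaluate_mentions(preds, golds, "strict", per_category = TRUE)
  expect_equal(r$categories$tp[r$categories$category == "contiguous"], 1L)
  expect_equal(r$categories$tp[r$categories$category == "discontiguous"], 1L)
  expect_equal(r$categories$tp[r$categories$category == "overlapping"], 2L)
})

test_that("corpus statistics tabulate categories, breakpoints, overlap and span", {
  sentences <- list(
    list(tokens = abdomen_tokens, mentions = abdomen_mentions),
    list(tokens = tokenize_clinical(tricuspid_text)$token,
         mentions = list(tricuspid_mention)),
    list(tokens = sprintf("t%d", 1:6), mentions = list(1:2))
  )
  st <- corpus_stats(sentences)
  expect_equal(st$n_mentions, 5L)
  expect_equal(st$category$amount, c(1L, 1L, 3L))
  expect_equal(sum(st$category$percentage), 100)
  expect_equal(sum(st$span$percentage), 100)
  # the valve mention: 2 breakpoints, span 6
  expect_equal(st$breakpoints$amount[2], 1L)
  expect_equal(st$span$amount[6], 2L)   # "6 or more": spans 10 and 6
  # abdomen cluster: 3 mentions overlapping together
  expect_equal(st$overlap$amount[2], 3L)

  only_contig <- list(list(tokens = letters[1:5], mentions = list(0:1, 3:4)))
  st2 <- corpus_stats(only_contig)
  expect_equal(st2$category$percentage[1], 100)
})
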