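test_that("a shared left boundary becomes one head with D continuations", {
  toks <- c("Abdomen", "is", "soft", ",", "nontender", ",", "nondistended", ".")
  ments <- list(c(0L, 4L), c(0L, 6L))
  enc <- biohd_encode(toks, ments, "plain")
  expect_true(enc$encodable)
  expect_equal(enc$tags[1], "B-H")
  expect_equal(enc$tags[5], "B-D")
  expect_equal(enc$tags[7], "B-D")
  expect_true(mention_set_equal(biohd_decode(enc$tags, "plain"), ments))

  enc4 <- biohd_encode(toks, ments, "1234")
  expect_true(enc4$encodable)
  expect_equal(enc4$tags[5], "B-D1")  # combines with the head at left
  expect_true(mention_set_equal(biohd_decode(enc4$tags, "1234"), ments))
})

test_that("simple sentences keep plain BIO tags", {
  toks <- c("denies", "dyspnea", "on", "exertion", "today")
  enc <- biohd_encode(toks, list(1:3), "plain")
  expect_equal(enc$tags, c("O", "B", "I", "I", "O"))
  expect_true(mention_set_equal(biohd_decode(enc$tags, "plain"), list(1:3)))
  # plain BIO decode: B I O B gives two mentions
  expect_true(mention_set_equal(biohd_decode(c("B", "I", "O", "B"), "plain"),
                                list(c(0L, 1L), 3L)))
  expect_length(biohd_decode(rep("O", 4), "plain"), 0L)
})

test_that("a lone discontiguous mention uses paired D segments", {
  toks <- c("the", "spleen", "was", "enlarged")
  ments <- list(c(1L, 3L))
  for (v in c("plain", "1234")) {
    enc <- biohd_encode(toks, ments, v)
    expect_true(enc$encodable)
    expect_true(mention_set_equal(biohd_decode(enc$tags, v), ments))
  }
  enc4 <- biohd_encode(toks, ments, "1234")
  expect_equal(enc4$tags[c(2, 4)], c("B-D4", "B-D2"))
})

test_that("two head segments are unrepresentable in either variant", {
  for (v in c("plain", "1234")) {
    enc <- biohd_encode(ventricles_tokens, ventricles_mentions, v)
    expect_false(enc$encodable)
    expect_match(enc$reason, "head segments")
    expect_null(enc$tags)
  }
})

test_that("the multi-label scheme is a strict superset of BIOHD", {
  # everything BIOHD encodes round-trips in both schemes
  encodable <- list(
    list(tokens = c("a", "b", "c", "d"), mentions = list(1:2)),
    list(tokens = c("the", "spleen", "was", "enlarged"),
         mentions = list(c(1L, 3L))),
    list(tokens = c("Abdomen", "x", "nontender", "y", "nondistended"),
         mentions = list(c(0L, 2L), c(0L, 4L)))
  )
  for (s in encodable) {
    enc <- biohd_encode(s$tokens, s$mentions, "plain")
    expect_true(enc$encodable)
    labs <- encode_sentence(s$tokens, s$mentions)
    expect_true(mention_set_equal(decode_labels(labs), s$mentions))
  }
  # the two-head and double-role structures only round-trip as multi-labels
  hard <- list(
    list(tokens = ventricles_tokens, mentions = ventricles_mentions),
    list(tokens = pacemaker_tokens, mentions = pacemaker_mentions)
  )
  for (s in hard) {
    for (v in c("plain", "1234")) {
      expect_false(biohd_encode(s$tokens, s$mentions, v)$encodable)
    }
    labs <- encode_sentence(s$tokens, s$mentions)
    expect_true(mention_set_equal(decode_labels(labs), s$mentions))
  }
})

test_that("the corpus audit reports per-sentence representability", {
  sentences <- list(
    list(tokens = c("a", "b", "c"), mentions = list(0:1)),
    list(tokens = ventricles_tokens, mentions = ventricles_mentions)
  )
  rep <- audit_baseline(sentences, "plain")
  expect_equal(rep$encodable, c(TRUE, FALSE))
  expect_true(all(rep$multilabel_ok))
  expect_match(rep$reason[2], "head segments")
})
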