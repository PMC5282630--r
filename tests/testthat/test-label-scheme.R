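test_that("sub-labels put their single bit at the (role, channel) position", {
  cases <- list(
    list("B", 1L, "000000,000000,000001,000000"),
    list("L", 1L, "000000,000001,000000,000000"),
    list("U", 3L, "000000,000000,000000,000100"),
    list("I", 1L, "000001,000000,000000,000000"),
    list("U", 1L, "000000,000000,000000,000001"),
    list("I", 6L, "100000,000000,000000,000000")
  )
  for (cs in cases) {
    s <- make_sublabel(cs[[1]], cs[[2]])
    expect_equal(format_label(s$bits), cs[[3]])
    expect_equal(sum(strsplit(gsub(",", "", format_label(s$bits)), "")[[1]] == "1"),
                 1L)
  }
  expect_error(make_sublabel("O", 1), "never")
  expect_error(make_sublabel("B", 7), "capacity")
  expect_error(make_sublabel("B", 0), "capacity")
})

test_that("integration ORs sub-labels and the empty set gives class O", {
  b1 <- make_sublabel("B", 1)
  b2 <- make_sublabel("B", 2)
  expect_equal(format_label(integrate_sublabels(list(b1, b2))),
               "000000,000000,000011,000000")
  expect_equal(integrate_sublabels(list()), 0)
  expect_equal(classify_label(integrate_sublabels(list())), "O")
  expect_equal(integrate_sublabels(list(b1)), b1$bits)
  # commutative, associative, idempotent
  expect_equal(integrate_sublabels(list(b2, b1)),
               integrate_sublabels(list(b1, b2)))
  expect_equal(integrate_sublabels(list(b1, b1, b2)),
               integrate_sublabels(list(b1, b2)))
})

test_that("extraction inverts integration and orders by bit position", {
  f <- parse_label("000000,000000,000011,000000")
  subs <- extract_sublabels(f)
  expect_length(subs, 2L)
  expect_equal(vapply(subs, `[[`, character(1), "role"), c("B", "B"))
  expect_equal(vapply(subs, `[[`, integer(1), "channel"), c(1L, 2L))
  expect_length(extract_sublabels(0), 0L)

  set.seed(101)
  vals <- sample(0:(2^24 - 1), 500)
  for (v in vals) {
    expect_equal(integrate_sublabels(extract_sublabels(v)), v)
  }
  # popcount conservation: one sub-label per set bit
  pops <- vapply(vals, function(v) {
    sum((v %/% 2^(0:23)) %% 2)
  }, numeric(1))
  expect_equal(vapply(vals, function(v) length(extract_sublabels(v)),
                      integer(1)), as.integer(pops))
})

test_that("classification follows the occupied regions", {
  expect_equal(classify_label(parse_label("000000,000000,000101,000000")), "B")
  expect_equal(classify_label(parse_label("000010,000001,000000,000000")), "C")
  expect_equal(classify_label(0), "O")
  expect_equal(classify_label(parse_label("000000,000000,000000,000100")), "U")
  expect_equal(classify_label(parse_label("000000,100001,000000,000000")), "L")
  expect_equal(classify_label(parse_label("111111,000000,000000,000000")), "I")
  # vectorized call agrees with scalar calls
  set.seed(7)
  v <- sample(0:(2^24 - 1), 2000)
  expect_equal(classify_label(v),
               vapply(v, classify_label, character(1)))
})

test_that("decimal conversion is a range-checked bijection", {
  expect_equal(label_to_decimal(parse_label("000000,000000,000011,000000")),
               192)
  expect_equal(label_from_decimal(0), 0)
  expect_error(label_from_decimal(2^24), "2\\^24")
  expect_error(label_from_decimal(-1), "2\\^24")
  set.seed(11)
  v <- sample(0:(2^24 - 1), 200)
  expect_equal(label_from_decimal(label_to_decimal(v)), as.numeric(v))
  expect_equal(parse_label(format_label(v)), as.numeric(v))
})

test_that("capacity is a parameter and widening scales the label width", {
  sch <- label_scheme(8)
  expect_equal(sch$width, 32L)
  s <- make_sublabel("I", 8, sch)
  expect_equal(s$bits, 2^31)
  expect_equal(format_label(s$bits, sch),
               "10000000,00000000,00000000,00000000")
  expect_equal(classify_label(s$bits, sch), "I")
  # a 7-cluster sentence encodes at capacity 8 but not at 6
  toks <- sprintf("t%d", 1:15)
  ments <- lapply(1:7, function(i) c(0L, 2L * i))
  expect_error(encode_sentence(toks, ments), "capacity")
  labs <- encode_sentence(toks, ments, sch)
  expect_true(mention_set_equal(decode_labels(labs, sch), ments))
  expect_error(label_scheme(0), "between")
  expect_error(label_scheme(14), "between")
})
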