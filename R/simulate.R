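#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the structural make-up of an annotated clinical
#' corpus: the default category mix (88.45% contiguous, 5.06%
#' discontiguous, 6.49% overlapping), breakpoint distribution (94.31% one
#' breakpoint, 5.69% two), overlap-multiplicity distribution over 2..6
#' mutually overlapping mentions and span-length distribution are the
#' observed proportions of the disorder-mention corpus the method targets.
#' Because an overlap cluster of k mentions contributes k overlapping
#' mentions at once, the per-group sampling probability of the overlapping
#' category is divided by the expected cluster size so the *per-mention*
#' category mix matches the configured proportions in expectation.
#'
#' Sentences are synthetic token streams, not real clinical text: the
#' disorder sub-vocabulary is disjoint from the background vocabulary and
#' partitioned into structural-role pools, so token identity carries the
#' signal a learner needs. See the package vignette for what this does and
#' does not emulate.
#'
#' @param n_sentences Number of sentences to generate.
#' @param sentence_length Range of background-only sentence lengths (also
#'   scales padding around mention groups).
#' @param n_background Background vocabulary size.
#' @param n_disorder Disorder sub-vocabulary size (split across role pools).
#' @param category_mix Named proportions for contiguous / discontiguous /
#'   overlapping mentions; must sum to 1.
#' @param overlap_multiplicity Proportions of overlap-cluster sizes 2..6.
#' @param breakpoint_dist Proportions of 1 and 2 breakpoints for
#'   discontiguous mentions.
#' @param span_dist Proportions of span lengths 1..5 and "6 or more".
#' @param groups_per_sentence Probabilities of 0, 1, 2 mention groups per
#'   sentence.
#' @param p_chain Probability that a 2-mention overlap cluster uses the
#'   chain pattern (two mentions sharing a middle token, which yields a
#'   class-C label) rather than the shared-head star pattern.
#' @param p_nested_unit Probability that an overlap cluster's last mention
#'   is a nested unit-length mention (span-covered, no token shared).
#' @param n_clusters Cluster count K for the companion synthetic lexicon.
#' @param capacity Channel capacity of the target [label_scheme()].
#' @param seed Integer seed; the corpus is a deterministic function of the
#'   configuration.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    n_sentences = 200L,
    sentence_length = c(8L, 20L),
    n_background = 705L,
    n_disorder = 180L,
    category_mix = c(contiguous = 0.8845, discontiguous = 0.0506,
                     overlapping = 0.0649),
    overlap_multiplicity = c(`2` = 0.6657, `3` = 0.2735, `4` = 0.0387,
                             `5` = 0.0138, `6` = 0.0083),
    breakpoint_dist = c(`1` = 0.9431, `2` = 0.0569),
    span_dist = c(`1` = 0.4636, `2` = 0.2831, `3` = 0.1416, `4` = 0.0425,
                  `5` = 0.0305, `6` = 0.0387),
    groups_per_sentence = c(`0` = 0.15, `1` = 0.55, `2` = 0.30),
    p_chain = 0.35,
    p_nested_unit = 0.3,
    n_clusters = 700L,
    capacity = 6L,
    seed = 1L) {
  check_simplex <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop(sprintf("%s must be non-negative and sum to 1", what),
           call. = FALSE)
    }
  }
  check_simplex(category_mix, "category_mix")
  check_simplex(overlap_multiplicity, "overlap_multiplicity")
  check_simplex(breakpoint_dist, "breakpoint_dist")
  check_simplex(span_dist, "span_dist")
  check_simplex(groups_per_sentence, "groups_per_sentence")
  if (length(overlap_multiplicity) > capacity - 1L) {
    stop("overlap multiplicities would exceed the scheme capacity",
         call. = FALSE)
  }
  if (breakpoint_dist[["2"]] > 0 && sum(span_dist[-(1:4)]) <= 0) {
    stop(paste("infeasible configuration: 2-breakpoint mentions need span",
               ">= 5 but span_dist has no mass there"), call. = FALSE)
  }
  if (breakpoint_dist[["1"]] > 0 && sum(span_dist[-(1:2)]) <= 0) {
    stop(paste("infeasible configuration: discontiguous mentions need span",
               ">= 3 but span_dist has no mass there"), call. = FALSE)
  }
  structure(list(
    n_sentences = as.integer(n_sentences),
    sentence_length = as.integer(sentence_length),
    n_background = as.integer(n_background),
    n_disorder = as.integer(n_disorder),
    category_mix = category_mix,
    overlap_multiplicity = overlap_multiplicity,
    breakpoint_dist = breakpoint_dist,
    span_dist = span_dist,
    groups_per_sentence = groups_per_sentence,
    p_chain = p_chain,
    p_nested_unit = p_nested_unit,
    n_clusters = as.integer(n_clusters),
    capacity = as.integer(capacity),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# disorder vocabulary split into structural-role pools; lexical identity
# cues the role/channel a token plays, which keeps the corpus learnable
.disorder_pools <- function(n_disorder) {
  mk <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  share <- function(frac, lo) max(lo, round(n_disorder * frac))
  pools <- list(
    contig = mk("dolor", share(0.25, 4L)),
    unit = mk("ulcus", share(0.16, 2L)),
    disc_first = mk("dfira", share(0.08, 2L)),
    disc_mid = mk("dmida", share(0.06, 2L)),
    disc_last = mk("dlasa", share(0.08, 2L)),
    chain = list(a = mk("chaina", 4L), b = mk("chainb", 4L),
                 c = mk("chainc", 4L))
  )
  pools$head <- lapply(2:6, function(m) mk(sprintf("hed%d", m), 3L))
  pools$tail <- lapply(1:6, function(i) mk(sprintf("tal%d", i), 4L))
  pools$ovunit <- lapply(2:6, function(m) mk(sprintf("ovu%d", m), 2L))
  names(pools$head) <- names(pools$ovunit) <- as.character(2:6)
  names(pools$tail) <- as.character(1:6)
  pools
}

.pool_words <- function(pools) {
  unique(unlist(pools, use.names = FALSE))
}

# sample a span length from the configured distribution truncated to
# `min_span`; the "6 or more" slot realizes as 6..9
.sample_span <- function(span_dist, min_span = 1L) {
  support <- c(1:5, 6L)
  keep <- support >= min_span
  if (sum(span_dist[keep]) <= 0) {
    stop("infeasible configuration: no admissible span length", call. = FALSE)
  }
  p <- span_dist[keep] / sum(span_dist[keep])
  s <- sample(support[keep], 1L, prob = p)
  if (s == 6L) s <- sample(6:9, 1L, prob = c(0.5, 0.25, 0.15, 0.1))
  s
}

.pick <- function(pool, n = 1L) sample(pool, n, replace = TRUE)

# one mention group: list(words, mention_sets (0-based, relative), extent)
.make_group <- function(kind, cfg, pools, bg_vocab) {
  if (kind == "contiguous") {
    s <- .sample_span(cfg$span_dist, 1L)
    if (s == 1L) {
      list(words = .pick(pools$unit), mentions = list(0L), extent = 1L)
    } else {
      list(words = .pick(pools$contig, s),
           mentions = list(seq_len(s) - 1L), extent = s)
    }
  } else if (kind == "discontiguous") {
    b <- sample(c(1L, 2L), 1L, prob = cfg$breakpoint_dist)
    s <- .sample_span(cfg$span_dist, if (b == 1L) 3L else 5L)
    words <- .pick(bg_vocab, s)
    mid_cand <- seq(2L, s - 3L)  # interior slot with gaps on both sides
    idx <- if (b == 1L) c(0L, s - 1L) else
      c(0L, mid_cand[sample.int(length(mid_cand), 1L)], s - 1L)
    words[idx[1] + 1L] <- .pick(pools$disc_first)
    if (b == 2L) words[idx[2] + 1L] <- .pick(pools$disc_mid)
    words[idx[length(idx)] + 1L] <- .pick(pools$disc_last)
    list(words = words, mentions = list(idx), extent = s)
  } else {
    m <- sample(2:6, 1L, prob = cfg$overlap_multiplicity)
    if (m == 2L && stats::runif(1) < cfg$p_chain) {
      # chain: two mentions share the middle token (a class-C label)
      list(words = c(.pick(pools$chain$a), .pick(pools$chain$b),
                     .pick(pools$chain$c)),
           mentions = list(c(0L, 1L), c(1L, 2L)), extent = 3L)
    } else if (stats::runif(1) < cfg$p_nested_unit) {
      # star with m-1 shared-head mentions plus one nested unit mention
      n_tail <- m - 1L
      extent <- 2L * n_tail + 1L
      words <- .pick(bg_vocab, extent)
      words[1] <- .pick(pools$head[[as.character(m)]])
      mentions <- vector("list", m)
      for (i in seq_len(n_tail)) {
        words[2L * i + 1L] <- .pick(pools$tail[[as.character(i)]])
        mentions[[i]] <- c(0L, 2L * i)
      }
      words[2] <- .pick(pools$ovunit[[as.character(m)]])
      mentions[[m]] <- 1L
      list(words = words, mentions = mentions, extent = extent)
    } else {
      # star: one head token shared by all m mentions
      extent <- 2L * m + 1L
      words <- .pick(bg_vocab, extent)
      words[1] <- .pick(pools$head[[as.character(m)]])
      mentions <- vector("list", m)
      for (i in seq_len(m)) {
        words[2L * i + 1L] <- .pick(pools$tail[[as.character(i)]])
        mentions[[i]] <- c(0L, 2L * i)
      }
      list(words = words, mentions = mentions, extent = extent)
    }
  }
}

#' Generate a synthetic annotated corpus
#'
#' Draws sentences containing 0-2 mention groups (a contiguous mention, a
#' discontiguous mention, or an overlap cluster of 2-6 mutually overlapping
#' mentions) separated by background padding, per the distributions in the
#' [generator_config()]. Mention tokens come from the disorder
#' sub-vocabulary and everything else from the disjoint background
#' vocabulary. Every sentence is encoded on the fly, so the returned corpus
#' is guaranteed encodable; mentions are stored in generation order (the
#' channel order used for encoding).
#'
#' @param config A [generator_config()].
#' @return Object of class `synthetic_corpus`: `sentences` (each with
#'   `tokens`, `pos`, `mentions`, `labels`), `vocabulary`, `config`, `log`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  scheme <- label_scheme(config$capacity)
  pools <- .disorder_pools(config$n_disorder)
  bg_vocab <- sprintf("fill%04d", seq_len(config$n_background))
  exp_cluster <- sum(2:6 * config$overlap_multiplicity)
  g_prob <- config$category_mix
  g_prob[["overlapping"]] <- g_prob[["overlapping"]] / exp_cluster
  g_prob <- g_prob / sum(g_prob)
  kinds <- names(config$category_mix)

  sentences <- vector("list", config$n_sentences)
  n_mentions <- 0L
  for (s in seq_len(config$n_sentences)) {
    n_groups <- sample(0:2, 1L, prob = config$groups_per_sentence)
    tokens <- .pick(bg_vocab, sample(0:3, 1L))
    mentions <- list()
    if (n_groups == 0L) {
      tokens <- .pick(bg_vocab,
                      sample(seq(config$sentence_length[1],
                                 config$sentence_length[2]), 1L))
    } else {
      for (g in seq_len(n_groups)) {
        grp <- .make_group(sample(kinds, 1L, prob = g_prob),
                           config, pools, bg_vocab)
        offset <- length(tokens)
        tokens <- c(tokens, grp$words)
        mentions <- c(mentions,
                      lapply(grp$mentions, function(ix) mention(ix + offset)))
        tokens <- c(tokens, .pick(bg_vocab, sample(1:4, 1L)))
      }
    }
    labels <- encode_sentence(tokens, mentions, scheme)
    n_mentions <- n_mentions + length(mentions)
    sentences[[s]] <- list(tokens = tokens, pos = pos_tag_rules(tokens),
                           mentions = mentions, labels = labels)
  }
  structure(list(
    sentences = sentences,
    vocabulary = list(background = bg_vocab, disorder = .pool_words(pools)),
    config = config,
    log = sprintf("generated %d sentences, %d mentions (seed %d)",
                  config$n_sentences, n_mentions, config$seed)
  ), class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus>", x$log, "\n")
  invisible(x)
}

#' Generate a synthetic word-cluster lexicon
#'
#' Stands in for distributional word clusters induced from unlabeled
#' clinical text: a deterministic assignment of every vocabulary word to
#' one of K clusters in which the disorder sub-vocabulary is concentrated
#' in a few clusters of its own, so the cluster-id feature carries signal.
#' With `purity` 1 no disorder word shares a cluster with a background
#' word; lower purity mixes that fraction of disorder words into background
#' clusters. When K equals the vocabulary size every word gets its own
#' cluster.
#'
#' @param vocab Character vector of all words.
#' @param k Number of clusters (K <= length(vocab)).
#' @param seed Integer seed.
#' @param disorder_words Subset of `vocab` to concentrate.
#' @param purity Fraction of disorder words kept in pure disorder clusters.
#' @return A [cluster_lexicon()].
#' @export
generate_cluster_lexicon <- function(vocab, k = 700L, seed = 1L,
                                     disorder_words = character(0),
                                     purity = 1) {
  vocab <- unique(vocab)
  k <- as.integer(k)
  if (k > length(vocab)) {
    stop("k must not exceed the vocabulary size", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (k == length(vocab)) {
    return(cluster_lexicon(vocab, seq_along(vocab) - 1L))
  }
  disorder_words <- intersect(disorder_words, vocab)
  n_dis <- if (length(disorder_words)) {
    min(max(1L, ceiling(length(disorder_words) / 20)), k - 1L)
  } else 0L
  ids <- integer(length(vocab))
  names(ids) <- vocab
  bg_ids <- seq.int(n_dis, k - 1L)
  dis_ids <- if (n_dis > 0L) seq.int(0L, n_dis - 1L) else integer(0)
  for (w in vocab) {
    if (w %in% disorder_words && n_dis > 0L && stats::runif(1) < purity) {
      ids[w] <- if (n_dis == 1L) dis_ids else sample(dis_ids, 1L)
    } else {
      ids[w] <- if (length(bg_ids) == 1L) bg_ids else sample(bg_ids, 1L)
    }
  }
  cluster_lexicon(vocab, ids)
}
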