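#' Does a predicted mention match a gold mention?
#'
#' Strict mode requires identical token-index sets; left match requires only
#' an equal left boundary (minimum index) and right match an equal right
#' boundary (maximum index). A strict match is always also a left and a
#' right match.
#'
#' @param pred,gold Mentions (0-based token-index sets) from one sentence.
#' @param mode One of `"strict"`, `"left"`, `"right"`.
#' @return Logical scalar.
#' @export
mention_matches <- function(pred, gold, mode = c("strict", "left", "right")) {
  mode <- match.arg(mode)
  p <- unclass(.as_mention(pred))
  g <- unclass(.as_mention(gold))
  switch(mode,
         strict = length(p) == length(g) && all(p == g),
         left = min(p) == min(g),
         right = max(p) == max(g))
}

#' Categorize a mention as contiguous, discontiguous or overlapping
#'
#' A mention is overlapping when its `[min, max]` token-span interval
#' intersects any other mention's interval in the sentence (the same
#' relation used for channel assignment); otherwise it is discontiguous if
#' it has at least one breakpoint, and contiguous if not. Overlap takes
#' precedence over discontiguity.
#'
#' @param m A mention.
#' @param others The other mentions of the same sentence (`m` itself is
#'   ignored if present).
#' @return One of `"contiguous"`, `"discontiguous"`, `"overlapping"`.
#' @export
categorize_mention <- function(m, others = list()) {
  m <- .as_mention(m)
  key <- .mention_key(m)
  for (o in others) {
    o <- .as_mention(o)
    if (.mention_key(o) == key) next
    if (.intervals_overlap(m, o)) return("overlapping")
  }
  if (breakpoints(m) >= 1L) "discontiguous" else "contiguous"
}

.f_scores <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

#' Mention-level evaluation
#'
#' Scores predictions against gold mentions sentence by sentence with
#' greedy one-to-one matching: each prediction, in order, consumes the
#' leftmost still-unmatched gold mention it matches under `mode`; leftover
#' predictions are false positives and leftover golds false negatives.
#' Counts are aggregated corpus-wide before computing precision
#' TP/(TP+FP), recall TP/(TP+FN) and F1 = 2PR/(P+R) (all defined as 0 when
#' their denominator is 0).
#'
#' @param preds,golds Lists (one element per sentence) of mention lists.
#' @param mode `"strict"`, `"left"` or `"right"`.
#' @param per_category Also break scores down by gold/predicted mention
#'   category?
#' @return Object of class `eval_report`: counts, scores, and optionally a
#'   `categories` data frame.
#' @export
evaluate_mentions <- function(preds, golds,
                              mode = c("strict", "left", "right"),
                              per_category = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(preds) == length(golds))
  cats <- c("contiguous", "discontiguous", "overlapping")
  tp <- fp <- fn <- 0L
  cat_tp <- cat_fp <- cat_fn <- stats::setNames(integer(3), cats)
  for (s in seq_along(golds)) {
    g <- lapply(golds[[s]], .as_mention)
    p <- .unique_mentions(lapply(preds[[s]], .as_mention))
    g_cat <- vapply(g, categorize_mention, character(1), others = g)
    p_cat <- vapply(p, categorize_mention, character(1), others = p)
    # golds ordered by position so "leftmost unmatched gold" is well defined
    g_order <- order(vapply(g, min, integer(1)), vapply(g, max, integer(1)))
    used <- logical(length(g))
    for (i in seq_along(p)) {
      hit <- 0L
      for (j in g_order) {
        if (!used[j] && mention_matches(p[[i]], g[[j]], mode)) {
          hit <- j
          break
        }
      }
      if (hit > 0L) {
        used[hit] <- TRUE
        tp <- tp + 1L
        cat_tp[g_cat[hit]] <- cat_tp[g_cat[hit]] + 1L
      } else {
        fp <- fp + 1L
        cat_fp[p_cat[i]] <- cat_fp[p_cat[i]] + 1L
      }
    }
    fn <- fn + sum(!used)
    for (j in which(!used)) cat_fn[g_cat[j]] <- cat_fn[g_cat[j]] + 1L
  }
  out <- .f_scores(tp, fp, fn)
  out$mode <- mode
  if (per_category) {
    out$categories <- do.call(rbind, lapply(cats, function(ct) {
      sc <- .f_scores(cat_tp[[ct]], cat_fp[[ct]], cat_fn[[ct]])
      data.frame(category = ct, tp = sc$tp, fp = sc$fp, fn = sc$fn,
                 precision = sc$precision, recall = sc$recall, f1 = sc$f1,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> mode %s: TP %d FP %d FN %d\n",
              x$mode, x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  if (!is.null(x$categories)) {
    print(x$categories, row.names = FALSE)
  }
  invisible(x)
}

.pct_table <- function(counts, labels) {
  total <- sum(counts)
  data.frame(type = labels, amount = as.integer(counts),
             percentage = if (total > 0) 100 * counts / total else
               rep(0, length(counts)),
             stringsAsFactors = FALSE)
}

#' Structural statistics of an annotated corpus
#'
#' Tabulates, with counts and percentages: mention categories
#' (contiguous / discontiguous / overlapping, with overlap taking
#' precedence); breakpoint counts over all mentions in discontiguous form
#' (including overlapping mentions that are themselves discontiguous);
#' overlap multiplicity (for each mention in an overlap cluster of k >= 2
#' mentions, its cluster size); and span lengths (1..5 and "6 or more").
#' Percentages in each table sum to 100.
#'
#' @param sentences List of sentences, each a list with `tokens` and
#'   `mentions`.
#' @return Object of class `corpus_stats`: data frames `category`,
#'   `breakpoints`, `overlap`, `span`, plus `n_mentions`.
#' @export
corpus_stats <- function(sentences) {
  cat_counts <- stats::setNames(integer(3),
                                c("contiguous", "discontiguous", "overlapping"))
  bp_counts <- stats::setNames(integer(3), c("1", "2", "3 or more"))
  ov_counts <- stats::setNames(integer(6), c(as.character(2:6), "7 or more"))
  span_counts <- stats::setNames(integer(6), c(as.character(1:5), "6 or more"))
  n_mentions <- 0L
  for (sent in sentences) {
    ms <- lapply(sent$mentions, .as_mention)
    n_mentions <- n_mentions + length(ms)
    for (i in seq_along(ms)) {
      ct <- categorize_mention(ms[[i]], ms[-i])
      cat_counts[ct] <- cat_counts[ct] + 1L
      b <- breakpoints(ms[[i]])
      if (b >= 1L) {
        bp_counts[min(b, 3L)] <- bp_counts[min(b, 3L)] + 1L
      }
      s <- span_length(ms[[i]])
      span_counts[min(s, 6L)] <- span_counts[min(s, 6L)] + 1L
    }
    for (cl in cluster_overlaps(ms)) {
      if (length(cl) >= 2L) {
        slot <- min(length(cl), 7L) - 1L
        ov_counts[slot] <- ov_counts[slot] + length(cl)
      }
    }
  }
  structure(list(
    category = .pct_table(cat_counts, names(cat_counts)),
    breakpoints = .pct_table(bp_counts, paste(names(bp_counts), "breakpoint(s)")),
    overlap = .pct_table(ov_counts,
                         paste(names(ov_counts), "mentions overlap")),
    span = .pct_table(span_counts, paste("span", names(span_counts))),
    n_mentions = n_mentions
  ), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus_stats> %d mentions\n", x$n_mentions))
  for (nm in c("category", "breakpoints", "overlap", "span")) {
    cat("--", nm, "--\n")
    tab <- x[[nm]]
    tab$percentage <- sprintf("%.2f%%", tab$percentage)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
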