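#' Construct a mention from token indices
#'
#' A mention is a non-empty set of 0-based token positions within one
#' sentence, stored as a sorted integer vector. Discontiguous mentions have
#' more than one maximal run of consecutive indices; the gaps between runs
#' are the mention's breakpoints.
#'
#' @param indices Integer vector of 0-based token positions (duplicates are
#'   collapsed).
#' @param n_tokens Optional sentence length for bounds checking.
#' @return Sorted integer vector of class `mention`.
#' @examples
#' m <- mention(c(1, 3, 6))
#' span_length(m)  # 6
#' breakpoints(m)  # 2
#' @export
mention <- function(indices, n_tokens = NULL) {
  idx <- sort(unique(as.integer(indices)))
  if (length(idx) == 0L || anyNA(idx) || any(idx < 0L)) {
    stop("a mention needs at least one non-negative token index", call. = FALSE)
  }
  if (!is.null(n_tokens) && any(idx >= n_tokens)) {
    stop("mention token index beyond sentence length", call. = FALSE)
  }
  structure(idx, class = "mention")
}

.as_mention <- function(m, n_tokens = NULL) {
  if (inherits(m, "mention") && is.null(n_tokens)) return(m)
  mention(m, n_tokens)
}

#' @export
print.mention <- function(x, ...) {
  cat(sprintf("<mention> tokens {%s} (1-based: %s), span %d, %d breakpoint(s)\n",
              paste(unclass(x), collapse = ","),
              paste(unclass(x) + 1L, collapse = ","),
              span_length(x), breakpoints(x)))
  invisible(x)
}

#' Maximal runs of consecutive token indices
#'
#' @param m A [mention()] or integer vector of token indices.
#' @return List of integer vectors, one per contiguous segment, left to
#'   right.
#' @export
mention_segments <- function(m) {
  idx <- unclass(.as_mention(m))
  split(idx, cumsum(c(1L, diff(idx) != 1L)))
}

#' Span length and breakpoint count of a mention
#'
#' The span length is the inclusive token distance from the mention's first
#' to its last token (1 for unit-length mentions). The breakpoint count is
#' the number of maximal gaps separating the mention's segments (0 for
#' contiguous mentions).
#'
#' @param m A [mention()] or integer vector of token indices.
#' @return Integer scalar.
#' @export
span_length <- function(m) {
  idx <- unclass(.as_mention(m))
  max(idx) - min(idx) + 1L
}

#' @rdname span_length
#' @export
breakpoints <- function(m) {
  length(mention_segments(m)) - 1L
}

# do the [min,max] token intervals of two mentions intersect?
.intervals_overlap <- function(a, b) {
  min(a) <= max(b) && min(b) <= max(a)
}

#' Group mentions into overlap clusters
#'
#' Two mentions overlap when their `[min, max]` token-span intervals
#' intersect — this covers token sharing and pure nesting (a mention lying
#' inside another's span without sharing a token). Clusters are the
#' connected components of this relation; every mention in a cluster must be
#' assigned a distinct channel for the sentence to be encodable.
#'
#' @param mentions List of mentions (in caller order).
#' @return List of clusters ordered by leftmost token; each cluster is an
#'   integer vector of positions into `mentions`, preserving the supplied
#'   order.
#' @export
cluster_overlaps <- function(mentions) {
  n <- length(mentions)
  if (n == 0L) return(list())
  mentions <- lapply(mentions, .as_mention)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (.intervals_overlap(mentions[[i]], mentions[[j]])) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), roots)
  starts <- vapply(clusters, function(ix) {
    min(vapply(mentions[ix], min, integer(1)))
  }, integer(1))
  unname(clusters[order(starts)])
}

#' Assign encoding channels to mentions
#'
#' Within each overlap cluster, channels 1, 2, 3, ... are handed out in the
#' supplied mention order; whenever a mention overlaps none of the earlier
#' ones the channel counter resets, so every singleton cluster uses channel
#' 1. A cluster larger than the scheme capacity cannot be encoded (widen the
#' scheme to represent more mutual overlaps).
#'
#' @param mentions List of mentions in the order they should be encoded.
#' @param scheme A [label_scheme()].
#' @return Integer vector of channels aligned with `mentions`.
#' @export
assign_channels <- function(mentions, scheme = label_scheme()) {
  .check_scheme(scheme)
  channels <- integer(length(mentions))
  for (cl in cluster_overlaps(mentions)) {
    if (length(cl) > scheme$capacity) {
      stop(sprintf(
        "overlap cluster of %d mentions exceeds scheme capacity %d",
        length(cl), scheme$capacity), call. = FALSE)
    }
    channels[cl] <- seq_along(cl)
  }
  channels
}

#' Canonical mention order
#'
#' Sorts mentions by (first token, last token). Channel assignment honors
#' the caller's order; use this helper when no particular order is intended.
#'
#' @param mentions List of mentions.
#' @return The same mentions, reordered.
#' @export
canonicalize_mentions <- function(mentions) {
  mentions <- lapply(mentions, .as_mention)
  lo <- vapply(mentions, min, integer(1))
  hi <- vapply(mentions, max, integer(1))
  mentions[order(lo, hi)]
}

# set-of-sets equality helper used throughout tests and evaluation
.mention_key <- function(m) paste(unclass(.as_mention(m)), collapse = ",")

.unique_mentions <- function(mentions) {
  mentions[!duplicated(vapply(mentions, .mention_key, character(1)))]
}
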