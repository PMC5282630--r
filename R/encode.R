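#' BILU roles of a mention's tokens
#'
#' A unit-length mention assigns role U to its only token; a longer mention
#' assigns B to its first token, L to its last and I to every other mention
#' token. Tokens outside the mention (including gap tokens inside a
#' discontiguous span) receive no role.
#'
#' @param m A [mention()] or integer vector of token indices.
#' @return Data frame with columns `index` (0-based) and `role`.
#' @export
roles_for_mention <- function(m) {
  idx <- unclass(.as_mention(m))
  if (length(idx) == 1L) {
    roles <- "U"
  } else {
    roles <- c("B", rep("I", length(idx) - 2L), "L")
  }
  data.frame(index = idx, role = roles, stringsAsFactors = FALSE)
}

#' Encode a sentence's mentions as one multi-label per token
#'
#' Assigns channels with [assign_channels()] (honoring the supplied mention
#' order within each overlap cluster), builds one sub-label per
#' (mention, token) role and integrates each token's sub-labels into a final
#' label by bitwise OR. Tokens belonging to no mention get the all-zero
#' class-O label.
#'
#' @param tokens Character vector of sentence tokens.
#' @param mentions List of mentions (0-based token-index sets) in encoding
#'   order.
#' @param scheme A [label_scheme()].
#' @return Numeric vector of final labels, one per token.
#' @examples
#' toks <- c("Abdomen", "is", "soft", ",", "nontender", ",", "nondistended",
#'           ",", "negative", "bruits", ".")
#' labs <- encode_sentence(toks, list(c(0, 9), c(0, 4), 6))
#' format_label(labs[1])  # "000000,000000,000011,000000"
#' @export
encode_sentence <- function(tokens, mentions, scheme = label_scheme()) {
  .check_scheme(scheme)
  n <- length(tokens)
  mentions <- lapply(mentions, .as_mention, n_tokens = n)
  channels <- assign_channels(mentions, scheme)
  per_token <- vector("list", n)
  for (k in seq_along(mentions)) {
    r <- roles_for_mention(mentions[[k]])
    for (j in seq_len(nrow(r))) {
      i <- r$index[j] + 1L
      per_token[[i]] <- c(per_token[[i]],
                          list(make_sublabel(r$role[j], channels[k], scheme)))
    }
  }
  vapply(per_token, function(subs) {
    if (is.null(subs)) 0 else integrate_sublabels(subs, scheme)
  }, numeric(1))
}

#' Decode a label sequence back into mentions
#'
#' Extracts every sub-label, gathers those sharing a channel (the same bit
#' rank within their region) and reads each channel as a BILOU sequence,
#' scanning left to right. Class-O gaps are permitted inside an open B...L
#' span, which is how discontiguous mentions are recovered. Malformed
#' channel sequences — possible in model predictions — are repaired rather
#' than rejected: a B left open at the end of the sentence emits what it
#' gathered; an L with no open B is treated as a unit mention; an I with no
#' open B is dropped; a second B on an open channel emits the open mention
#' and starts a new one.
#'
#' The result does not depend on which channel carried which mention: any
#' channel permutation of a valid encoding decodes to the same mention set.
#'
#' @param labels Numeric vector of final labels (one per token).
#' @param scheme A [label_scheme()].
#' @return List of mentions (sorted 0-based index vectors), ordered by first
#'   token then last token, duplicates removed.
#' @export
decode_labels <- function(labels, scheme = label_scheme()) {
  .check_scheme(scheme)
  .check_label_bits(labels, scheme)
  cap <- scheme$capacity
  found <- list()
  role_bit <- function(lab, role, ch) {
    pos <- (.role_region[[role]] - 1L) * cap + ch
    .bit_at(lab, pos) == 1
  }
  for (ch in seq_len(cap)) {
    open <- NULL
    for (i in seq_along(labels)) {
      lab <- labels[i]
      if (lab == 0) next
      if (role_bit(lab, "U", ch)) {
        found <- c(found, list(i - 1L))
      }
      if (role_bit(lab, "B", ch)) {
        if (!is.null(open)) found <- c(found, list(open))  # reopened channel
        open <- i - 1L
      }
      if (role_bit(lab, "I", ch)) {
        if (!is.null(open)) open <- c(open, i - 1L)        # else: stray I, drop
      }
      if (role_bit(lab, "L", ch)) {
        if (!is.null(open)) {
          found <- c(found, list(c(open, i - 1L)))
          open <- NULL
        } else {
          found <- c(found, list(i - 1L))                  # stray L -> unit
        }
      }
    }
    if (!is.null(open)) found <- c(found, list(open))      # dangling B
  }
  if (length(found) == 0L) return(list())
  out <- .unique_mentions(lapply(found, mention))
  canonicalize_mentions(out)
}
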