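#' Encode mentions with the BIOHD or BIOHD1234 baseline scheme
#'
#' Baseline single-tag-per-token encodings for discontiguous and overlapping
#' mentions. A head segment is a maximal token run shared by two or more
#' mentions; non-shared segments of complicated mentions are D segments, and
#' ordinary contiguous non-overlapping mentions keep plain B/I tags. The
#' `1234` variant suffixes each D segment with the direction of the segment
#' it combines with: 1 = nearest head at left, 2 = nearest non-head at left,
#' 3 = nearest head at right, 4 = nearest non-head at right (checked in that
#' priority order; a D segment with combinable segments in more than one
#' direction is flagged ambiguous).
#'
#' These schemes cannot represent every annotation: a sentence with two or
#' more head segments has no encoding, and some single-head configurations
#' do not decode back to the original mentions. `biohd_encode` audits its
#' own output by round-tripping through [biohd_decode()] and returns a
#' representability report instead of usable tags when the structure is not
#' representable.
#'
#' @param tokens Character vector of sentence tokens.
#' @param mentions List of mentions (0-based token-index sets).
#' @param variant `"plain"` (BIOHD) or `"1234"` (BIOHD1234).
#' @return Object of class `biohd_encoding`: `encodable` flag, `tags`
#'   (character vector, NULL when unencodable), `reason`, `ambiguous`.
#' @export
biohd_encode <- function(tokens, mentions, variant = c("plain", "1234")) {
  variant <- match.arg(variant)
  n <- length(tokens)
  mentions <- lapply(mentions, .as_mention, n_tokens = n)
  report <- function(reason, tags = NULL, ambiguous = FALSE) {
    structure(list(encodable = is.null(reason) || !nzchar(reason),
                   tags = tags, reason = reason, ambiguous = ambiguous,
                   variant = variant),
              class = "biohd_encoding")
  }
  count <- integer(n)
  for (m in mentions) count[m + 1L] <- count[m + 1L] + 1L

  head_tok <- count >= 2L
  head_runs <- .bool_runs(head_tok)
  if (length(head_runs) >= 2L) {
    return(report("two or more head segments"))
  }

  simple <- vapply(mentions, function(m) {
    breakpoints(m) == 0L && all(count[m + 1L] == 1L)
  }, logical(1))

  tags <- rep("O", n)
  for (hr in head_runs) {
    tags[hr] <- c("B-H", rep("I-H", length(hr) - 1L))
  }
  for (m in mentions[simple]) {
    tags[m + 1L] <- c("B", rep("I", length(m)))[seq_along(m)]
  }

  # D runs: maximal consecutive single-mention tokens of non-simple mentions
  ambiguous <- FALSE
  for (k in which(!simple)) {
    m <- mentions[[k]]
    d_idx <- m[count[m + 1L] == 1L]
    if (length(d_idx) == 0L) next  # mention fully inside the head run
    for (seg in mention_segments(mention(d_idx))) {
      code <- ""
      if (variant == "1234") {
        has_head_in_m <- any(count[m + 1L] >= 2L)
        head_left <- has_head_in_m && length(head_runs) &&
          (min(head_runs[[1]]) - 1L) < min(seg)
        head_right <- has_head_in_m && length(head_runs) &&
          (min(head_runs[[1]]) - 1L) > max(seg)
        other <- setdiff(d_idx, seg)
        d_left <- length(other) > 0L && any(other < min(seg))
        d_right <- length(other) > 0L && any(other > max(seg))
        dirs <- c(head_left, d_left, head_right, d_right)
        if (!any(dirs)) {
          return(report("D segment with nothing to combine with"))
        }
        if (sum(dirs) > 1L) ambiguous <- TRUE
        code <- as.character(which(dirs)[1])
      }
      pos <- seg + 1L
      tags[pos] <- c(paste0("B-D", code),
                     rep(paste0("I-D", code), length(pos) - 1L))
    }
  }

  # round-trip audit: the tags must decode back to the annotation
  got <- biohd_decode(tags, variant)
  if (!.same_mention_set(got, mentions)) {
    return(report("tag sequence does not decode back to the annotation",
                  ambiguous = ambiguous))
  }
  report(NULL, tags = tags, ambiguous = ambiguous)
}

#' @export
print.biohd_encoding <- function(x, ...) {
  if (x$encodable) {
    cat(sprintf("<biohd_encoding> (%s) %s%s\n", x$variant,
                paste(x$tags, collapse = " "),
                if (x$ambiguous) " [ambiguous combination direction]" else ""))
  } else {
    cat(sprintf("<biohd_encoding> (%s) unrepresentable: %s\n",
                x$variant, x$reason))
  }
  invisible(x)
}

# maximal runs of TRUE, as 1-based index vectors
.bool_runs <- function(flag) {
  if (!any(flag)) return(list())
  idx <- which(flag)
  split(idx, cumsum(c(1L, diff(idx) != 1L)))
}

.same_mention_set <- function(a, b) {
  setequal(vapply(a, .mention_key, character(1)),
           vapply(b, .mention_key, character(1)))
}

# parse a BIOHD tag sequence into runs: list(kind, code, idx (1-based))
.biohd_runs <- function(tags) {
  kind_of <- function(tag) {
    if (tag == "O") return(c("O", ""))
    if (tag %in% c("B", "I")) return(c("plain", ""))
    if (tag %in% c("B-H", "I-H")) return(c("H", ""))
    m <- regmatches(tag, regexec("^([BI])-D([1-4]?)$", tag))[[1]]
    if (length(m)) return(c("D", m[3]))
    stop(sprintf("malformed BIOHD tag \"%s\"", tag), call. = FALSE)
  }
  runs <- list()
  cur <- NULL
  for (i in seq_along(tags)) {
    k <- kind_of(tags[i])
    begin <- startsWith(tags[i], "B") || k[1] == "O"
    if (!is.null(cur) && !begin && cur$kind == k[1] && cur$code == k[2]) {
      cur$idx <- c(cur$idx, i)
    } else {
      if (!is.null(cur) && cur$kind != "O") runs <- c(runs, list(cur))
      cur <- list(kind = k[1], code = k[2], idx = i)
    }
  }
  if (!is.null(cur) && cur$kind != "O") runs <- c(runs, list(cur))
  runs
}

#' Decode a BIOHD(1234) tag sequence into mentions
#'
#' Plain B/I runs decode conventionally. D segments combine with the head
#' segment (plain variant: the nearest head; with no head in the sentence,
#' consecutive D segments combine with each other) or per their direction
#' code (1234 variant). Malformed structures are repaired rather than
#' rejected: a D segment with nothing to combine with becomes its own
#' mention, and an unattached head segment is emitted standalone.
#'
#' @param tags Character vector of BIOHD(1234) tags.
#' @param variant `"plain"` or `"1234"`.
#' @return List of mentions (sorted 0-based index vectors).
#' @export
biohd_decode <- function(tags, variant = c("plain", "1234")) {
  variant <- match.arg(variant)
  runs <- .biohd_runs(tags)
  out <- list()
  head_runs <- Filter(function(r) r$kind == "H", runs)
  d_runs <- Filter(function(r) r$kind == "D", runs)
  for (r in Filter(function(r) r$kind == "plain", runs)) {
    out <- c(out, list(r$idx - 1L))
  }
  head_idx <- if (length(head_runs)) head_runs[[1]]$idx else NULL
  head_used <- FALSE
  if (length(d_runs)) {
    nd <- length(d_runs)
    group <- seq_len(nd)      # union-find over D runs
    attach_head <- logical(nd)
    find <- function(i) { while (group[i] != i) i <- group[i]; i }
    starts <- vapply(d_runs, function(r) min(r$idx), integer(1))
    for (i in seq_len(nd)) {
      code <- d_runs[[i]]$code
      if (variant == "plain" || code == "") {
        if (!is.null(head_idx)) {
          attach_head[i] <- TRUE
        } else if (i > 1L) {
          group[find(i)] <- find(i - 1L)   # chain neighbouring D segments
        }
      } else if (code %in% c("1", "3")) {
        if (!is.null(head_idx)) attach_head[i] <- TRUE
        # no head anywhere: leave standalone (repair)
      } else {
        cand <- if (code == "2") which(starts < starts[i]) else
          which(starts > starts[i])
        if (length(cand)) {
          j <- cand[which.min(abs(starts[cand] - starts[i]))]
          group[find(i)] <- find(j)
        }
      }
    }
    roots <- vapply(seq_len(nd), find, integer(1))
    for (g in unique(roots)) {
      members <- which(roots == g)
      toks <- sort(unique(unlist(lapply(d_runs[members], `[[`, "idx"))))
      if (any(attach_head[members]) && !is.null(head_idx)) {
        toks <- sort(unique(c(toks, head_idx)))
        head_used <- TRUE
      }
      out <- c(out, list(toks - 1L))
    }
  }
  if (!is.null(head_idx) && !head_used) {
    out <- c(out, list(head_idx - 1L))
  }
  if (length(out) == 0L) return(list())
  canonicalize_mentions(.unique_mentions(lapply(out, mention)))
}

#' Audit baseline representability over a corpus
#'
#' Runs [biohd_encode()] on every sentence and reports which annotations the
#' baseline scheme can represent, alongside whether the multi-label scheme
#' round-trips the same sentence (it does whenever no overlap cluster
#' exceeds the scheme capacity).
#'
#' @param sentences List of sentences, each a list with elements `tokens`
#'   and `mentions`.
#' @param variant `"plain"` or `"1234"`.
#' @param scheme A [label_scheme()] for the multi-label comparison.
#' @return Data frame with columns `sentence`, `encodable`, `reason`,
#'   `ambiguous`, `multilabel_ok`.
#' @export
audit_baseline <- function(sentences, variant = c("plain", "1234"),
                           scheme = label_scheme()) {
  variant <- match.arg(variant)
  rows <- lapply(seq_along(sentences), function(s) {
    sent <- sentences[[s]]
    enc <- biohd_encode(sent$tokens, sent$mentions, variant)
    ml_ok <- tryCatch({
      labs <- encode_sentence(sent$tokens, sent$mentions, scheme)
      .same_mention_set(decode_labels(labs, scheme),
                        lapply(sent$mentions, .as_mention))
    }, error = function(e) FALSE)
    data.frame(sentence = s, encodable = enc$encodable,
               reason = if (is.null(enc$reason)) "" else enc$reason,
               ambiguous = enc$ambiguous, multilabel_ok = ml_ok,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
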