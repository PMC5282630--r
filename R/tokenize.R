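#' Tokenize clinical-style text
#'
#' Whitespace tokenization followed by detachment of leading and trailing
#' punctuation into their own tokens. Internal punctuation is preserved, so
#' "NT/ND" and "Addison's" stay single tokens; a trailing period is kept
#' when the remainder still contains one, so the abbreviation "t.i.d." stays
#' intact while a sentence-final "thickened." splits into "thickened" and
#' ".". Character offsets are 0-based half-open into the input string.
#'
#' @param text A single string (one sentence or line).
#' @return Data frame with columns `token`, `start`, `end`.
#' @examples
#' tokenize_clinical("The tricuspid valve leaflets are mildly thickened.")$token
#' @export
tokenize_clinical <- function(text) {
  stopifnot(length(text) == 1L)
  out_tok <- character(0)
  out_start <- integer(0)
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (w in seq_along(starts)) {
      chunk <- substr(text, starts[w], starts[w] + lens[w] - 1L)
      base <- starts[w] - 1L  # 0-based offset of chunk start
      chars <- strsplit(chunk, "")[[1]]
      lo <- 1L
      hi <- length(chars)
      lead <- character(0)
      trail <- character(0)
      while (lo < hi && grepl("[[:punct:]]", chars[lo])) {
        lead <- c(lead, chars[lo]); lo <- lo + 1L
      }
      while (hi > lo && grepl("[[:punct:]]", chars[hi])) {
        core <- paste(chars[lo:(hi - 1L)], collapse = "")
        # keep a trailing period on abbreviation-like tokens ("t.i.d.")
        if (chars[hi] == "." && grepl("\\.", core)) break
        trail <- c(chars[hi], trail); hi <- hi - 1L
      }
      pieces <- c(lead, paste(chars[lo:hi], collapse = ""), trail)
      offs <- base + c(seq_along(lead) - 1L, lo - 1L,
                       hi - 1L + seq_along(trail))
      out_tok <- c(out_tok, pieces)
      out_start <- c(out_start, offs)
    }
  }
  data.frame(token = out_tok,
             start = out_start,
             end = out_start + nchar(out_tok),
             stringsAsFactors = FALSE)
}

.pos_closed_class <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", no = "DT",
  of = "IN", "in" = "IN", on = "IN", at = "IN", to = "IN", with = "IN",
  within = "IN", without = "IN", "for" = "IN", by = "IN", after = "IN",
  upon = "IN", and = "CC", or = "CC", but = "CC", is = "VBZ", are = "VBP",
  was = "VBD", were = "VBD", be = "VB", been = "VBN", has = "VBZ",
  have = "VBP", had = "VBD", not = "RB", there = "EX", he = "PRP",
  she = "PRP", it = "PRP", patient = "NN"
)

#' Rule-based part-of-speech tagger
#'
#' A small deterministic tagger used as the default POS source: a
#' closed-class lexicon, digit and punctuation rules, then suffix rules
#' (-ed/-en past participles, -ing gerunds, -ly adverbs, common adjectival
#' suffixes, plural -s), defaulting to NN. It exists so the full feature set
#' is exercisable offline; corpora may instead carry their own POS column,
#' and any `function(tokens) -> tags` can be plugged in wherever a tagger
#' argument is accepted.
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of Penn-style coarse tags.
#' @export
pos_tag_rules <- function(tokens) {
  vapply(tokens, function(w) {
    lw <- tolower(w)
    if (!is.na(.pos_closed_class[lw])) return(unname(.pos_closed_class[lw]))
    if (grepl("^[[:punct:]]+$", w)) return(".")
    if (grepl("^[0-9.,/%-]*[0-9][0-9.,/%-]*$", w)) return("CD")
    if (grepl("(ed|en)$", lw) && nchar(lw) > 3L) return("VBN")
    if (grepl("ing$", lw) && nchar(lw) > 4L) return("VBG")
    if (grepl("ly$", lw) && nchar(lw) > 3L) return("RB")
    if (grepl("(ous|ive|al|ic|ary|able)$", lw) && nchar(lw) > 4L) return("JJ")
    if (grepl("s$", lw) && nchar(lw) > 3L) return("NNS")
    "NN"
  }, character(1), USE.NAMES = FALSE)
}
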