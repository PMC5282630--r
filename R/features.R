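#' Capitalization normal form
#'
#' Uppercases every alphabetic character, leaving digits and punctuation
#' unchanged, so spelling variants like "t.i.d." and "T.I.D." share one
#' feature value.
#'
#' @param word Character vector of tokens.
#' @return Character vector.
#' @export
capitalization <- function(word) {
  stopifnot(all(nzchar(word)))
  toupper(word)
}

#' Case pattern of a token
#'
#' Replaces every uppercase letter with "A", every lowercase letter with "a"
#' and every digit with "0"; other characters pass through. Tokens of the
#' same semantic type (e.g. "C-polyp", "E-polyp") often share a pattern.
#'
#' @param word Character vector of tokens.
#' @return Character vector of patterns.
#' @examples
#' case_pattern("C-polyp")  # "A-aaaaa"
#' @export
case_pattern <- function(word) {
  stopifnot(all(nzchar(word)))
  x <- gsub("[[:upper:]]", "A", word)
  x <- gsub("[[:lower:]]", "a", x)
  gsub("[0-9]", "0", x)
}

#' Word-cluster lexicon
#'
#' Wraps a word-to-cluster-id map (cluster ids `0..K-1`, serial numbers of
#' distributional word clusters). Lookup lowercases the word first, since
#' cluster induction on raw clinical text is case-noisy; out-of-vocabulary
#' words map to the sentinel id -1.
#'
#' @param words Character vector of vocabulary words.
#' @param ids Integer cluster ids aligned with `words`.
#' @return Object of class `cluster_lexicon`.
#' @export
cluster_lexicon <- function(words, ids) {
  stopifnot(length(words) == length(ids), !anyNA(ids))
  ids <- as.integer(ids)
  if (any(ids < 0L)) stop("cluster ids must be non-negative", call. = FALSE)
  map <- ids
  names(map) <- tolower(words)
  map <- map[!duplicated(names(map))]
  structure(list(map = map, k = max(ids) + 1L), class = "cluster_lexicon")
}

#' @export
print.cluster_lexicon <- function(x, ...) {
  cat(sprintf("<cluster_lexicon> %d words, %d clusters\n",
              length(x$map), x$k))
  invisible(x)
}

#' @rdname cluster_lexicon
#' @param word Character vector of tokens to look up.
#' @param lex A `cluster_lexicon`.
#' @export
cluster_id <- function(word, lex) {
  stopifnot(inherits(lex, "cluster_lexicon"))
  id <- unname(lex$map[tolower(word)])
  id[is.na(id)] <- -1L
  id
}

#' Feature-extraction configuration
#'
#' Window sizes (odd, centered on the focus token) for each feature family:
#' bag of words (5), part of speech (7), capitalization normal form (5),
#' case pattern (3) and word-cluster id (3).
#'
#' @param bow,pos,cap,shape,cluster Odd window sizes.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(bow = 5L, pos = 7L, cap = 5L,
                           shape = 3L, cluster = 3L) {
  sizes <- c(bow = bow, pos = pos, cap = cap, shape = shape, cluster = cluster)
  if (any(sizes %% 2L != 1L) || any(sizes < 1L)) {
    stop("window sizes must be odd and positive", call. = FALSE)
  }
  structure(as.list(sizes), class = "feature_config")
}

.window_offsets <- function(size) seq.int(-(size %/% 2L), size %/% 2L)

# values for one family across one window; out-of-sentence positions get
# boundary sentinels
.window_values <- function(values, i, size, left = "<s>", right = "</s>") {
  n <- length(values)
  vapply(.window_offsets(size), function(d) {
    j <- i + d
    if (j < 1L) left else if (j > n) right else values[j]
  }, character(1))
}

#' Token-level feature map
#'
#' Emits the sparse binary feature keys for one token position: word
#' identities, POS tags, capitalization forms, case patterns and cluster
#' ids, each over its configured window centered at `i`. Keys are
#' namespaced by family and window offset (e.g. `"bow[-2]=valve"`);
#' positions beyond the sentence edges yield boundary sentinels. Extraction
#' is a pure function of its arguments.
#'
#' @param tokens Character vector of sentence tokens.
#' @param i Focus position (1-based).
#' @param lex A [cluster_lexicon()] (or NULL to emit OOV ids throughout).
#' @param config A [feature_config()].
#' @param pos Character vector of POS tags; defaults to [pos_tag_rules()].
#' @return Character vector of feature keys (length 23 at the default
#'   windows).
#' @export
window_features <- function(tokens, i, lex = NULL,
                            config = feature_config(),
                            pos = NULL) {
  stopifnot(inherits(config, "feature_config"),
            i >= 1L, i <= length(tokens))
  if (is.null(pos)) pos <- pos_tag_rules(tokens)
  stopifnot(length(pos) == length(tokens))
  clu <- if (is.null(lex)) rep("-1", length(tokens)) else
    as.character(cluster_id(tokens, lex))
  fam <- list(
    bow = list(tokens, config$bow),
    pos = list(pos, config$pos),
    cap = list(capitalization(tokens), config$cap),
    shape = list(case_pattern(tokens), config$shape),
    clu = list(clu, config$cluster)
  )
  unlist(lapply(names(fam), function(f) {
    vals <- .window_values(fam[[f]][[1]], i, fam[[f]][[2]])
    offs <- .window_offsets(fam[[f]][[2]])
    sprintf("%s[%+d]=%s", f, offs, vals)
  }), use.names = FALSE)
}
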