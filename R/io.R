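#' Read and write BRAT-dialect standoff annotation
#'
#' A standoff document is a plain-text file (`.txt`, one sentence per line)
#' plus an annotation file (`.ann`) with one text-bound annotation per
#' line: `T<id>\t<type> <start> <end>[;<start> <end>...]\t<surface>`.
#' Character offsets are 0-based half-open into the text file;
#' discontinuous mentions carry semicolon-separated fragments whose surface
#' strings are joined with a single space. Reading verifies every
#' fragment's surface text against the offsets and fails naming the
#' offending annotation id.
#'
#' @param path Path to the `.ann` or `.txt` file (the sibling is derived).
#' @return A `standoff_document`: `text` and `annotations` (list of
#'   `id`, `type`, `fragments` two-column matrix, `text`).
#' @export
read_standoff <- function(path) {
  stem <- sub("\\.(ann|txt)$", "", path)
  txt_path <- paste0(stem, ".txt")
  ann_path <- paste0(stem, ".ann")
  if (!file.exists(txt_path) || !file.exists(ann_path)) {
    stop("need both ", txt_path, " and ", ann_path, call. = FALSE)
  }
  text <- paste(readLines(txt_path, warn = FALSE), collapse = "\n")
  anns <- list()
  for (line in readLines(ann_path, warn = FALSE)) {
    if (!nzchar(line) || startsWith(line, "#")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L || !startsWith(parts[1], "T")) {
      stop("malformed annotation line: ", line, call. = FALSE)
    }
    head_bits <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    type <- head_bits[1]
    frag_str <- paste(head_bits[-1], collapse = " ")
    frags <- do.call(rbind, lapply(
      strsplit(frag_str, ";", fixed = TRUE)[[1]],
      function(f) as.integer(strsplit(trimws(f), " ")[[1]])))
    if (ncol(frags) != 2L || any(is.na(frags)) ||
        any(frags[, 2] <= frags[, 1])) {
      stop("bad fragment offsets in annotation ", parts[1], call. = FALSE)
    }
    frags <- frags[order(frags[, 1]), , drop = FALSE]
    surfaces <- apply(frags, 1, function(f) {
      substr(text, f[1] + 1L, f[2])
    })
    if (paste(surfaces, collapse = " ") != parts[3]) {
      stop(sprintf(
        "annotation %s: surface text \"%s\" does not match offsets (\"%s\")",
        parts[1], parts[3], paste(surfaces, collapse = " ")), call. = FALSE)
    }
    anns <- c(anns, list(list(id = parts[1], type = type,
                              fragments = frags, text = parts[3])))
  }
  structure(list(text = text, annotations = anns),
            class = "standoff_document")
}

#' @rdname read_standoff
#' @param doc A `standoff_document`.
#' @export
write_standoff <- function(doc, path) {
  stopifnot(inherits(doc, "standoff_document"))
  stem <- sub("\\.(ann|txt)$", "", path)
  writeLines(strsplit(doc$text, "\n", fixed = TRUE)[[1]],
             paste0(stem, ".txt"))
  lines <- vapply(doc$annotations, function(a) {
    frag_str <- paste(apply(a$fragments, 1, paste, collapse = " "),
                      collapse = ";")
    sprintf("%s\t%s %s\t%s", a$id, a$type, frag_str, a$text)
  }, character(1))
  writeLines(lines, paste0(stem, ".ann"))
  invisible(path)
}

#' Align a standoff document to tokenized sentences
#'
#' Splits the text into lines (one sentence each), tokenizes every line
#' with [tokenize_clinical()] and maps each annotation fragment to token
#' indices under a strict alignment check: every fragment must start at a
#' token start and end at a token end within a single line, otherwise an
#' error names the annotation.
#'
#' @param doc A `standoff_document`.
#' @return List of sentences (`tokens`, `mentions`); mentions are 0-based
#'   token-index sets.
#' @export
standoff_to_sentences <- function(doc) {
  stopifnot(inherits(doc, "standoff_document"))
  lines <- strsplit(doc$text, "\n", fixed = TRUE)[[1]]
  line_start <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]
  toks <- lapply(lines, tokenize_clinical)
  sentences <- lapply(toks, function(tt) list(tokens = tt$token,
                                              mentions = list()))
  for (a in doc$annotations) {
    s <- findInterval(a$fragments[1, 1], line_start)
    base <- line_start[s]
    tt <- toks[[s]]
    idx <- integer(0)
    for (r in seq_len(nrow(a$fragments))) {
      lo <- a$fragments[r, 1] - base
      hi <- a$fragments[r, 2] - base
      if (findInterval(a$fragments[r, 1], line_start) != s) {
        stop("annotation ", a$id, " spans multiple sentences", call. = FALSE)
      }
      first <- which(tt$start == lo)
      last <- which(tt$end == hi)
      if (length(first) != 1L || length(last) != 1L || last < first) {
        stop(sprintf(
          "annotation %s: fragment [%d,%d) does not align with token boundaries",
          a$id, a$fragments[r, 1], a$fragments[r, 2]), call. = FALSE)
      }
      idx <- c(idx, seq(first, last) - 1L)
    }
    sentences[[s]]$mentions <- c(sentences[[s]]$mentions,
                                 list(mention(idx, length(tt$token))))
  }
  sentences
}

#' Build a standoff document from tokenized sentences
#'
#' Reconstructs the text as space-joined tokens (one sentence per line) and
#' emits one annotation per mention, with one fragment per contiguous
#' mention segment.
#'
#' @param sentences List of sentences with `tokens` and `mentions`.
#' @param type Annotation type string.
#' @return A `standoff_document`.
#' @export
sentences_to_standoff <- function(sentences, type = "Disorder") {
  lines <- vapply(sentences, function(s) paste(s$tokens, collapse = " "),
                  character(1))
  line_start <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]
  anns <- list()
  n <- 0L
  for (s in seq_along(sentences)) {
    toks <- sentences[[s]]$tokens
    starts <- line_start[s] +
      c(0L, cumsum(nchar(toks) + 1L))[seq_along(toks)]
    ends <- starts + nchar(toks)
    for (m in sentences[[s]]$mentions) {
      n <- n + 1L
      segs <- mention_segments(m)
      frags <- do.call(rbind, lapply(segs, function(seg) {
        c(starts[min(seg) + 1L], ends[max(seg) + 1L])
      }))
      surface <- paste(vapply(segs, function(seg) {
        paste(toks[seg + 1L], collapse = " ")
      }, character(1)), collapse = " ")
      anns <- c(anns, list(list(id = paste0("T", n), type = type,
                                fragments = frags, text = surface)))
    }
  }
  structure(list(text = paste(lines, collapse = "\n"), annotations = anns),
            class = "standoff_document")
}

#' Read and write the CoNLL-style token/label format
#'
#' Tab-separated columns `token`, `pos`, `gold` decimal label, and
#' optionally `pred` decimal label and the grouped bit string of the gold
#' label; sentences are separated by blank lines and `#` lines are
#' comments. Decimal labels are validated against the scheme width; ragged
#' rows raise a parse error with the line number.
#'
#' @param path File path.
#' @param scheme A [label_scheme()].
#' @return List of sentences: `tokens`, `pos`, `labels`, optional `pred`.
#' @export
read_conll <- function(path, scheme = label_scheme()) {
  lines <- readLines(path, warn = FALSE)
  sentences <- list()
  rows <- list()
  ncol_seen <- NA_integer_
  flush <- function() {
    if (length(rows) == 0L) return()
    m <- do.call(rbind, rows)
    sent <- list(tokens = m[, 1], pos = m[, 2],
                 labels = as.numeric(m[, 3]))
    .check_label_bits(sent$labels, scheme)
    if (ncol(m) >= 4L && !any(grepl(",", m[, 4], fixed = TRUE))) {
      # a comma-grouped 4th column is the bit-string rendering, not pred
      sent$pred <- as.numeric(m[, 4])
      .check_label_bits(sent$pred, scheme)
    }
    sentences[[length(sentences) + 1L]] <<- sent
    rows <<- list()
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (startsWith(line, "#")) next
    if (!nzchar(trimws(line))) { flush(); next }
    cells <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cells) < 3L) {
      stop(sprintf("line %d: expected at least 3 tab-separated columns", i),
           call. = FALSE)
    }
    if (is.na(ncol_seen)) ncol_seen <- length(cells)
    if (length(cells) != ncol_seen) {
      stop(sprintf("line %d: ragged row (%d columns, expected %d)",
                   i, length(cells), ncol_seen), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- cells
  }
  flush()
  sentences
}

#' @rdname read_conll
#' @param sentences List of sentences with `tokens`, `pos` (optional),
#'   `labels`, optional `pred`.
#' @param bits Include a grouped bit-string column for the gold label?
#' @export
write_conll <- function(sentences, path, scheme = label_scheme(),
                        bits = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# token<TAB>pos<TAB>gold[<TAB>pred][<TAB>bits]; 0-based tokens",
             con)
  for (s in sentences) {
    pos <- if (is.null(s$pos)) pos_tag_rules(s$tokens) else s$pos
    .check_label_bits(s$labels, scheme)
    cols <- list(s$tokens, pos, format(s$labels, scientific = FALSE,
                                       trim = TRUE))
    if (!is.null(s$pred)) {
      cols <- c(cols, list(format(s$pred, scientific = FALSE, trim = TRUE)))
    }
    if (bits) cols <- c(cols, list(format_label(s$labels, scheme)))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read and write a word-cluster lexicon TSV
#'
#' Two tab-separated columns, word and integer cluster id, UTF-8.
#'
#' @param path File path.
#' @return `read_cluster_lexicon` returns a [cluster_lexicon()].
#' @export
read_cluster_lexicon <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, col.names = c("word", "id"),
                           colClasses = c("character", "integer"),
                           quote = "", comment.char = "#")
  cluster_lexicon(tab$word, tab$id)
}

#' @rdname read_cluster_lexicon
#' @param lex A [cluster_lexicon()].
#' @export
write_cluster_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "cluster_lexicon"))
  utils::write.table(
    data.frame(word = names(lex$map), id = unname(lex$map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}
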