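#' Multi-label tagging scheme configuration
#'
#' A scheme bundles the channel capacity (how many mutually overlapping
#' mentions one sentence may carry) with the derived label width. Labels are
#' unsigned binary numbers of `4 * capacity` bits split into four regions,
#' one per BILU role. At the default capacity of 6 a label is 24 bits wide:
#' bits 1-6 (from the right) are the U region, 7-12 the B region, 13-18 the
#' L region and 19-24 the I region; channel i occupies the i-th bit of each
#' region. A label with no set bit is class O; set bits confined to one
#' region give class U/B/L/I; set bits in two or more regions give class C
#' (a token playing several roles at once).
#'
#' @param capacity Maximum number of mutually overlapping mentions that can
#'   be encoded (width of each bit region). Default 6; values up to 13 are
#'   supported (labels are stored as doubles and must stay exactly
#'   representable).
#' @return An object of class `label_scheme` with elements `capacity` and
#'   `width`.
#' @examples
#' sch <- label_scheme()
#' sch$width  # 24
#' @export
label_scheme <- function(capacity = 6L) {
  capacity <- as.integer(capacity)
  if (is.na(capacity) || capacity < 1L || capacity > 13L) {
    stop("`capacity` must be an integer between 1 and 13", call. = FALSE)
  }
  structure(list(capacity = capacity, width = 4L * capacity),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme> capacity %d, width %d bits, classes U/B/I/L/O/C\n",
              x$capacity, x$width))
  invisible(x)
}

# role -> region index (1-based from the right); region k occupies bits
# (k-1)*capacity + 1 .. k*capacity
.role_region <- c(U = 1L, B = 2L, L = 3L, I = 4L)
.region_role <- c("U", "B", "L", "I")

.check_scheme <- function(scheme) {
  if (!inherits(scheme, "label_scheme")) {
    stop("`scheme` must be a label_scheme object", call. = FALSE)
  }
  scheme
}

.check_label_bits <- function(bits, scheme) {
  if (any(is.na(bits)) || any(bits < 0) || any(bits >= 2^scheme$width) ||
      any(bits != floor(bits))) {
    stop(sprintf("labels must be integers in [0, 2^%d)", scheme$width),
         call. = FALSE)
  }
  bits
}

# 0/1 value of bit `pos` (1-based from the right); vectorized over x
.bit_at <- function(x, pos) (x %/% 2^(pos - 1)) %% 2

# positions (ascending) of set bits in a single label
.set_bits <- function(x, width) {
  pos <- seq_len(width)
  pos[.bit_at(x, pos) == 1]
}

#' Construct a sub-label
#'
#' A sub-label records one role of one token in one mention: a label-width
#' binary value with exactly one set bit, at the position selected by the
#' (role, channel) pair. Role O never yields a sub-label (outside tokens
#' contribute no bits), and class C has no sub-labels (it only arises when
#' several sub-labels are integrated).
#'
#' @param role One of "U", "B", "I", "L".
#' @param channel Channel index in `1:capacity`, distinguishing overlapping
#'   mentions.
#' @param scheme A [label_scheme()].
#' @return An object of class `sublabel` with fields `role`, `channel`,
#'   `bits`.
#' @examples
#' format_label(make_sublabel("B", 1)$bits)  # "000000,000000,000001,000000"
#' @export
make_sublabel <- function(role, channel, scheme = label_scheme()) {
  .check_scheme(scheme)
  if (length(role) != 1L || !role %in% c("U", "B", "I", "L")) {
    stop("`role` must be one of \"U\", \"B\", \"I\", \"L\" (never \"O\")",
         call. = FALSE)
  }
  channel <- as.integer(channel)
  if (length(channel) != 1L || is.na(channel) ||
      channel < 1L || channel > scheme$capacity) {
    stop(sprintf("`channel` must lie in 1..%d (scheme capacity exceeded)",
                 scheme$capacity), call. = FALSE)
  }
  region <- .role_region[[role]]
  pos <- (region - 1L) * scheme$capacity + channel
  structure(list(role = role, channel = channel, bits = 2^(pos - 1)),
            class = "sublabel")
}

#' @export
print.sublabel <- function(x, ...) {
  cat(sprintf("<sublabel> role %s, channel %d: %s\n",
              x$role, x$channel, format_label(x$bits)))
  invisible(x)
}

#' Integrate sub-labels into a final label
#'
#' Bitwise OR of the sub-labels' bit patterns. The empty set integrates to
#' the all-zero class-O label. Integration is commutative, associative and
#' idempotent.
#'
#' @param subs A list of `sublabel` objects (or a numeric vector of
#'   single-bit patterns).
#' @param scheme A [label_scheme()].
#' @return A numeric final label.
#' @export
integrate_sublabels <- function(subs, scheme = label_scheme()) {
  .check_scheme(scheme)
  if (is.list(subs)) {
    subs <- vapply(subs, function(s) {
      if (inherits(s, "sublabel")) s$bits else as.numeric(s)
    }, numeric(1))
  }
  if (length(subs) == 0L) return(0)
  .check_label_bits(subs, scheme)
  pos <- unique(unlist(lapply(subs, .set_bits, width = scheme$width)))
  sum(2^(pos - 1))
}

#' Extract sub-labels from a final label
#'
#' Scans every bit of the final label and emits one single-bit sub-label per
#' set bit (bitwise AND masking), in ascending bit position. The inverse of
#' [integrate_sublabels()].
#'
#' @param bits A final label (single numeric value).
#' @param scheme A [label_scheme()].
#' @return A list of `sublabel` objects; empty for a class-O label.
#' @export
extract_sublabels <- function(bits, scheme = label_scheme()) {
  .check_scheme(scheme)
  stopifnot(length(bits) == 1L)
  .check_label_bits(bits, scheme)
  lapply(.set_bits(bits, scheme$width), function(pos) {
    region <- (pos - 1L) %/% scheme$capacity + 1L
    channel <- (pos - 1L) %% scheme$capacity + 1L
    make_sublabel(.region_role[region], channel, scheme)
  })
}

#' Classify a final label
#'
#' Returns "O" for the all-zero label, the region's role letter when every
#' set bit lies in a single region, and "C" when set bits occupy two or more
#' regions. Vectorized over `bits`.
#'
#' @param bits Numeric vector of final labels.
#' @param scheme A [label_scheme()].
#' @return Character vector in `c("U","B","I","L","O","C")`.
#' @examples
#' classify_label(parse_label("000000,000000,000101,000000"))  # "B"
#' @export
classify_label <- function(bits, scheme = label_scheme()) {
  .check_scheme(scheme)
  .check_label_bits(bits, scheme)
  cap <- scheme$capacity
  base <- 2^cap
  present <- matrix(FALSE, length(bits), 4L)
  for (k in 1:4) present[, k] <- (bits %/% base^(k - 1)) %% base > 0
  n <- rowSums(present)
  out <- rep("O", length(bits))
  out[n >= 2] <- "C"
  one <- which(n == 1)
  if (length(one)) {
    out[one] <- .region_role[max.col(present[one, , drop = FALSE],
                                     ties.method = "first")]
  }
  out
}

#' Render a label as a grouped bit string
#'
#' Formats a label as four comma-separated groups of `capacity` bits with
#' the I region leftmost and the U region rightmost, e.g.
#' `"000000,000000,000011,000000"` for a token beginning two overlapping
#' mentions.
#'
#' @param bits Numeric vector of labels.
#' @param scheme A [label_scheme()].
#' @return Character vector of grouped bit strings.
#' @export
format_label <- function(bits, scheme = label_scheme()) {
  .check_scheme(scheme)
  .check_label_bits(bits, scheme)
  cap <- scheme$capacity
  vapply(bits, function(x) {
    groups <- vapply(4:1, function(k) {
      chunk <- (x %/% 2^((k - 1L) * cap)) %% 2^cap
      paste(rev(.bit_at(chunk, seq_len(cap))), collapse = "")
    }, character(1))
    paste(groups, collapse = ",")
  }, character(1))
}

#' Parse a grouped bit string back into a label
#'
#' Accepts the comma-grouped rendering of [format_label()] (commas and
#' spaces are ignored). The string must contain exactly `width` binary
#' digits.
#'
#' @param x Character vector of bit strings.
#' @param scheme A [label_scheme()].
#' @return Numeric vector of labels.
#' @export
parse_label <- function(x, scheme = label_scheme()) {
  .check_scheme(scheme)
  vapply(x, function(s) {
    digits <- strsplit(gsub("[ ,]", "", s), "")[[1]]
    if (length(digits) != scheme$width || !all(digits %in% c("0", "1"))) {
      stop(sprintf("expected %d binary digits, got \"%s\"", scheme$width, s),
           call. = FALSE)
    }
    sum(as.numeric(digits) * 2^(rev(seq_along(digits)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Convert between final labels and decimal training labels
#'
#' The sequence labeler trains on decimal class identifiers; these helpers
#' make the positional binary/decimal bijection explicit and validate the
#' range. The round trip is the identity.
#'
#' @param bits,n Numeric vector of labels / decimal values in
#'   `[0, 2^width)`.
#' @param scheme A [label_scheme()].
#' @return Numeric vector.
#' @export
label_to_decimal <- function(bits, scheme = label_scheme()) {
  .check_scheme(scheme)
  .check_label_bits(bits, scheme)
  as.numeric(bits)
}

#' @rdname label_to_decimal
#' @export
label_from_decimal <- function(n, scheme = label_scheme()) {
  .check_scheme(scheme)
  .check_label_bits(n, scheme)
  as.numeric(n)
}
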