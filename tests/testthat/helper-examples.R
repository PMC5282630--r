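# worked clinical examples used across tests

# "Abdomen is soft, nontender, nondistended, negative bruits."
# three mutually overlapping mentions, encoded in this order
abdomen_tokens <- c("Abdomen", "is", "soft", ",", "nontender", ",",
                    "nondistended", ",", "negative", "bruits", ".")
abdomen_mentions <- list(c(0L, 9L),   # Abdomen bruits
                         c(0L, 4L),   # Abdomen nontender
                         6L)          # nondistended
abdomen_expected_bits <- c(
  Abdomen = "000000,000000,000011,000000",
  is = "000000,000000,000000,000000",
  soft = "000000,000000,000000,000000",
  `,` = "000000,000000,000000,000000",
  nontender = "000000,000010,000000,000000",
  `,2` = "000000,000000,000000,000000",
  nondistended = "000000,000000,000000,000100",
  `,3` = "000000,000000,000000,000000",
  negative = "000000,000000,000000,000000",
  bruits = "000000,000001,000000,000000",
  `.` = "000000,000000,000000,000000")

# "The tricuspid valve leaflets are mildly thickened." — one discontiguous
# mention {tricuspid, leaflets, thickened}
tricuspid_text <- "The tricuspid valve leaflets are mildly thickened."
tricuspid_mention <- c(1L, 3L, 6L)

# "There is a small amount of blood seen within the third and fourth
# ventricles." — two mentions sharing two head segments (blood, ventricles)
ventricles_tokens <- c("There", "is", "a", "small", "amount", "of", "blood",
                       "seen", "within", "the", "third", "and", "fourth",
                       "ventricles", ".")
ventricles_mentions <- list(c(6L, 10L, 13L),  # blood third ventricles
                            c(6L, 12L, 13L))  # blood fourth ventricles

# "There is intermittent appearance of apparent atrial pacemaker artifact
# without capture." — {atrial pacemaker artifact} and {pacemaker capture}
pacemaker_tokens <- c("There", "is", "intermittent", "appearance", "of",
                      "apparent", "atrial", "pacemaker", "artifact",
                      "without", "capture", ".")
pacemaker_mentions <- list(c(6L, 7L, 8L), c(7L, 10L))

mention_set_equal <- function(a, b) {
  key <- function(m) paste(sort(unique(as.integer(m))), collapse = ",")
  setequal(vapply(a, key, character(1)), vapply(b, key, character(1)))
}

extdata <- function(...) {
  # during R CMD check/test the package is installed; fall back to source tree
  p <- system.file("extdata", ..., package = "multibilou")
  if (nzchar(p)) p else file.path("..", "..", "inst", "extdata", ...)
}
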