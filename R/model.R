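#' Label alphabet of an encoded corpus
#'
#' The sequence labeler predicts only decimal labels that were observed in
#' training (the full 2^24 label space is never enumerated). The alphabet is
#' the sorted set of distinct observed decimal labels, always including the
#' class-O label 0.
#'
#' @param labels_list List of numeric decimal-label vectors, one per
#'   sentence.
#' @param scheme A [label_scheme()].
#' @return Object of class `label_alphabet` with sorted `labels` and a
#'   lookup helper.
#' @export
build_alphabet <- function(labels_list, scheme = label_scheme()) {
  if (length(labels_list) == 0L) stop("empty corpus", call. = FALSE)
  labs <- sort(unique(c(0, unlist(labels_list))))
  .check_label_bits(labs, scheme)
  structure(list(labels = labs, size = length(labs)),
            class = "label_alphabet")
}

.alphabet_index <- function(alphabet, labels) {
  ix <- match(labels, alphabet$labels)
  if (anyNA(ix)) stop("label outside the training alphabet", call. = FALSE)
  ix
}

#' Exact Viterbi decoding for a linear-chain model
#'
#' Maximizes the sum of per-position emission scores and label-bigram
#' transition scores over all label sequences. Ties are broken toward the
#' lower label index.
#'
#' @param emissions Numeric matrix, positions x labels.
#' @param transitions Numeric matrix, labels x labels (`transitions[a, b]`
#'   scores label `a` followed by label `b`).
#' @return Integer vector of label indices, one per position.
#' @export
viterbi <- function(emissions, transitions) {
  n <- nrow(emissions)
  k <- ncol(emissions)
  stopifnot(n >= 1L, all(dim(transitions) == c(k, k)),
            all(is.finite(emissions)), all(is.finite(transitions)))
  delta <- matrix(-Inf, n, k)
  back <- matrix(1L, n, k)
  delta[1, ] <- emissions[1, ]
  if (n > 1L) {
    for (i in 2:n) {
      for (b in seq_len(k)) {
        sc <- delta[i - 1L, ] + transitions[, b]
        j <- which.max(sc)  # first max = lowest index
        delta[i, b] <- sc[j] + emissions[i, b]
        back[i, b] <- j
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1L) for (i in n:2) path[i - 1L] <- back[i, path[i]]
  path
}

#' Training configuration for the sequence labeler
#'
#' The labeler is an averaged online large-margin learner: at each sentence
#' it decodes with a Hamming cost added to every non-gold label
#' (cost-augmented decoding, so updates keep being made until the gold path
#' wins by a margin), applies a perceptron-style update on mistakes, and
#' averages the weight iterates. Training stops early once a full pass makes
#' no update, after which further passes provably change nothing; the
#' remaining passes are credited to the average.
#'
#' @param epochs Maximum passes over the training data.
#' @param seed Integer seed driving sentence shuffling.
#' @param cost Hamming cost added per mislabeled position during training
#'   decoding (the margin scale).
#' @param shuffle Shuffle sentence order each epoch?
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, seed = 1L, cost = 1, shuffle = TRUE) {
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  structure(list(epochs = epochs, seed = as.integer(seed), cost = cost,
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

# feature keys -> integer ids via an environment hash; grows on demand
.feature_indexer <- function() {
  env <- new.env(hash = TRUE, parent = emptyenv())
  n <- 0L
  list(
    id = function(keys, grow = TRUE) {
      vapply(keys, function(k) {
        v <- env[[k]]
        if (!is.null(v)) return(v)
        if (!grow) return(NA_integer_)
        n <<- n + 1L
        env[[k]] <- n
        n
      }, integer(1), USE.NAMES = FALSE)
    },
    size = function() n,
    names = function() {
      out <- character(n)
      for (k in ls(env)) out[env[[k]]] <- k
      out
    }
  )
}

.sentence_feature_ids <- function(tokens, pos, lex, fconf, indexer,
                                  grow = TRUE) {
  vapply(seq_along(tokens), function(i) {
    indexer$id(window_features(tokens, i, lex, fconf, pos), grow = grow)
  }, integer(length(window_features(tokens, 1L, lex, fconf, pos))))
}

.emission_matrix <- function(ids, W) {
  # ids: nkeys x n matrix of feature ids (NA = unseen); W: nfeat x k
  n <- ncol(ids)
  E <- matrix(0, n, ncol(W))
  for (j in seq_len(n)) {
    f <- ids[, j]
    f <- f[!is.na(f)]
    if (length(f)) E[j, ] <- colSums(W[f, , drop = FALSE])
  }
  E
}

#' Train the structured sequence labeler
#'
#' Fits a linear chain model (sparse emission features from
#' [window_features()] plus label-bigram transitions) over decimal
#' multi-labels with the averaged cost-augmented online learner described
#' in [train_config()]. Fully deterministic given the corpus, feature
#' configuration and seed.
#'
#' @param corpus List of sentences, each a list with `tokens`, optional
#'   `pos`, and `labels` (decimal final labels).
#' @param lex A [cluster_lexicon()] or NULL.
#' @param fconf A [feature_config()].
#' @param tconf A [train_config()].
#' @param scheme A [label_scheme()].
#' @return Object of class `sequence_model`.
#' @export
train_tagger <- function(corpus, lex = NULL, fconf = feature_config(),
                         tconf = train_config(), scheme = label_scheme()) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  alphabet <- build_alphabet(lapply(corpus, `[[`, "labels"), scheme)
  k <- alphabet$size
  if (k == 1L) warning("corpus contains a single distinct label; ",
                       "the model will be trivial")
  indexer <- .feature_indexer()
  feats <- lapply(corpus, function(s) {
    pos <- if (is.null(s$pos)) pos_tag_rules(s$tokens) else s$pos
    .sentence_feature_ids(s$tokens, pos, lex, fconf, indexer)
  })
  gold <- lapply(corpus, function(s) .alphabet_index(alphabet, s$labels))
  nfeat <- indexer$size()

  W <- matrix(0, nfeat, k)
  Tm <- matrix(0, k, k)
  Wa <- matrix(0, nfeat, k)   # averaging accumulators (Daume's trick)
  Ta <- matrix(0, k, k)
  c_t <- 1
  set.seed(tconf$seed)
  epochs_run <- 0L
  converged <- FALSE
  for (ep in seq_len(tconf$epochs)) {
    order_s <- if (tconf$shuffle) sample.int(length(corpus)) else
      seq_along(corpus)
    updates <- 0L
    for (s in order_s) {
      ids <- feats[[s]]
      g <- gold[[s]]
      E <- .emission_matrix(ids, W)
      Ec <- E + tconf$cost
      Ec[cbind(seq_along(g), g)] <- E[cbind(seq_along(g), g)]
      pred <- viterbi(Ec, Tm)
      if (any(pred != g)) {
        updates <- updates + 1L
        for (j in which(pred != g)) {
          f <- ids[, j]
          W[f, g[j]] <- W[f, g[j]] + 1
          W[f, pred[j]] <- W[f, pred[j]] - 1
          Wa[f, g[j]] <- Wa[f, g[j]] + c_t
          Wa[f, pred[j]] <- Wa[f, pred[j]] - c_t
        }
        if (length(g) > 1L) {
          for (j in 2:length(g)) {
            if (g[j - 1L] != pred[j - 1L] || g[j] != pred[j]) {
              Tm[g[j - 1L], g[j]] <- Tm[g[j - 1L], g[j]] + 1
              Tm[pred[j - 1L], pred[j]] <- Tm[pred[j - 1L], pred[j]] - 1
              Ta[g[j - 1L], g[j]] <- Ta[g[j - 1L], g[j]] + c_t
              Ta[pred[j - 1L], pred[j]] <- Ta[pred[j - 1L], pred[j]] - c_t
            }
          }
        }
      }
      c_t <- c_t + 1
    }
    epochs_run <- ep
    if (updates == 0L) {
      converged <- TRUE
      # no further pass can update; credit the untouched passes to the average
      c_t <- c_t + (tconf$epochs - ep) * length(corpus)
      break
    }
  }
  structure(list(
    weights = W - Wa / c_t,
    transitions = Tm - Ta / c_t,
    alphabet = alphabet,
    feature_names = indexer$names(),
    feature_config = fconf,
    train_config = tconf,
    scheme = scheme,
    epochs_run = epochs_run,
    converged = converged
  ), class = "sequence_model")
}

#' @export
print.sequence_model <- function(x, ...) {
  cat(sprintf(paste0("<sequence_model> %d labels, %d features, ",
                     "%d epoch(s)%s\n"),
              x$alphabet$size, length(x$feature_names), x$epochs_run,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Predict labels for a sentence
#'
#' Builds the sentence's feature ids (unseen features are ignored), scores
#' every alphabet label per position, runs [viterbi()] and maps the path
#' back to decimal final labels. Predictions always lie in the training
#' alphabet.
#'
#' @param model A trained [train_tagger()] model.
#' @param tokens Character vector of tokens.
#' @param lex A [cluster_lexicon()] or NULL (use the same lexicon as in
#'   training).
#' @param pos Optional POS tags; defaults to [pos_tag_rules()].
#' @return Numeric vector of decimal final labels.
#' @export
predict_tagger <- function(model, tokens, lex = NULL, pos = NULL) {
  stopifnot(inherits(model, "sequence_model"))
  indexer <- .feature_indexer()
  indexer$id(model$feature_names)  # rebuild the training-time index
  if (is.null(pos)) pos <- pos_tag_rules(tokens)
  ids <- .sentence_feature_ids(tokens, pos, lex, model$feature_config,
                               indexer, grow = FALSE)
  E <- .emission_matrix(ids, model$weights)
  path <- viterbi(E, model$transitions)
  model$alphabet$labels[path]
}

#' Persist and restore a trained model
#'
#' The model is written as a versioned JSON file containing the alphabet,
#' feature names, dense weight matrices, configuration and seed, so a
#' prediction run is reproducible from the file alone.
#'
#' @param model A `sequence_model`.
#' @param path File path.
#' @return `load_model` returns the restored `sequence_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sequence_model"))
  payload <- list(
    format = "multibilou-model", version = 1L,
    capacity = model$scheme$capacity,
    alphabet = model$alphabet$labels,
    feature_names = model$feature_names,
    weights = model$weights,
    transitions = model$transitions,
    feature_config = unclass(model$feature_config),
    train_config = unclass(model$train_config),
    epochs_run = model$epochs_run,
    converged = model$converged
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "multibilou-model")) {
    stop("not a multibilou model file", call. = FALSE)
  }
  scheme <- label_scheme(p$capacity)
  k <- length(p$alphabet)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = k)
  structure(list(
    weights = as_mat(p$weights),
    transitions = as_mat(p$transitions),
    alphabet = structure(list(labels = as.numeric(p$alphabet),
                              size = length(p$alphabet)),
                         class = "label_alphabet"),
    feature_names = p$feature_names,
    feature_config = do.call(feature_config, as.list(p$feature_config)),
    train_config = do.call(train_config, as.list(p$train_config)),
    scheme = scheme,
    epochs_run = p$epochs_run,
    converged = p$converged
  ), class = "sequence_model")
}
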