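#' Label a tweet by its emoticons
#'
#' Distant supervision: a tweet is usable as a training example when the
#' emoticons it carries map to exactly one distinct emotion. Tweets with no
#' mapped emoticon, or whose emoticons disagree, are excluded (return `NA`).
#'
#' @param emoticons Character vector of emoticon tokens on one tweet.
#' @param map Emoticon map (data.frame with `emoticon`, `emotion`).
#' @return An emotion name, or `NA_character_` when the tweet is not
#'   unambiguously labelable.
#' @examples
#' map <- default_emoticon_map()
#' label_by_emoticon("E30", map)           # a joy emoticon
#' label_by_emoticon(c("E1", "E30"), map)  # anger vs joy -> NA
#' @export
label_by_emoticon <- function(emoticons, map) {
  validate_emoticon_map(map)
  if (length(emoticons) == 0L) return(NA_character_)
  hits <- map$emotion[match(emoticons, map$emoticon)]
  hits <- unique(hits[!is.na(hits)])
  if (length(hits) == 1L) hits else NA_character_
}

#' Extract the emoticon-labeled training corpus from a tweet stream
#'
#' Applies [label_by_emoticon()] to every tweet and keeps the unambiguous
#' ones. Emoticon tokens never enter the token sequences used for training
#' (tweet tokens and emoticons are separate fields), so labels cannot leak
#' into features.
#'
#' @param tweets A tweet data.frame as returned by [read_tweets()] or
#'   [generate_tweets()]: list-columns `tokens` and `emoticons`.
#' @param map Emoticon map.
#' @return A data.frame with columns `tokens` (list) and `label` (character);
#'   one row per labelable tweet.
#' @export
build_training_corpus <- function(tweets, map) {
  labels <- label_tweets_by_emoticon(tweets, map)
  keep <- !is.na(labels)
  if (!any(keep)) stop("no labelable tweets", call. = FALSE)
  out <- data.frame(label = labels[keep], stringsAsFactors = FALSE)
  out$tokens <- tweets$tokens[keep]
  out[, c("tokens", "label")]
}

# vectorised emoticon labeling over a tweet table
label_tweets_by_emoticon <- function(tweets, map) {
  validate_emoticon_map(map)
  vapply(tweets$emoticons, function(e) {
    if (length(e) == 0L || all(is.na(e))) return(NA_character_)
    hits <- unique(map$emotion[match(e, map$emoticon)])
    hits <- hits[!is.na(hits)]
    if (length(hits) == 1L) hits else NA_character_
  }, character(1))
}

#' Train a four-class multinomial naive Bayes model
#'
#' Builds the word-by-class occurrence count table, per-class token totals
#' and per-class document counts from a labeled tweet set. Class priors are
#' the training document frequencies `doc_count(c) / N_docs`. Conditionals
#' use Laplace (add-one) smoothing, see [word_prob()].
#'
#' @param corpus Labeled set from [build_training_corpus()]: columns
#'   `tokens` (list of character vectors) and `label`.
#' @return An object of class `nb_model`: list with `vocab`, `counts`
#'   (|V| x 4 integer matrix, columns in canonical emotion order), `total`
#'   (per-class token totals), `doc_count`, `n_docs`.
#' @export
nb_train <- function(corpus) {
  if (nrow(corpus) == 0L) stop("empty training corpus", call. = FALSE)
  labels <- corpus$label
  if (length(unique(labels)) < 2L) {
    stop("training corpus covers a single class; classifier degenerate",
         call. = FALSE)
  }
  model <- nb_empty()
  nb_accumulate(model, corpus)
}

nb_empty <- function() {
  counts <- matrix(0L, nrow = 0L, ncol = length(EMOTIONS),
                   dimnames = list(NULL, EMOTIONS))
  structure(
    list(vocab = character(0),
         counts = counts,
         total = stats::setNames(integer(length(EMOTIONS)), EMOTIONS),
         doc_count = stats::setNames(integer(length(EMOTIONS)), EMOTIONS),
         n_docs = 0L),
    class = "nb_model")
}

# add a labeled batch's counts into a model (shared by train and update)
nb_accumulate <- function(model, corpus) {
  labels <- corpus$label
  stopifnot(all(labels %in% EMOTIONS))
  ntok <- lengths(corpus$tokens)
  word <- unlist(corpus$tokens, use.names = FALSE)
  cls <- rep(factor(labels, levels = EMOTIONS), ntok)
  if (length(word)) {
    tab <- table(word = word, cls = cls)
    new_words <- setdiff(rownames(tab), model$vocab)
    if (length(new_words)) {
      grow <- matrix(0L, nrow = length(new_words), ncol = length(EMOTIONS),
                     dimnames = list(new_words, EMOTIONS))
      model$counts <- rbind(model$counts, grow)
      model$vocab <- c(model$vocab, new_words)
    }
    idx <- match(rownames(tab), rownames(model$counts))
    model$counts[idx, ] <- model$counts[idx, , drop = FALSE] +
      matrix(as.integer(tab), nrow = nrow(tab),
             dimnames = dimnames(tab))[, EMOTIONS, drop = FALSE]
  }
  batch_docs <- table(factor(labels, levels = EMOTIONS))
  model$doc_count <- model$doc_count + as.integer(batch_docs)
  model$n_docs <- model$n_docs + length(labels)
  # keep the vocabulary sorted so incremental updates reproduce a fresh
  # retrain exactly, row order included
  ord <- order(model$vocab)
  model$vocab <- model$vocab[ord]
  model$counts <- model$counts[ord, , drop = FALSE]
  model$total <- stats::setNames(as.integer(colSums(model$counts)), EMOTIONS)
  model
}

#' @export
print.nb_model <- function(x, ...) {
  cat("Multinomial naive Bayes emotion classifier\n")
  cat("  vocabulary:", length(x$vocab), "words;",
      x$n_docs, "training tweets\n")
  cat("  class priors:",
      paste(sprintf("%s %.3f", EMOTIONS, nb_priors(x)), collapse = ", "),
      "\n")
  invisible(x)
}

nb_priors <- function(model) model$doc_count / model$n_docs

#' Laplace-smoothed word conditional probability
#'
#' Returns `(count(w, c) + 1) / (total(c) + |V|)` where `count(w, c)` is the
#' number of times word `w` occurred in training tweets of class `c`,
#' `total(c)` the total token count of class `c`, and `|V|` the trained
#' vocabulary size. Out-of-vocabulary words use count 0 with the trained
#' `|V|`; the vocabulary never grows at inference time.
#'
#' @param model An `nb_model`.
#' @param word Word token (character scalar or vector).
#' @param emotion One of [EMOTIONS].
#' @return Probability (vectorised over `word`).
#' @export
word_prob <- function(model, word, emotion) {
  check_emotion(emotion)
  idx <- match(word, model$vocab)
  cnt <- rep(0L, length(word))
  cnt[!is.na(idx)] <- model$counts[idx[!is.na(idx)], emotion]
  unname((cnt + 1) / (model$total[[emotion]] + length(model$vocab)))
}

# log conditional matrix: (|V|+1) x 4; last row is the OOV pseudo-word
nb_log_cond <- function(model) {
  denom <- model$total + length(model$vocab)
  lc <- log(sweep(model$counts + 1, 2, denom, "/"))
  oov <- log(1 / denom)
  rbind(lc, .oov = oov)
}

#' Classify token sequences
#'
#' Computes `argmax_c log P(c) + sum_i log P(w_i | c)` in log space, with
#' Laplace-smoothed conditionals. Ties are broken by the canonical emotion
#' order; an empty token sequence returns the prior argmax.
#'
#' @param model An `nb_model`.
#' @param tokens A character vector (one tweet) or a list of character
#'   vectors (many tweets).
#' @return An emotion name, or a character vector of them for a list input.
#' @examples
#' corpus <- data.frame(label = c("joy", "joy", "anger"))
#' corpus$tokens <- list(c("a", "b"), "a", "c")
#' m <- nb_train(corpus)
#' nb_classify(m, "a")
#' @export
nb_classify <- function(model, tokens) {
  if (!inherits(model, "nb_model")) stop("'model' must be an nb_model")
  single <- !is.list(tokens)
  toklist <- if (single) list(as.character(tokens)) else tokens
  scores <- nb_log_posterior(model, toklist)
  out <- EMOTIONS[apply(scores, 1L, which.max)]
  if (single) out[[1L]] else out
}

# log-posterior matrix (n_tweets x 4), vectorised over tweets
nb_log_posterior <- function(model, toklist) {
  lc <- nb_log_cond(model)
  prior <- log(nb_priors(model))
  ntok <- lengths(toklist)
  n <- length(toklist)
  scores <- matrix(rep(prior, each = n), nrow = n,
                   dimnames = list(NULL, EMOTIONS))
  if (sum(ntok) > 0L) {
    word <- unlist(toklist, use.names = FALSE)
    row <- match(word, model$vocab)
    row[is.na(row)] <- nrow(lc)  # OOV row
    tweet <- rep.int(seq_len(n), ntok)
    contrib <- rowsum(lc[row, , drop = FALSE], group = tweet, reorder = TRUE)
    ids <- as.integer(rownames(contrib))
    scores[ids, ] <- scores[ids, , drop = FALSE] + contrib
  }
  scores
}

#' Incrementally update a trained model with a labeled batch
#'
#' Adds the batch's word and document counts to the existing tables; the
#' vocabulary grows with unseen words. The result is identical (same count
#' tables) to retraining on the union of the original corpus and the batch.
#'
#' @param model An `nb_model`.
#' @param corpus Labeled batch, same shape as for [nb_train()]. An empty
#'   batch leaves the model unchanged.
#' @return The updated `nb_model`.
#' @export
nb_update <- function(model, corpus) {
  if (!inherits(model, "nb_model")) stop("'model' must be an nb_model")
  if (nrow(corpus) == 0L) return(model)
  nb_accumulate(model, corpus)
}

#' Serialize / deserialize a naive Bayes model
#'
#' The on-disk format is a flat tab-separated dump of (word, class, count)
#' triples preceded by comment header lines carrying the per-class document
#' counts. Counts are integers, so the round trip is exact.
#'
#' @param model An `nb_model`.
#' @param path File path.
#' @return `write_nb_model()` returns `path` invisibly; `read_nb_model()`
#'   returns the reconstructed `nb_model`.
#' @export
write_nb_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# doc_count\t%s\t%d", EMOTIONS, model$doc_count), con)
  long <- data.frame(
    word = rep(model$vocab, times = length(EMOTIONS)),
    class = rep(EMOTIONS, each = length(model$vocab)),
    count = as.integer(model$counts),
    stringsAsFactors = FALSE)
  long <- long[long$count > 0L, , drop = FALSE]
  # zero-count vocabulary rows must survive the round trip: dump them once
  zero_vocab <- model$vocab[rowSums(model$counts) == 0L]
  if (length(zero_vocab)) {
    long <- rbind(long, data.frame(word = zero_vocab,
                                   class = EMOTIONS[[1L]], count = 0L))
  }
  long <- long[order(long$word, long$class), , drop = FALSE]
  writeLines("word\tclass\tcount", con)
  writeLines(sprintf("%s\t%s\t%d", long$word, long$class, long$count), con)
  invisible(path)
}

#' @rdname write_nb_model
#' @export
read_nb_model <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# doc_count\t", lines)
  doc <- do.call(rbind, strsplit(sub("^# doc_count\t", "", lines[hdr]), "\t"))
  model <- nb_empty()
  model$doc_count[doc[, 1L]] <- as.integer(doc[, 2L])
  model$n_docs <- sum(model$doc_count)
  body <- lines[!hdr]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE)
  vocab <- sort(unique(tab$word))
  counts <- matrix(0L, nrow = length(vocab), ncol = length(EMOTIONS),
                   dimnames = list(vocab, EMOTIONS))
  counts[cbind(match(tab$word, vocab), match(tab$class, EMOTIONS))] <-
    as.integer(tab$count)
  model$vocab <- vocab
  model$counts <- counts
  model$total <- stats::setNames(as.integer(colSums(counts)), EMOTIONS)
  model
}
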