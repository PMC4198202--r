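#' Read a line-delimited tweet file
#'
#' One JSON record per line with fields `tweet_id`, `user_id`, `timestamp`
#' (integer epoch seconds), `tokens`, `emoticons`, `retweet_of` (user id or
#' null) and `mentions`. Malformed lines are skipped with a warning carrying
#' the final count; if more than 10% of lines are malformed the file is
#' rejected (most likely the wrong file).
#'
#' @param path Path to a `.jsonl` tweet file.
#' @return Tweet data.frame (list-columns `tokens`, `emoticons`,
#'   `mentions`).
#' @export
read_tweets <- function(path) {
  if (!file.exists(path)) stop("tweet file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty tweet file: ", path)
    return(empty_tweets())
  }
  recs <- lapply(lines, function(l) {
    tryCatch({
      r <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      stopifnot(is.character(r$tweet_id), is.character(r$user_id),
                !is.null(r$timestamp))
      r
    }, error = function(e) NULL)
  })
  bad <- vapply(recs, is.null, logical(1))
  if (mean(bad) > 0.1) {
    stop(sprintf("%d of %d lines malformed in %s; refusing to continue",
                 sum(bad), length(lines), path), call. = FALSE)
  }
  if (any(bad)) {
    warning(sprintf("skipped %d malformed line(s) of %d in %s",
                    sum(bad), length(lines), path))
  }
  recs <- recs[!bad]
  df <- data.frame(
    tweet_id = vapply(recs, function(r) r$tweet_id, character(1)),
    user_id = vapply(recs, function(r) r$user_id, character(1)),
    timestamp = vapply(recs, function(r) as.integer(r$timestamp), integer(1)),
    stringsAsFactors = FALSE)
  df$tokens <- lapply(recs, function(r) as.character(r$tokens))
  df$emoticons <- lapply(recs, function(r) as.character(r$emoticons))
  df$retweet_of <- vapply(recs, function(r) {
    if (is.null(r$retweet_of) || length(r$retweet_of) == 0L) NA_character_
    else as.character(r$retweet_of)
  }, character(1))
  df$mentions <- lapply(recs, function(r) as.character(r$mentions))
  df
}

empty_tweets <- function() {
  df <- data.frame(tweet_id = character(0), user_id = character(0),
                   timestamp = integer(0), stringsAsFactors = FALSE)
  df$tokens <- list()
  df$emoticons <- list()
  df$retweet_of <- character(0)
  df$mentions <- list()
  df
}

#' Write tweets as line-delimited JSON
#'
#' Inverse of [read_tweets()]; field order and number formatting are fixed,
#' so the same tweet table always produces the same bytes.
#'
#' @param tweets Tweet data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path) {
  n <- nrow(tweets)
  json_str <- function(s) {
    if (length(s) == 0L) return(character(0))
    paste0('"', gsub('"', '\\\\"', s), '"')
  }
  json_arr <- function(v) paste0("[", paste(json_str(v), collapse = ","), "]")
  lines <- vapply(seq_len(n), function(i) {
    rt <- tweets$retweet_of[[i]]
    sprintf(paste0('{"tweet_id":"%s","user_id":"%s","timestamp":%d,',
                   '"tokens":%s,"emoticons":%s,"retweet_of":%s,',
                   '"mentions":%s}'),
            tweets$tweet_id[[i]], tweets$user_id[[i]],
            as.integer(tweets$timestamp[[i]]),
            json_arr(tweets$tokens[[i]]),
            json_arr(tweets$emoticons[[i]]),
            if (is.na(rt)) "null" else json_str(rt),
            json_arr(tweets$mentions[[i]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write correlation estimates as long-format CSV
#'
#' Stable column order (`stratum_type`, `stratum_value`, `emotion`,
#' `method`, `r_mean`, `r_std`, `n_pairs`, `n_degenerate`) and
#' deterministic row order (stratum type, stratum value, emotion). An empty
#' estimate table yields a header-only file.
#'
#' @param estimates data.frame of correlation estimates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(estimates, path) {
  cols <- c("stratum_type", "stratum_value", "emotion", "method",
            "r_mean", "r_std", "n_pairs", "n_degenerate")
  stopifnot(all(cols %in% names(estimates)))
  est <- estimates[order(estimates$stratum_type, estimates$stratum_value,
                         match(estimates$emotion, EMOTIONS)), cols,
                   drop = FALSE]
  utils::write.csv(format(est, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a correlation results CSV
#'
#' @param path Path written by [write_results()].
#' @return data.frame of correlation estimates.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Sequences corpus acquisition (synthetic generation or a tweet file),
#' emoticon labeling, classifier training, classification into per-user
#' emotion vectors, interaction-network construction, and hop-distance
#' correlation, writing all artifacts into `out_dir`:
#' `edge_list.tsv`, `vectors.tsv`, `correlations.csv` and `manifest.json`
#' (plus the generated corpus in synthetic mode). Rerunning with the same
#' configuration and seed reproduces every output byte for byte.
#'
#' @param out_dir Output directory for the run.
#' @param tweets_path Path to an existing tweet file; `NULL` for synthetic
#'   mode.
#' @param emoticon_map_path Path to an emoticon map; defaults to the
#'   built-in inventory.
#' @param generator [generator_config()] used in synthetic mode.
#' @param n Interaction threshold (minimum events per link).
#' @param window_days,min_rate Activity-filter parameters.
#' @param hops Hop distances for the correlation profile.
#' @param method `"pearson"` or `"spearman"`.
#' @param B Bootstrap repetitions.
#' @param seed Global seed, fanned out to per-stage child seeds.
#' @return Invisibly, a list with the run directory, the graph, the emotion
#'   vectors and the correlation table.
#' @export
run_pipeline <- function(out_dir,
                         tweets_path = NULL,
                         emoticon_map_path = NULL,
                         generator = generator_config(seed = seed),
                         n = 5L, window_days = 180L, min_rate = 0.5,
                         hops = 1:3, method = "pearson",
                         B = 1000L, seed = 1L) {
  if (!is.null(tweets_path) && !file.exists(tweets_path)) {
    stop("tweets path does not exist: ", tweets_path, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  map <- if (is.null(emoticon_map_path)) default_emoticon_map()
         else read_emoticon_map(emoticon_map_path)

  if (is.null(tweets_path)) {
    corpus <- generate_corpus(generator, file.path(out_dir, "corpus"))
    tweets <- corpus$tweets
    map <- default_emoticon_map(generator$n_emoticons)
    window_days <- generator$window_days
  } else {
    tweets <- read_tweets(tweets_path)
  }
  if (nrow(tweets) == 0L) stop("no tweets to analyse", call. = FALSE)

  # distant supervision + training
  training <- build_training_corpus(tweets, map)
  model <- nb_train(training)

  # per-user emotion vectors (emoticon labels kept, rest classified)
  vectors <- user_emotion_vectors(tweets, model, map)

  # interaction network
  pair_counts <- count_interactions(tweets)
  act <- active_users(tweets, window_days, min_rate)
  graph <- build_graph(pair_counts, act, n)
  if (igraph::vcount(graph) == 0L) {
    stop("interaction network is empty at threshold n = ", n, call. = FALSE)
  }

  # hop-distance correlation profile for all four emotions
  rows <- list()
  for (h in hops) {
    for (m in EMOTIONS) {
      est <- tryCatch(
        pairwise_correlation(graph, vectors$fractions, h = h, emotion = m,
                             method = method, B = B,
                             seed = child_seed(seed, sprintf("corr_h%d_%s", h, m))),
        error = function(e) NULL)
      if (!is.null(est)) rows[[length(rows) + 1L]] <- est
    }
  }
  estimates <- if (length(rows)) do.call(rbind, rows) else empty_estimates()

  write_edge_list(graph, file.path(out_dir, "edge_list.tsv"))
  vec_df <- data.frame(user_id = rownames(vectors$fractions),
                       stringsAsFactors = FALSE)
  vec_df[paste0("e_", EMOTIONS)] <- as.data.frame(vectors$fractions)
  vec_df$tweet_count <- vectors$tweet_count
  utils::write.table(format(vec_df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     file.path(out_dir, "vectors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_results(estimates, file.path(out_dir, "correlations.csv"))

  n_labeled <- nrow(training)
  manifest <- list(
    mode = if (is.null(tweets_path)) "synthetic" else "file",
    seed = seed, threshold_n = as.integer(n),
    window_days = as.integer(window_days), min_rate = min_rate,
    method = method, bootstrap_B = as.integer(B), hops = hops,
    n_tweets = nrow(tweets),
    n_labeled = n_labeled,
    n_model_classified = nrow(tweets) - n_labeled,
    n_active_users = length(act),
    n_graph_nodes = igraph::vcount(graph),
    n_graph_edges = igraph::ecount(graph),
    vocabulary_size = length(model$vocab))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = out_dir, graph = graph, model = model,
                 vectors = vectors, estimates = estimates,
                 manifest = manifest))
}
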