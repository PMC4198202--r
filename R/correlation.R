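#' Pearson product-moment correlation
#'
#' Direct implementation of the product-moment formula: the mean-centered
#' cross product divided by `N * sigma_X * sigma_Y` with population standard
#' deviations. Constant sequences have zero variance and make the
#' correlation undefined; this raises an error so the caller can decide its
#' policy (e.g. drop a degenerate bootstrap resample).
#'
#' @param x,y Numeric vectors of equal length `N >= 2`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_pair(x, y)
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / n)
  sy <- sqrt(sum((y - my)^2) / n)
  if (sx == 0 || sy == 0) {
    stop("undefined correlation: constant sequence", call. = FALSE)
  }
  r <- sum((x - mx) * (y - my)) / (n * sx * sy)
  min(1, max(-1, r))
}

#' Spearman rank correlation
#'
#' Ranks are assigned with average-rank tie handling. When the sequences are
#' tie-free the classic rank-difference form `1 - 6 sum(d_i^2) / (N (N^2 - 1))`
#' is used; with ties, the Pearson correlation of the rank sequences (the two
#' coincide exactly in the tie-free case).
#'
#' @inheritParams pearson_r
#' @return Rank correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  check_pair(x, y)
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  no_ties <- !anyDuplicated(rx) && !anyDuplicated(ry)
  if (no_ties) {
    d <- rx - ry
    return(1 - 6 * sum(d^2) / (n * (n^2 - 1)))
  }
  pearson_r(rx, ry)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) {
    stop("need at least 2 paired observations", call. = FALSE)
  }
  invisible(NULL)
}

corr_fun <- function(method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (method == "pearson") pearson_r else spearman_rho
}

#' Bootstrap mean and error of a pairwise correlation
#'
#' Each repetition samples `N` integer indexes uniformly with replacement,
#' applies the same index sequence to both `x` and `y`, and computes the
#' correlation of the resampled pair. The result is the mean and standard
#' deviation (the error) over non-degenerate repetitions; resamples in which
#' either sequence comes out constant are dropped and counted.
#'
#' @inheritParams pearson_r
#' @param B Number of bootstrap repetitions (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r_mean`, `r_std`, `n_degenerate`, `B`.
#' @export
bootstrap_corr <- function(x, y, B = 1000L, seed = 1L,
                           method = c("pearson", "spearman")) {
  check_pair(x, y)
  stopifnot(B >= 1L)
  f <- corr_fun(method)
  n <- length(x)
  rs <- numeric(B)
  ok <- logical(B)
  withr_seed(seed, {
    for (b in seq_len(B)) {
      k <- sample.int(n, n, replace = TRUE)
      xb <- x[k]; yb <- y[k]
      if (var_zero(xb) || var_zero(yb)) next
      rs[b] <- f(xb, yb)
      ok[b] <- TRUE
    }
  })
  if (!any(ok)) {
    stop("all bootstrap resamples degenerate (constant sequences)",
         call. = FALSE)
  }
  kept <- rs[ok]
  list(r_mean = mean(kept),
       r_std = if (length(kept) > 1L) stats::sd(kept) else 0,
       n_degenerate = sum(!ok),
       B = as.integer(B))
}

var_zero <- function(x) all(x == x[[1L]])

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Shuffle-null correlation
#'
#' Correlation between `x` and a uniform random permutation of `y`; the
#' no-association baseline against which observed correlations are judged.
#'
#' @inheritParams bootstrap_corr
#' @return Correlation coefficient of the shuffled pair.
#' @export
shuffle_null <- function(x, y, seed = 1L, method = c("pearson", "spearman")) {
  check_pair(x, y)
  f <- corr_fun(method)
  yp <- withr_seed(seed, y[sample.int(length(y))])
  f(x, yp)
}

#' Per-user emotion vectors from classified tweets
#'
#' Every tweet gets one of the four emotion labels: tweets carrying an
#' unambiguous emoticon keep their emoticon label; all others are classified
#' with the naive Bayes model. A user's emotion vector is the per-class
#' fraction of their tweets.
#'
#' @param tweets Tweet data.frame.
#' @param model Trained `nb_model`; may be `NULL` when `labels` is given.
#' @param map Emoticon map (used for the distant-supervision labels).
#' @param labels Optional character vector of per-tweet labels overriding
#'   classification entirely (e.g. ground-truth labels from the generator).
#' @return List with `fractions` (users x 4 matrix, rows sum to 1), `counts`
#'   (users x 4 integer matrix of tweet counts) and `tweet_count` (named
#'   integer vector). Row names are user ids.
#' @export
user_emotion_vectors <- function(tweets, model = NULL,
                                 map = default_emoticon_map(),
                                 labels = NULL) {
  if (nrow(tweets) == 0L) stop("no tweets to classify", call. = FALSE)
  if (is.null(labels)) {
    labels <- label_tweets_by_emoticon(tweets, map)
    todo <- is.na(labels)
    if (any(todo)) {
      if (is.null(model)) {
        stop("tweets without emoticon labels require a trained model",
             call. = FALSE)
      }
      labels[todo] <- nb_classify(model, tweets$tokens[todo])
    }
  }
  stopifnot(length(labels) == nrow(tweets), all(labels %in% EMOTIONS))
  counts <- table(user = tweets$user_id,
                  emotion = factor(labels, levels = EMOTIONS))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(rownames(counts), EMOTIONS))
  totals <- rowSums(counts)
  fractions <- counts / totals
  list(fractions = fractions, counts = counts,
       tweet_count = stats::setNames(as.integer(totals), rownames(counts)))
}

#' Emotion vector of a single user
#'
#' @param user_tweets Tweet data.frame restricted to one user (>= 1 row).
#' @inheritParams user_emotion_vectors
#' @return Named numeric vector of the four emotion fractions.
#' @export
emotion_vector <- function(user_tweets, model = NULL,
                           map = default_emoticon_map(), labels = NULL) {
  if (nrow(user_tweets) == 0L) {
    stop("user has no tweets in the window", call. = FALSE)
  }
  if (length(unique(user_tweets$user_id)) != 1L) {
    stop("'user_tweets' must belong to a single user", call. = FALSE)
  }
  ev <- user_emotion_vectors(user_tweets, model, map, labels)
  ev$fractions[1L, ]
}

#' Dominant emotion of a vector
#'
#' The class with the maximum fraction of a user's tweets in the sampling
#' period; ties broken by the canonical emotion order.
#'
#' @param fractions Numeric vector of 4 emotion fractions (canonical order),
#'   or a matrix with one row per user.
#' @return Emotion name(s).
#' @export
dominant_emotion <- function(fractions) {
  if (is.matrix(fractions)) {
    return(stats::setNames(EMOTIONS[apply(fractions, 1L, which.max)],
                           rownames(fractions)))
  }
  EMOTIONS[which.max(fractions)]
}

#' Pairwise emotion correlation at hop distance h
#'
#' Builds the source and target sequences over all ordered user pairs at
#' shortest-path distance `h` (both orientations of each unordered pair),
#' filling them with the two users' fractions for the chosen emotion, and
#' applies the bootstrap correlation estimator.
#'
#' @param graph Interaction graph (`igraph`).
#' @param fractions Users x 4 fraction matrix from [user_emotion_vectors()].
#' @param h Hop distance.
#' @param emotion One of [EMOTIONS].
#' @param method `"pearson"` or `"spearman"`.
#' @param B Bootstrap repetitions.
#' @param seed Seed for the bootstrap stream.
#' @return A one-row data.frame (a `CorrelationEstimate`): `stratum_type`,
#'   `stratum_value`, `emotion`, `method`, `r_mean`, `r_std`, `n_pairs`,
#'   `n_degenerate`.
#' @export
pairwise_correlation <- function(graph, fractions, h = 1L, emotion = "anger",
                                 method = c("pearson", "spearman"),
                                 B = 1000L, seed = 1L) {
  check_emotion(emotion)
  method <- match.arg(method)
  pairs <- hop_pairs(graph, h)
  if (nrow(pairs) < 2L) {
    stop("insufficient data: fewer than 2 pairs at hop distance ", h,
         call. = FALSE)
  }
  x <- fractions[pairs$source, emotion]
  y <- fractions[pairs$target, emotion]
  if (anyNA(x) || anyNA(y)) {
    stop("emotion vectors missing for some graph users", call. = FALSE)
  }
  if (var_zero(x) || var_zero(y)) {
    stop("undefined correlation: constant sequence", call. = FALSE)
  }
  bs <- bootstrap_corr(x, y, B = B, seed = seed, method = method)
  estimate_row("hop", h, emotion, method, bs, nrow(pairs))
}

estimate_row <- function(stratum_type, stratum_value, emotion, method,
                         bs, n_pairs) {
  data.frame(stratum_type = stratum_type,
             stratum_value = as.numeric(stratum_value),
             emotion = emotion, method = method,
             r_mean = bs$r_mean, r_std = bs$r_std,
             n_pairs = as.integer(n_pairs),
             n_degenerate = bs$n_degenerate,
             stringsAsFactors = FALSE)
}

#' Neighborhood emotion vector
#'
#' Sums the raw per-class tweet counts over all neighbors of a node (not an
#' average of their fraction vectors — neighbors with more tweets weigh
#' more) and normalizes to fractions.
#'
#' @param graph Interaction graph.
#' @param v Vertex name.
#' @param counts Users x 4 integer count matrix from
#'   [user_emotion_vectors()].
#' @return Named numeric vector of 4 fractions.
#' @export
neighborhood_vector <- function(graph, v, counts) {
  nb <- igraph::neighbors(graph, v)$name
  if (length(nb) == 0L) {
    stop("node ", v, " has no neighbors", call. = FALSE)
  }
  nb <- intersect(nb, rownames(counts))
  tot <- colSums(counts[nb, , drop = FALSE])
  if (sum(tot) == 0) {
    stop("neighborhood of ", v, " has no classified tweets", call. = FALSE)
  }
  tot / sum(tot)
}

# node-vs-neighborhood sequences for a set of vertices
node_vs_neighborhood <- function(graph, vs, fractions, counts, emotion) {
  x <- fractions[vs, emotion]
  y <- vapply(vs, function(v) neighborhood_vector(graph, v, counts)[[emotion]],
              numeric(1))
  list(x = unname(x), y = unname(y))
}

#' Degree-stratified node-vs-neighborhood correlation
#'
#' For each degree `k` represented by at least `min_group` nodes, correlates
#' each node's own emotion fraction with its neighborhood's fraction (counts
#' summed over neighbors) and bootstraps the estimate within the group.
#'
#' @inheritParams pairwise_correlation
#' @param counts Users x 4 count matrix (see [user_emotion_vectors()]).
#' @param min_group Minimum nodes per degree group (default 10).
#' @return data.frame of correlation estimates, one row per retained degree;
#'   zero rows (with a warning) when no group is large enough. Degenerate
#'   groups (constant sequences) are skipped.
#' @export
degree_stratified <- function(graph, fractions, counts, emotion = "anger",
                              method = c("pearson", "spearman"),
                              B = 1000L, min_group = 10L, seed = 1L) {
  check_emotion(emotion)
  method <- match.arg(method)
  deg <- igraph::degree(graph)
  groups <- split(names(deg), deg)
  groups <- groups[lengths(groups) >= min_group]
  if (length(groups) == 0L) {
    warning("no degree group reaches min_group = ", min_group)
    return(empty_estimates())
  }
  rows <- lapply(names(groups), function(k) {
    vs <- groups[[k]]
    seqs <- node_vs_neighborhood(graph, vs, fractions, counts, emotion)
    if (var_zero(seqs$x) || var_zero(seqs$y)) return(NULL)
    bs <- bootstrap_corr(seqs$x, seqs$y, B = B,
                         seed = child_seed(seed, paste0("degree", k)),
                         method = method)
    estimate_row("degree", as.numeric(k), emotion, method, bs, length(vs))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_estimates() else out
}

#' Clustering-binned node-vs-neighborhood correlation
#'
#' Nodes are assigned to linear (equal-width) bins of the local clustering
#' coefficient: half-open intervals `[i w, (i + 1) w)` over `[0, 1]`, the
#' last bin closed at 1. Within each sufficiently large bin the
#' node-vs-neighborhood correlation is bootstrapped as in
#' [degree_stratified()]. The reported `stratum_value` is the bin's lower
#' edge.
#'
#' @inheritParams degree_stratified
#' @param bin_width Bin width in `(0, 1]`.
#' @export
clustering_binned <- function(graph, fractions, counts, emotion = "anger",
                              bin_width = 0.1,
                              method = c("pearson", "spearman"),
                              B = 1000L, min_group = 10L, seed = 1L) {
  stopifnot(bin_width > 0, bin_width <= 1)
  check_emotion(emotion)
  method <- match.arg(method)
  cc <- local_clustering(graph)
  bin <- floor(cc / bin_width)
  bin[cc >= 1] <- floor(1 / bin_width) - 1  # close the last bin at 1
  groups <- split(names(cc), bin)
  groups <- groups[lengths(groups) >= min_group]
  if (length(groups) == 0L) {
    warning("no clustering bin reaches min_group = ", min_group)
    return(empty_estimates())
  }
  rows <- lapply(names(groups), function(b) {
    vs <- groups[[b]]
    seqs <- node_vs_neighborhood(graph, vs, fractions, counts, emotion)
    if (var_zero(seqs$x) || var_zero(seqs$y)) return(NULL)
    bs <- bootstrap_corr(seqs$x, seqs$y, B = B,
                         seed = child_seed(seed, paste0("clustering", b)),
                         method = method)
    estimate_row("clustering", as.numeric(b) * bin_width, emotion, method,
                 bs, length(vs))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_estimates() else out
}

empty_estimates <- function() {
  data.frame(stratum_type = character(0), stratum_value = numeric(0),
              emotion = character(0), method = character(0),
              r_mean = numeric(0), r_std = numeric(0),
              n_pairs = integer(0), n_degenerate = integer(0),
              stringsAsFactors = FALSE)
}

#' Interaction-threshold sweep of hop correlations
#'
#' Rebuilds the interaction network for each threshold `n` and computes the
#' pairwise correlation for each requested hop distance and emotion. Cells
#' with insufficient data (too few pairs, or constant sequences) are emitted
#' as missing rows, not errors.
#'
#' @param tweets Tweet data.frame (for the interaction counts and activity
#'   filter).
#' @param fractions Users x 4 fraction matrix.
#' @param n_values Integer vector of thresholds to sweep.
#' @param h_values Integer vector of hop distances.
#' @param emotions Character vector of emotions (default all four).
#' @param window_days,min_rate Activity-filter parameters.
#' @inheritParams pairwise_correlation
#' @return Long-format data.frame: `n`, `h`, `emotion`, `method`, `r_mean`,
#'   `r_std`, `n_pairs`, `n_degenerate`.
#' @export
threshold_sweep <- function(tweets, fractions, n_values = 1:10,
                            h_values = 1:3, emotions = EMOTIONS,
                            method = c("pearson", "spearman"),
                            B = 1000L, seed = 1L,
                            window_days = 180L, min_rate = 0.5) {
  stopifnot(length(n_values) >= 1L, all(n_values >= 1))
  method <- match.arg(method)
  pc <- count_interactions(tweets)
  act <- active_users(tweets, window_days, min_rate)
  rows <- list()
  for (n in n_values) {
    g <- build_graph(pc, act, n)
    for (h in h_values) {
      for (m in emotions) {
        est <- tryCatch(
          pairwise_correlation(g, fractions, h = h, emotion = m,
                               method = method, B = B,
                               seed = child_seed(seed, sprintf("n%dh%d%s", n, h, m))),
          error = function(e) NULL)
        if (!is.null(est)) {
          rows[[length(rows) + 1L]] <-
            cbind(data.frame(n = n, h = h), est[, -(1:2)])
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(n = integer(0), h = integer(0), emotion = character(0),
                      method = character(0), r_mean = numeric(0),
                      r_std = numeric(0), n_pairs = integer(0),
                      n_degenerate = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
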