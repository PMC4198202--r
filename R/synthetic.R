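#' Configuration for the synthetic corpus generator
#'
#' Bundles and validates every knob of the synthetic microblog corpus. The
#' generator emulates the features of a Weibo-like dataset the analysis
#' depends on: an interaction network with tunable degree and clustering, a
#' per-user four-class emotion mixture whose similarity across ties decays
#' with hop distance, tweet emission with emotion-specific word
#' distributions, sparse emoticon usage, and per-edge retweet/mention
#' counts so the tie-strength threshold is exercisable.
#'
#' @param n_users Number of users (>= 4).
#' @param graph_model One of `"small-world"` (default; local mixing keeps
#'   the hop-1 correlation monotone in rho), `"preferential-attachment"`
#'   (heavy-tailed degrees up to ~30 at the default size, for
#'   degree-stratified analyses), `"random"`.
#' @param graph_params Named list of model parameters: small-world uses
#'   `k` (neighbors each side) and `p` (rewiring probability);
#'   preferential-attachment uses `m` (edges per new node); random uses
#'   `p` (edge probability).
#' @param assortativity_rho Neighborhood-mixing weight rho in `[0, 1]`;
#'   0 gives independent users, larger values give stronger emotion
#'   assortativity across ties.
#' @param smoothing_rounds Number of neighborhood-mixing rounds S (>= 0).
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet from
#'   which base emotion mixtures are drawn.
#' @param tweets_per_user Mean tweets per user (Poisson, truncated at 1).
#' @param window_days Observation window in days.
#' @param emoticon_prob Probability that a tweet carries an emoticon
#'   (default 0.05: roughly 95% of microblog posts carry none).
#' @param tokens_per_tweet Mean tokens per tweet (Poisson, truncated at 1).
#' @param vocab_size_per_emotion Words in each emotion's vocabulary.
#' @param vocab_overlap Fraction of each emotion's vocabulary shared with
#'   every other emotion, in `[0, 1]`.
#' @param interaction_mean Mean total retweet+mention events per edge
#'   (shifted geometric, minimum 1).
#' @param weight_similarity If `TRUE`, an edge's expected interaction count
#'   scales with the emotional similarity of its endpoints, coupling tie
#'   strength to assortativity (used for threshold-sweep experiments).
#' @param low_activity_frac Fraction of users re-drawn as low-activity
#'   posters (mean 30 tweets), to exercise the activity filter.
#' @param n_emoticons Size of the synthetic emoticon inventory.
#' @param seed Integer seed; the same config and seed reproduce the corpus
#'   byte for byte.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_users = 500L,
                             graph_model = c("small-world",
                                             "preferential-attachment",
                                             "random"),
                             graph_params = NULL,
                             assortativity_rho = 0.6,
                             smoothing_rounds = 3L,
                             dirichlet_alpha = 1.0,
                             tweets_per_user = 200,
                             window_days = 180L,
                             emoticon_prob = 0.05,
                             tokens_per_tweet = 8,
                             vocab_size_per_emotion = 250L,
                             vocab_overlap = 0.2,
                             interaction_mean = 6,
                             weight_similarity = FALSE,
                             low_activity_frac = 0,
                             n_emoticons = 95L,
                             seed = 1L) {
  graph_model <- match.arg(graph_model)
  if (is.null(graph_params)) {
    graph_params <- switch(graph_model,
      "preferential-attachment" = list(m = 3L),
      "small-world" = list(k = 3L, p = 0.1),
      "random" = list(p = 0.02))
  }
  cfg <- list(n_users = as.integer(n_users), graph_model = graph_model,
              graph_params = graph_params,
              assortativity_rho = assortativity_rho,
              smoothing_rounds = as.integer(smoothing_rounds),
              dirichlet_alpha = dirichlet_alpha,
              tweets_per_user = tweets_per_user,
              window_days = as.integer(window_days),
              emoticon_prob = emoticon_prob,
              tokens_per_tweet = tokens_per_tweet,
              vocab_size_per_emotion = as.integer(vocab_size_per_emotion),
              vocab_overlap = vocab_overlap,
              interaction_mean = interaction_mean,
              weight_similarity = isTRUE(weight_similarity),
              low_activity_frac = low_activity_frac,
              n_emoticons = as.integer(n_emoticons),
              seed = as.integer(seed))
  in01 <- function(v) is.numeric(v) && length(v) == 1L && v >= 0 && v <= 1
  if (cfg$n_users < 4L) stop("n_users must be >= 4", call. = FALSE)
  if (!in01(cfg$assortativity_rho)) stop("assortativity_rho must be in [0, 1]", call. = FALSE)
  if (!in01(cfg$emoticon_prob)) stop("emoticon_prob must be in [0, 1]", call. = FALSE)
  if (!in01(cfg$vocab_overlap)) stop("vocab_overlap must be in [0, 1]", call. = FALSE)
  if (!in01(cfg$low_activity_frac)) stop("low_activity_frac must be in [0, 1]", call. = FALSE)
  if (cfg$smoothing_rounds < 0L) stop("smoothing_rounds must be >= 0", call. = FALSE)
  if (cfg$dirichlet_alpha <= 0) stop("dirichlet_alpha must be > 0", call. = FALSE)
  if (cfg$tweets_per_user <= 0) stop("tweets_per_user must be > 0", call. = FALSE)
  if (cfg$interaction_mean < 1) stop("interaction_mean must be >= 1", call. = FALSE)
  structure(cfg, class = "generator_config")
}

# zero-padded user ids: lexicographic order == numeric order
user_ids <- function(n) sprintf("u%04d", seq_len(n) - 1L)

#' Generate the synthetic social graph
#'
#' Draws an undirected, unweighted graph from the configured model
#' (Watts-Strogatz small world, Barabasi-Albert preferential attachment, or
#' Erdos-Renyi random) and keeps only draws whose giant connected component
#' covers at least 90% of the nodes, restricting the graph to that
#' component. Retries with perturbed seeds a bounded number of times.
#'
#' @param config A [generator_config()].
#' @return An `igraph` with vertex names `u0000`, `u0001`, ...
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_users
  p <- config$graph_params
  for (try in 0:19) {
    g <- withr_seed(child_seed(config$seed, paste0("network", try)), {
      switch(config$graph_model,
        "small-world" = igraph::sample_smallworld(1L, n, p$k, p$p),
        "preferential-attachment" = igraph::sample_pa(n, m = p$m,
                                                      directed = FALSE),
        "random" = igraph::sample_gnp(n, p$p),
        stop("unknown graph model: ", config$graph_model, call. = FALSE))
    })
    g <- igraph::simplify(g)
    comp <- igraph::components(g)
    if (max(comp$csize) >= 0.9 * n) {
      giant <- which.max(comp$csize)
      igraph::V(g)$name <- user_ids(n)
      return(igraph::induced_subgraph(g, which(comp$membership == giant)))
    }
  }
  stop("could not generate a graph with a >= 90% giant component; ",
       "adjust graph_params", call. = FALSE)
}

#' Assign ground-truth emotion mixtures
#'
#' Each user's base mixture over the four emotions is drawn from a symmetric
#' Dirichlet(alpha). Assortativity is then induced by `S` rounds of
#' neighborhood mixing: `v_i <- (1 - rho) v_i + rho * mean(v_j over
#' neighbors j)`, applied synchronously. Rho = 0 leaves users independent;
#' rho near 1 with several rounds drives neighborhoods toward a shared
#' mixture, with similarity decaying over hop distance. Isolated nodes keep
#' their base mixture. Mixtures remain on the simplex at every round.
#'
#' @param graph Graph from [generate_network()].
#' @param config A [generator_config()].
#' @return List of class `ground_truth`: `mixtures` (users x 4 matrix, rows
#'   summing to 1), `dominant` (named character), `graph`.
#' @export
assign_emotions <- function(graph, config) {
  stopifnot(inherits(config, "generator_config"))
  ids <- igraph::V(graph)$name
  n <- length(ids)
  base <- withr_seed(child_seed(config$seed, "mixtures"), {
    gm <- matrix(stats::rgamma(n * 4L, shape = config$dirichlet_alpha),
                 nrow = n)
    gm / rowSums(gm)
  })
  dimnames(base) <- list(ids, EMOTIONS)
  rho <- config$assortativity_rho
  mix <- base
  if (rho > 0 && config$smoothing_rounds > 0L) {
    adj <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
    deg <- igraph::degree(graph)
    for (s in seq_len(config$smoothing_rounds)) {
      nb_mean <- as.matrix(adj %*% mix)
      has_nb <- deg > 0
      nb_mean[has_nb, ] <- nb_mean[has_nb, , drop = FALSE] / deg[has_nb]
      upd <- (1 - rho) * mix + rho * nb_mean
      mix[has_nb, ] <- upd[has_nb, , drop = FALSE]
    }
  }
  structure(list(mixtures = mix,
                 dominant = dominant_emotion(mix),
                 graph = graph),
            class = "ground_truth")
}

# per-emotion vocabularies with a configurable shared fraction
build_vocabulary <- function(config) {
  v <- config$vocab_size_per_emotion
  n_shared <- round(config$vocab_overlap * v)
  shared <- if (n_shared > 0) sprintf("w_common_%03d", seq_len(n_shared))
            else character(0)
  vocab <- lapply(EMOTIONS, function(m) {
    own <- v - n_shared
    distinct <- if (own > 0) sprintf("w_%s_%03d", m, seq_len(own))
                else character(0)
    c(distinct, shared)
  })
  stats::setNames(vocab, EMOTIONS)
}

#' Generate the synthetic tweet stream
#'
#' Each user emits a Poisson number of tweets (mean `tweets_per_user`,
#' truncated at 1) with integer timestamps uniform over the observation
#' window. Each tweet's latent emotion is drawn from the user's ground-truth
#' mixture; its tokens come from that emotion's vocabulary, and with
#' probability `emoticon_prob` it carries one emoticon from that emotion's
#' inventory. Per-edge retweet/mention events are then attached to the
#' endpoint users' tweets so each edge's total interaction count follows a
#' shifted-geometric distribution with the configured mean (optionally
#' scaled by the endpoints' emotional similarity).
#'
#' @param graph Graph from [generate_network()].
#' @param truth Ground truth from [assign_emotions()].
#' @param config A [generator_config()].
#' @return A tweet data.frame with columns `tweet_id`, `user_id`,
#'   `timestamp`, list-columns `tokens`, `emoticons`, `mentions`,
#'   `retweet_of`, and the latent `emotion_true` (not part of the on-disk
#'   corpus format).
#' @export
generate_tweets <- function(graph, truth, config) {
  stopifnot(inherits(config, "generator_config"),
            inherits(truth, "ground_truth"))
  ids <- igraph::V(graph)$name
  stopifnot(all(ids %in% rownames(truth$mixtures)))
  vocab <- build_vocabulary(config)
  emo_map <- default_emoticon_map(config$n_emoticons)
  emo_sets <- split(emo_map$emoticon, emo_map$emotion)[EMOTIONS]

  tweets <- withr_seed(child_seed(config$seed, "tweets"), {
    n_low <- round(config$low_activity_frac * length(ids))
    low <- rep(FALSE, length(ids))
    if (n_low > 0) low[sample.int(length(ids), n_low)] <- TRUE
    mean_tw <- ifelse(low, 30, config$tweets_per_user)
    n_tweets <- pmax(1L, stats::rpois(length(ids), mean_tw))
    total <- sum(n_tweets)
    user <- rep.int(ids, n_tweets)
    ts <- as.integer(floor(stats::runif(total, 0,
                                        config$window_days * 86400)))
    # latent emotion per tweet from the author's mixture
    mixt <- truth$mixtures[user, , drop = FALSE]
    u <- stats::runif(total)
    cum <- mixt %*% upper.tri(diag(4), diag = TRUE)
    emo_idx <- 1L + rowSums(u > cum[, 1:3, drop = FALSE])
    emotion <- EMOTIONS[emo_idx]
    # tokens: per-tweet lengths, then one uniform draw per token from the
    # tweet emotion's vocabulary
    len <- pmax(1L, stats::rpois(total, config$tokens_per_tweet))
    tok_emo <- rep.int(emo_idx, len)
    pick <- ceiling(stats::runif(sum(len)) * config$vocab_size_per_emotion)
    words <- character(sum(len))
    for (ci in 1:4) {
      sel <- tok_emo == ci
      words[sel] <- vocab[[ci]][pick[sel]]
    }
    tokens <- split(words, rep.int(seq_len(total), len))
    names(tokens) <- NULL
    # sparse emoticons
    has_emo <- stats::runif(total) < config$emoticon_prob
    emoticons <- vector("list", total)
    emoticons[] <- list(character(0))
    if (any(has_emo)) {
      sets <- emo_sets[emo_idx[has_emo]]
      picks <- vapply(sets, function(s) s[ceiling(stats::runif(1) * length(s))],
                      character(1))
      emoticons[has_emo] <- as.list(picks)
    }
    df <- data.frame(tweet_id = sprintf("t%07d", seq_len(total) - 1L),
                     user_id = user, timestamp = ts,
                     stringsAsFactors = FALSE)
    df$tokens <- tokens
    df$emoticons <- emoticons
    df$retweet_of <- rep(NA_character_, total)
    df$mentions <- rep(list(character(0)), total)
    df$emotion_true <- emotion
    df
  })

  # per-edge interaction events
  withr_seed(child_seed(config$seed, "interactions"), {
    el <- igraph::as_data_frame(graph, what = "edges")
    if (nrow(el) > 0L) {
      mean_edge <- rep(config$interaction_mean, nrow(el))
      if (config$weight_similarity) {
        sim <- 1 - 0.5 * rowSums(abs(truth$mixtures[el$from, , drop = FALSE] -
                                     truth$mixtures[el$to, , drop = FALSE]))
        # rank-based coupling: the most similar edges get about twice the
        # configured mean, the least similar about 1; scale-free in rho and
        # mean-preserving, so thresholding on count selects similar pairs
        pct <- (rank(sim, ties.method = "first") - 0.5) / length(sim)
        mean_edge <- 1 + (config$interaction_mean - 1) * 2 * pct
      }
      p_edge <- 1 / pmax(mean_edge, 1)
      n_events <- 1L + stats::rgeom(nrow(el), p_edge)
      tweets_by_user <- split(seq_len(nrow(tweets)), tweets$user_id)
      edge_of <- rep.int(seq_len(nrow(el)), n_events)
      pick_a <- stats::runif(length(edge_of)) < 0.5
      author <- ifelse(pick_a, el$from[edge_of], el$to[edge_of])
      target <- ifelse(pick_a, el$to[edge_of], el$from[edge_of])
      is_rt <- stats::runif(length(edge_of)) < 0.5
      urand <- stats::runif(length(edge_of))
      for (i in seq_along(edge_of)) {
        cand <- tweets_by_user[[author[i]]]
        tw <- cand[ceiling(urand[i] * length(cand))]
        if (is_rt[i] && is.na(tweets$retweet_of[tw])) {
          tweets$retweet_of[tw] <- target[i]
        } else {
          tweets$mentions[[tw]] <- c(tweets$mentions[[tw]], target[i])
        }
      }
    }
    tweets
  })
}

#' Generate and write a complete synthetic corpus
#'
#' Orchestrates [generate_network()], [assign_emotions()] and
#' [generate_tweets()], then writes the corpus to `dir`: `tweets.jsonl`
#' (line-delimited tweet records), `ground_truth.tsv` (per-user mixture and
#' dominant emotion), `emoticon_map.tsv`, and `manifest.json` (config echo,
#' seed, record counts). Rerunning with the same config produces
#' byte-identical files.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory `tweets`, `truth`, `graph`
#'   and the output `dir`.
#' @export
generate_corpus <- function(config, dir) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  graph <- generate_network(config)
  truth <- assign_emotions(graph, config)
  tweets <- generate_tweets(graph, truth, config)

  write_tweets(tweets, file.path(dir, "tweets.jsonl"))
  gt <- data.frame(user_id = rownames(truth$mixtures),
                   stringsAsFactors = FALSE)
  gt[paste0("p_", EMOTIONS)] <- as.data.frame(truth$mixtures)
  gt$dominant_emotion <- unname(truth$dominant)
  utils::write.table(format(gt, digits = 15, scientific = FALSE, trim = TRUE),
                     file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_emoticon_map(default_emoticon_map(config$n_emoticons),
                     file.path(dir, "emoticon_map.tsv"))
  manifest <- list(config = unclass(config),
                   n_users = igraph::vcount(graph),
                   n_edges = igraph::ecount(graph),
                   n_tweets = nrow(tweets),
                   n_with_emoticon = sum(lengths(tweets$emoticons) > 0))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tweets = tweets, truth = truth, graph = graph, dir = dir))
}
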