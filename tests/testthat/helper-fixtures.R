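# Shared fixtures and independent oracles for the test suite.

# build a tweet table from parallel lists; defaults give inert fields
make_tweets <- function(user_id, tokens = NULL, emoticons = NULL,
                        retweet_of = NULL, mentions = NULL,
                        timestamp = NULL) {
  n <- length(user_id)
  df <- data.frame(
    tweet_id = sprintf("t%04d", seq_len(n)),
    user_id = user_id,
    timestamp = if (is.null(timestamp)) seq_len(n) else timestamp,
    stringsAsFactors = FALSE)
  df$tokens <- if (is.null(tokens)) rep(list(character(0)), n) else tokens
  df$emoticons <- if (is.null(emoticons)) rep(list(character(0)), n)
                  else emoticons
  df$retweet_of <- if (is.null(retweet_of)) rep(NA_character_, n)
                   else retweet_of
  df$mentions <- if (is.null(mentions)) rep(list(character(0)), n)
                 else mentions
  df
}

# the three-tweet corpus used across classifier examples:
# ("a b", joy), ("a", joy), ("c", anger)
tiny_corpus <- function() {
  corpus <- data.frame(label = c("joy", "joy", "anger"),
                       stringsAsFactors = FALSE)
  corpus$tokens <- list(c("a", "b"), "a", "c")
  corpus[, c("tokens", "label")]
}

# independent shortest-path oracle: Floyd-Warshall on the adjacency matrix,
# no igraph involvement
brute_force_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], nd)
    }
  }
  d
}

# independent local-clustering oracle: explicit neighbor-pair enumeration
brute_force_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    ties <- 0L
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] > 0) ties <- ties + 1L
      }
    }
    2 * ties / (k * (k - 1))
  }, numeric(1))
}

# random undirected simple graph as an adjacency matrix + igraph twin
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  list(adj = adj, graph = g)
}

# synthetic labeled corpus with class-specific vocabularies for classifier
# accuracy checks; overlap is the shared fraction of each class vocabulary
synth_labeled_corpus <- function(n_docs, vocab_per_class = 50,
                                 overlap = 0, len = 8, seed = 1) {
  set.seed(seed)
  n_shared <- round(overlap * vocab_per_class)
  shared <- sprintf("s%03d", seq_len(max(n_shared, 0)))
  vocabs <- lapply(EMOTIONS, function(m) {
    own <- vocab_per_class - n_shared
    c(sprintf("%s%03d", substr(m, 1, 2), seq_len(own)),
      if (n_shared > 0) shared)
  })
  label <- sample(EMOTIONS, n_docs, replace = TRUE)
  tokens <- lapply(label, function(m) {
    sample(vocabs[[match(m, EMOTIONS)]], pmax(1, stats::rpois(1, len)),
           replace = TRUE)
  })
  corpus <- data.frame(label = label, stringsAsFactors = FALSE)
  corpus$tokens <- tokens
  corpus[, c("tokens", "label")]
}
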