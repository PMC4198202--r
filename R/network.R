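#' Count pairwise retweet/mention interactions
#'
#' Every retweet target and every entry in a tweet's mention list contributes
#' one interaction event between the tweet's author and the target user.
#' Events are aggregated over both directions into unordered pairs;
#' self-interactions (a user retweeting or mentioning themselves) are
#' ignored. Repeated mentions of the same user within one tweet count once
#' per occurrence in the mentions list, as provided.
#'
#' @param tweets Tweet data.frame (columns `user_id`, `retweet_of`,
#'   list-column `mentions`).
#' @return data.frame with columns `u`, `v` (endpoints, `u < v`
#'   lexicographically) and `count` (total interaction events).
#' @export
count_interactions <- function(tweets) {
  n <- nrow(tweets)
  empty <- data.frame(u = character(0), v = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  rt_author <- tweets$user_id[!is.na(tweets$retweet_of)]
  rt_target <- tweets$retweet_of[!is.na(tweets$retweet_of)]
  m_len <- lengths(tweets$mentions)
  m_author <- rep.int(tweets$user_id, m_len)
  m_target <- unlist(tweets$mentions, use.names = FALSE)
  a <- c(rt_author, m_author)
  b <- c(rt_target, m_target)
  keep <- !is.na(b) & a != b
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(empty)
  u <- pmin(a, b)
  v <- pmax(a, b)
  key <- paste(u, v, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  out <- data.frame(u = parts[, 1L], v = parts[, 2L],
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select active users
#'
#' A user is active when their tweet count over the observation window
#' strictly exceeds `min_rate * window_days`. The default rate of 0.5 tweets
#' per day encodes the "more than one tweet every two days" rule: over 180
#' days, 91 tweets make a user active, 90 do not.
#'
#' @param tweets Tweet data.frame.
#' @param window_days Observation window length in days.
#' @param min_rate Minimum average tweets per day (default 0.5).
#' @return Character vector of active user ids.
#' @export
active_users <- function(tweets, window_days, min_rate = 0.5) {
  stopifnot(window_days > 0, min_rate > 0)
  counts <- table(tweets$user_id)
  names(counts)[counts > min_rate * window_days]
}

#' Build the interaction network
#'
#' Keeps unordered user pairs whose total interaction count is at least the
#' threshold `n` and whose both endpoints are active; users left without any
#' link are omitted. The result is an undirected weighted graph whose edge
#' weights are the retained interaction counts.
#'
#' @param pair_counts Output of [count_interactions()].
#' @param active Character vector of active user ids (see [active_users()]).
#' @param n Minimum number of interactions per link (integer >= 1).
#' @return An `igraph` object with edge attribute `weight` and graph
#'   attribute `threshold_n`.
#' @export
build_graph <- function(pair_counts, active, n = 5L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("interaction threshold 'n' must be a single integer >= 1",
         call. = FALSE)
  }
  keep <- pair_counts$count >= n &
    pair_counts$u %in% active & pair_counts$v %in% active
  edges <- pair_counts[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$u, to = edges$v, weight = edges$count,
               stringsAsFactors = FALSE),
    directed = FALSE)
  g <- igraph::set_graph_attr(g, "threshold_n", as.integer(n))
  g
}

#' Ordered user pairs at a given hop distance
#'
#' Collects all user pairs at shortest-path distance exactly `h` in the
#' graph, returning both orientations of each unordered pair so that
#' downstream pair statistics are invariant to the source/target labeling.
#' Pairs in different connected components (infinite distance) are excluded.
#'
#' @param graph An `igraph` object.
#' @param h Hop distance (integer >= 1).
#' @return data.frame with columns `source`, `target` (vertex names).
#' @export
hop_pairs <- function(graph, h) {
  if (!is.numeric(h) || length(h) != 1L || h < 1) {
    stop("hop distance 'h' must be a single integer >= 1", call. = FALSE)
  }
  d <- igraph::distances(graph, weights = NA)  # unweighted BFS distances
  idx <- which(d == h, arr.ind = TRUE)         # both orientations included
  nm <- igraph::V(graph)$name
  data.frame(source = nm[idx[, 1L]], target = nm[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Local clustering coefficient
#'
#' Fraction of a node's neighbor pairs that are themselves connected:
#' `2 |E_i| / (k_i (k_i - 1))` where `E_i` is the set of ties among the
#' node's friends and `k_i` its degree. Nodes with degree below 2 are
#' assigned clustering 0.
#'
#' @param graph An `igraph` object.
#' @param v Vertex name(s); default all vertices.
#' @return Numeric vector of clustering coefficients in `[0, 1]`, named by
#'   vertex.
#' @export
local_clustering <- function(graph, v = igraph::V(graph)$name) {
  missing <- setdiff(v, igraph::V(graph)$name)
  if (length(missing)) {
    stop("vertex not in graph: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cc <- igraph::transitivity(graph, type = "local", vids = v, isolates = "zero")
  cc[is.nan(cc)] <- 0
  stats::setNames(cc, v)
}

#' Write an interaction graph as an edge list
#'
#' Three-column tab-separated file `u`, `v`, `weight` with `u < v`
#' lexicographically and rows sorted by (`u`, `v`).
#'
#' @param graph An `igraph` object with a `weight` edge attribute.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  u <- pmin(el$from, el$to)
  v <- pmax(el$from, el$to)
  out <- data.frame(u = u, v = v, weight = el$weight,
                    stringsAsFactors = FALSE)
  out <- out[order(out$u, out$v), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
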