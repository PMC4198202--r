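test_that("pearson matches perfect linear relations and the textbook formula", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  x <- c(0.1, 0.4, 0.3, 0.2)
  y <- c(0.2, 0.3, 0.5, 0.0)
  expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1, 1), "at least 2")
})

test_that("spearman follows the rank-difference formula and rank invariance", {
  # d^2 sums to 2: rho = 1 - 6*2 / (4 * 15) = 0.8
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # invariant under strictly increasing transforms
  x <- c(0.3, 1.2, 5.9, 2.2, 4.4)
  expect_equal(spearman_rho(x, exp(x)), 1)
  # ties fall back to pearson-of-ranks, matching stats::cor
  xt <- c(1, 2, 2, 3)
  yt <- c(4, 4, 5, 6)
  expect_equal(spearman_rho(xt, yt),
               stats::cor(xt, yt, method = "spearman"), tolerance = 1e-12)
})

test_that("both correlations agree with stats::cor on 1000 random pairs", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(2:50, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-12)
    expect_equal(spearman_rho(x, y),
                 stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
    # tie-free: the rank-difference form equals pearson on ranks
    expect_equal(spearman_rho(x, y), pearson_r(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap on identical sequences is exactly 1 with zero error", {
  bs <- bootstrap_corr(c(1, 2, 3), c(1, 2, 3), B = 50, seed = 4)
  expect_equal(bs$r_mean, 1)
  expect_equal(bs$r_std, 0)
  expect_true(bs$n_degenerate >= 0)
})

test_that("bootstrap is deterministic under a fixed seed", {
  set.seed(7)
  x <- stats::rnorm(40)
  y <- x + stats::rnorm(40)
  b1 <- bootstrap_corr(x, y, B = 100, seed = 12)
  b2 <- bootstrap_corr(x, y, B = 100, seed = 12)
  expect_identical(b1, b2)
  b3 <- bootstrap_corr(x, y, B = 100, seed = 13)
  expect_false(identical(b1$r_mean, b3$r_mean))
})

test_that("bootstrap error shrinks roughly as 1/sqrt(N)", {
  ratios <- vapply(1:3, function(s) {
    set.seed(s)
    make_xy <- function(n) {
      x <- stats::rnorm(n)
      y <- 0.5 * x + sqrt(1 - 0.25) * stats::rnorm(n)  # true r = 0.5
      list(x = x, y = y)
    }
    small <- make_xy(200)
    big <- make_xy(2000)
    sd_small <- bootstrap_corr(small$x, small$y, B = 300, seed = s)$r_std
    sd_big <- bootstrap_corr(big$x, big$y, B = 300, seed = s)$r_std
    sd_big / sd_small
  }, numeric(1))
  # expected ratio 1/sqrt(10) ~ 0.316; allow a factor of 2 either way
  expect_true(all(ratios > 0.316 / 2 & ratios < 0.316 * 2))
})

test_that("bootstrap mean converges to the plain estimate", {
  set.seed(9)
  n <- 2000
  x <- stats::rnorm(n)
  y <- 0.5 * x + stats::rnorm(n)
  plain <- pearson_r(x, y)
  bs <- bootstrap_corr(x, y, B = 1000, seed = 2)
  expect_lt(abs(bs$r_mean - plain), 0.02)
})

test_that("all-degenerate bootstrap raises", {
  expect_error(bootstrap_corr(c(0, 0, 0), c(1, 2, 3), B = 10, seed = 1),
               "degenerate|constant")
})

test_that("shuffling kills a strong correlation and is reproducible", {
  set.seed(11)
  n <- 2000
  x <- stats::rnorm(n)
  y <- 0.6 * x + stats::rnorm(n)
  expect_gt(pearson_r(x, y), 0.4)
  r_sh <- shuffle_null(x, y, seed = 5)
  expect_lt(abs(r_sh), 0.05)
  expect_identical(r_sh, shuffle_null(x, y, seed = 5))
  # length-2 sequences admit only the two perfect orderings
  expect_true(shuffle_null(c(1, 2), c(3, 4), seed = 1) %in% c(-1, 1))
})

test_that("per-user emotion vectors are the class fractions of tweet labels", {
  tw <- make_tweets(user_id = rep("u1", 4))
  labels <- c("anger", "anger", "joy", "sadness")
  v <- emotion_vector(tw, labels = labels)
  expect_equal(unname(v), c(0.5, 0.25, 0.25, 0))
  v2 <- emotion_vector(make_tweets(user_id = "u1"), labels = "joy")
  expect_equal(unname(v2), c(0, 1, 0, 0))
  expect_error(emotion_vector(make_tweets(character(0))), "no tweets")
})

test_that("emoticon-labeled tweets keep their label; the rest are classified", {
  map <- default_emoticon_map()
  sad_tok <- map$emoticon[map$emotion == "sadness"][1]
  train <- tiny_corpus()
  m <- nb_train(train)
  # tweet 1 carries a sadness emoticon but joy-looking text; tweet 2 has
  # no emoticon and classifies as joy
  tw <- make_tweets(user_id = c("u1", "u1"),
                    tokens = list(c("a", "b"), c("a", "b")),
                    emoticons = list(sad_tok, character(0)))
  ev <- user_emotion_vectors(tw, m, map)
  expect_equal(unname(ev$fractions["u1", ]), c(0, 0.5, 0.5, 0))
})

test_that("empirical vectors concentrate around the true mixture", {
  set.seed(15)
  mix <- c(0.7, 0.1, 0.1, 0.1)
  labels <- sample(EMOTIONS, 200, replace = TRUE, prob = mix)
  v <- emotion_vector(make_tweets(user_id = rep("u", 200)), labels = labels)
  expect_true(all(abs(v - mix) < 0.1))
})

test_that("dominant emotion is the argmax with canonical tie-break", {
  expect_identical(dominant_emotion(c(0.5, 0.25, 0.25, 0)), "anger")
  expect_identical(dominant_emotion(c(0.25, 0.25, 0.25, 0.25)), "anger")
  expect_identical(dominant_emotion(c(0, 1, 0, 0)), "joy")
  m <- rbind(a = c(0, 0, 1, 0), b = c(0.2, 0.1, 0.3, 0.4))
  expect_identical(unname(dominant_emotion(m)), c("sadness", "disgust"))
})

test_that("two mirrored users at hop 1 give r = -1 over both orientations", {
  g <- igraph::make_graph(~ a - b)
  fr <- rbind(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0))
  colnames(fr) <- EMOTIONS
  est <- pairwise_correlation(g, fr, h = 1, emotion = "anger", B = 50,
                              seed = 2)
  expect_equal(est$n_pairs, 2L)
  expect_equal(est$r_mean, -1)
})

test_that("identical vectors everywhere make the correlation undefined", {
  g <- igraph::make_graph(~ a - b, b - c)
  fr <- rbind(a = c(0.25, 0.25, 0.25, 0.25), b = c(0.25, 0.25, 0.25, 0.25),
              c = c(0.25, 0.25, 0.25, 0.25))
  colnames(fr) <- EMOTIONS
  expect_error(pairwise_correlation(g, fr, h = 1, emotion = "joy", B = 10),
               "constant")
})

test_that("pairwise correlation is invariant to source/target relabeling", {
  tg <- random_test_graph(40, 0.12, seed = 19)
  set.seed(20)
  fr <- matrix(stats::runif(40 * 4), ncol = 4,
               dimnames = list(as.character(1:40), EMOTIONS))
  fr <- fr / rowSums(fr)
  est <- pairwise_correlation(tg$graph, fr, h = 2, emotion = "anger",
                              B = 100, seed = 3)
  # with both orientations included, swapping X and Y changes nothing:
  # verify directly on the plain estimate
  p <- hop_pairs(tg$graph, 2)
  r_fwd <- pearson_r(fr[p$source, "anger"], fr[p$target, "anger"])
  r_rev <- pearson_r(fr[p$target, "anger"], fr[p$source, "anger"])
  expect_equal(r_fwd, r_rev, tolerance = 1e-12)
  expect_equal(est$r_mean, r_fwd, tolerance = 0.05)
})

test_that("neighborhood vectors sum counts, not fractions", {
  g <- igraph::make_graph(~ v - n1, v - n2)
  counts <- rbind(v = c(1L, 0L, 0L, 0L),
                  n1 = c(9L, 0L, 0L, 0L),
                  n2 = c(0L, 1L, 0L, 0L))
  colnames(counts) <- EMOTIONS
  nv <- neighborhood_vector(g, "v", counts)
  expect_equal(unname(nv), c(0.9, 0.1, 0, 0))
  # balanced case: (3 anger, 1 joy) + (1 anger, 3 joy) -> (0.5, 0.5)
  counts2 <- rbind(v = c(0L, 0L, 1L, 0L),
                   n1 = c(3L, 1L, 0L, 0L),
                   n2 = c(1L, 3L, 0L, 0L))
  colnames(counts2) <- EMOTIONS
  expect_equal(unname(neighborhood_vector(g, "v", counts2)),
               c(0.5, 0.5, 0, 0))
  # a single neighbor reproduces that neighbor's own vector
  expect_equal(unname(neighborhood_vector(g, "n1", counts)),
               c(1, 0, 0, 0))
  g2 <- igraph::make_graph(~ a - b) + igraph::vertices("lonely")
  expect_error(neighborhood_vector(g2, "lonely", counts), "no neighbors")
})

test_that("degree stratification drops small groups and degenerate strata", {
  tg <- random_test_graph(10, 0.3, seed = 23)
  set.seed(24)
  fr <- matrix(stats::runif(40), ncol = 4,
               dimnames = list(as.character(1:10), EMOTIONS))
  fr <- fr / rowSums(fr)
  cnt <- round(fr * 100)
  expect_warning(
    out <- degree_stratified(tg$graph, fr, cnt, emotion = "anger",
                             B = 20, min_group = 30, seed = 1),
    "min_group")
  expect_equal(nrow(out), 0L)
})

test_that("clustering bins follow the half-open linear-bin convention", {
  # width 1.0 puts everyone in a single bin: equals the all-nodes estimate
  tg <- random_test_graph(60, 0.1, seed = 29)
  set.seed(30)
  fr <- matrix(stats::runif(240), ncol = 4,
               dimnames = list(as.character(1:60), EMOTIONS))
  fr <- fr / rowSums(fr)
  cnt <- round(fr * 100)
  one <- clustering_binned(tg$graph, fr, cnt, emotion = "joy",
                           bin_width = 1.0, B = 50, min_group = 2, seed = 5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$stratum_value, 0)
  expect_equal(one$n_pairs, 60L)
  # a tree has clustering 0 everywhere: everything lands in bin 0
  tree <- igraph::make_tree(30, children = 2, mode = "undirected")
  igraph::V(tree)$name <- as.character(1:30)
  set.seed(31)
  fr_t <- matrix(stats::runif(120), ncol = 4,
                 dimnames = list(as.character(1:30), EMOTIONS))
  fr_t <- fr_t / rowSums(fr_t)
  binned <- clustering_binned(tree, fr_t, round(fr_t * 50), emotion = "joy",
                              bin_width = 0.1, B = 20, min_group = 2,
                              seed = 6)
  expect_equal(binned$stratum_value, 0)
  expect_equal(binned$n_pairs, 30L)
  # boundary value 0.1 with width 0.1 belongs to the second bin
  expect_equal(floor(0.1 / 0.1), 1)
})

test_that("threshold sweep reduces to a single pairwise call at one cell", {
  set.seed(35)
  n_users <- 30
  ids <- sprintf("u%02d", 1:n_users)
  tw <- make_tweets(
    user_id = rep(ids, each = 5),
    mentions = lapply(rep(ids, each = 5), function(u) {
      sample(setdiff(ids, u), 2)
    }))
  fr <- matrix(stats::runif(n_users * 4), ncol = 4,
               dimnames = list(ids, EMOTIONS))
  fr <- fr / rowSums(fr)
  sw <- threshold_sweep(tw, fr, n_values = 1, h_values = 1,
                        emotions = "anger", B = 50, seed = 8,
                        window_days = 2, min_rate = 0.5)
  expect_equal(nrow(sw), 1L)
  pc <- count_interactions(tw)
  g <- build_graph(pc, active_users(tw, 2, 0.5), 1)
  direct <- pairwise_correlation(g, fr, h = 1, emotion = "anger", B = 50,
                                 seed = emocorr:::child_seed(8, "n1h1anger"))
  expect_equal(sw$r_mean, direct$r_mean)
  # a threshold beyond every edge weight leaves no rows
  sw_empty <- threshold_sweep(tw, fr, n_values = 999, h_values = 1,
                              B = 10, seed = 1, window_days = 2)
  expect_equal(nrow(sw_empty), 0L)
})
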