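test_that("search bias follows the three-distance rule and rejects bad input", {
  for (pq in list(c(0.25, 4), c(4, 0.25), c(1, 2), c(2, 1))) {
    expect_equal(search_bias(1, pq[1], pq[2]), 1)
    expect_equal(search_bias(0, pq[1], pq[2]), 1 / pq[1])
    expect_equal(search_bias(2, pq[1], pq[2]), 1 / pq[2])
  }
  expect_equal(search_bias(0, 4, 1), 0.25)
  expect_equal(search_bias(2, 1, 2), 0.5)
  expect_error(search_bias(3, 1, 1), "0, 1 or 2")
  expect_error(search_bias(1, 0, 1), "positive")
  expect_error(search_bias(1, 1, -2), "positive")
})

test_that("second-step distribution matches the hand-derived toy example", {
  # t-v, t-x1, v-x1, v-x2 with unit weights, p=1, q=2:
  # from v given previous t: {t: 1/p=1, x1: 1 (shared nbr), x2: 1/q=0.5}
  net <- toy_net("t-v t-x1 v-x1 v-x2")
  idx <- build_transition_index(net, walk_config(p = 1, q = 2))
  t <- match("t", net$nodes); v <- match("v", net$nodes)
  d <- get(paste0(t, "|", v), envir = idx$second_step)
  got <- setNames(d$prob, net$nodes[d$nbr])
  expect_equal(got[c("t", "x1", "x2")], c(t = 0.4, x1 = 0.4, x2 = 0.2))
})

test_that("second-step mass vanishes in the q -> infinity limit", {
  net <- toy_net("t-v t-x1 v-x1 v-x2")
  idx <- build_transition_index(net, walk_config(p = 1, q = 1e12))
  t <- match("t", net$nodes); v <- match("v", net$nodes)
  d <- get(paste0(t, "|", v), envir = idx$second_step)
  expect_lt(d$prob[d$nbr == match("x2", net$nodes)], 1e-9)
})

test_that("single-neighbor nodes force a return step", {
  net <- toy_net("t-v")
  idx <- build_transition_index(net, walk_config(p = 7, q = 0.3))
  t <- match("t", net$nodes); v <- match("v", net$nodes)
  d <- get(paste0(t, "|", v), envir = idx$second_step)
  expect_equal(d$prob, 1)
  expect_equal(d$nbr, t)
})

test_that("transition index equals brute-force BFS recomputation on small graphs", {
  # exhaustive over all labeled 4-node graphs, plus random 5-8 node graphs
  check_graph <- function(net, p, q) {
    idx <- build_transition_index(net, walk_config(p = p, q = q))
    for (v in seq_along(net$nodes)) {
      for (t in net$adj$nbr[[v]]) {
        got <- get(paste0(t, "|", v), envir = idx$second_step)
        want <- oracle_second_step(net, t, v, p, q)
        expect_equal(sort(got$nbr), sort(want$nbr))
        expect_equal(got$prob[order(got$nbr)], want$prob[order(want$nbr)],
                     tolerance = 1e-12)
        expect_equal(sum(got$prob), 1, tolerance = 1e-9)
      }
    }
  }
  nodes4 <- c("a", "b", "c", "d")
  pairs4 <- t(combn(4, 2))
  for (mask in seq_len(2^6) - 1L) {
    on <- bitwAnd(bitwShiftR(mask, 0:5), 1L) == 1L
    if (!any(on)) next
    net <- ppi_network(nodes4, data.frame(from = nodes4[pairs4[on, 1]],
                                          to = nodes4[pairs4[on, 2]]))
    check_graph(net, p = 0.25, q = 4)
  }
  for (s in 1:20) {
    n <- sample(5:8, 1)
    net <- random_net(n, 0.4, seed = 1000 + s)
    if (!n_edges(net)) next
    check_graph(net, p = 2, q = 0.5)
  }
})

test_that("with p = q = 1 and unit weights the second step is uniform over neighbors", {
  net <- random_net(10, 0.4, seed = 5)
  idx <- build_transition_index(net, walk_config(p = 1, q = 1))
  for (v in seq_along(net$nodes)) {
    for (t in net$adj$nbr[[v]]) {
      d <- get(paste0(t, "|", v), envir = idx$second_step)
      expect_equal(d$prob, rep(1 / length(d$nbr), length(d$nbr)))
    }
  }
})

test_that("walks on a 2-node path alternate deterministically", {
  net <- toy_net("A-B")
  cfg <- walk_config(walks_per_node = 3, walk_length = 4, seed = 9)
  walks <- simulate_walks(net, build_transition_index(net, cfg), cfg)
  expect_length(walks, 6)
  for (w in walks) {
    expect_true(identical(w, c("A", "B", "A", "B")) ||
                identical(w, c("B", "A", "B", "A")))
  }
})

test_that("sampled second steps match the index distribution (chi-square)", {
  net <- toy_net("a-b b-c a-c a-d")  # triangle plus pendant, non-uniform bias
  cfg <- walk_config(p = 4, q = 0.25, walks_per_node = 2000,
                     walk_length = 10, seed = 11)
  idx <- build_transition_index(net, cfg)
  walks <- simulate_walks(net, idx, cfg)
  # collect empirical transitions following the directed edge (b, a)
  b <- match("b", net$nodes); a <- match("a", net$nodes)
  nxt <- character(0)
  for (w in walks) {
    L <- length(w)
    if (L < 3) next
    i <- 2:(L - 1)
    hits <- i[w[i - 1] == "b" & w[i] == "a"]
    if (length(hits)) nxt <- c(nxt, w[hits + 1L])
  }
  expect_gt(length(nxt), 5000)
  d <- get(paste0(b, "|", a), envir = idx$second_step)
  expected_p <- d$prob[order(d$nbr)]
  observed <- table(factor(nxt, levels = net$nodes[sort(d$nbr)]))
  chi <- suppressWarnings(stats::chisq.test(observed, p = expected_p))
  expect_gt(chi$p.value, 0.001)
})

test_that("walk simulation is bit-reproducible and covers every node", {
  net <- random_net(12, 0.35, seed = 3)
  cfg <- walk_config(walks_per_node = 4, walk_length = 8, seed = 21)
  idx <- build_transition_index(net, cfg)
  w1 <- simulate_walks(net, idx, cfg)
  w2 <- simulate_walks(net, idx, cfg)
  expect_identical(w1, w2)
  counts <- table(unlist(w1))
  for (v in net$nodes[degrees(net) > 0]) {
    expect_gte(unname(counts[v]), cfg$walks_per_node)
  }
})

test_that("isolated nodes are skipped and reported", {
  net <- ppi_network(c("A", "B", "Z"), data.frame(from = "A", to = "B"))
  cfg <- walk_config(walks_per_node = 2, walk_length = 3, seed = 1)
  walks <- simulate_walks(net, build_transition_index(net, cfg), cfg)
  expect_equal(attr(walks, "skipped"), "Z")
  expect_false("Z" %in% unlist(walks))
})

test_that("skip-gram: zero epochs returns the seeded initialization; training is deterministic", {
  net <- random_net(10, 0.5, seed = 2)
  cfg <- walk_config(walks_per_node = 3, walk_length = 10, seed = 4)
  walks <- simulate_walks(net, build_transition_index(net, cfg), cfg)
  sg0 <- skipgram_config(dim = 8, epochs = 0, seed = 31)
  e1 <- train_skipgram(walks, sg0)
  e2 <- train_skipgram(walks, sg0)
  expect_identical(e1$vectors, e2$vectors)
  expect_true(all(abs(e1$vectors) <= 0.5 / 8))  # untouched uniform init
  sg <- skipgram_config(dim = 8, epochs = 3, seed = 31)
  t1 <- train_skipgram(walks, sg)
  t2 <- train_skipgram(walks, sg)
  expect_identical(t1$vectors, t2$vectors)
  expect_false(identical(t1$vectors, e1$vectors))
  expect_error(train_skipgram(list(), sg), "empty")
})

test_that("embeddings separate two cliques joined by a bridge", {
  cliq <- function(tag) {
    v <- paste0(tag, 1:6)
    pr <- t(combn(6, 2))
    data.frame(from = v[pr[, 1]], to = v[pr[, 2]])
  }
  edges <- rbind(cliq("L"), cliq("R"),
                 data.frame(from = "L1", to = "R1"))
  net <- ppi_network(c(paste0("L", 1:6), paste0("R", 1:6)), edges)
  wins <- 0
  for (s in 1:5) {
    wc <- walk_config(walks_per_node = 10, walk_length = 20, seed = s)
    walks <- simulate_walks(net, build_transition_index(net, wc), wc)
    emb <- train_skipgram(walks, skipgram_config(dim = 16, window = 5,
                                                 seed = s))
    V <- emb$vectors[match(net$nodes, emb$genes), ]
    cs <- V / sqrt(rowSums(V^2))
    S <- cs %*% t(cs)
    grp <- rep(c(TRUE, FALSE), each = 6)
    intra <- mean(S[grp, grp][upper.tri(S[grp, grp])]) / 2 +
             mean(S[!grp, !grp][upper.tri(S[!grp, !grp])]) / 2
    inter <- mean(S[grp, !grp])
    if (intra > inter) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("embedding files round-trip through word2vec text format", {
  e <- embedding_matrix("G1", matrix(c(0, 0), 1, 2))
  f <- withr::local_tempfile()
  write_embeddings(e, f)
  lines <- readLines(f)
  expect_equal(lines[1], "1 2")
  expect_match(lines[2], "^G1 0(\\.0+)? 0(\\.0+)?$")

  set.seed(8)
  e2 <- embedding_matrix(sprintf("G%d", 1:5), matrix(rnorm(80), 5, 16))
  write_embeddings(e2, f)
  back <- read_embeddings(f)
  expect_equal(back$genes, e2$genes)
  expect_lt(max(abs(back$vectors - e2$vectors)), 1e-7)

  writeLines(c("3 2", "A 1 2", "B 3 4"), f)
  expect_error(read_embeddings(f), "declares 3 rows")
})

test_that("embed_network gives isolated nodes the zero vector and flags them", {
  net <- ppi_network(c("A", "B", "C", "Z"),
                     data.frame(from = c("A", "B", "A"),
                                to = c("B", "C", "C")))
  emb <- embed_network(net, walk_config(walks_per_node = 2, walk_length = 5,
                                        seed = 1),
                       skipgram_config(dim = 4, epochs = 1, seed = 1))
  expect_equal(emb$genes, net$nodes)
  expect_equal(unname(emb$vectors["Z", ]), rep(0, 4))
  expect_equal(attr(emb, "isolated"), "Z")
})
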