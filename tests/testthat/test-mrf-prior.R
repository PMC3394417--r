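# The regulation/interaction encodings and the seven feature functions are
# frozen against the printed enumeration (helper unary_feature_table()).

test_that("regulation encoding follows the state enumeration", {
  expect_equal(encode_regulation(1, 1), 1L)
  expect_equal(encode_regulation(1, 0), 2L)
  expect_equal(encode_regulation(0, 1), 3L)
  expect_equal(encode_regulation(0, 0), 4L)
  expect_error(encode_regulation(2, 0), "0 or 1")
})

test_that("interaction encoding is the bijection 4(Zi-1)+Zj on 1..16", {
  seen <- integer(0)
  for (zi in 1:4) for (zj in 1:4) {
    x <- encode_interaction(zi, zj)
    expect_equal(x, 4L * (zi - 1L) + zj)
    d <- decode_interaction(x)
    expect_equal(c(d$zi, d$zj), c(zi, zj))
    seen <- c(seen, x)
  }
  expect_setequal(seen, 1:16)
  expect_equal(encode_interaction(2, 3), 7L)
  expect_equal(decode_interaction(16), list(zi = 4L, zj = 4L))
  expect_error(encode_interaction(0, 1))
  expect_error(decode_interaction(17))
})

test_that("unary features reproduce the printed table for all 16 values", {
  tab <- unary_feature_table()
  for (r in seq_len(nrow(tab))) {
    f <- eval_features(tab$X[r])
    expect_equal(unname(f[c("F1", "F2", "F3", "F6", "F7")]),
                 unlist(tab[r, c("F1", "F2", "F3", "F6", "F7")], use.names = FALSE),
                 info = sprintf("X = %d", tab$X[r]))
    expect_equal(unname(f["F4"]), 0)  # no neighbors
    expect_equal(unname(f["F5"]), 0)
  }
  # exactly 8 values fire each internal-equality feature; F1 fires only at 2
  expect_equal(sum(tab$F6), 8)
  expect_equal(sum(tab$F7), 8)
  expect_equal(tab$X[tab$F1 == 1], 2)
  expect_equal(tab$X[tab$F2 == 1], 3)
})

test_that("pairwise features reproduce the left/right equality patterns", {
  rowz <- function(x) (x - 1) %/% 4 + 1
  colz <- function(x) (x - 1) %% 4 + 1
  n_left <- 0L; n_right <- 0L
  for (x in 1:16) for (u in 1:16) {
    if (colz(u) == colz(x)) { # reachable left-neighbor cell
      f <- eval_features(x, left = u)
      expect_equal(unname(f["F4"]), as.numeric(rowz(u) == rowz(x)),
                   info = sprintf("left x=%d u=%d", x, u))
      n_left <- n_left + 1L
    } else {
      expect_error(eval_features(x, left = u), "unreachable")
    }
    if (rowz(u) == rowz(x)) { # reachable right-neighbor cell
      f <- eval_features(x, right = u)
      expect_equal(unname(f["F5"]), as.numeric(colz(u) == colz(x)),
                   info = sprintf("right x=%d u=%d", x, u))
      n_right <- n_right + 1L
    } else {
      expect_error(eval_features(x, right = u), "unreachable")
    }
  }
  expect_equal(n_left, 64L)   # 16 rows x 4 filled cells
  expect_equal(n_right, 64L)
  # counting semantics: several agreeing neighbors accumulate
  expect_equal(unname(eval_features(6, left = c(6, 6, 2))["F4"]), 2)
})

test_that("interaction graph has one node per edge and the stated neighbors", {
  # chain g1 -> g2 -> g3 plus metagene
  ext <- extend_with_metagene(chain_network(3))
  ig <- build_interaction_graph(ext)
  expect_equal(nrow(ig$nodes), 5L)  # 3 metagene edges + 2 chain edges
  node <- function(i, j) which(ig$nodes$i == i & ig$nodes$j == j)
  # right neighbors of X_12 include the virtual X_13 (shared source, edge g2->g3)
  rn <- ig$right_nbrs[[node("g1", "g2")]]
  expect_true(any(rn$i == "g1" & rn$j == "g3"))
  expect_true(is.na(rn$node[rn$i == "g1" & rn$j == "g3"]))  # virtual: no such edge
  # left neighbors of X_23 include the real node X_12? no: left of (2,3) is
  # X_k3 for k in In(g2) = {g0, g1}; X_13 is virtual, X_03 is real
  ln <- ig$left_nbrs[[node("g2", "g3")]]
  expect_setequal(ln$i, c("__g0__", "g1"))
  expect_true(!is.na(ln$node[ln$i == "__g0__"]))
  expect_true(is.na(ln$node[ln$i == "g1"]))

  # disconnected edges share no MRF neighbors
  net2 <- gene_network(c("a", "c"), c("b", "d"))
  ig2 <- build_interaction_graph(extend_with_metagene(net2))
  nd <- function(i, j) which(ig2$nodes$i == i & ig2$nodes$j == j)
  ab <- nd("a", "b"); cd <- nd("c", "d")
  expect_false(cd %in% ig2$left_nbrs[[ab]]$node)
  expect_false(cd %in% ig2$right_nbrs[[ab]]$node)
})

test_that("nodes sharing a target are neighbors when their sources interact", {
  # g2 -> g3, both regulating g5: X_35 and X_25 are MRF neighbors
  net <- gene_network(c("g2", "g3", "g2"), c("g3", "g5", "g5"))
  ig <- build_interaction_graph(extend_with_metagene(net))
  n35 <- which(ig$nodes$i == "g3" & ig$nodes$j == "g5")
  ln <- ig$left_nbrs[[n35]]
  expect_true(any(ln$i == "g2" & ln$j == "g5" & !is.na(ln$node)))
})

test_that("conditional prior is a proper distribution with the stated limits", {
  # gamma = 0: uniform
  expect_equal(conditional_prior(rep(0, 7)), rep(1 / 16, 16))
  # gamma1 = ln 2, no neighbors: value 2 doubles its weight
  p <- conditional_prior(c(log(2), rep(0, 6)))
  expect_equal(p[2], 2 / 17)
  expect_equal(p[-2], rep(1 / 17, 15))
  # normalization and shift invariance under arbitrary gammas/neighbors
  set.seed(4)
  for (i in 1:20) {
    g <- runif(7, -5, 5)
    x <- sample(16, 1)
    left <- sample(16, sample(0:3, 1), replace = TRUE)
    left <- left[(left - 1) %% 4 == (x - 1) %% 4]
    p <- conditional_prior(g, left = left)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # adding a constant to the three frequency features shifts all weights
    # equally and leaves the distribution unchanged
    g2 <- g + c(3, 3, 3, 0, 0, 0, 0)
    expect_equal(conditional_prior(g2, left = left), p, tolerance = 1e-12)
  }
})

test_that("conditional prior matches brute-force enumeration on a tiny MRF", {
  # two nodes sharing a target: X_ab and X_cb with a -> c in the network.
  # brute force: enumerate the node's 16 candidates directly from the
  # feature definitions.
  gamma <- c(0.7, -0.3, 0.2, 0.9, -0.4, 0.5, 0.1)
  x_other <- 7L  # current value of the left neighbor
  rowz <- function(x) (x - 1) %/% 4 + 1
  colz <- function(x) (x - 1) %% 4 + 1
  # f4 compares the source-regulation components of the node and its left
  # neighbor; features are recomputed for each candidate with the neighbor
  # assignment held fixed
  brute <- vapply(1:16, function(t) {
    feats <- c(t == 2, t == 3, !(t %in% c(2, 3)),
               rowz(x_other) == rowz(t), 0,
               rowz(t) %in% c(1, 4), colz(t) %in% c(1, 4))
    exp(sum(gamma * feats))
  }, numeric(1))
  expect_equal(conditional_prior(gamma, left = x_other), brute / sum(brute),
               tolerance = 1e-12)
})
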