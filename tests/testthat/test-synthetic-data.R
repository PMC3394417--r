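test_that("control emulator draws per-gene Gaussians reproducibly", {
  g <- generate_control(1, 10000, mu_range = c(5, 5), sigma_range = c(1, 1),
                        seed = 1)
  expect_equal(mean(g$mat), 5, tolerance = 0.05)
  expect_equal(sd(g$mat[1, ]), 1, tolerance = 0.05)
  g2 <- generate_control(1, 10000, mu_range = c(5, 5), sigma_range = c(1, 1),
                         seed = 1)
  expect_identical(g$mat, g2$mat)
  # supplied per-gene parameters short-circuit the uniform draw
  g3 <- generate_control(3, 5, mu = c(1, 2, 3), sigma = c(1, 1, 1), seed = 2)
  expect_equal(unname(g3$mu), c(1, 2, 3))
  expect_error(generate_control(2, 5, sigma_range = c(-1, 1)))
})

test_that("secondary labelling follows the 1-(1-q)^eta rule on a star", {
  # hub -> 1000 leaves: with the hub as the single primary, every leaf is
  # visited once at eta = 1, so the labelling rate estimates q = 0.4
  # (binomial sd 0.015 at 1000 leaves).
  leaves <- paste0("leaf", 1:1000)
  net <- gene_network(rep("hub", 1000), leaves)
  stopifnot(net$genes[1] == "hub")  # lexicographic order puts the hub first
  hub_seed <- Find(function(s) {
    cmrf:::with_seed(s, function() sample.int(1001, 1)) == 1L
  }, 1:5000)
  sets <- select_affected_sets(net, n_primary = 1, q = 0.4, seed = hub_seed)
  expect_identical(sets$primary, "hub")
  rate <- length(sets$secondary) / 1000
  expect_gt(rate, 0.35)
  expect_lt(rate, 0.45)
})

test_that("affected sets respect exclusions, targets and determinism", {
  net <- random_scalefree_network(200, seed = 3)
  a <- select_affected_sets(net, 5, seed = 4)
  b <- select_affected_sets(net, 5, seed = 4)
  expect_identical(a, b)
  expect_length(a$primary, 5L)
  expect_length(intersect(a$primary, a$secondary), 0L)
  # exclusion: a second set avoids the first entirely
  c2 <- select_affected_sets(net, 5, seed = 9,
                             exclude = c(a$primary, a$secondary))
  expect_length(intersect(c(c2$primary, c2$secondary),
                          c(a$primary, a$secondary)), 0L)
  # exact secondary target
  t2 <- select_affected_sets(net, 8, seed = 5, n_secondary = 10)
  expect_length(t2$secondary, 10L)
  # zero-primary sets are empty
  z <- select_affected_sets(net, 0, seed = 1)
  expect_length(z$primary, 0L)
  expect_length(z$secondary, 0L)
  expect_error(select_affected_sets(net, 9999, seed = 1), "exceeds")
})

test_that("two-group truth plants disjoint sets with the requested counts", {
  net <- random_scalefree_network(400, seed = 11)
  truth <- build_two_group_truth(
    net, list(list(n_primary = 10), list(n_primary = 25), list(n_primary = 25)),
    seed = 12)
  expect_length(truth$pdr, 50L)  # 25 + 25 group-specific primaries
  all_members <- unlist(lapply(truth$sets, function(s) c(s$primary, s$secondary)))
  expect_false(any(duplicated(all_members)))
  lab <- truth$labels
  # group-A-only members are unaffected in B and vice versa
  setA <- c(truth$sets[[2]]$primary, truth$sets[[2]]$secondary)
  expect_true(all(lab$role_B[lab$gene %in% setA] == "unaffected"))
  expect_true(all(lab$role_A[lab$gene %in% setA] != "unaffected"))
  # the shared set is affected in both groups
  er <- truth$er_affected
  expect_true(all(lab$role_A[lab$gene %in% er] != "unaffected"))
  expect_true(all(lab$role_B[lab$gene %in% er] != "unaffected"))
})

test_that("Gaussian shifts respect the labels, sizes and variances", {
  net <- random_scalefree_network(120, seed = 21)
  truth <- build_two_group_truth(
    net, list(list(n_primary = 4), list(n_primary = 4), list(n_primary = 4)),
    seed = 22)
  cA <- generate_control(120, 155, seed = 23, genes = net$genes)
  cB <- generate_control(120, 155, seed = 24, genes = net$genes,
                         mu = cA$mu, sigma = cA$sigma)
  dat <- generate_two_group(cA$mat, cB$mat, truth, d_p = 2, d_s = 1, seed = 25)
  expect_identical(generate_two_group(cA$mat, cB$mat, truth, 2, 1, seed = 25)$A$noncontrol,
                   dat$A$noncontrol)
  # per-gene non-control variance tracks the control variance
  ratio <- apply(dat$A$noncontrol, 1, var) / apply(dat$A$control, 1, var)
  expect_true(all(ratio > 0.7 & ratio < 1.4))
  # primaries shift by ~ d_p sd, EE genes stay put (3 sigma/sqrt(N) slack)
  lab <- truth$labels
  primA <- lab$gene[lab$role_A == "primary"]
  eeA <- lab$gene[lab$role_A == "unaffected"]
  gapA <- abs(rowMeans(dat$A$noncontrol) - rowMeans(dat$A$control)) /
    apply(dat$A$control, 1, sd)
  expect_true(all(gapA[primA] > 2 - 0.35 & gapA[primA] < 2 + 0.35))
  expect_true(mean(gapA[eeA]) < 0.15)
  expect_error(generate_two_group(cA$mat, cB$mat, truth, 1, 1, seed = 1),
               "d_p > d_s")
})

test_that("large-sample shift estimate concentrates at d_p sd", {
  genes <- "g1"
  net <- gene_network(genes = genes)
  truth <- structure(list(labels = data.frame(
    gene = genes, role_A = "primary", role_B = "unaffected",
    stringsAsFactors = FALSE)), class = "truth_labels")
  ctrl <- matrix(rnorm(1000, 5, 1), 1, dimnames = list(genes, NULL))
  dat <- generate_two_group(ctrl, ctrl, truth, d_p = 2, d_s = 1,
                            n_noncontrol = 1000, seed = 31)
  gap <- abs(mean(dat$A$noncontrol) - mean(dat$A$control)) / sd(ctrl)
  expect_equal(gap, 2, tolerance = 0.12)
})

test_that("sigmoid propagation attenuates along the network and is local", {
  net <- chain_network(6)  # g1 -> g2 -> ... -> g6
  ctrl <- matrix(rnorm(6 * 20, 8, 1), 6, dimnames = list(net$genes, NULL))
  pr <- sigmoid_propagate(ctrl, "g1", deviation = 0.8, net = net)
  d <- abs(pr$delta)
  expect_equal(unname(d["g1"]), 0.8)
  expect_gt(d[["g2"]], 0)
  expect_lt(d[["g2"]], d[["g1"]])  # strictly attenuated
  expect_true(all(diff(unname(d[paste0("g", 1:6)])) <= 1e-12))
  # an isolated gene is never touched
  net2 <- gene_network(c("g1"), c("g2"), genes = c("g1", "g2", "iso"))
  ctrl2 <- matrix(rnorm(60, 8, 1), 3, dimnames = list(net2$genes, NULL))
  pr2 <- sigmoid_propagate(ctrl2, "g1", 0.6, net = net2)
  expect_identical(pr2$noncontrol["iso", ], ctrl2["iso", ])
  # empty primary set: non-control equals control exactly
  pr0 <- sigmoid_propagate(ctrl, character(0), 0.5, net = net)
  expect_identical(pr0$noncontrol, ctrl)
  # the non-control values carry the propagated relative change exactly
  expect_equal(pr$noncontrol["g2", ], ctrl["g2", ] * (1 + pr$delta[["g2"]]))
  # whole published deviation grid is accepted
  for (dev in c(0.5, 0.6, 0.7, 0.8)) {
    expect_silent(sigmoid_propagate(ctrl, "g1", dev, net = net))
  }
})

test_that("inhibiting edges push the target change the other way", {
  net <- gene_network(c("a", "a"), c("b", "c"), sign = c(1, -1))
  ctrl <- matrix(rnorm(3 * 10, 8, 0.5), 3, dimnames = list(c("a", "b", "c"), NULL))
  pr <- sigmoid_propagate(ctrl, "a", 0.8, net = net)
  expect_gt(pr$delta[["b"]], 0)
  expect_lt(pr$delta[["c"]], 0)
})

test_that("the primary-shift grid matches the published schedule", {
  g <- dp_grid()
  expect_equal(nrow(g), 30L)
  expect_equal(g$d_p[1], 0.1)
  expect_equal(g$d_p[30], 3.0)
  expect_equal(g$d_s[g$d_p == 1.0], 0.5)   # 0.5 x d_p below the threshold
  expect_equal(g$d_s[g$d_p == 1.1], 0.55)
  expect_equal(g$d_s[g$d_p == 1.2], 1)     # capped above 1.1
  expect_equal(g$d_s[g$d_p == 2.0], 1)
  expect_true(all(g$d_p > g$d_s))
})
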