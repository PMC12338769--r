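unit_triangle <- function() {
  semanticNetwork(data.frame(
    node_i = c("a", "a", "b"), node_j = c("b", "c", "c"), weight = 1
  ))
}

test_that("strengths sum incident weights; isolated nodes count as zero", {
  single <- semanticNetwork(data.frame(node_i = "a", node_j = "b", weight = 0.6))
  expect_equal(unname(nodeStrengths(single)), c(0.6, 0.6))
  expect_equal(averageStrength(single), 0.6)

  expect_equal(unname(nodeStrengths(unit_triangle())), rep(2, 3))
  expect_equal(averageStrength(unit_triangle()), 2)

  star <- semanticNetwork(data.frame(
    node_i = c("a", "a", "a"), node_j = c("b", "c", "d"), weight = 0.5
  ))
  expect_equal(nodeStrengths(star)[["a"]], 1.5)
  expect_equal(averageStrength(star), 0.75)

  iso <- semanticNetwork(single@edges, nodes = c("a", "b", "z"))
  expect_equal(nodeStrengths(iso)[["z"]], 0)
  expect_equal(averageStrength(iso), 1.2 / 3)
})

test_that("aspl uses 1 - weight step costs and drops unreachable pairs", {
  single <- semanticNetwork(data.frame(node_i = "a", node_j = "b", weight = 0.8))
  expect_equal(aspl(single), 0.2)
  # unit weights make every step free
  path <- semanticNetwork(data.frame(
    node_i = c("a", "b"), node_j = c("b", "c"), weight = 1
  ))
  expect_equal(aspl(path), 0)
  # two-step detour beats the weak direct edge: d(a,c) = min(0.9, 0.2)
  tri <- semanticNetwork(data.frame(
    node_i = c("a", "b", "a"), node_j = c("b", "c", "c"),
    weight = c(0.9, 0.9, 0.1)
  ))
  expect_equal(aspl(tri), mean(c(0.1, 0.1, 0.2)))
  # disconnected pairs are dropped; an edgeless network is undefined
  iso <- semanticNetwork(single@edges, nodes = c("a", "b", "z"))
  expect_equal(aspl(iso), 0.2)
  expect_true(is.na(aspl(semanticNetwork(nodes = c("a", "b")))))
})

test_that("aspl agrees with exhaustive path enumeration on random graphs", {
  for (s in 1:20) {
    net <- rand_net(sample(4:8, 1), p_edge = 0.45, seed = 100 + s)
    expect_equal(aspl(net), bf_aspl(net), tolerance = 1e-9)
  }
})

test_that("averageCC reproduces the weighted local clustering formula", {
  expect_equal(averageCC(unit_triangle()), 1)
  # open path: center has cc 0, endpoints are excluded (degree < 2)
  path <- semanticNetwork(data.frame(
    node_i = c("a", "b"), node_j = c("b", "c"), weight = 1
  ))
  expect_equal(averageCC(path, edgeQuantile = 0), 0)
  # triangle plus pendant: cc(a) = 1/3, cc(b) = cc(c) = 1
  pend <- semanticNetwork(data.frame(
    node_i = c("a", "a", "b", "a"), node_j = c("b", "c", "c", "d"), weight = 1
  ))
  expect_equal(averageCC(pend, edgeQuantile = 0), 7 / 9)
  # all nodes below degree 2 after filtering: undefined
  single <- semanticNetwork(data.frame(node_i = "a", node_j = "b", weight = 1))
  expect_true(is.na(averageCC(single)))
})

test_that("averageCC agrees with the brute-force triple loop", {
  for (s in 1:20) {
    net <- rand_net(sample(5:12, 1), p_edge = 0.5, seed = 200 + s)
    expect_equal(averageCC(net, edgeQuantile = 0), bf_average_cc(net),
                 tolerance = 1e-9)
  }
})

test_that("median filtering keeps the 50% strongest edges (ties kept)", {
  net <- semanticNetwork(data.frame(
    node_i = c("a", "a", "b", "c"), node_j = c("b", "c", "c", "d"),
    weight = c(0.9, 0.8, 0.9, 0.1)
  ))
  # median weight 0.85: the 0.1 and 0.8 edges drop, the triangle opens
  expect_equal(averageCC(net, edgeQuantile = 0.5), 0)
  # cc values stay in [0, 1] when weights do
  for (s in 1:10) {
    net <- rand_net(8, 0.6, seed = 300 + s)
    v <- averageCC(net)
    if (!is.na(v)) expect_true(v >= 0 && v <= 1)
  }
})

test_that("modularity matches the weighted formula for known partitions", {
  # one community: Q = 0 exactly
  k4 <- rand_net(4, 1, seed = 1, wmin = 1, wmax = 1)
  q0 <- modularityLouvain(k4, membership = rep(1, 4))
  expect_equal(as.numeric(q0), 0, tolerance = 1e-12)
  # two disjoint unit triangles: Louvain finds them, Q = 0.5
  two_tri <- semanticNetwork(data.frame(
    node_i = c("a", "a", "b", "x", "x", "y"),
    node_j = c("b", "c", "c", "y", "z", "z"), weight = 1
  ))
  q <- modularityLouvain(two_tri, seed = 3)
  expect_equal(as.numeric(q), 0.5, tolerance = 1e-12)
  mb <- attr(q, "membership")
  expect_equal(length(unique(mb)), 2)
  expect_equal(as.numeric(bf_modularity(two_tri, mb)), 0.5, tolerance = 1e-12)
  expect_error(modularityLouvain(semanticNetwork(nodes = c("a", "b"))),
               "edgeless")
})

test_that("modularity formula agrees with brute force on random graphs", {
  for (s in 1:20) {
    net <- rand_net(sample(5:15, 1), p_edge = 0.4, seed = 400 + s)
    if (numEdges(net) == 0) next
    q <- modularityLouvain(net, seed = s)
    expect_equal(as.numeric(q), bf_modularity(net, attr(q, "membership")),
                 tolerance = 1e-9)
  }
})

test_that("modularity is invariant to uniform weight scaling", {
  net <- rand_net(10, 0.5, seed = 7)
  q1 <- modularityLouvain(net, seed = 1)
  scaled <- semanticNetwork(
    transform(edgeTable(net), weight = weight * 0.37), nodes = nodes(net)
  )
  q2 <- modularityLouvain(scaled, membership = attr(q1, "membership"))
  expect_equal(as.numeric(q1), as.numeric(q2), tolerance = 1e-12)
})

test_that("measurePanel assembles consistent measures and NA states", {
  pan <- measurePanel(unit_triangle(), seed = 1)
  expect_equal(pan@averageStrength, 2)
  expect_equal(pan@aspl, 0)
  expect_equal(pan@averageCC, 1)
  expect_equal(pan@modularity, 0, tolerance = 1e-12)  # single community
  expect_equal(pan@averageStrength, mean(pan@nodeStrengths))

  empty <- measurePanel(semanticNetwork(nodes = c("a", "b", "c")))
  expect_equal(unname(empty@nodeStrengths), rep(0, 3))
  expect_true(is.na(empty@aspl))
  expect_true(is.na(empty@averageCC))
  expect_true(is.na(empty@modularity))

  rand <- measurePanel(rand_net(9, 0.5, seed = 17), seed = 2)
  expect_equal(rand@averageStrength, mean(rand@nodeStrengths))
  expect_equal(unname(betweenMeasures(rand)["aspl"]), rand@aspl)
})
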