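# Term-conditional topology feature families

# star: centre Q with 4 leaves, selectable membership / confidences
star_net <- function(conf = c(1, 1, 1, 1), dval = c(1, 1, 1, 1)) {
  leaves <- paste0("f", 1:4)
  net <- ppi_network(data.frame(a = "Q", b = leaves, confidence = conf))
  D <- matrix(0, 5, 2, dimnames = list(net$vertices, c("d1", "d2")))
  D[leaves, "d1"] <- dval
  set_node_weights(net, D)
}

fam <- function(v, name) unname(v[grep(paste0("^", name, "_L"), names(v))])

test_that("star-graph hand computations hold for every family", {
  members <- paste0("f", 1:4)
  net <- star_net(dval = c(3, 3, 3, 3))
  v <- featurize(net, members, "Q")
  # all leaves in F with descriptor value 3 -> APVW_d1(1) = 3
  expect_equal(unname(v[["apvw_L1.d1"]]), 3)
  expect_equal(fam(v, "pwpfp")[1], 1)       # every endpoint has the function
  expect_equal(fam(v, "pp")[1], 1)
  # 2 of 4 leaves in F, unit weights -> PWPFP(1) = 0.5
  v <- featurize(net, c("f1", "f2"), "Q")
  expect_equal(fam(v, "pwpfp")[1], 0.5)
  expect_equal(fam(v, "pp")[1], 0.5)
  # APWPF(1): query adjacent to the single member with confidence 0.8
  net <- star_net(conf = c(0.8, 0.5, 0.5, 0.5))
  v <- featurize(net, "f1", "Q")
  expect_equal(fam(v, "apwpf")[1], 0.8)
  # ADPF: leaves have degree 1
  expect_equal(fam(v, "adpf")[1], 1)
  # ADPWPF: degree 1 x wsum 0.8
  expect_equal(fam(v, "adpwpf")[1], 0.8)
  # empty function set -> everything zero
  v <- featurize(net, character(0), "Q")
  expect_true(all(v == 0))
})

test_that("PINPFP counts level-set edges on both sides of the ratio", {
  # Q adjacent to a,b,c; level-1 edges: a-b, b-c; F = {a,b}
  net <- ppi_network(data.frame(
    a = c("Q", "Q", "Q", "a", "b"),
    b = c("a", "b", "c", "b", "c"), confidence = 1))
  D <- matrix(0, 4, 1, dimnames = list(net$vertices, "d1"))
  v <- featurize(set_node_weights(net, D), c("a", "b"), "Q")
  expect_equal(fam(v, "pinpfp")[1], 1 / 2)
})

test_that("PPL follows the through-query path proportion", {
  # path f1 - Q - f2: the only length-2 path between members runs through Q
  net <- ppi_network(data.frame(a = c("f1", "Q"), b = c("Q", "f2"),
                                confidence = 1))
  D <- matrix(0, 3, 1, dimnames = list(net$vertices, "d1"))
  v <- featurize(set_node_weights(net, D), c("f1", "f2"), "Q")
  expect_equal(unname(v[["ppl_L2"]]), 1)
  # 4-cycle f1-Q-f2 / f1-x-f2 with x not in F: half the paths go through Q
  net <- ppi_network(data.frame(a = c("f1", "Q", "f1", "x"),
                                b = c("Q", "f2", "x", "f2"),
                                confidence = 1))
  D <- matrix(0, 4, 1, dimnames = list(net$vertices, "d1"))
  v <- featurize(set_node_weights(net, D), c("f1", "f2"), "Q")
  expect_equal(unname(v[["ppl_L2"]]), 1 / 2)
})

test_that("every family matches exhaustive geodesic enumeration", {
  set.seed(2024)
  for (rep in 1:30) {
    net <- with_random_descriptors(random_connected_net())
    members <- sample(net$vertices, max(2, rbinom(1, length(net$vertices), 0.4)))
    query <- sample(net$vertices, 1)
    got <- featurize(net, members, query)
    want <- oracle_featurize(net, members, query)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("featurize_all shares the BFS cache and preserves row order", {
  set.seed(10)
  net <- with_random_descriptors(random_connected_net(n = 9))
  members <- net$vertices[1:3]
  qs <- rev(net$vertices)[1:4]
  M <- featurize_all(net, members, queries = qs)
  expect_equal(rownames(M), qs)
  for (q in qs)
    expect_equal(M[q, ], featurize(net, members, q))
})

test_that("bounded families stay in [0,1] and degenerate cases are zero", {
  set.seed(33)
  for (rep in 1:20) {
    net <- with_random_descriptors(random_connected_net())
    members <- sample(net$vertices, rbinom(1, length(net$vertices), 0.5))
    query <- sample(net$vertices, 1)
    v <- featurize(net, members, query)
    for (f in c("pwpfp", "pinpfp", "pp"))
      expect_true(all(fam(v, f) >= 0 & fam(v, f) <= 1))
    ppl <- unname(v[grep("^ppl_L", names(v))])
    expect_true(all(ppl >= 0 & ppl <= 1))
    expect_true(all(fam(v, "adpf") >= 0))
    expect_true(all(fam(v, "adpwpf") >= 0))
  }
})

test_that("with F = all other vertices, PWPFP and PP are 1 on non-empty levels", {
  set.seed(4)
  net <- with_random_descriptors(random_connected_net(n = 10))
  q <- net$vertices[1]
  v <- featurize(net, net$vertices, q)   # query removed internally
  b <- bfs_paths(net, q)
  for (L in seq_along(b$levels)) {
    expect_equal(fam(v, "pwpfp")[L], 1)
    expect_equal(fam(v, "pp")[L], 1)
  }
})

test_that("with unit confidences PWPFP reduces to the path-count proportion", {
  set.seed(6)
  net <- random_connected_net(n = 8)
  net$edges$confidence <- 1
  net <- with_random_descriptors(ppi_network(net$edges))
  members <- net$vertices[1:3]
  q <- net$vertices[8]
  v <- featurize(net, members, q)
  b <- bfs_paths(net, q)
  for (L in seq_along(b$levels)) {
    lv <- b$levels[[L]]
    NP <- sum(b$sigma[lv])
    FP <- sum(b$sigma[intersect(lv, setdiff(members, q))])
    expect_equal(fam(v, "pwpfp")[L], if (NP > 0) FP / NP else 0)
  }
})

test_that("the query protein is excluded from its own function set", {
  # if the query stayed in F, PP(1) of a member would count itself at L>=1
  net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C"),
                                confidence = 1))
  D <- matrix(0, 3, 1, dimnames = list(net$vertices, "d1"))
  net <- set_node_weights(net, D)
  v <- featurize(net, c("A"), "A")    # F collapses to empty
  expect_true(all(v == 0))
})

test_that("members of a dense planted module score higher PWPFP(1)", {
  s <- simulate_ppi_study(n_proteins = 120, seq_len_range = c(30, 50),
                          positive_fraction = 0.3, homophily = 0.8,
                          seed = 21)
  net <- ppi_network(s$edges)
  net <- largest_connected_component(net)
  D <- matrix(0, length(net$vertices), 1,
              dimnames = list(net$vertices, "d1"))
  net <- set_node_weights(net, D)
  members <- intersect(s$members[[1]], net$vertices)
  non <- setdiff(net$vertices, members)
  paths <- all_pairs_paths(net)
  p1 <- vapply(members, function(q)
    featurize(net, members, q, paths = paths)[["pwpfp_L1"]], numeric(1))
  p0 <- vapply(sample(non, 30), function(q)
    featurize(net, members, q, paths = paths)[["pwpfp_L1"]], numeric(1))
  expect_lt(stats::wilcox.test(p1, p0, alternative = "greater",
                               exact = FALSE)$p.value, 1e-4)
})
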