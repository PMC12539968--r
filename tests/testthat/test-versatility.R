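test_that("supra-transition rows are stochastic and teleport arithmetic holds", {
  # single-layer undirected star, 3 alters, equal weights: from the ego the
  # walker reaches each alter w.p. damping/3 + (1-damping)/4
  mn <- star_multilayer(layers = list(list(alters = c("A1", "A2", "A3"),
                                           weights = c(2, 2, 2))))
  st <- build_supra_transition(mn, damping = 0.85)
  expect_equal(unname(rowSums(st$transition)), rep(1, 4), tolerance = 1e-12)
  ego_row <- st$transition[1, ]
  expect_equal(unname(ego_row[2:4]), rep(0.85 / 3 + 0.15 / 4, 3),
               tolerance = 1e-12)
  expect_error(build_supra_transition(mn, damping = 1.2), "damping")
})

test_that("replica of an alter absent from a layer is coupled only across layers", {
  mn <- star_multilayer(layers = list(
    list(alters = c("A1", "A2"), weights = c(1, 1)),
    list(alters = "A2", weights = 3)))
  st <- build_supra_transition(mn, damping = 0.85, interlayer_weight = 1)
  expect_equal(unname(rowSums(st$transition)), rep(1, 6), tolerance = 1e-12)
  # A1's layer-2 replica (node 2 in layer 2) has no within-layer edges:
  # all its directed mass goes to its layer-1 replica
  i <- with(st$node_layer_index, which(node == "A1" & layer == 2))
  j <- with(st$node_layer_index, which(node == "A1" & layer == 1))
  expect_equal(st$transition[i, j], 0.85 + 0.15 / 6, tolerance = 1e-12)
})

test_that("power iteration matches the dense eigen-oracle on random multiplexes", {
  set.seed(101)
  for (rep in 1:60) {
    mn <- random_multiplex()
    st <- build_supra_transition(mn, damping = 0.85,
                                 coupling = sample(c("categorical",
                                                     "ordinal"), 1))
    v <- pagerank_stationary(st)
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
    expect_lt(max(abs(v - eigen_stationary(st))), 1e-8)
  }
})

test_that("single-layer versatility equals an independent PageRank implementation", {
  skip_if_not_installed("igraph")
  set.seed(202)
  for (rep in 1:20) {
    mn <- random_multiplex(max_layers = 1)
    st <- build_supra_transition(mn, damping = 0.85)
    v <- node_versatility(pagerank_stationary(st, tol = 1e-13),
                          st$node_layer_index)
    # independent oracle: igraph's PageRank on the same star graph
    ed <- mn$layers[[1]]$edges
    g <- igraph::make_empty_graph(n = length(mn$node_set),
                                  directed = TRUE)
    idx <- function(id) match(id, mn$node_set)
    if (nrow(ed)) {
      from <- ifelse(ed$direction == "received", idx(ed$alter_id),
                     idx(mn$ego_id))
      to <- ifelse(ed$direction == "received", idx(mn$ego_id),
                   idx(ed$alter_id))
      if (any(ed$direction == "undirected")) {
        u <- ed$direction == "undirected"
        from <- c(from, idx(ed$alter_id[u]))
        to <- c(to, rep(idx(mn$ego_id), sum(u)))
      }
      g <- igraph::add_edges(g, rbind(from, to))
      igraph::E(g)$weight <- c(ed$weight,
                               ed$weight[ed$direction == "undirected"])
    }
    pr <- igraph::page_rank(g, damping = 0.85)$vector
    expect_lt(max(abs(as.numeric(v[mn$node_set]) - pr)), 1e-10)
  }
})

test_that("two-node symmetric graph has the uniform stationary distribution", {
  mn <- star_multilayer(layers = list(list(alters = "A1", weights = 5)))
  st <- build_supra_transition(mn)
  expect_equal(as.numeric(pagerank_stationary(st)), c(0.5, 0.5),
               tolerance = 1e-9)
})

test_that("versatility sums stationary mass over layer replicas", {
  nl <- data.frame(node = rep(c("a", "b", "c", "d"), 2),
                   layer = rep(1:2, each = 4))
  vers <- node_versatility(rep(1 / 8, 8), nl)
  expect_equal(as.numeric(vers), rep(0.25, 4))
})

test_that("multi-layer presence amplifies versatility", {
  # A1 connected in 3 of 3 layers vs A2 in 1 of 3, equal weights
  mn <- star_multilayer(layers = list(
    list(alters = c("A1", "A2"), weights = c(1, 1)),
    list(alters = "A1", weights = 1),
    list(alters = "A1", weights = 1)))
  st <- build_supra_transition(mn)
  v <- node_versatility(pagerank_stationary(st), st$node_layer_index)
  expect_gt(v[["A1"]], v[["A2"]])
})

test_that("bidirectional ties beat unidirectional ties at equal weights", {
  # A1 is tied in both directions; A2's single tie is its own action
  # toward the ego (received). The walker reaches an alter mainly through
  # the ego's outgoing edges, so the reciprocated dyad scores strictly
  # higher.
  mn <- star_multilayer(behaviour = "groom", layers = list(
    list(alters = c("A1", "A1", "A2"), weights = c(1, 1, 1),
         directions = c("given", "received", "received"))))
  st <- build_supra_transition(mn)
  v <- node_versatility(pagerank_stationary(st), st$node_layer_index)
  expect_gt(v[["A1"]], v[["A2"]])
  # the ordering also holds across layers of a temporal multiplex
  mn2 <- star_multilayer(behaviour = "groom", layers = list(
    list(alters = c("A1", "A2"), weights = c(1, 1),
         directions = c("given", "received")),
    list(alters = c("A1", "A2"), weights = c(1, 1),
         directions = c("received", "received"))))
  st2 <- build_supra_transition(mn2)
  v2 <- node_versatility(pagerank_stationary(st2), st2$node_layer_index)
  expect_gt(v2[["A1"]], v2[["A2"]])
})

test_that("normalization drops the ego and rescales alters to sum to one", {
  v <- c(EGO = 0.6, A1 = 0.2, A2 = 0.1, A3 = 0.1)
  nv <- normalize_versatility(v, "EGO")
  expect_equal(as.numeric(nv), c(0.5, 0.25, 0.25))
  k4 <- star_multilayer(layers = list(
    list(alters = paste0("A", 1:4), weights = rep(3, 4))))
  tab <- multilayer_versatility(k4)
  expect_equal(tab$versatility, rep(0.25, 4), tolerance = 1e-9)
  # empty network -> no rows
  empty <- star_multilayer(layers = list(list(alters = character())))
  expect_equal(nrow(multilayer_versatility(empty)), 0)
})

test_that("normalized alter versatilities sum to 1 in every realized network", {
  set.seed(303)
  for (rep in 1:25) {
    mn <- random_multiplex()
    tab <- multilayer_versatility(mn)
    if (nrow(tab)) expect_equal(sum(tab$versatility), 1, tolerance = 1e-9)
  }
})

test_that("adding a layer connecting only one alter never lowers its share", {
  base_layers <- list(list(alters = c("A1", "A2"), weights = c(2, 3)),
                      list(alters = c("A2", "A3"), weights = c(1, 4)))
  for (target in c("A1", "A2", "A3")) {
    mn0 <- star_multilayer(layers = base_layers)
    mn1 <- star_multilayer(layers = c(base_layers,
                                      list(list(alters = target,
                                                weights = 2))))
    t0 <- multilayer_versatility(mn0)
    t1 <- multilayer_versatility(mn1)
    expect_gte(t1$versatility[t1$alter_id == target],
               t0$versatility[t0$alter_id == target] - 1e-12)
  }
})

test_that("zero-population adds only feasible dyads and is idempotent", {
  dem <- tiny_demography()
  # E1 (born 2016-04-15) saw A1 only in proximity partition 2,
  # and A2 only in groom partition 3
  tab <- data.frame(
    ego_id = "E1", behaviour = c("proximity", "groom"),
    partition_index = c(2L, 3L), alter_id = c("A1", "A2"),
    versatility = c(0.4, 0.6), zero_populated = FALSE,
    stringsAsFactors = FALSE)
  out <- zero_populate(tab, dem, partition_scheme())
  # both observed partitions (2, 3) x 5 behaviours x feasible alters
  expect_equal(sum(!out$zero_populated), 2)
  expect_true(all(out$versatility[out$zero_populated] == 0))
  # A1 born 2016-06-01 is feasible in both partitions: 2*5 - 1 zero rows
  expect_equal(sum(out$alter_id == "A1" & out$zero_populated), 9)
  # A2 removed 2018-06-15 during E1's partition 3 (May 2017 - Apr 2018)?
  # partition 3 spans months 13-24 = 2017-05..2018-04; removal is after,
  # so A2 remains feasible in partitions 2 and 3
  expect_equal(sum(out$alter_id == "A2"), 10)
  # never in a partition the ego was not observed in
  expect_setequal(unique(out$partition_index), c(2L, 3L))
  # idempotent and preserves existing non-zero values
  again <- zero_populate(out, dem, partition_scheme())
  expect_equal(nrow(again), nrow(out))
  expect_equal(sort(again$versatility[!again$zero_populated]),
               c(0.4, 0.6))
})

test_that("zero-population respects birth and removal windows", {
  dem <- tiny_demography()
  dem$birth_date[dem$animal_id == "A1"] <- as.Date("2017-08-01")
  dem$removal_date[dem$animal_id == "A2"] <- as.Date("2017-06-15")
  tab <- data.frame(
    ego_id = "E1",
    behaviour = "proximity",
    partition_index = c(1L, 2L, 3L, 3L, 4L),
    alter_id = c("A3", "A3", "A1", "A2", "A3"),
    versatility = c(0.3, 0.2, 0.5, 0.1, 0.4), zero_populated = FALSE,
    stringsAsFactors = FALSE)
  out <- zero_populate(tab, dem, partition_scheme())
  # A1 born 2017-08-01: E1's partitions 1 (Apr-Sep 2016) and 2
  # (Oct 2016-Mar 2017) end before the birth -> absent there
  expect_false(any(out$alter_id == "A1" & out$partition_index %in% 1:2))
  expect_true(any(out$alter_id == "A1" & out$partition_index == 4))
  # A2 removed 2017-06-15 (in partition 3): no partition-4 rows
  expect_false(any(out$alter_id == "A2" & out$partition_index == 4))
  expect_true(any(out$alter_id == "A2" & out$partition_index == 3))
})
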