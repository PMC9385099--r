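# Brute-force betweenness for tiny graphs: enumerate all shortest directed
# paths and count interior appearances.
brute_betweenness <- function(g) {
  ig <- as_igraph(g)
  counts <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  for (s in g$nodes) for (t in setdiff(g$nodes, s)) {
    sp <- suppressWarnings(igraph::all_shortest_paths(ig, s, t,
                                                      mode = "out"))$res
    if (!length(sp)) next
    for (path in sp) {
      inner <- setdiff(names(path), c(s, t))
      counts[inner] <- counts[inner] + 1 / length(sp)
    }
  }
  counts
}

test_that("betweenness selection finds path centres and star hubs", {
  path5 <- chain_graph(LETTERS[1:5])
  expect_equal(select_affected_betweenness(path5, 1), "C")
  expect_equal(names(which.max(brute_betweenness(path5))), "C")

  st <- star_graph()
  # only the centre lies on any path in a star
  expect_equal(select_affected_betweenness(st, 1), "H")

  expect_setequal(select_affected_betweenness(path5, 5), LETTERS[1:5])
  expect_warning(sel <- select_affected_betweenness(path5, 9), "fewer")
  expect_setequal(sel, LETTERS[1:5])
})

test_that("community selection samples from the densest module", {
  # two 10-cliques joined by a single bridge
  cl <- function(prefix) {
    pairs <- t(utils::combn(paste0(prefix, 1:10), 2))
    data.frame(from = pairs[, 1], to = pairs[, 2], weight = 1L)
  }
  ed <- rbind(cl("a"), cl("b"),
              data.frame(from = "a1", to = "b1", weight = 1L))
  g <- pathway_graph("cliques", ed)
  sel <- select_affected_community(g, 3, seed = 5)
  expect_length(sel, 3)
  side <- substr(sel, 1, 1)
  expect_length(unique(side), 1)  # all from one clique

  expect_identical(select_affected_community(g, 3, seed = 5),
                   select_affected_community(g, 3, seed = 5))

  # one-community graph: sampled from all nodes
  one <- pathway_graph("clique", cl("x"))
  expect_true(all(select_affected_community(one, 4, seed = 1) %in%
                    one$nodes))
})

test_that("neighbourhood selection uses the largest order-2 ball", {
  path5 <- chain_graph(LETTERS[1:5])
  # C's order-2 neighbourhood is the whole path (BFS oracle), unique max
  expect_setequal(select_affected_neighbourhood(path5, 5, seed = 1),
                  LETTERS[1:5])
  st <- star_graph()
  expect_true(all(select_affected_neighbourhood(st, 3, seed = 2) %in%
                    st$nodes))
  expect_identical(select_affected_neighbourhood(path5, 2, seed = 9),
                   select_affected_neighbourhood(path5, 2, seed = 9))
})

test_that("build_design tracks unique affected genes, signs and q0 membership", {
  mk <- function(name, nodes) {
    k <- length(nodes)
    pathway_graph(name, data.frame(from = nodes[-k], to = nodes[-1],
                                   weight = 1L))
  }
  p1 <- mk("p1", paste0("a", 1:6))
  p2 <- mk("p2", paste0("b", 1:6))    # disjoint from p1
  p3 <- mk("p3", paste0("a", 1:6))    # identical genes to p1
  # q0 candidates: one sharing 2 affected genes, one sharing none
  p4 <- mk("p4", c("a2", "a3", paste0("c", 1:4)))
  p5 <- mk("p5", paste0("d", 1:6))

  d1 <- build_design(list(p1, p2, p4, p5), c("p1", "p2"), "betweenness",
                     s = 3)
  expect_equal(nrow(d1$affected), 6)   # disjoint: s * q1
  expect_true(all(lengths(d1$per_pathway) == 3))
  # chain centres of p1 are a2/a3/a4, so p4 holds two affected genes and
  # is excluded from q0 while the untouched p5 stays
  expect_setequal(d1$per_pathway$p1, c("a2", "a3", "a4"))
  expect_equal(d1$q0_names, "p5")

  d2 <- build_design(list(p1, p3), c("p1", "p3"), "betweenness", s = 3)
  expect_equal(nrow(d2$affected), 3)   # full overlap: s unique genes

  # signs follow the summed outgoing weights, 0 -> +1
  neg <- pathway_graph("neg", data.frame(from = c("x", "y"),
                                         to = c("y", "z"),
                                         weight = c(-1L, -1L)))
  d3 <- build_design(list(neg), "neg", "betweenness", s = 3)
  sg <- stats::setNames(d3$affected$sign, d3$affected$gene)
  expect_equal(unname(sg["x"]), -1L)
  expect_equal(unname(sg["y"]), -1L)
  expect_equal(unname(sg["z"]), 1L)    # sink: outgoing sum 0 -> +1
})

test_that("unique affected genes never exceed s x q1 over random collections", {
  set.seed(71)
  for (rep in 1:5) {
    gs <- simulate_pathways(6, c(12, 20))
    q1 <- vapply(gs[1:3], function(g) g$name, "")
    d <- build_design(gs, q1, "betweenness", s = 4)
    expect_lte(nrow(d$affected), 4 * 3)
  }
})

test_that("base data are standardized per gene within each group", {
  d <- generate_base_data(paste0("g", 1:30), 20, 15,
                          corr = "independent", seed = 1)
  for (lev in 0:1) {
    sub <- d$matrix[d$group == lev, ]
    expect_equal(unname(colMeans(sub)), rep(0, 30), tolerance = 1e-12)
    expect_equal(unname(apply(sub, 2, stats::sd)), rep(1, 30),
                 tolerance = 1e-12)
  }
})

test_that("block correlation structure reaches its target rho", {
  genes <- paste0("g", 1:40)
  blocks <- stats::setNames(rep(c("b1", "b2"), each = 20), genes)
  d <- generate_base_data(genes, 300, 300, corr = "block", rho = 0.5,
                          blocks = blocks, seed = 4)
  C <- stats::cor(d$matrix)
  within <- c(C[1:20, 1:20][upper.tri(diag(20))],
              C[21:40, 21:40][upper.tri(diag(20))])
  across <- C[1:20, 21:40]
  expect_equal(mean(within), 0.5, tolerance = 0.05)
  expect_equal(mean(across), 0, tolerance = 0.05)

  d0 <- generate_base_data(genes, 300, 300, corr = "independent", seed = 4)
  C0 <- stats::cor(d0$matrix)
  expect_equal(mean(abs(C0[upper.tri(C0)])), 0, tolerance = 0.06)
})

test_that("signal injection shifts case means by sign x signal exactly", {
  genes <- paste0("g", 1:10)
  d <- generate_base_data(genes, 25, 20, corr = "independent", seed = 2)
  aff <- data.frame(gene = c("g1", "g2"), sign = c(1L, -1L))
  d2 <- inject_signal(d, aff, 0.7)
  cases <- d2$group == 1L
  expect_equal(mean(d2$matrix[cases, "g1"]), 0.7, tolerance = 1e-12)
  expect_equal(mean(d2$matrix[cases, "g2"]), -0.7, tolerance = 1e-12)
  expect_equal(mean(d2$matrix[!cases, "g1"]), 0, tolerance = 1e-12)
  expect_equal(mean(d2$matrix[cases, "g3"]), 0, tolerance = 1e-12)
  expect_error(inject_signal(d, data.frame(gene = "nope", sign = 1L), 0.5),
               "nope")
})

test_that("run_simulation is deterministic and returns valid fractions", {
  gs <- simulate_pathways(6, c(10, 16), seed = 13)
  q1 <- vapply(gs[1:3], function(g) g$name, "")
  des <- simulation_design(topology = "betweenness", signal = 0.7, s = 3,
                           q1_pathways = q1, n_replicates = 3, n_rep = 100,
                           n_cases = 20, n_controls = 15,
                           corr = "independent", seed = 6)
  m1 <- suppressWarnings(run_simulation(des, gs))
  m2 <- suppressWarnings(run_simulation(des, gs))
  expect_identical(m1$replicates, m2$replicates)
  expect_true(m1$power >= 0 && m1$power <= 1)
  expect_true(is.na(m1$type_i_error) ||
                (m1$type_i_error >= 0 && m1$type_i_error <= 1))
})
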