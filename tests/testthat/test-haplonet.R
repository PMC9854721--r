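test_that("two haplotypes give a single edge at their Hamming distance", {
  states <- rbind(H1 = c("A", "A", "A"), H2 = c("C", "A", "G"))
  counts <- matrix(c(3L, 2L), 2, 1, dimnames = list(rownames(states), "r"))
  m <- variable_site_matrix(c(1, 2, 3), states, c("x", "x"), counts)
  net <- median_joining_network(m)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 2)
})

test_that("within-species adjacencies on the COI data are 1-2 steps", {
  m <- table2_matrix()
  am <- grepl("^PamCOI\\.[0-9]$", rownames(m$states))
  m_am <- variable_site_matrix(m$positions, m$states[am, ],
                               m$lineage[am], m$region_counts[am, ])
  net <- median_joining_network(m_am)
  ekey <- paste(pmin(net$edges$from, net$edges$to),
                pmax(net$edges$from, net$edges$to))
  w <- setNames(net$edges$weight, ekey)
  expect_equal(unname(w["PamCOI.1 PamCOI.3"]), 1)
  expect_equal(unname(w["PamCOI.2 PamCOI.3"]), 1)
  expect_equal(unname(w["PamCOI.3 PamCOI.4"]), 2)
  # edge weights equal the Hamming distances of their endpoints
  smap <- setNames(net$nodes$states, net$nodes$name)
  for (r in seq_len(nrow(net$edges))) {
    a <- strsplit(smap[net$edges$from[r]], "")[[1]]
    b <- strsplit(smap[net$edges$to[r]], "")[[1]]
    expect_equal(sum(a != b), net$edges$weight[r])
  }
})

test_that("a chain of single mutations reproduces the spanning tree", {
  # haplotypes on a perfect (homoplasy-free) path: H1 -1- H2 -1- H3 -1- H4
  states <- rbind(H1 = c("A", "A", "A"), H2 = c("C", "A", "A"),
                  H3 = c("C", "G", "A"), H4 = c("C", "G", "T"))
  counts <- matrix(1L, 4, 1, dimnames = list(rownames(states), "r"))
  m <- variable_site_matrix(c(10, 20, 30), states, rep("x", 4), counts)
  net <- median_joining_network(m)
  expect_equal(sum(net$nodes$type == "median"), 0)
  expect_equal(nrow(net$edges), 3)
  expect_equal(sum(net$edges$weight), 3)
  # equals the MST from an independent routine
  d <- hamming_matrix(states)$d
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst_w <- sum(igraph::E(igraph::mst(g))$weight)
  expect_equal(sum(net$edges$weight), mst_w)
})

test_that("network output is invariant under haplotype input order", {
  m <- table2_matrix()
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  m2 <- variable_site_matrix(m$positions, m$states[perm, ],
                             m$lineage[perm], m$region_counts[perm, ])
  n1 <- median_joining_network(m)
  n2 <- median_joining_network(m2)
  canon <- function(n) {
    e <- n$edges
    k <- paste(pmin(e$from, e$to), pmax(e$from, e$to), e$weight)
    sort(k)
  }
  expect_identical(canon(n1), canon(n2))
  expect_identical(sort(n1$nodes$states), sort(n2$nodes$states))
})

test_that("the network is connected and Steiner-improves the MST weight", {
  m <- table2_matrix()
  net <- median_joining_network(m)
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
  # minimum spanning weight over nodes incl. medians never exceeds the
  # observed-only MST weight
  obs_d <- hamming_matrix(m$states)$d
  go <- igraph::graph_from_adjacency_matrix(obs_d, mode = "undirected",
                                            weighted = TRUE)
  w_obs <- sum(igraph::E(igraph::mst(go))$weight)
  w_net <- sum(igraph::E(igraph::mst(g))$weight)
  expect_lte(w_net, w_obs)
})

test_that("epsilon = 0 nodes persist in the epsilon = 1 network", {
  m <- table2_matrix()
  n0 <- median_joining_network(m, epsilon = 0)
  n1 <- median_joining_network(m, epsilon = 1)
  expect_true(all(n0$nodes$states[n0$nodes$type == "observed"] %in%
                    n1$nodes$states))
})

test_that("the Saf haplotype attaches between the two species clusters", {
  net <- median_joining_network(table2_matrix())
  pam <- paste0("PamCOI.", 1:4)
  oxy <- paste0("PoxyCOI.", 1:3)
  d_saf_pam <- network_steps(net, "PamCOI.Saf", pam)
  d_saf_oxy <- network_steps(net, "PamCOI.Saf", oxy)
  d_pam_oxy <- network_steps(net, pam, oxy)
  expect_gte(d_saf_pam, d_pam_oxy + 4)
  expect_gte(d_saf_oxy, d_pam_oxy + 4)
})

test_that("GraphML and edge-list exports are written", {
  net <- median_joining_network(table2_matrix())
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, graphml = gml, edges_tsv = tsv)
  expect_true(file.exists(gml))
  e <- read.delim(tsv)
  expect_equal(nrow(e), nrow(net$edges))
})
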