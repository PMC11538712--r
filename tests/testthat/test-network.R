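# build a network directly from fabricated rho / p matrices
fabricate_network <- function(rho, p, edge_fdr = 0.01) {
  build_network(rho, p, sparcc_config(edge_fdr = edge_fdr))
}

sym <- function(n, ids = paste0("sp", seq_len(n))) {
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  m
}

test_that("edge retention follows one BH family at the configured FDR", {
  # all p = 1: empty edge set
  rho <- sym(6) * 0.5; diag(rho) <- 1
  p <- sym(6); diag(p) <- NA
  net <- fabricate_network(rho, p)
  expect_identical(nrow(net$edges), 0L)
  expect_true(all(net$nodes$degree == 0L))

  # three tiny-p pairs among 45: hand BH gives q = p * 45 / rank
  rho <- sym(10) * 0; diag(rho) <- 1
  p <- sym(10)
  pairs <- list(c(1, 2), c(3, 4), c(5, 6))
  for (ij in pairs) { rho[ij[1], ij[2]] <- rho[ij[2], ij[1]] <- 0.7
                      p[ij[1], ij[2]] <- p[ij[2], ij[1]] <- 1 / 2001 }
  diag(p) <- NA
  net <- fabricate_network(rho, p)
  expect_identical(nrow(net$edges), 3L)
  expect_setequal(paste(net$edges$species_a, net$edges$species_b),
                  c("sp1 sp2", "sp3 sp4", "sp5 sp6"))
  expect_equal(net$edges$q, rep((1 / 2001) * 45 / 3, 3), tolerance = 1e-12)
  expect_true(all(net$edges$sign == "+"))

  # degree bookkeeping: sum of degrees = 2 * edge count
  expect_identical(sum(net$nodes$degree), 2L * nrow(net$edges))
})

test_that("hub degrees match hand-built star and triangle topologies", {
  # star on 5 nodes
  rho <- sym(5) * 0; diag(rho) <- 1
  p <- sym(5); diag(p) <- NA
  for (leaf in 2:5) { rho[1, leaf] <- rho[leaf, 1] <- 0.6
                      p[1, leaf] <- p[leaf, 1] <- 1e-6 }
  star <- fabricate_network(rho, p)
  deg <- hub_degrees(star)
  expect_identical(deg$degree[deg$species_id == "sp1"], 4L)
  expect_identical(deg$degree[deg$species_id != "sp1"], rep(1L, 4))

  # triangle
  rho <- sym(4) * 0; diag(rho) <- 1
  p <- sym(4); diag(p) <- NA
  for (ij in list(c(1, 2), c(2, 3), c(1, 3))) {
    rho[ij[1], ij[2]] <- rho[ij[2], ij[1]] <- 0.5
    p[ij[1], ij[2]] <- p[ij[2], ij[1]] <- 1e-6
  }
  tri <- fabricate_network(rho, p)
  expect_identical(hub_degrees(tri)$degree, c(2L, 2L, 2L, 0L))
})

# exhaustive weighted-modularity maximisation over all partitions (Bell number
# enumeration), the independent oracle for small graphs
best_partition_modularity <- function(edges, ids) {
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    i <- edges$species_a[r]; j <- edges$species_b[r]
    w[i, j] <- w[j, i] <- edges$rho[r]
  }
  m2 <- sum(w)  # 2m
  k <- rowSums(w)
  best <- list(q = -Inf, part = NULL)
  recurse <- function(assign, next_node, n_groups) {
    if (next_node > n) {
      q <- 0
      for (g in seq_len(n_groups)) {
        idx <- which(assign == g)
        q <- q + sum(w[idx, idx]) - sum(k[idx])^2 / m2
      }
      q <- q / m2
      if (q > best$q) best <<- list(q = q, part = assign)
      return(invisible())
    }
    for (g in seq_len(n_groups + 1)) {
      assign[next_node] <- g
      recurse(assign, next_node + 1, max(n_groups, g))
    }
  }
  recurse(integer(n), 1L, 0L)
  best
}

test_that("Louvain recovers two disconnected cliques, matching exhaustive modularity", {
  ids <- paste0("sp", 1:8)
  rho <- sym(8, ids) * 0; diag(rho) <- 1
  p <- sym(8, ids); diag(p) <- NA
  for (grp in list(1:4, 5:8))
    for (i in grp) for (j in grp) if (i < j) {
      rho[i, j] <- rho[j, i] <- 0.6
      p[i, j] <- p[j, i] <- 1e-8
    }
  net <- fabricate_network(rho, p)
  net <- louvain_modules(net, seed = 1)
  expect_identical(net$nodes$module[1:4], rep(1L, 4))
  expect_identical(net$nodes$module[5:8], rep(2L, 4))

  oracle <- best_partition_modularity(net$edges, ids)
  expect_identical(unname(tapply(seq_len(8), oracle$part, list)[["1"]]), 1:4)
  # the Louvain partition attains the exhaustive maximum modularity
  louvain_as_oracle <- net$nodes$module
  q_louvain <- local({
    w <- matrix(0, 8, 8, dimnames = list(ids, ids))
    for (r in seq_len(nrow(net$edges)))
      w[net$edges$species_a[r], net$edges$species_b[r]] <-
        w[net$edges$species_b[r], net$edges$species_a[r]] <- net$edges$rho[r]
    m2 <- sum(w); k <- rowSums(w); q <- 0
    for (g in unique(louvain_as_oracle)) {
      idx <- which(louvain_as_oracle == g)
      q <- q + sum(w[idx, idx]) - sum(k[idx])^2 / m2
    }
    q / m2
  })
  expect_equal(q_louvain, oracle$q, tolerance = 1e-12)
})

test_that("module assignment is a partition with singletons for isolated nodes", {
  rho <- sym(5) * 0; diag(rho) <- 1
  p <- sym(5); diag(p) <- NA
  rho[1, 2] <- rho[2, 1] <- 0.9; p[1, 2] <- p[2, 1] <- 1e-9
  net <- louvain_modules(fabricate_network(rho, p), seed = 3)
  expect_false(any(is.na(net$nodes$module)))
  expect_identical(net$nodes$module[1], net$nodes$module[2])
  # isolated nodes occupy their own modules
  expect_identical(length(unique(net$nodes$module[3:5])), 3L)
  # stable under a fixed seed
  net2 <- louvain_modules(fabricate_network(rho, p), seed = 3)
  expect_identical(net$nodes$module, net2$nodes$module)
})

test_that("negative edges are kept in the network but not the modularity objective", {
  rho <- sym(6) * 0; diag(rho) <- 1
  p <- sym(6); diag(p) <- NA
  for (ij in list(c(1, 2), c(3, 4))) {
    rho[ij[1], ij[2]] <- rho[ij[2], ij[1]] <- 0.8
    p[ij[1], ij[2]] <- p[ij[2], ij[1]] <- 1e-9
  }
  rho[1, 3] <- rho[3, 1] <- -0.8; p[1, 3] <- p[3, 1] <- 1e-9
  net <- louvain_modules(fabricate_network(rho, p), seed = 1)
  expect_identical(sum(net$edges$sign == "-"), 1L)
  expect_identical(sum(net$edges$sign == "+"), 2L)
  # the negative edge does not merge sp1's and sp3's modules
  expect_false(net$nodes$module[1] == net$nodes$module[3])
})

test_that("networks export to GraphML and edge TSV with attributes intact", {
  rho <- sym(5) * 0; diag(rho) <- 1
  p <- sym(5); diag(p) <- NA
  rho[1, 2] <- rho[2, 1] <- 0.9; p[1, 2] <- p[2, 1] <- 1e-9
  net <- louvain_modules(fabricate_network(rho, p), seed = 1)
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$rho, 0.9)
  tdir <- withr::local_tempdir()
  write_graphml(net, file.path(tdir, "net.graphml"))
  expect_true(file.size(file.path(tdir, "net.graphml")) > 0)
  write_edges(net, file.path(tdir, "edges.tsv"))
  back <- readr::read_tsv(file.path(tdir, "edges.tsv"), show_col_types = FALSE)
  expect_equal(back$rho, net$edges$rho)
  expect_identical(glance(net)$n_edges, 1L)
  expect_identical(nrow(tidy(net)), 1L)
})
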