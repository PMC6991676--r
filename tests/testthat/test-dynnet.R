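test_that("background merging is a canonical union with source tracking", {
  t1 <- edge_table("A", "B", 0.5, "db1")
  t2 <- edge_table(c("A", "B"), c("B", "C"), c(0.9, NA), "db2")
  m <- merge_backgrounds(list(t1, t2))
  expect_equal(nrow(m), 2L)
  ab <- m[m$geneA == "A", ]
  expect_equal(ab$confidence, 0.9)
  expect_equal(ab$source, "db1;db2")
  expect_equal(as.data.frame(merge_backgrounds(list(t2))),
               as.data.frame(t2))

  # union oracle on random tables
  set.seed(5)
  g <- sprintf("N%02d", 1:20)
  tabs <- lapply(1:3, function(i)
    edge_table(sample(g, 30, TRUE), sample(g, 30, TRUE),
               source = paste0("db", i)))
  m3 <- merge_backgrounds(tabs)
  want <- unique(unlist(lapply(tabs, function(t)
    paste(t$geneA, t$geneB))))
  expect_setequal(paste(m3$geneA, m3$geneB), want)
})

test_that("mapping DLs onto the background uses edge-intersection
           semantics", {
  dls <- data.frame(geneA = c("A", "C"), geneB = c("B", "D"))
  bg <- edge_table(c("A", "B"), c("B", "C"))
  net <- map_dls_to_ppi(dls, bg)
  expect_equal(paste(net$edges$geneA, net$edges$geneB), "A B")
  expect_setequal(net$nodes$gene, c("A", "B"))  # isolated nodes dropped

  # background superset keeps all DLs
  bg2 <- edge_table(c("A", "C", "E"), c("B", "D", "F"))
  expect_equal(nrow(map_dls_to_ppi(dls, bg2)$edges), 2L)

  # node mode keeps DLs whose endpoints both occur in the background
  netn <- map_dls_to_ppi(data.frame(geneA = "A", geneB = "C"), bg,
                         mode = "nodes")
  expect_equal(nrow(netn$edges), 1L)

  # random instances equal a brute-force membership scan
  set.seed(23)
  g <- sprintf("N%02d", 1:15)
  ga <- sample(g, 40, TRUE)
  gb <- sample(g, 40, TRUE)
  dls_r <- unique(data.frame(geneA = pmin(ga, gb), geneB = pmax(ga, gb)))
  dls_r <- dls_r[dls_r$geneA != dls_r$geneB, ]
  bg_r <- edge_table(sample(g, 40, TRUE), sample(g, 40, TRUE))
  got <- map_dls_to_ppi(dls_r, bg_r)$edges
  want <- dls_r[paste(dls_r$geneA, dls_r$geneB) %in%
                  paste(bg_r$geneA, bg_r$geneB), ]
  expect_setequal(paste(got$geneA, got$geneB),
                  paste(want$geneA, want$geneB))
})

test_that("degree accounting: sum of degrees is twice the edge count and the
           network is a subgraph of both inputs", {
  sim <- generate_dataset(generator_config(n_genes = 80,
                                           samples_per_stage = c(10, 10, 10),
                                           n_dynamic_de = 0,
                                           n_rewired_pairs = 10,
                                           n_modules = 0,
                                           trait_module_index = 0,
                                           seed = 2))
  bg <- generate_background_ppi(sim$truth)
  dlt <- dynamic_link_table(sim$dataset)
  net <- map_dls_to_ppi(dlt, bg)
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  dyn_keys <- paste(dlt$geneA, dlt$geneB)[dlt$is_dynamic_dl]
  expect_true(all(paste(net$edges$geneA, net$edges$geneB) %in% dyn_keys))
  expect_true(all(paste(net$edges$geneA, net$edges$geneB) %in%
                    paste(bg$geneA, bg$geneB)))
})

test_that("shared-neighbour scores count common background neighbours", {
  tri <- edge_table(c("A", "B", "A"), c("B", "C", "C"))
  expect_equal(shared_neighbour_score(tri, "A", "B"),
               c(count = 1, jaccard = 1))
  two <- edge_table(c("A", "C"), c("B", "D"))
  expect_equal(unname(shared_neighbour_score(two, "A", "D")["count"]), 0)
  expect_true(is.na(shared_neighbour_score(two, "A", "Z")["count"]))
  # symmetry and set-intersection oracle on a random graph
  set.seed(31)
  g <- sprintf("N%02d", 1:30)
  bg <- edge_table(sample(g, 120, TRUE), sample(g, 120, TRUE))
  nb <- split(c(bg$geneB, bg$geneA), c(bg$geneA, bg$geneB))
  for (i in 1:10) {
    p <- sample(names(nb), 2)
    s <- shared_neighbour_score(bg, p[1], p[2])
    expect_equal(s, shared_neighbour_score(bg, p[2], p[1]))
    expect_equal(unname(s["count"]),
                 length(intersect(setdiff(nb[[p[1]]], p),
                                  setdiff(nb[[p[2]]], p))))
  }
  net <- map_dls_to_ppi(data.frame(geneA = "A", geneB = "B"), tri)
  ann <- annotate_shared_neighbours(net, tri)
  expect_equal(ann$edges$shared_count, 1)
})

test_that("hub ranking sorts by degree with lexicographic ties", {
  star <- data.frame(geneA = rep("HUB", 5),
                     geneB = c("N1", "N2", "N3", "N4", "N5"))
  bg <- edge_table(star$geneA, star$geneB)
  net <- map_dls_to_ppi(star, bg)
  expect_equal(hub_ranking(net, 1)$gene, "HUB")
  expect_equal(hub_ranking(net, 1)$degree, 5L)

  # tie between Z and A: A first
  path <- data.frame(geneA = c("M1", "M2", "M3", "M1", "M2", "M3"),
                     geneB = c(rep("Z", 3), rep("A", 3)))
  bg2 <- edge_table(path$geneA, path$geneB)
  net2 <- map_dls_to_ppi(path, bg2)
  top <- hub_ranking(net2, 2)
  expect_equal(top$gene, c("A", "Z"))

  # counting oracle on a random graph + restriction to a gene universe
  set.seed(41)
  g <- sprintf("N%02d", 1:20)
  ed <- edge_table(sample(g, 60, TRUE), sample(g, 60, TRUE))
  net3 <- map_dls_to_ppi(data.frame(geneA = ed$geneA, geneB = ed$geneB), ed)
  tab <- hub_ranking(net3)
  cnt <- table(c(ed$geneA, ed$geneB))
  expect_equal(setNames(tab$degree, tab$gene)[names(cnt)],
               setNames(as.integer(cnt), names(cnt)))
  few <- hub_ranking(net3, genes = g[1:5])
  expect_true(all(few$gene %in% g[1:5]))
})

test_that("network gene overlap is the node-set intersection", {
  bg <- edge_table(c("A", "C"), c("B", "D"))
  n1 <- map_dls_to_ppi(data.frame(geneA = c("A", "C"), geneB = c("B", "D")),
                       bg)
  n2 <- map_dls_to_ppi(data.frame(geneA = "A", geneB = "B"), bg)
  ov <- network_gene_overlap(n1, n2)
  expect_equal(ov$count, 2L)
  expect_setequal(ov$genes, c("A", "B"))
  expect_equal(network_gene_overlap(n1, n1)$count, nrow(n1$nodes))
})
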