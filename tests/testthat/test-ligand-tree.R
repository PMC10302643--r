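test_that("buildTree assigns BFS layers and keeps ring closures", {
  # trimethylphosphine: three layer-1 nodes, no inter-node edges
  pm <- buildTree(c("Me", "Me", "Me"), "PMe3")
  expect_equal(nrow(treeNodes(pm)), 3L)
  expect_true(all(treeNodes(pm)$layer == 1L))
  expect_true(all(treeEdges(pm)$i == 0L))

  # tri-n-butylphosphine: 12 nodes, 3 per layer for layers 1-4
  bu <- buildTree(c("nBu", "nBu", "nBu"), "PnBu3")
  expect_equal(nrow(treeNodes(bu)), 12L)
  expect_equal(as.integer(table(treeNodes(bu)$layer)), rep(3L, 4))

  # benzyl aromatic ring spans layers 2-5 with an order-1.5 closure
  bn <- canonicalize(buildTree(c("Me", "Me", "Bn"), "Me2PBn"))
  nd <- treeNodes(bn)
  aromLayers <- nd$layer[nd$id %in%
    unique(c(treeEdges(bn)$i, treeEdges(bn)$j)[
      rep(treeEdges(bn)$order == 1.5, 2)])]
  expect_setequal(sort(unique(aromLayers)), 2:5)
  # ring closure kept: 6 aromatic bonds over 6 ring atoms (a tree would
  # only have 5)
  expect_equal(sum(treeEdges(bn)$order == 1.5), 6L)
  expect_equal(length(unique(aromLayers)), 4L)

  # layers match an independent BFS (igraph) on every fixture ligand
  skip_if_not_installed("igraph")
  for (tr in fixtureTrees()) {
    ed <- treeEdges(tr)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$i + 1L, to = ed$j + 1L),
      directed = FALSE,
      vertices = data.frame(name = c(1L, treeNodes(tr)$id + 1L)))
    d <- igraph::distances(g, v = "1")[1, as.character(treeNodes(tr)$id + 1L)]
    expect_equal(unname(d), treeNodes(tr)$layer, info = ligandName(tr))
  }
})

test_that("buildTree rejects malformed specs", {
  bad <- phosphineSpec("X", c("Me", "Me", "Me"))
  bad$nodes[[2]]$element <- "N"
  expect_error(buildTree(bad), "unsupported element")
  disc <- phosphineSpec("X", c("Me", "Me", "Me"))
  disc$edges <- disc$edges[-1]       # orphan the first carbon
  expect_error(buildTree(disc), "disconnected")
  expect_error(buildTree(c("Me", "Me")), "three substituents")
})

test_that("canonicalize ranks branches by the CIP-like comparison", {
  # tert-butyl ({C,C,C} at the first carbon) outranks cyclohexyl ({C,C,H})
  tr <- canonicalize(buildTree(c("Cy", "tBu", "tBu"), "CyPtBu2"))
  nd <- treeNodes(tr)
  kids <- vapply(c("1", "2", "3"), function(p)
    sum(startsWith(nd$path, paste0(p, ".")) & nd$layer == 2L), integer(1))
  expect_equal(unname(kids), c(3L, 3L, 2L))

  # branches differing only deep in the chain are ordered at the first
  # differing layer: 3-methylbutyl vs n-butyl diverge at layer 3
  spec <- list(name = "deep", root = "P",
               nodes = lapply(1:9, function(i) list(id = i, element = "C")),
               edges = c(list(list(i = "P", j = 1, order = 1),
                              list(i = "P", j = 5, order = 1),
                              list(i = "P", j = 9, order = 1)),
                         lapply(1:3, function(i)
                           list(i = i, j = i + 1, order = 1)),
                         lapply(5:7, function(i)
                           list(i = i, j = i + 1, order = 1)),
                         list(list(i = 3, j = 9, order = 1))[0]))
  # give branch 1 an extra methyl at its layer-3 carbon
  spec$nodes[[10]] <- list(id = 10, element = "C")
  spec$edges[[length(spec$edges) + 1]] <- list(i = 3, j = 10, order = 1)
  tr2 <- canonicalize(buildTree(spec))
  nd2 <- treeNodes(tr2)
  # the branched chain must take rank 1; its layer-3 node has two children
  expect_equal(sum(startsWith(nd2$path, "1.1.1.") ), 2L)
  expect_equal(sum(startsWith(nd2$path, "2.1.1.")), 1L)

  # symmetric ligand: any permutation yields the identical canonical form
  sp <- phosphineSpec("PEt3", c("Et", "Et", "Et"))
  base <- canonicalize(buildTree(sp))
  for (i in 1:5) {
    sp2 <- sp
    sp2$nodes <- sp$nodes[sample(seq_along(sp$nodes))]
    out <- canonicalize(buildTree(sp2))
    expect_equal(treeNodes(out)$path, treeNodes(base)$path)
    expect_equal(treeEdges(out), treeEdges(base))
  }
})

test_that("templates are unions of canonical paths and idempotent", {
  pm <- buildTree(c("Me", "Me", "Me"), "PMe3")
  pe <- buildTree(c("Et", "Et", "Et"), "PEt3")
  expect_equal(totalSlots(buildTemplate(list(pm))), 3L)
  tpl <- buildTemplate(list(pm, pe))
  expect_equal(totalSlots(tpl), 6L)
  # adding a tree that already fits leaves the template unchanged
  tpl2 <- buildTemplate(list(pm, pe, buildTree(c("Me", "Me", "Et"), "X")))
  expect_identical(templatePaths(tpl2), templatePaths(tpl))
  expect_error(buildTemplate(list()), "empty")
})

test_that("encodeGraph writes presence and bond orders into the template", {
  pm <- buildTree(c("Me", "Me", "Me"), "PMe3")
  pe <- buildTree(c("Et", "Et", "Et"), "PEt3")
  tpl <- buildTemplate(list(pm, pe))
  g <- encodeGraph(pm, tpl)
  expect_equal(nodePresence(g), c(1, 1, 1, 0, 0, 0))
  E <- edgeOrder(g)
  expect_equal(unname(E[1, 2:4]), c(1, 1, 1))     # three P-C bonds
  expect_equal(sum(E > 0), 6)                     # symmetric, no others
  expect_true(validObject(g))
  # capacity error names the offending layer
  big <- buildTree(c("nBu", "nBu", "nBu"), "PnBu3")
  expect_error(encodeGraph(big, tpl), "layer 3")
})

test_that("encode/decode round trip is isomorphic and permutation invariant", {
  skip_if_not_installed("igraph")
  trees <- fixtureTrees()
  tpl <- buildTemplate(trees)
  asIgraph <- function(tr) {
    ed <- treeEdges(tr)
    igraph::graph_from_data_frame(
      data.frame(from = as.character(ed$i), to = as.character(ed$j),
                 label = ed$order),
      directed = FALSE,
      vertices = data.frame(name = as.character(c(0L, treeNodes(tr)$id))))
  }
  for (nm in names(trees)) {
    tr <- canonicalize(trees[[nm]])
    dec <- decodeGraph(encodeGraph(tr, tpl), tpl)
    expect_true(igraph::isomorphic(asIgraph(tr), asIgraph(dec)),
                info = nm)
    expect_equal(stericProxy(dec), stericProxy(tr), info = nm)
  }
})

test_that("tree-spec JSON round trips through write and read", {
  tr <- canonicalize(buildTree(c("Ad", "Cy", "Bn"), "AdCyBn"))
  path <- withr::local_tempfile(fileext = ".json")
  writeTreeSpec(tr, path)
  back <- canonicalize(readTreeSpec(path))
  expect_equal(treeNodes(back)$path, treeNodes(tr)$path)
  expect_equal(treeEdges(back), treeEdges(tr))
  expect_equal(ligandName(back), "AdCyBn")
})

test_that("bundled fixtures load and have the expected bulk ordering", {
  trees <- fixtureTrees()
  expect_setequal(names(trees),
                  c("PnBu3", "PCy3", "Cy2PAd", "Cy2PtBu", "iPr2PtBu",
                    "EtPAd2", "CyPtBu2", "PtBu2Bn", "Ad2PBn"))
  s <- vapply(trees, stericProxy, integer(1))
  # tri-n-butylphosphine is the least bulky named ligand near the metal,
  # di(1-adamantyl)benzylphosphine the bulkiest
  expect_equal(unname(s[["PnBu3"]]), 9L)
  expect_equal(unname(s[["Ad2PBn"]]), 18L)
  expect_true(all(s >= s[["PnBu3"]] & s <= s[["Ad2PBn"]]))
})
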