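test_that("a linear chain reads as 4 metabolites and 3 reactions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  toy_chain_tsv(path)
  net <- suppressMessages(metnet_read_tsv(path))
  v <- igraph::V(net$graph)
  expect_equal(sum(v$type == "metabolite"), 4)
  expect_equal(sum(v$type == "reaction"), 3)
  # round trip
  out <- withr::local_tempfile(fileext = ".tsv")
  metnet_write_tsv(net, out)
  net2 <- suppressMessages(metnet_read_tsv(out))
  expect_setequal(igraph::V(net2$graph)$name, v$name)
  expect_equal(igraph::ecount(net2$graph), igraph::ecount(net$graph))
})

test_that("dangling reactions and malformed files are reported", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(source = c("a", "b"),
                                  target = c("r1", "r2"),
                                  type = c("substrate", "substrate")),
                   path, progress = FALSE)
  expect_warning(suppressMessages(metnet_read_tsv(path)), "dangling")
  readr::write_tsv(tibble::tibble(source = "a", target = "r1",
                                  type = "mystery"), path, progress = FALSE)
  expect_error(suppressMessages(metnet_read_tsv(path)), "unknown edge type")
})

test_that("SBML reversible reactions become two directed reaction arcs", {
  sbml <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="toy">
  <listOfSpecies>
   <species id="a"/><species id="b"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="r1" reversible="true">
    <listOfReactants><speciesReference species="a"/></listOfReactants>
    <listOfProducts><speciesReference species="b"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>', sbml)
  net <- metnet_read_sbml(sbml)
  fw <- connect_pair(net, "a", "b")
  bw <- connect_pair(net, "b", "a")
  expect_true(fw$reachable && bw$reachable)
  # the reverse path traverses the same reaction id
  expect_identical(rev(bw$nodes$node), fw$nodes$node)
})

test_that("adjacent metabolites are one reaction apart", {
  path <- withr::local_tempfile(fileext = ".tsv")
  toy_chain_tsv(path)
  net <- suppressMessages(metnet_read_tsv(path))
  p <- connect_pair(net, "a", "b")
  expect_equal(p$n_reactions, 1)
  expect_identical(p$nodes$node, c("a", "r1", "b"))
  expect_error(connect_pair(net, "a", "nope"), "unknown metabolite")
})

test_that("unreachable pairs are values, not exceptions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  toy_chain_tsv(path)
  net <- suppressMessages(metnet_read_tsv(path))
  p <- connect_pair(net, "d", "a")  # chain is directed a -> d
  expect_false(p$reachable)
  expect_true(is.na(p$weight))
})

test_that("degree weighting routes around the hub cofactor", {
  path <- withr::local_tempfile(fileext = ".tsv")
  toy_diamond_tsv(path)
  net <- suppressMessages(metnet_read_tsv(path))
  pd <- connect_pair(net, "a", "b", weighting = "degree")
  expect_true("m1" %in% pd$nodes$node)
  expect_false("atp" %in% pd$nodes$node)
  # unit weighting ties; lexicographic tie-break picks the r1 branch
  pu <- connect_pair(net, "a", "b", weighting = "unit")
  expect_identical(pu$nodes$node, c("a", "r1", "atp", "r2", "b"))
})

test_that("path weights equal the brute-force minimum over simple paths", {
  edges <- toy_diamond_edges()
  types <- edges_node_types(edges)
  path <- withr::local_tempfile(fileext = ".tsv")
  toy_diamond_tsv(path)
  net <- suppressMessages(metnet_read_tsv(path))
  for (wt in c("degree", "unit")) {
    for (pair in list(c("a", "b"), c("a", "x5"), c("m1", "b"))) {
      got <- connect_pair(net, pair[1], pair[2], weighting = wt)
      oracle <- brute_force_path(edges, types, pair[1], pair[2],
                                 weighting = wt)
      expect_equal(got$weight, oracle$weight,
                   info = paste(wt, paste(pair, collapse = "->")))
    }
  }
  # with the hub blocked as a side compound the only a->b route is via m1
  blocked <- connect_pair(net, "a", "b", side_compounds = "atp")
  oracle_b <- brute_force_path(edges, types, "a", "b",
                               side_compounds = "atp")
  expect_equal(blocked$weight, oracle_b$weight)
  expect_true("m1" %in% blocked$nodes$node)
})

test_that("union sub-network gathers pairwise paths with provenance", {
  path <- withr::local_tempfile(fileext = ".tsv")
  toy_chain_tsv(path)
  net <- suppressMessages(metnet_read_tsv(path))
  # collinear biomarkers: the union is the path itself
  sub <- union_subnetwork(net, c("a", "b", "d"))
  expect_setequal(sub$nodes$node, c("a", "r1", "b", "r2", "c", "r3", "d"))
  # every node lies on at least one pairwise path
  expect_true(all(nchar(sub$nodes$provenance) > 0))
  # the intermediate c carries the provenance of pairs spanning it
  expect_match(sub$nodes$provenance[sub$nodes$node == "c"], "b~d")
  # input order does not matter
  sub2 <- union_subnetwork(net, c("d", "a", "b"))
  expect_identical(sub$nodes, sub2$nodes)
})

test_that("disconnected biomarkers are reported, not bridged", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    source = c("a", "r1", "x", "r9"),
    target = c("r1", "b", "r9", "y"),
    type = c("substrate", "product", "substrate", "product")),
    path, progress = FALSE)
  net <- suppressMessages(metnet_read_tsv(path))
  sub <- union_subnetwork(net, c("a", "b", "x", "y"))
  expect_true(nrow(sub$unreachable) > 0)
  comp <- igraph::components(sub$graph)
  expect_equal(comp$no, 2)
  # fully unreachable set gives an empty sub-network with a warning
  expect_warning(empty <- union_subnetwork(net, c("b", "y")), "unreachable")
  expect_equal(nrow(empty$nodes), 0)
})

test_that("an inositol-like intermediate joins its pair with provenance", {
  # glucose -> r_a -> inositol -> r_b -> glycerol, plus an unrelated branch
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    source = c("glucose", "r_a", "inositol", "r_b",
               "leucine", "r_c"),
    target = c("r_a", "inositol", "r_b", "glycerol",
               "r_c", "glucose"),
    type = c("substrate", "product", "substrate", "product",
             "substrate", "product")), path, progress = FALSE)
  net <- suppressMessages(metnet_read_tsv(path))
  sub <- union_subnetwork(net, c("glucose", "glycerol", "leucine"))
  ino <- sub$nodes[sub$nodes$node == "inositol", ]
  expect_equal(nrow(ino), 1)
  expect_match(ino$provenance, "glucose~glycerol")
  expect_false(grepl("leucine", ino$provenance))
})

test_that("graphml export writes node attributes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  toy_chain_tsv(path)
  net <- suppressMessages(metnet_read_tsv(path))
  sub <- union_subnetwork(net, c("a", "d"))
  out <- withr::local_tempfile(fileext = ".graphml")
  subnetwork_write(sub, out)
  txt <- readLines(out)
  expect_true(any(grepl("provenance", txt)))
})
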