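# Enumeration and rule checks, validated against brute force, the
# supercell-growth oracle, and igraph-based isomorphism.

test_that("closed-symmetry rule: monomers valid, fibers rejected with witness", {
  g <- graph_fixture("fiber")
  expect_true(check_closed_symmetry(g, integer(0))$valid)
  v <- check_closed_symmetry(g, 1L)
  expect_false(v$valid)
  expect_identical(v$failed_rule, "closure")
  expect_identical(v$witness$edge, 1L)  # the self-loop is the witness
  # the capped arrangement fails the same way through its 2-cycle
  gc <- graph_fixture("fiber_capped")
  expect_false(check_closed_symmetry(gc, 1L)$valid)
})

test_that("rule-4 verdicts match the supercell-growth oracle", {
  set.seed(1)
  n_checked <- 0
  for (seed in 1:50) {
    g <- random_graph_fixture(n_types = sample(1:4, 1), seed = 100 + seed)
    engaged_sets <- list(g$types$type,
                         sample(g$types$type, sample(nrow(g$types), 1)))
    for (engaged in engaged_sets) {
      got <- check_closed_symmetry(g, engaged)$valid
      expect_identical(got, oracle_rule4_supercell(g, engaged))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("assembly extraction lifts offsets along a spanning tree", {
  # empty engaged set: one monomeric assembly per chain
  g <- random_graph_fixture(2, seed = 4, n_chains = 4)
  asms <- extract_assemblies(g, integer(0))
  expect_length(asms, 4)
  expect_true(all(vapply(asms, function(a) a$size, integer(1)) == 1))
  # a dimer wrapping the cell boundary gets consistent offsets
  nodes <- data.frame(id = 1:2, chain = c("A", "B"), op = 1L, entity = 1L)
  edges <- data.frame(src = 1, dst = 2, iface = 1L, type = 1L,
                      hx = 1L, hy = 0L, hz = 0L, area = 100)
  types <- data.frame(type = 1L, p = 0.5, mean_area = 100,
                      isologous = TRUE)
  gw <- quotient_graph(nodes, edges, types)
  a <- extract_assemblies(gw, 1L)
  expect_length(a, 1)
  expect_equal(sort(a[[1]]$members$ox), c(0, 1))
  # extraction refuses rule-4-violating sets
  gf <- graph_fixture("fiber")
  expect_error(extract_assemblies(gf, 1L), "closed-symmetry")
})

test_that("offset lifting is independent of traversal order up to a shift", {
  g <- graph_fixture("d3_hexamer")
  a1 <- extract_assemblies(g, c(1L, 2L))[[1]]
  g2 <- g
  g2$edges <- g2$edges[rev(seq_len(nrow(g2$edges))), ]
  a2 <- extract_assemblies(g2, c(1L, 2L))[[1]]
  m1 <- a1$members[order(a1$members$node), c("ox", "oy", "oz")]
  m2 <- a2$members[order(a2$members$node), c("ox", "oy", "oz")]
  d <- as.matrix(m1) - as.matrix(m2)
  expect_true(all(apply(d, 2, function(col) length(unique(col)) == 1)))
})

test_that("isomorphism rule separates dimers+monomers but exempts orthogonal", {
  # all single-node assemblies of one entity: valid
  g0 <- random_graph_fixture(1, seed = 2, n_chains = 3, n_entities = 1)
  expect_true(check_isomorphism(extract_assemblies(g0, integer(0)))$valid)
  # non_isomorphic fixture: C2 dimer + leftover monomer of the same entity
  gn <- graph_fixture("non_isomorphic")
  expect_true(check_closed_symmetry(gn, 1L)$valid)  # passes rule 4 ...
  v <- check_isomorphism(extract_assemblies(gn, 1L))
  expect_false(v$valid)                             # ... but not rule 3
  expect_identical(v$failed_rule, "isomorphism")
  expect_length(v$witness, 2)
  # orthogonal stoichiometries (A2 dimer + B3 trimer) are exempt
  nodes <- data.frame(id = 1:5, chain = LETTERS[1:5], op = 1L,
                      entity = c(1L, 1L, 2L, 2L, 2L))
  edges <- data.frame(src = c(1, 3, 4, 5), dst = c(2, 4, 5, 3),
                      iface = 1:4, type = c(1L, 2L, 2L, 2L),
                      hx = 0L, hy = 0L, hz = 0L, area = c(500, 300, 300,
                                                          300))
  types <- data.frame(type = 1:2, p = c(0.8, 0.7),
                      mean_area = c(500, 300), isologous = c(TRUE, FALSE))
  go <- quotient_graph(nodes, edges, types)
  expect_true(check_isomorphism(extract_assemblies(go, 1:2))$valid)
})

test_that("labelled-multigraph isomorphism agrees with the igraph oracle", {
  set.seed(8)
  n_pairs <- 0
  for (seed in 1:30) {
    g <- random_graph_fixture(sample(2:4, 1), seed = 300 + seed,
                              n_chains = sample(3:4, 1), mode = "closed")
    subsets <- list(g$types$type, g$types$type[1],
                    g$types$type[-1])
    for (engaged in subsets) {
      asms <- extract_assemblies(g, engaged)
      if (length(asms) < 2) next
      for (i in 1:(length(asms) - 1)) for (j in (i + 1):length(asms)) {
        got <- qslattice:::.assembly_isomorphic(asms[[i]], asms[[j]])
        expect_identical(got, oracle_iso_igraph(asms[[i]], asms[[j]]))
        n_pairs <- n_pairs + 1
      }
    }
  }
  expect_gte(n_pairs, 10)
})

test_that("canned topologies enumerate to their designed valid sets", {
  expect_identical(engaged_set_keys(
    enumerate_superassemblies(graph_fixture("c2_dimer"))), c("", "1"))
  expect_identical(engaged_set_keys(
    enumerate_superassemblies(graph_fixture("fiber"))), "")
  expect_identical(engaged_set_keys(
    enumerate_superassemblies(graph_fixture("fiber_capped"))), "")
  expect_identical(engaged_set_keys(
    enumerate_superassemblies(graph_fixture("non_isomorphic"))), "")
  expect_identical(engaged_set_keys(
    enumerate_superassemblies(graph_fixture("d3_hexamer"))),
    c("", "1", "1,2", "1,2,3", "1,3", "2", "2,3", "3"))
  expect_identical(engaged_set_keys(
    enumerate_superassemblies(graph_fixture("heterodimer_ab"))),
    c("", "1"))
})

test_that("pruned enumeration equals unpruned brute force on random graphs", {
  for (seed in 1:40) {
    g <- random_graph_fixture(n_types = sample(1:5, 1), seed = 500 + seed,
                              n_chains = sample(2:4, 1),
                              n_entities = sample(1:3, 1))
    pruned <- engaged_set_keys(enumerate_superassemblies(g))
    brute <- engaged_set_keys(brute_force_valid_sets(g))
    expect_identical(pruned, brute)
    expect_true("" %in% pruned)  # the all-monomer set is always valid
  }
})

test_that("returned superassemblies pass independent re-checks of all rules", {
  for (seed in c(3, 14, 27)) {
    g <- random_graph_fixture(4, seed = 700 + seed)
    for (sa in enumerate_superassemblies(g)) {
      # rule 4 via the exported Paton check and via the supercell oracle
      expect_true(check_closed_symmetry(g, sa$engaged)$valid)
      expect_true(oracle_rule4_supercell(g, sa$engaged))
      # rules 1+3: assemblies partition the nodes and are isomorphic
      all_nodes <- sort(unlist(lapply(sa$assemblies, function(a)
        a$members$node)))
      expect_identical(all_nodes, sort(g$nodes$id))   # full coverage
      expect_true(check_isomorphism(sa$assemblies)$valid)
      # rule 2 by construction: engaged edge types subset of engaged set
      for (a in sa$assemblies)
        expect_true(all(a$edges$type %in% sa$engaged))
    }
  }
})

test_that("invalidity is monotone: supersets of invalid sets stay invalid", {
  for (seed in c(5, 9)) {
    g <- random_graph_fixture(4, seed = 900 + seed)
    valid_keys <- engaged_set_keys(brute_force_valid_sets(g))
    all_types <- g$types$type
    key <- function(e) paste(sort(e), collapse = ",")
    for (mask in 0:(2^length(all_types) - 1)) {
      engaged <- all_types[bitwAnd(mask, 2^(seq_along(all_types) - 1)) != 0]
      if (key(engaged) %in% valid_keys) next
      # rule-4-invalid sets must have rule-4-invalid supersets
      if (!check_closed_symmetry(g, engaged)$valid) {
        extra <- setdiff(all_types, engaged)
        if (length(extra) > 0) {
          sup <- c(engaged, extra[1])
          expect_false(check_closed_symmetry(g, sup)$valid)
        }
      }
    }
  }
})

test_that("heteromeric assemblies are even-stoichiometric or flagged asymmetric", {
  # for lattices that emulate real crystals (the canned fixtures) every
  # valid heteromeric assembly has equal entity counts; abstract random
  # graphs can realise uneven heteromers topologically (pseudosymmetric
  # 2:1 binding), which the point-group heuristic flags as "none"
  for (sa in enumerate_superassemblies(graph_fixture("heterodimer_ab"))) {
    for (a in sa$assemblies) {
      present <- a$stoich[a$stoich > 0]
      if (length(present) >= 2) expect_length(unique(present), 1)
    }
  }
  for (seed in 1:15) {
    g <- random_graph_fixture(3, seed = 1100 + seed, n_chains = 4,
                              n_entities = 2)
    for (sa in enumerate_superassemblies(g)) {
      for (a in sa$assemblies) {
        present <- a$stoich[a$stoich > 0]
        if (length(present) >= 2 && length(unique(present)) > 1)
          expect_identical(detect_point_group(a), "none")
      }
    }
  }
})

test_that("enumeration guard trips on too many interface types", {
  g <- graph_fixture("d3_hexamer")
  expect_error(enumerate_superassemblies(g, max_types = 2), "max_types")
})

test_that("entity contraction preserves the enumeration exactly", {
  # homomer: nothing to contract
  gh <- graph_fixture("c2_dimer")
  ch <- contract_entities(gh)
  expect_length(ch$forced, 0)
  expect_identical(ch$graph$nodes$label, gh$nodes$label)
  # heterodimer: one meta-entity, type 1 forced, stoichiometry [1,1]
  ga <- graph_fixture("heterodimer_ab")
  ca <- contract_entities(ga)
  expect_identical(ca$forced, 1L)
  expect_equal(nrow(ca$graph$nodes), 1)
  expect_length(unique(ca$graph$nodes$entity), 1)
  lifted <- extract_assemblies(ga, 1L)
  expect_equal(unname(lifted[[1]]$stoich), c(1L, 1L))
  # random multi-entity fixtures: contraction-based enumeration equals
  # direct enumeration
  for (seed in 1:25) {
    g <- random_graph_fixture(n_types = sample(2:4, 1), seed = 1300 + seed,
                              n_chains = sample(3:4, 1), n_entities = 3)
    expect_identical(
      engaged_set_keys(enumerate_with_contraction(g)),
      engaged_set_keys(enumerate_superassemblies(g)))
  }
})

test_that("point groups are detected geometrically from crystal isometries", {
  # monomer -> C1
  s1 <- crystal_fixture("heterodimer_ab")
  a1 <- structure(list(
    members = data.frame(node = 1, chain = "A", op = 1L, entity = 1L,
                         ox = 0L, oy = 0L, oz = 0L),
    stoich = c("1" = 1L, "2" = 0L), size = 1L,
    edges = qslattice:::.empty_edges(), engaged = integer(0),
    point_group = NA_character_), class = "assembly")
  expect_identical(detect_point_group(a1, s1), "C1")
  # crystallographic 2-fold dimer -> C2
  s2 <- crystal_fixture("c2_dimer")
  ifs <- find_interfaces(s2)
  types <- cluster_interface_types(ifs)
  g2 <- build_lattice_graph(s2, attr(types, "interfaces"), types)
  a2 <- extract_assemblies(g2, 1L)[[1]]
  expect_identical(detect_point_group(a2, s2), "C2")
  # D3 hexamer built from explicit P321 operators
  cellh <- crystal_cell(40, 40, 30, 90, 90, 120)
  ctr <- orthogonalize(cellh, c(0.15, 0.05, 0.10))
  xyz <- rbind(ctr, ctr + c(2, 0, 0), ctr + c(0, 1.5, 0), ctr + c(0, 0, 1))
  chain <- list(chain_id = "A", entity_id = 1L, xyz = xyz, resno = 1:4,
                resname = rep("ALA", 4), atom = rep("CA", 4),
                elem = rep("X", 4), radius = rep(1.9, 4),
                sequence = "AAAA", is_protein = TRUE)
  s3 <- structure(list(cell = cellh,
                       ops = space_group_operators("P 3 2 1"),
                       chains = list(A = chain), space_group = "P 3 2 1",
                       pdb_id = NA_character_), class = "xtal_structure")
  # the operator group has order 6: composition table closes
  for (a in s3$ops) for (b in s3$ops)
    expect_true(symop_match(symop_compose(a, b), s3$ops)$op_id %in% 1:6)
  a3 <- structure(list(
    members = data.frame(node = 1:6, chain = "A", op = 1:6, entity = 1L,
                         ox = 0L, oy = 0L, oz = 0L),
    stoich = c("1" = 6L), size = 6L,
    edges = qslattice:::.empty_edges(), engaged = integer(0),
    point_group = NA_character_), class = "assembly")
  expect_identical(detect_point_group(a3, s3), "D3")
  # a heterodimer with one chain per entity reduces to a meta-monomer: C1
  a4 <- structure(list(
    members = data.frame(node = 1:2, chain = c("A", "B"), op = 1L,
                         entity = c(1L, 2L), ox = 0L, oy = 0L, oz = 0L),
    stoich = c("1" = 1L, "2" = 1L), size = 2L,
    edges = qslattice:::.empty_edges(), engaged = integer(0),
    point_group = NA_character_), class = "assembly")
  expect_identical(detect_point_group(a4, s1), "C1")
  # two same-entity chains with no relating isometry -> "none" + warning
  a5 <- structure(list(
    members = data.frame(node = 1:2, chain = "A", op = 1L, entity = 1L,
                         ox = c(0L, 0L), oy = c(0L, 0L), oz = c(0L, 1L)),
    stoich = c("1" = 2L, "2" = 0L), size = 2L,
    edges = qslattice:::.empty_edges(), engaged = integer(0),
    point_group = NA_character_), class = "assembly")
  expect_warning(pg <- detect_point_group(a5, s1), "none")
  expect_identical(pg, "none")
})

test_that("topological point-group labels cover the canned fixtures", {
  res_d3 <- predict_assembly(graph_fixture("d3_hexamer"))
  expect_identical(res_d3$prediction$point_groups, "D3")
  res_c2 <- predict_assembly(graph_fixture("c2_dimer"))
  expect_identical(res_c2$prediction$point_groups, "C2")
  # every multi-chain assembly of a valid superassembly gets a label
  for (nm in c("c2_dimer", "d3_hexamer", "heterodimer_ab")) {
    res <- predict_assembly(graph_fixture(nm))
    for (pr in res$predictions) {
      for (a in pr$assemblies) {
        if (a$size > 1) expect_false(a$point_group %in% c(NA, "none"))
      }
    }
  }
})
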