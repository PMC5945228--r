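# Interface detection validated against a brute-force all-pairs distance
# scan over the 3x3x3 supercell (helper-oracles.R), plus constructed
# fixtures for clustering, isologous detection and core/rim labels.

test_that("chains far apart yield no interfaces", {
  s <- structure(list(
    cell = crystal_cell(200, 200, 200),
    ops = space_group_operators("P 1"),
    chains = list(
      A = qslattice:::.blob_chain("A", 1L, x = 10, y0 = 100, z0 = 100),
      B = qslattice:::.blob_chain("B", 1L, x = 110, y0 = 100, z0 = 100,
                                  "ALA")),
    space_group = "P 1", pdb_id = NA_character_),
    class = "xtal_structure")
  expect_length(find_interfaces(s), 0)
})

test_that("the C2 dimer crystal has exactly one isologous interface", {
  s <- crystal_fixture("c2_dimer")
  ifs <- find_interfaces(s)
  expect_length(ifs, 1)
  f <- ifs[[1]]
  expect_true(f$isologous)
  expect_identical(f$chain_b$op_id, 2L)
  expect_identical(f$chain_b$shift, c(0L, 0L, 0L))
  # brute-force supercell scan sees exactly this contact orbit
  hits <- oracle_contacts_supercell(s)
  expect_identical(hits, "A 1 0,0,0 :: A 2 0,0,0")
})

test_that("the fiber crystal has one self-contact with cell shift (1,0,0)", {
  s <- crystal_fixture("fiber")
  ifs <- find_interfaces(s)
  expect_length(ifs, 1)
  f <- ifs[[1]]
  expect_identical(f$chain_a$chain, f$chain_b$chain)
  expect_identical(f$chain_b$op_id, 1L)
  expect_identical(sort(abs(f$chain_b$shift)), c(0L, 0L, 1L))
  expect_false(f$isologous)
  hits <- oracle_contacts_supercell(s)
  expect_setequal(hits, c("A 1 -1,0,0 :: A 1 0,0,0",
                          "A 1 0,0,0 :: A 1 1,0,0"))
})

test_that("interfaces are invariant under re-choice of asymmetric unit", {
  s <- crystal_fixture("c2_dimer")
  base <- find_interfaces(s)
  # re-choose the AU: move the chain through operator 2
  s2 <- s
  s2$chains$A <- apply_operator(s$chains$A, s$ops[[2]], c(0, 0, 0), s$cell)
  alt <- find_interfaces(s2)
  expect_length(alt, length(base))
  expect_lt(abs(alt[[1]]$area - base[[1]]$area), 0.5)
  expect_identical(alt[[1]]$isologous, base[[1]]$isologous)
})

fake_interface <- function(id, contacts, ea = 1L, eb = 1L, area = 100) {
  structure(list(id = id,
                 chain_a = node_ref("A"), chain_b = node_ref("B", 2L),
                 entity_a = ea, entity_b = eb, area = area,
                 contacts = contacts, detail = NULL,
                 isologous = NA, type_id = NA_integer_),
            class = "interface")
}

test_that("isologous detection keys on transpose symmetry of contacts", {
  sym <- cbind(c(1, 2, 2, 3), c(1, 3, 2, 2))  # equals its transpose
  expect_true(detect_isologous(fake_interface(1, sym)))
  disjoint <- cbind(1:3, 4:6)                  # face-to-back
  expect_false(detect_isologous(fake_interface(2, disjoint)))
  # different entities are never isologous, even with symmetric contacts
  expect_false(detect_isologous(fake_interface(3, sym, ea = 1L, eb = 2L)))
  # 17 of 20 pairs transpose-symmetric (85% overlap) -> above the 0.8 bar
  pairs <- cbind(rep(1:5, each = 4), rep(1:4, 5))[1:17, ]
  near <- rbind(pairs[pairs[, 1] >= pairs[, 2], , drop = FALSE],
                pairs[, 2:1][pairs[, 1] > pairs[, 2], , drop = FALSE],
                cbind(8:9, 11:12))
  k <- qslattice:::.contact_keys(near)
  kt <- qslattice:::.contact_keys(near, flip = TRUE)
  jac <- length(intersect(k, kt)) / length(union(k, kt))
  expect_gte(jac, 0.8)
  expect_true(detect_isologous(fake_interface(4, near)))
})

test_that("type clustering is single-linkage and matches a components oracle", {
  # crystallographically equivalent copies: identical contacts, one type
  i1 <- fake_interface(1, cbind(1:4, 5:8))
  i2 <- fake_interface(2, cbind(1:4, 5:8))
  t12 <- cluster_interface_types(list(i1, i2))
  expect_length(t12, 1)
  expect_identical(sort(t12[[1]]$members), c(1L, 2L))
  # disjoint contacts: two types
  i3 <- fake_interface(3, cbind(11:14, 15:18))
  expect_length(cluster_interface_types(list(i1, i3)), 2)
  # chained similarities 0.5 / 0.5 / 0.1: single linkage joins the chain
  base <- cbind(1:4, 21:24)
  c1 <- rbind(base, cbind(5:6, 25:26))           # 6 pairs
  c2 <- rbind(base, cbind(7:8, 27:28))           # J(c1,c2) = 4/8 = 0.5
  c3 <- rbind(base[1:2, , drop = FALSE], cbind(9:14, 29:34))
  ifs <- list(fake_interface(1, c1, area = 300),
              fake_interface(2, c2, area = 200),
              fake_interface(3, c3, area = 100))
  got <- cluster_interface_types(ifs, sim_cutoff = 0.3)
  # oracle: connected components of the thresholded similarity graph
  jac <- function(a, b) {
    ka <- paste(a[, 1], a[, 2]); kb <- paste(b[, 1], b[, 2])
    length(intersect(ka, kb)) / length(union(ka, kb))
  }
  n <- 3
  adj <- matrix(FALSE, n, n)
  cons <- list(c1, c2, c3)
  for (i in 1:n) for (j in 1:n)
    adj[i, j] <- jac(cons[[i]], cons[[j]]) >= 0.3
  reach <- adj
  for (k in 1:n) reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  oracle_groups <- match(apply(reach, 1, paste, collapse = ""),
                         unique(apply(reach, 1, paste, collapse = "")))
  got_groups <- integer(3)
  for (tt in got) got_groups[tt$members] <- tt$type_id
  expect_identical(length(unique(got_groups)), length(unique(oracle_groups)))
  split_got <- unname(split(1:3, got_groups))
  split_oracle <- unname(split(1:3, oracle_groups))
  expect_setequal(lapply(split_got, sort), lapply(split_oracle, sort))
})

test_that("type ids are ordered by descending mean area", {
  small <- fake_interface(1, cbind(1:3, 11:13), area = 50)
  big <- fake_interface(2, cbind(21:24, 31:34), area = 500)
  types <- cluster_interface_types(list(small, big))
  expect_identical(types[[1]]$members, 2L)  # larger area is type 1
  expect_gt(types[[1]]$mean_area, types[[2]]$mean_area)
})

test_that("core/rim/surface labels follow engineered burial fractions", {
  # residue 1 fully caged by the partner (burial 1 -> core), residue 2
  # partially buried (-> rim), residue 3 untouched (-> surface)
  cage <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                c(0, 0, 3), c(0, 0, -3))
  achain <- list(chain_id = "A", entity_id = 1L,
                 xyz = rbind(c(0, 0, 0), c(10, 0, 0), c(22, 0, 0)),
                 resno = 1:3, resname = rep("ALA", 3),
                 atom = rep("CA", 3), elem = rep("X", 3),
                 radius = rep(1.9, 3), sequence = "AAA", is_protein = TRUE)
  bxyz <- rbind(cage, c(10, 0, 4.6))
  bchain <- list(chain_id = "B", entity_id = 1L, xyz = bxyz,
                 resno = seq_len(nrow(bxyz)),
                 resname = rep("ALA", nrow(bxyz)),
                 atom = rep("CA", nrow(bxyz)),
                 elem = rep("X", nrow(bxyz)),
                 radius = rep(1.9, nrow(bxyz)),
                 sequence = paste(rep("A", nrow(bxyz)), collapse = ""),
                 is_protein = TRUE)
  s <- structure(list(cell = crystal_cell(120, 120, 120),
                      ops = space_group_operators("P 1"),
                      chains = list(A = achain, B = bchain),
                      space_group = "P 1", pdb_id = NA_character_),
                 class = "xtal_structure")
  ifs <- find_interfaces(s)
  expect_length(ifs, 1)
  lab <- classify_core_rim(s, ifs[[1]])
  a <- lab$a
  expect_identical(a$label[a$resno == 1], "core")
  expect_identical(a$label[a$resno == 2], "rim")
  expect_identical(a$label[a$resno == 3], "surface")
  # a residue with no buried area is never part of the interface
  expect_identical(a$bsa[a$resno == 3], 0)
})
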