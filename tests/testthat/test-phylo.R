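test_that("Poisson distances follow the closed form", {
  al <- c(a = strrep("A", 100),
          b = paste0(strrep("A", 90), strrep("C", 10)))
  d <- protein_distance(al)
  expect_equal(d["a", "b"], -log(0.9), tolerance = 1e-12)
  expect_equal(d["a", "a"], 0)
  expect_equal(d, t(d))

  ident <- c(x = "ACDEF", y = "ACDEF")
  expect_equal(protein_distance(ident)["x", "y"], 0)

  gappy <- c(x = "AC---", y = "--CDE")
  expect_error(protein_distance(gappy), "no aligned columns")

  sat <- c(x = strrep("A", 100), y = strrep("C", 100))
  expect_warning(dd <- protein_distance(sat), "saturated")
  expect_equal(dd["x", "y"], -log(0.05))
})

test_that("three-taxon NJ matches the three-point closed form", {
  d <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["A"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(len["B"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(len["C"]), (0.4 + 0.5 - 0.3) / 2)
  bad <- d; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
})

test_that("NJ recovers the generating topology of additive matrices", {
  set.seed(99)
  for (i in 1:40) {
    t0 <- ape::rtree(sample(4:8, 1))
    dm <- ape::cophenetic.phylo(t0)
    tr <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(t0), tr), 0,
                 ignore_attr = TRUE)
  }
  # equidistant taxa: ties broken deterministically
  de <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(de) <- 0
  expect_identical(ape::write.tree(nj_tree(de)),
                   ape::write.tree(nj_tree(de)))
})

test_that("bootstrap support is reproducible and bounded", {
  root <- cdmine:::random_protein(150, seed = 3)
  tr <- ape::read.tree(
    text = "((a1:0.05,a2:0.05):0.4,(b1:0.05,b2:0.05):0.4);")
  fam <- evolve_family(root, tr, rate = 1, seed = 17)
  bt1 <- bootstrap_support(fam, n_reps = 30, seed = 5)
  bt2 <- bootstrap_support(fam, n_reps = 30, seed = 5)
  expect_identical(bt1$node.label, bt2$node.label)
  sup <- suppressWarnings(as.numeric(bt1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # single replicate: supports are all-or-nothing
  b1 <- bootstrap_support(fam, n_reps = 1, seed = 2)
  s1 <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
})

test_that("monophyly is an exact bipartition test", {
  tr <- ape::read.tree(text = "((a1:1,a2:1)90:1,(b1:1,(b2:1,b3:1)80:1)95:1);")
  expect_true(is_monophyletic(tr, c("a1", "a2"))$monophyletic)
  expect_equal(is_monophyletic(tr, c("b2", "b3"))$support, 80)
  expect_false(is_monophyletic(tr, c("a1", "b1"))$monophyletic)
  expect_true(is_monophyletic(tr, tr$tip.label)$monophyletic)
  expect_true(is_monophyletic(tr, "a1")$monophyletic)
  expect_error(is_monophyletic(tr, "zz"), "unknown label")
})

test_that("Newick round-trip preserves topology, lengths and supports", {
  root <- cdmine:::random_protein(120, seed = 4)
  tr <- ape::read.tree(
    text = "((a1:0.05,a2:0.05):0.3,((b1:0.05,b2:0.05):0.2,c:0.4):0.1);")
  fam <- evolve_family(root, tr, rate = 1, seed = 23)
  bt <- bootstrap_support(fam, n_reps = 20, seed = 7)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bt, tf)
  back <- read_newick(tf)
  expect_equal(ape::dist.topo(bt, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(bt$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, bt$node.label)
})
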