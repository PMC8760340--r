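test_that("identity-targeted mutation is exact, protected and deterministic", {
  base <- cdmine:::random_protein(500, seed = 1)
  expect_identical(mutate_to_identity(base, 100, seed = 2), base)
  m1 <- mutate_to_identity(base, 80, seed = 7)
  m2 <- mutate_to_identity(base, 80, seed = 7)
  expect_identical(m1, m2)
  expect_equal(column_identity(base, m1), 80, tolerance = 0.2)
  # aligner recount agrees with the column recount
  expect_equal(percent_identity(base, m1)[["identity_pct"]], 80,
               tolerance = 2)
  # calibration: realized identity is within a point of target on average
  err <- vapply(1:100, function(i) {
    t <- sample(c(98, 80, 60, 45, 38), 1)
    abs(column_identity(base, mutate_to_identity(base, t, seed = i)) - t)
  }, 0)
  expect_lte(mean(err), 1)
  # protection is honored and can make a target unreachable
  prot <- 1:450
  m3 <- mutate_to_identity(base, 95, seed = 3, protect_positions = prot)
  expect_identical(substr(m3, 1, 450), substr(base, 1, 450))
  expect_error(mutate_to_identity(base, 20, seed = 4,
                                  protect_positions = prot),
               "unreachable")
})

test_that("family evolution is substitution-only and seed-deterministic", {
  root <- cdmine:::random_protein(100, seed = 5)
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.2,(c:0.1,d:0.1):0.2);")
  tr0 <- tr; tr0$edge.length[] <- 0
  f0 <- evolve_family(root, tr0, rate = 1, seed = 6)
  expect_true(all(f0 == root))
  f1 <- evolve_family(root, tr, rate = 1, seed = 6)
  f2 <- evolve_family(root, tr, rate = 1, seed = 6)
  expect_identical(f1, f2)
  expect_true(all(nchar(f1) == 100))
  expect_setequal(names(f1), c("a", "b", "c", "d"))
})

test_that("decoys carry exactly the specified edits", {
  s <- cgt_reference_seeds()$CLD3
  flip <- make_decoy(s, "AMYLASE_FLIP")
  diff <- which(cdmine:::seq_chars(flip$seq) != cdmine:::seq_chars(s$seq))
  expect_equal(diff, unname(s$slots[["csrV_center"]]))
  ko <- make_decoy(s, "TRIAD_KO")
  expect_equal(which(cdmine:::seq_chars(ko$seq) !=
                       cdmine:::seq_chars(s$seq)),
               unname(s$slots[["nucleophile"]]))
  tr <- make_decoy(s, "TRUNCATE")
  expect_lt(nchar(tr$seq), s$domain_spans$B[2])
  sh <- make_decoy(s, "SHUFFLE", seed = 9)
  expect_equal(sort(cdmine:::seq_chars(sh$seq)),
               sort(cdmine:::seq_chars(s$seq)))
})

test_that("the generator is byte-deterministic and truth-complete", {
  sim1 <- shared_sim()
  sim2 <- build_synthetic_genome(sim_config(seed = 1))
  expect_identical(sim1$contigs, sim2$contigs)
  expect_identical(sim1$genes, sim2$genes)
  expect_equal(nrow(sim1$genes), length(sim1$proteins))
  expect_equal(nrow(sim1$truth$proteins), nrow(sim1$genes))
  expect_length(sim1$truth$clusters, 1)
  expect_equal(sim1$truth$clusters[[1]]$n_genes, 30)
  # a different master seed changes the realization
  sim3 <- build_synthetic_genome(sim_config(seed = 2))
  expect_false(identical(sim1$contigs, sim3$contigs))
})

test_that("a clusterless configuration yields no cluster call", {
  sim <- build_synthetic_genome(sim_config(seed = 4, n_clusters = 0))
  expect_length(sim$truth$clusters, 0)
  gm <- synthetic_gene_models(sim)
  roles <- assign_roles(lapply(gm, `[[`, "protein"))
  sc <- find_cmcd_clusters(gm, roles)
  expect_length(sc$calls, 0)
})

test_that("written fixture files round-trip through the standard readers", {
  dir <- withr::local_tempdir()
  sim <- shared_sim()
  write_synthetic_genome(sim, dir)
  gm <- read_gff3(file.path(dir, "genes.gff3"),
                  file.path(dir, "genome.fna"))
  expect_length(gm, nrow(sim$genes))
  seqs <- vapply(gm, function(g) g$protein$seq, "")
  names(seqs) <- vapply(gm, `[[`, "", "gene_id")
  truth_seqs <- vapply(sim$proteins, `[[`, "", "seq")
  expect_identical(unname(seqs[names(truth_seqs)]), unname(truth_seqs))
  faa <- read_fasta(file.path(dir, "proteins.faa"))
  expect_length(faa, length(sim$proteins))
})
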