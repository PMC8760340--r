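# Gene-model scaffolding for cluster-logic tests: the detector consumes a
# role table, so cluster geometry can be exercised with placeholder
# proteins and hand-built roles.
toy_genes <- function(roles, contig = "c1", strand = NULL) {
  n <- length(roles)
  if (is.null(strand)) strand <- rep("+", n)
  lapply(seq_len(n), function(i)
    gene_model(sprintf("%s_g%02d", contig, i), contig,
               start = i * 1000L, end = i * 1000L + 300L,
               strand = strand[i],
               protein = protein_record(sprintf("%s_g%02d", contig, i),
                                        "MAG")))
}
toy_roles <- function(genes, roles) {
  data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"), role = roles)
}

core_order <- c("CGTASE", "MDXE", "MDXF", "MDXG", "CDASE", "GP")

test_that("a window with the complete core chain yields one call", {
  roles <- c("NONE", "NONE", core_order, "GA", "PGI", "NONE", "NONE")
  g <- toy_genes(roles)
  sc <- find_cmcd_clusters(g, toy_roles(g, roles))
  expect_length(sc$calls, 1)
  call <- sc$calls[[1]]
  expect_equal(call$n_genes, 8)          # trimmed to role-bearing genes
  expect_equal(call$gene_span, c(3L, 10L))
  expect_true(call$cassette_adjacent)
  expect_true(call$cgt_upstream)
  expect_equal(call$tier, "EXTENDED")
})

test_that("removing any single core role abolishes the call", {
  for (drop in core_order) {
    roles <- c("NONE", setdiff(core_order, drop), "GA", "PGI", "NONE")
    g <- toy_genes(roles)
    sc <- find_cmcd_clusters(g, toy_roles(g, roles))
    expect_length(sc$calls, 0)
  }
})

test_that("removing extended-only roles downgrades the tier but keeps the call", {
  roles <- c(core_order, "GA")     # one EMP-tier role only
  g <- toy_genes(roles)
  sc <- find_cmcd_clusters(g, toy_roles(g, roles))
  expect_length(sc$calls, 1)
  expect_equal(sc$calls[[1]]$tier, "CORE")
})

test_that("cassette adjacency requires one strand and tight spacing", {
  roles <- core_order
  g1 <- toy_genes(roles, strand = c("+", "+", "-", "+", "+", "+"))
  sc1 <- find_cmcd_clusters(g1, toy_roles(g1, roles))
  expect_false(sc1$calls[[1]]$cassette_adjacent)
  # two genes inserted into the cassette break adjacency
  roles2 <- c("CGTASE", "MDXE", "NONE", "NONE", "MDXF", "MDXG", "CDASE",
              "GP")
  g2 <- toy_genes(roles2)
  sc2 <- find_cmcd_clusters(g2, toy_roles(g2, roles2))
  expect_false(sc2$calls[[1]]$cassette_adjacent)
})

test_that("distant genes never affect a call and msmX is flagged distal", {
  roles <- c(core_order, rep("NONE", 45), "MSMX")
  g <- toy_genes(roles)
  sc <- find_cmcd_clusters(g, toy_roles(g, roles))
  expect_length(sc$calls, 1)
  expect_equal(sc$calls[[1]]$gene_span, c(1L, 6L))
  expect_true(sc$msmx$distal[1])
  # permuting genes beyond the window is a no-op for the call
  roles_p <- c(core_order, rep("NONE", 40), "MSMX", rep("NONE", 5))
  gp <- toy_genes(roles_p)
  scp <- find_cmcd_clusters(gp, toy_roles(gp, roles_p))
  expect_equal(scp$calls[[1]]$gene_span, sc$calls[[1]]$gene_span)
})

test_that("role assignment recovers exemplar roles and rejects noise", {
  ex <- cmcd_role_exemplars()
  probes <- list(
    protein_record("p_cgt", ex$cgtase_ex$seq),
    protein_record("p_mdxE", mutate_to_identity(ex$mdxE_ex$seq, 60,
                                                seed = 3,
                                                protect_positions = 1:25)),
    protein_record("p_shuf", cdmine:::with_seed(5, paste(
      sample(cdmine:::seq_chars(ex$gp_ex$seq)), collapse = ""))))
  roles <- assign_roles(probes)
  expect_equal(roles$role, c("CGTASE", "MDXE", "NONE"))
  expect_equal(roles$identity_pct[1], 100)
  expect_true(roles$lipobox_ok[2])
  expect_error(assign_roles(probes, exemplars = list()), "empty")
})

test_that("promoter scanning reports the planted box pair and spacer", {
  spacer17 <- strrep("GC", 9)
  spacer17 <- substr(spacer17, 1, 17)   # GC-rich spacer: no chance boxes
  w <- paste0(cdmine:::random_dna(80, seed = 31), "TGCACT",
              spacer17, "TAATAT",
              cdmine:::random_dna(60, seed = 33))
  hits <- scan_promoter(w)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$spacer[1], 17L)
  expect_equal(hits$pos_35[1], 81L)
  expect_equal(hits$pos_10[1], 104L)
  expect_equal(hits$spacer[1],
               hits$pos_10[1] - (hits$pos_35[1] + 6L))

  # second printed pair also detected
  w2 <- paste0(cdmine:::random_dna(80, seed = 34), "TTTCGA",
               spacer17, "CATATT",
               cdmine:::random_dna(60, seed = 36))
  expect_equal(scan_promoter(w2)$spacer[1], 17L)

  # boxes out of spacer range are not paired
  w3 <- paste0(cdmine:::random_dna(80, seed = 37), "TGCACT",
               cdmine:::random_dna(25, seed = 38), "TAATAT",
               cdmine:::random_dna(60, seed = 39))
  h3 <- scan_promoter(w3)
  expect_false(any(h3$pos_35 == 81 & h3$pos_10 == 112))

  expect_equal(nrow(scan_promoter("ACGTACGTACGT")), 0)
  # random windows rarely contain qualifying pairs
  n_hit <- sum(vapply(1:40, function(i)
    nrow(scan_promoter(cdmine:::random_dna(200, seed = 21000 + i))) > 0,
    NA))
  expect_lte(n_hit, 6)
})
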