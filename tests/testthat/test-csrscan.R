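seeds <- cgt_reference_seeds()

test_that("every packaged seed recovers its own annotation exactly", {
  for (s in seeds) {
    anc <- anchor_to_reference(s$seq)
    expect_equal(anc$ref$id, s$id)
    expect_equal(anc$nscore, 1, tolerance = 1e-9)
    rep <- map_csr(s$seq, anc)
    for (nm in names(s$csr_spans)) {
      hit <- rep$hits[rep$hits$csr == nm, ]
      expect_equal(c(hit$start, hit$end), unname(s$csr_spans[[nm]]),
                   info = paste(s$id, nm))
    }
    expect_equal(rep$nucleophile_pos, unname(s$slots[["nucleophile"]]))
    expect_equal(rep$glu_pos, unname(s$slots[["glu"]]))
    expect_equal(rep$asp2_pos, unname(s$slots[["asp2"]]))
    expect_equal(rep$h1_pos, unname(s$slots[["h1"]]))
    expect_true(rep$arg_minus2_ok)
    expect_true(rep$nucleophile_pos < rep$glu_pos)
    expect_true(rep$glu_pos < rep$asp2_pos)
  }
})

test_that("the three-domain seed carries the canonical precursor numbers", {
  rep <- map_csr(seeds$CLD3$seq, anchor_to_reference(seeds$CLD3$seq))
  expect_equal(rep$nucleophile_pos, 250L)
  expect_equal(rep$glu_pos, 279L)
  expect_equal(rep$asp2_pos, 351L)
  expect_equal(rep$h1_pos, 204L)
  expect_equal(rep$h1_res, "W")
  expect_equal(substr(seeds$CLD3$seq, 199, 205), "GSISNWN")
  expect_equal(rep$csrV_center_pos, 216L)
  expect_equal(rep$csrV_center_res, "F")
  expect_equal(rep$h2_pos, 281L)
  expect_equal(rep$h2_res, "M")
})

test_that("substitutions outside CSR spans never move reported positions", {
  s <- seeds$CLD3
  prot <- cdmine:::cgtase_protected_positions(s)
  for (t in c(90, 70, 50)) {
    m <- mutate_to_identity(s$seq, t, seed = 21, protect_positions = prot)
    anc <- anchor_to_reference(m)
    expect_equal(anc$ref$id, "CLD3")
    rep <- map_csr(m, anc)
    base <- map_csr(s$seq, anchor_to_reference(s$seq))
    expect_equal(rep$hits$start, base$hits$start, info = paste("target", t))
    expect_equal(rep$nucleophile_pos, 250L)
    expect_equal(rep$h1_pos, 204L)
  }
})

test_that("shuffled sequences do not anchor", {
  for (i in 1:5) {
    sh <- cdmine:::with_seed(1000 + i,
      paste(sample(cdmine:::seq_chars(seeds$CLD3$seq)), collapse = ""))
    expect_null(anchor_to_reference(sh))
  }
})

test_that("the decision table separates CGTases, amylases and other GH13", {
  s <- seeds$CLD3
  rep <- map_csr(s$seq, anchor_to_reference(s$seq))
  expect_equal(classify_enzyme(rep)$label, "CGTASE_LIKE")
  expect_gte(nrow(rep$hits[rep$hits$csr %in% c("I", "II", "III", "IV"), ]), 4)

  flip <- make_decoy(s, "AMYLASE_FLIP")
  rep_f <- map_csr(flip$seq, anchor_to_reference(flip$seq))
  expect_equal(classify_enzyme(rep_f)$label, "ALPHA_AMYLASE_LIKE")

  # reverting the single point mutation restores the call
  chars <- cdmine:::seq_chars(flip$seq)
  chars[s$slots[["csrV_center"]]] <- "F"
  back <- paste(chars, collapse = "")
  rep_b <- map_csr(back, anchor_to_reference(back))
  expect_equal(classify_enzyme(rep_b)$label, "CGTASE_LIKE")

  ko <- make_decoy(s, "TRIAD_KO")
  rep_k <- map_csr(ko$seq, anchor_to_reference(ko$seq))
  expect_equal(classify_enzyme(rep_k)$label, "GH13_OTHER")
})
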