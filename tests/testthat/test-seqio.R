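test_that("FASTA reading preserves order, validates alphabet and ids", {
  tf <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 first protein", "MKKLLVAC", ">p2", "ACDEFGHIKX"), tf)
  recs <- read_fasta(tf)
  expect_length(recs, 2)
  expect_equal(vapply(recs, `[[`, "", "id"), c("p1", "p2"))
  expect_equal(recs[[1]]$description, "first protein")
  expect_equal(recs[[2]]$seq, "ACDEFGHIKX")

  empty <- withr::local_tempfile(fileext = ".faa")
  file.create(empty)
  expect_length(read_fasta(empty), 0)

  bad <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MKJLL"), bad)
  expect_error(read_fasta(bad), "invalid residue")

  dup <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MKL", ">p1", "MKV"), dup)
  expect_error(read_fasta(dup), "duplicate")
})

test_that("FASTA round-trip reproduces sequences with wrapping normalized", {
  recs <- list(protein_record("a", strrep("ACDEFGHIKLMNPQRSTVWY", 8), "x y"),
               protein_record("b", "MG"))
  tf <- withr::local_tempfile(fileext = ".faa")
  write_fasta(recs, tf)
  back <- read_fasta(tf)
  expect_equal(lapply(back, `[[`, "seq"), lapply(recs, `[[`, "seq"))
  expect_equal(back[[1]]$description, "x y")
})

test_that("GFF3 CDS parsing translates both strands and checks geometry", {
  dir <- withr::local_tempdir()
  fwd <- "ATGGCTTGTTAA"                    # M A C *
  rev_prot <- "MGD"                        # on the minus strand
  rev_cds <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGGTGATTAA")))
  contig <- paste0("GGGG", fwd, "TT", rev_cds, "AAAA")
  writeLines(c(">c1", contig), file.path(dir, "g.fna"))
  gff <- c("##gff-version 3",
           sprintf("c1\tsrc\tCDS\t%d\t%d\t.\t+\t0\tID=g2", 19, 30),
           sprintf("c1\tsrc\tCDS\t%d\t%d\t.\t+\t0\tID=g1", 5, 16))
  gff[3] <- sub("\\+", "+", gff[3])
  writeLines(gff, file.path(dir, "g.gff3"))
  # fix g2 to minus strand
  lines <- readLines(file.path(dir, "g.gff3"))
  lines[2] <- sprintf("c1\tsrc\tCDS\t%d\t%d\t.\t-\t0\tID=g2", 19, 30)
  writeLines(lines, file.path(dir, "g.gff3"))
  gm <- read_gff3(file.path(dir, "g.gff3"), file.path(dir, "g.fna"))
  expect_length(gm, 2)
  # sorted by start: g1 first
  expect_equal(vapply(gm, `[[`, "", "gene_id"), c("g1", "g2"))
  expect_equal(gm[[1]]$protein$seq, "MAC")
  expect_equal(gm[[2]]$protein$seq, rev_prot)
  # translated length = (end - start + 1)/3 - 1
  for (g in gm)
    expect_equal(nchar(g$protein$seq), (g$end - g$start + 1) / 3 - 1)

  lines[2] <- "c1\tsrc\tCDS\t19\t29\t.\t-\t0\tID=g2"
  writeLines(lines, file.path(dir, "g.gff3"))
  expect_error(read_gff3(file.path(dir, "g.gff3"), file.path(dir, "g.fna")),
               "divisible by 3")
  lines[2] <- "c1\tsrc\tCDS\t19\t3000\t.\t-\t0\tID=g2"
  writeLines(lines, file.path(dir, "g.gff3"))
  expect_error(read_gff3(file.path(dir, "g.gff3"), file.path(dir, "g.fna")),
               "outside contig bounds")
  writeLines(lines[2:3], file.path(dir, "g.gff3"))
  expect_error(read_gff3(file.path(dir, "g.gff3"), file.path(dir, "g.fna")),
               "pragma")
})

test_that("physicochemistry matches hand-derived masses and charge curve", {
  expect_equal(compute_physchem("G")$mw_da, 75.07, tolerance = 1e-4)
  expect_equal(compute_physchem("GG")$mw_da, 132.12, tolerance = 1e-4)
  # appending one Gly adds exactly the Gly residue mass
  s <- "MKWVTFISLLFLFSSAYS"
  expect_equal(compute_physchem(paste0(s, "G"))$mw_da -
                 compute_physchem(s)$mw_da, 57.0519, tolerance = 1e-9)
  # all-acidic peptide: pI below 4, and bisection agrees with an
  # independent grid search of the charge curve
  pi_dddd <- compute_physchem("DDDD")$pi
  expect_lt(pi_dddd, 4)
  grid <- seq(0, 14, by = 1e-4)
  pi_oracle <- grid[which.min(abs(vapply(grid, function(ph)
    oracle_net_charge("DDDD", ph), 0)))]
  expect_equal(pi_dddd, pi_oracle, tolerance = 1e-3)
  expect_error(compute_physchem("MKX"), "X")
})
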