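test_that("gap filter removes gappy sequences and applies the length verdict", {
  seqs <- c(s1 = strrep("ACDEFGHIKL", 10),
            s2 = paste0(strrep("-", 30), strrep("A", 70)),  # 30% gaps
            s3 = paste0(strrep("?", 10), strrep("C", 90)),  # 10% unobserved
            s4 = strrep("KLMNPQRSTV", 10))
  tr <- parse_newick("((s1:0.1,s2:0.1):0.1,(s3:0.1,s4:0.1):0.1);")
  fam <- gene_family("f1", aa_alignment(seqs), tr)
  out <- gap_length_filter(fam)
  expect_setequal(rownames(out$alignment), c("s1", "s3", "s4"))
  expect_identical(out$verdict, "kept")
  expect_equal(out$log$sequence, "s2")
  expect_equal(out$log$reason, "gap_fraction")

  # exactly 50 columns: excluded (strictly more than 50 required)
  short <- gene_family("f2", aa_alignment(
    c(a = strrep("A", 50), b = strrep("C", 50), c = strrep("D", 50))),
    parse_newick("((a:1,b:1):1,c:1);"))
  expect_identical(gap_length_filter(short)$verdict, "excluded_too_short")
  ok51 <- gene_family("f3", aa_alignment(
    c(a = strrep("A", 51), b = strrep("C", 51), c = strrep("D", 51))),
    parse_newick("((a:1,b:1):1,c:1);"))
  expect_identical(gap_length_filter(ok51)$verdict, "kept")

  # gap-free family is untouched
  clean <- gene_family("f4", aa_alignment(
    c(a = strrep("AC", 50), b = strrep("DF", 50))),
    parse_newick("(a:1,b:1);"))
  out4 <- gap_length_filter(clean)
  expect_equal(nrow(out4$log), 0L)
  expect_equal(unclass(out4$alignment), unclass(clean$alignment))
})

test_that("one extreme branch is caught in pass 1, nothing more remains", {
  # 18 branches: 17 of length 0.1 plus one terminal 5.0
  # mean = 6.7/18 = 0.372, sample SD = 1.155, threshold = 2.68
  lens <- c(rep(0.1, 9), 5.0)
  names(lens) <- sprintf("s%d", 1:10)
  fam <- family_from_lengths(lens)
  all_lens <- fam$gene_tree$edge.length
  expect_equal(mean(all_lens), 0.3722, tolerance = 1e-3)
  expect_equal(sd(all_lens), 1.1549, tolerance = 1e-3)
  out <- long_branch_filter(fam)
  expect_equal(out$log$sequence, "s10")
  expect_equal(out$log$reason, "long_branch_pass1")
  expect_equal(out$log$pass, 1L)
  expect_false("s10" %in% out$gene_tree$tip.label)
})

test_that("equal branch lengths are never filtered (SD = 0)", {
  lens <- stats::setNames(rep(0.25, 8), sprintf("s%d", 1:8))
  fam <- family_from_lengths(lens, internal_length = 0.25)
  out <- long_branch_filter(fam)
  expect_equal(nrow(out$log), 0L)
  expect_setequal(out$gene_tree$tip.label, sprintf("s%d", 1:8))
})

test_that("the second pass removes outliers shielded by the first", {
  # terminals 0.1 except s9 = 3 and s10 = 50: pass 1's mean/SD are inflated
  # by the 50 (threshold ~ 26.5), shielding the 3; pass 2 catches it
  lens <- c(rep(0.1, 8), 3, 50)
  names(lens) <- sprintf("s%d", 1:10)
  fam <- family_from_lengths(lens)
  pass1_mean <- mean(fam$gene_tree$edge.length)
  pass1_sd <- sd(fam$gene_tree$edge.length)
  expect_gt(pass1_mean + 2 * pass1_sd, 3)   # 3 is shielded in pass 1
  out <- long_branch_filter(fam)
  expect_equal(out$log$sequence, c("s10", "s9"))
  expect_equal(out$log$pass, c(1L, 2L))
  # a single pass would have kept s9
  one_pass <- long_branch_filter(fam, n_passes = 1)
  expect_equal(one_pass$log$sequence, "s10")
})

test_that("long-branch filtering never removes a sub-mean terminal branch", {
  for (s in 1:5) {
    set.seed(s)
    lens <- stats::setNames(rexp(8, 2) + 0.01, sprintf("s%d", 1:8))
    fam <- family_from_lengths(lens)
    mu1 <- mean(fam$gene_tree$edge.length)
    out <- long_branch_filter(fam)
    expect_true(all(lens[out$log$sequence] > mu1))
  }
})

test_that("in-paralogues collapse to the shortest copy, out-paralogues exclude", {
  # taxon X has two copies forming a cherry: keep the shorter one
  tr <- parse_newick("(((X1:0.1,X2:0.3):0.1,A:0.2):0.1,(B:0.2,C:0.2):0.1);")
  seqs <- stats::setNames(rep(strrep("ACDEFGHIKL", 6), 5),
                          c("X1", "X2", "A", "B", "C"))
  fam <- gene_family("f", aa_alignment(seqs), tr,
                     taxon_of = c(X1 = "X", X2 = "X", A = "A", B = "B", C = "C"))
  out <- resolve_paralogs(fam)
  expect_identical(out$verdict, "kept")
  expect_false("X2" %in% rownames(out$alignment))
  expect_true("X1" %in% out$gene_tree$tip.label)
  expect_equal(out$log$reason, "paralog_pruned")

  # copies on opposite sides of the tree: whole family excluded
  tr2 <- parse_newick("(((X1:0.1,A:0.2):0.1,B:0.2):0.1,(X2:0.3,C:0.2):0.1);")
  fam2 <- gene_family("g", aa_alignment(seqs), tr2,
                      taxon_of = c(X1 = "X", X2 = "X", A = "A", B = "B", C = "C"))
  out2 <- resolve_paralogs(fam2)
  expect_identical(out2$verdict, "excluded_out_paralog")
  # excluded families keep their alignment untouched for the audit trail
  expect_equal(rownames(out2$alignment), rownames(fam2$alignment))

  # all single-copy: identity
  fam3 <- gene_family("h", aa_alignment(seqs[3:5]),
                      parse_newick("((A:0.2,B:0.2):0.1,C:0.2);"))
  out3 <- resolve_paralogs(fam3)
  expect_equal(nrow(out3$log), 0L)
})

test_that("filters are stable when re-applied to their own output", {
  lens <- c(rep(0.1, 8), 3, 50)
  names(lens) <- sprintf("s%d", 1:10)
  fam <- family_from_lengths(lens)
  fam$alignment <- aa_alignment(
    stats::setNames(rep(strrep("ACDEFGHIKL", 10), 10), sprintf("s%d", 1:10)))
  fam <- gene_family("f", fam$alignment, fam$gene_tree)
  once <- curate_family(fam)
  again_gap <- gap_length_filter(once)
  expect_equal(nrow(again_gap$log), nrow(once$log))
  again_par <- resolve_paralogs(once)
  expect_equal(nrow(again_par$log), nrow(once$log))
})

test_that("replaying the curation log reproduces the curated family", {
  lens <- c(rep(0.1, 8), 3, 50)
  names(lens) <- sprintf("s%d", 1:10)
  seqs <- stats::setNames(c(rep(strrep("ACDEFGHIKL", 10), 9),
                            paste0(strrep("-", 40), strrep("A", 60))),
                          sprintf("s%d", 1:10))
  # s1/s2 are two copies of one taxon forming the deepest cherry
  taxon_of <- stats::setNames(c("T1", "T1", sprintf("T%d", 2:9)),
                              sprintf("s%d", 1:10))
  fam <- family_from_lengths(lens, seqs = seqs, taxon_of = taxon_of)
  curated <- curate_family(fam)
  replayed <- replay_curation_log(fam, curated$log, curated$verdict)
  expect_equal(unclass(replayed$alignment), unclass(curated$alignment))
  expect_equal(write_newick(replayed$gene_tree), write_newick(curated$gene_tree))
  expect_identical(replayed$verdict, curated$verdict)
  # every removed sequence appears exactly once with one reason
  expect_false(anyDuplicated(curated$log$sequence) > 0)
})

test_that("gene families round-trip through their file formats", {
  dir <- withr::local_tempdir()
  seqs <- c(q1 = "ACDEFGHIKL", q2 = "ACDEF-HIKL", q3 = "ACDWFGHIKL")
  tr <- parse_newick("((q1:0.1,q2:0.2):0.05,q3:0.3);")
  aln_f <- file.path(dir, "fam.fasta")
  tree_f <- file.path(dir, "fam.nwk")
  map_f <- file.path(dir, "fam.tsv")
  write_alignment(aa_alignment(seqs), aln_f)
  write_newick(tr, tree_f)
  writeLines(c("q1\tTaxA", "q2\tTaxA", "q3\tTaxB"), map_f)
  fam <- read_gene_family("fam", aln_f, tree_f, map_f)
  expect_equal(unname(fam$taxon_of), c("TaxA", "TaxA", "TaxB"))
  out <- write_gene_family(fam, file.path(dir, "out"))
  expect_true(all(file.exists(out)))
  log <- utils::read.delim(out[3])
  expect_true("verdict" %in% names(log) || nrow(log) == 0L)
})
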