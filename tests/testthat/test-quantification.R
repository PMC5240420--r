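# shared toy setup: two unrelated matures, one nested pair, one precursor
toy_counting_ref <- function() {
  mature <- data.frame(
    gene_name = c("mirA", "mirB", "mirS", "mirL"),
    sequence = c("TGAGGTAGTAGGTTGTATAGTT", "CCTTCATTCCACCGGAGTCTGT",
                 "ACTGGACTTGGAGTCAGAAG", "ACTGGACTTGGAGTCAGAAGG"),
    stringsAsFactors = FALSE)
  prec <- data.frame(gene_name = "hpA", sequence = paste0(
    "GGCATCC", "TGAGGTAGTAGGTTGTATAGTT", "CATCTACTATCTTCTCTGTCTTGGC"),
    stringsAsFactors = FALSE)
  prec$mature_children <- I(list("mirA"))
  build_reference(mature, prec)
}

test_that("priority rules: perfect beats 1-mismatch, mature beats precursor", {
  ref <- toy_counting_ref()
  idx <- build_alignment_index(ref)

  # read = mirA with 1 mutation: perfect nowhere, 1mm on mirA only
  r_mm <- "TGAGGTAGTAGGTTGTATAGTA"
  # read perfect on mirB
  r_b <- "CCTTCATTCCACCGGAGTCTGT"
  # read from the unmasked precursor flank: precursor-exclusive
  r_hp <- substr(ref$targets$sequence[ref$targets$target_name == "hpA"],
                 30, 49)
  ur <- ur_table(c(r_b, r_mm, r_hp), mult = c(5L, 3L, 2L))
  hits <- align_reads(ur, idx)
  a <- assign_counts(ur, hits, ref)
  cnt <- setNames(a$counts$total, a$counts$target_name)
  mm <- setNames(a$counts$mismatch, a$counts$target_name)
  expect_equal(cnt[["mirB"]], 5)
  expect_equal(cnt[["mirA"]], 3)
  expect_equal(mm[["mirA"]], 3)     # counted via its 1-mismatch hit
  expect_equal(mm[["mirB"]], 0)
  expect_equal(cnt[["hpA"]], 2)     # exclusively-precursor read
  expect_equal(a$ambiguous, 0)
  # conservation
  expect_equal(sum(a$counts$total) + a$ambiguous + a$unmapped,
               sum(ur$multiplicity))
})

test_that("a read with perfect and 1-mismatch matches counts only to the perfect target", {
  # mirB read whose single mutation makes it 1mm from mirB; plant a decoy
  # target equal to the mutated read so it has a perfect hit there
  mutated <- "CCTTCATTCCACCGGAGTCTGA"
  mature <- data.frame(gene_name = c("mirB", "decoy"),
                       sequence = c("CCTTCATTCCACCGGAGTCTGT", mutated),
                       stringsAsFactors = FALSE)
  ref <- build_reference(mature,
                         data.frame(gene_name = character(0),
                                    sequence = character(0),
                                    mature_children = I(list()))[0, ])
  idx <- build_alignment_index(ref)
  ur <- ur_table(mutated, 7L)
  a <- assign_counts(ur, align_reads(ur, idx), ref)
  cnt <- setNames(a$counts$total, a$counts$target_name)
  expect_equal(cnt[["decoy"]], 7)
  expect_equal(cnt[["mirB"]], 0)
  expect_equal(sum(a$counts$mismatch), 0)
})

test_that("reads hitting two unrelated matures are ambiguous, not counted", {
  # two targets sharing a 20-nt core, read matches both perfectly
  core <- "ACCGTTAGACCGTTAGACCG"
  mature <- data.frame(gene_name = c("m1", "m2"),
                       sequence = c(paste0(core, "AA"), paste0(core, "CC")),
                       stringsAsFactors = FALSE)
  ref <- build_reference(mature,
                         data.frame(gene_name = character(0),
                                    sequence = character(0),
                                    mature_children = I(list()))[0, ])
  idx <- build_alignment_index(ref)
  ur <- ur_table(core, 4L)
  a <- assign_counts(ur, align_reads(ur, idx), ref)
  expect_equal(sum(a$counts$total), 0)
  expect_equal(a$ambiguous, 4)
  expect_equal(a$mapped_total, 4)
  expect_equal(sum(a$counts$total) + a$ambiguous + a$unmapped,
               sum(ur$multiplicity))
})

test_that("nested subtraction redistributes shared reads and conserves totals", {
  ref <- toy_counting_ref()
  idx <- build_alignment_index(ref)
  short_seq <- "ACTGGACTTGGAGTCAGAAG"
  long_seq <- "ACTGGACTTGGAGTCAGAAGG"
  # 10 reads of the short sequence (shared), 5 unique to the long
  ur <- ur_table(c(short_seq, long_seq), mult = c(10L, 5L))
  a <- assign_counts(ur, align_reads(ur, idx), ref)
  cnt0 <- setNames(a$counts$total, a$counts$target_name)
  expect_equal(cnt0[["mirL"]], 15)  # provisional: all toward the long
  expect_equal(cnt0[["mirS"]], 0)
  adj <- nested_subtraction(a)
  cnt <- setNames(adj$counts$total, adj$counts$target_name)
  expect_equal(cnt[["mirS"]], 10)   # total-to-long minus unique-to-long
  expect_equal(cnt[["mirL"]], 5)
  expect_equal(cnt[["mirS"]] + cnt[["mirL"]], 15)

  # boundary: no shared reads
  ur2 <- ur_table(long_seq, 5L)
  a2 <- nested_subtraction(assign_counts(ur2, align_reads(ur2, idx), ref))
  cnt2 <- setNames(a2$counts$total, a2$counts$target_name)
  expect_equal(cnt2[["mirS"]], 0)
  expect_equal(cnt2[["mirL"]], 5)

  # boundary: all reads shared
  ur3 <- ur_table(short_seq, 8L)
  a3 <- nested_subtraction(assign_counts(ur3, align_reads(ur3, idx), ref))
  cnt3 <- setNames(a3$counts$total, a3$counts$target_name)
  expect_equal(cnt3[["mirS"]], 8)
  expect_equal(cnt3[["mirL"]], 0)
})

test_that("count tables assemble, print, and round-trip through TSV", {
  ref <- toy_counting_ref()
  idx <- build_alignment_index(ref)
  mk <- function(seqs, mult) {
    ur <- ur_table(seqs, mult)
    nested_subtraction(assign_counts(ur, align_reads(ur, idx), ref))
  }
  a1 <- mk(c("TGAGGTAGTAGGTTGTATAGTT", "CCTTCATTCCACCGGAGTCTGT"),
           c(3L, 7L))
  a2 <- mk("CCTTCATTCCACCGGAGTCTGT", 10L)
  ct <- build_count_table(list(lib1 = a1, lib2 = a2), ref)
  expect_equal(dim(ct$total), c(5L, 2L))
  expect_equal(ct$total["mirB", ], c(lib1 = 7, lib2 = 10))
  expect_true(all(ct$mismatch <= ct$total))
  expect_true(all(colSums(ct$total) <= ct$mapped_total))

  p <- tempfile(fileext = ".tsv")
  write_count_table(ct, p)
  ct2 <- read_count_table(p)
  expect_equal(ct2$total, ct$total)
  expect_equal(ct2$mismatch, ct$mismatch)
  expect_equal(ct2$mapped_total, ct$mapped_total)
})

test_that("CPM and percent normalization have the right scale and invariances", {
  total <- matrix(c(50, 50, 30, 90), nrow = 2,
                  dimnames = list(c("A", "B"), c("l1", "l2")))
  ct <- structure(list(targets = data.frame(target_name = c("A", "B"),
                                            kind = "mature"),
                       member_genes = c("A", "B"),
                       libraries = c("l1", "l2"), total = total,
                       mismatch = total * 0,
                       mapped_total = c(l1 = 100, l2 = 120)),
                  class = "mirna_count_table")
  ab <- cpm_normalize(ct)
  expect_equal(ab$cpm[, "l1"], c(A = 5e5, B = 5e5))
  expect_equal(ab$percent[, "l1"], c(A = 50, B = 50))
  expect_equal(colSums(ab$cpm), c(l1 = 1e6, l2 = 1e6))
  expect_equal(colSums(ab$percent), c(l1 = 100, l2 = 100))
  # invariance under uniform scaling of a library
  ct2 <- ct; ct2$total[, "l1"] <- ct$total[, "l1"] * 13
  expect_equal(cpm_normalize(ct2)$cpm[, "l1"], ab$cpm[, "l1"])
  # single-target library: 1e6 CPM
  ct3 <- ct; ct3$total["B", ] <- 0
  expect_equal(cpm_normalize(ct3)$cpm["A", ], c(l1 = 1e6, l2 = 1e6))
  ct4 <- ct; ct4$total[, "l1"] <- 0
  expect_error(cpm_normalize(ct4), "zero-count")
})

test_that("highly-expressed filter uses a strict CPM threshold", {
  cpm <- matrix(c(101, 100, 99, 0, 100, 0), nrow = 3,
                dimnames = list(c("hi", "edge", "lo"), c("l1", "l2")))
  ab <- structure(list(cpm = cpm, percent = cpm / 1e4,
                       libraries = c("l1", "l2")),
                  class = "mirna_abundance")
  expect_equal(filter_highly_expressed(ab, 100, 1), "hi")
  # exactly at threshold everywhere: dropped (strict >)
  expect_false("edge" %in% filter_highly_expressed(ab, 100, 1))
  expect_equal(filter_highly_expressed(ab, 50, 2), "edge")
  expect_equal(filter_highly_expressed(ab, 50, 1), c("hi", "edge", "lo"))
})

test_that("pooling correlation is 1 when pooled equals the replicate mean", {
  set.seed(9)
  ind <- matrix(rpois(30, 200), nrow = 10,
                dimnames = list(sprintf("m%02d", 1:10), c("a", "b", "c")))
  pooled <- rowMeans(ind)
  pc <- pooling_correlation(ind, pooled, rownames(ind))
  expect_equal(pc$r_squared, 1)
  expect_lt(pc$p_value, 1e-6)
  expect_error(pooling_correlation(ind * 0 + 5, pooled, rownames(ind)),
               "constant")
})

test_that("zero-noise synthetic counts equal generator truth exactly", {
  cfg <- simulation_config(n_mature_genes = 60, n_shared_families = 3,
                           n_nested_pairs = 3, depth = 2e4,
                           error_rate = 0, other_rna_fraction = 0)
  exp <- generate_fcg_experiment(cfg, seed = 5)
  q <- quantify_experiment(exp)
  truth <- sapply(exp$libraries, function(l) l$truth_counts)
  common <- intersect(rownames(q$count_table$total), rownames(truth))
  expect_equal(length(common), nrow(q$count_table$total))
  expect_equal(q$count_table$total[common, ], truth[common, ],
               ignore_attr = FALSE)
  expect_true(all(q$per_library$ambiguous == 0))
})
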