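test_that("FASTA parsing converts U to T and links matures to hairpins", {
  mat <- write_tmp_fasta(c("syn-mir-1-5p" = "UGAGGUAG"))
  hp <- write_tmp_fasta(c("syn-mir-1" = "aaUGAGGUAGcc"))
  parsed <- parse_mirbase_fasta(mat, hp)
  expect_equal(parsed$matures$sequence, "TGAGGTAG")
  expect_equal(parsed$precursors$sequence, "AATGAGGTAGCC")
  expect_equal(parsed$precursors$mature_children[[1]], "syn-mir-1-5p")

  # empty inputs
  empty <- write_tmp_fasta(character(0))
  p0 <- parse_mirbase_fasta(empty, empty)
  expect_equal(nrow(p0$matures), 0L)
  expect_equal(nrow(p0$precursors), 0L)

  # duplicate names and malformed sequences are rejected
  dup <- write_tmp_fasta(c(a = "ACGU", a = "ACGU"))
  expect_error(parse_mirbase_fasta(dup, empty), "duplicate")
  bad <- write_tmp_fasta(c(x = "ACGX"))
  expect_error(parse_mirbase_fasta(bad, empty), "malformed")
})

test_that("explicit child map overrides the name convention", {
  mat <- write_tmp_fasta(c("mirA" = "UGAGGUAGUA"))
  hp <- write_tmp_fasta(c("hpB" = "CCUGAGGUAGUAGG"))
  p <- parse_mirbase_fasta(mat, hp)
  expect_length(p$precursors$mature_children[[1]], 0L)  # no name relation
  p2 <- parse_mirbase_fasta(mat, hp,
                            child_map = data.frame(mature = "mirA",
                                                   hairpin = "hpB"))
  expect_equal(p2$precursors$mature_children[[1]], "mirA")
})

test_that("collapsing groups identical matures and partitions all genes", {
  m <- data.frame(gene_name = c("g2", "g1", "g3"),
                  sequence = c("TGAGGTA", "TGAGGTA", "CCCTTTA"),
                  stringsAsFactors = FALSE)
  t <- collapse_identical_matures(m)
  expect_equal(nrow(t), 2L)
  shared <- t[t$sequence == "TGAGGTA", ]
  expect_equal(shared$target_name, "g1")  # byte-order-first member
  expect_setequal(shared$member_genes[[1]], c("g1", "g2"))
  expect_equal(sum(lengths(t$member_genes)), nrow(m))

  # all-distinct input: one singleton target per record
  m2 <- data.frame(gene_name = c("a", "b"),
                   sequence = c("AAAACCCC", "GGGGTTTT"),
                   stringsAsFactors = FALSE)
  t2 <- collapse_identical_matures(m2)
  expect_equal(nrow(t2), 2L)
  expect_true(all(lengths(t2$member_genes) == 1L))

  # idempotence: collapsing the collapsed targets changes nothing
  t3 <- collapse_identical_matures(
    data.frame(gene_name = t$target_name, sequence = t$sequence,
               stringsAsFactors = FALSE))
  expect_equal(t3$sequence, t$sequence)
})

test_that("masking replaces only a precursor's own matures, in place", {
  prec <- data.frame(gene_name = "hp1", sequence = "AATGAGGTACC",
                     stringsAsFactors = FALSE)
  prec$mature_children <- I(list("m1"))
  mat <- data.frame(gene_name = "m1", sequence = "TGAGGTA",
                    stringsAsFactors = FALSE)
  out <- mask_matures_in_precursors(prec, mat)
  expect_equal(out$sequence, "AANNNNNNNCC")
  expect_equal(nchar(out$sequence), nchar(prec$sequence))

  # precursor without children is untouched
  p0 <- prec; p0$mature_children <- I(list(character(0)))
  expect_equal(mask_matures_in_precursors(p0, mat)$sequence,
               prec$sequence)

  # both arms masked, loop left intact
  m2 <- data.frame(gene_name = c("m5", "m3"),
                   sequence = c("TGAGGTAGT", "CATCGTGCA"),
                   stringsAsFactors = FALSE)
  p2 <- data.frame(gene_name = "hp2",
                   sequence = paste0("GG", "TGAGGTAGT", "AAACCC",
                                     "CATCGTGCA", "TT"),
                   stringsAsFactors = FALSE)
  p2$mature_children <- I(list(c("m5", "m3")))
  out2 <- mask_matures_in_precursors(p2, m2)
  expect_equal(out2$sequence,
               paste0("GG", strrep("N", 9), "AAACCC", strrep("N", 9), "TT"))
  # no masked precursor still contains its child as plain ACGT substring
  expect_false(grepl("TGAGGTAGT", out2$sequence, fixed = TRUE))

  # child absent from the precursor: warning, left unmasked
  p3 <- data.frame(gene_name = "hp3", sequence = "AAAACCCCGGGG",
                   stringsAsFactors = FALSE)
  p3$mature_children <- I(list("m5"))
  expect_warning(out3 <- mask_matures_in_precursors(p3, m2), "not found")
  expect_equal(out3$sequence, p3$sequence)
})

test_that("nested-pair detection matches brute force and the 1-nt rule", {
  t <- collapse_identical_matures(data.frame(
    gene_name = c("a", "b", "c", "d"),
    sequence = c("TGAGGTAGT", "TGAGGTAGTA", "CCCTTTAAA", "TGAGGTAGTACC"),
    stringsAsFactors = FALSE))
  expect_warning(np <- detect_nested_pairs(t), "length difference >= 2")
  expect_equal(np$short_target, "a")
  expect_equal(np$long_target, "b")

  # no containment -> empty
  t2 <- collapse_identical_matures(data.frame(
    gene_name = c("a", "b"), sequence = c("TGAGGTAGT", "CCCTTTAAA"),
    stringsAsFactors = FALSE))
  expect_equal(nrow(detect_nested_pairs(t2)), 0L)

  # brute-force agreement on random targets with planted containments
  set.seed(11)
  for (rep in 1:5) {
    seqs <- unique(vapply(1:40, function(i) random_seq(sample(18:24, 1)),
                          character(1)))
    k <- sample(seq_along(seqs), 3)
    seqs <- c(seqs, paste0(seqs[k], "A"))   # some planted extensions
    seqs <- unique(seqs)
    tg <- data.frame(target_name = sprintf("t%02d", seq_along(seqs)),
                     sequence = seqs, stringsAsFactors = FALSE)
    got <- suppressWarnings(detect_nested_pairs(tg))
    # brute force over all ordered pairs
    want <- list()
    for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
      if (i != j && nchar(seqs[j]) - nchar(seqs[i]) == 1 &&
          grepl(seqs[i], seqs[j], fixed = TRUE))
        want[[length(want) + 1]] <- c(tg$target_name[i], tg$target_name[j])
    }
    want <- do.call(rbind, want)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$short_target, got$long_target),
                    paste(want[, 1], want[, 2]))
  }
})

test_that("build_reference composes and round-trips through FASTA+TSV", {
  mat <- write_tmp_fasta(c("syn-mir-1-5p" = "UGAGGUAGU",
                           "syn-mir-2-5p" = "UGAGGUAGU",
                           "syn-mir-3-5p" = "UGAGGUAGUA"))
  hp <- write_tmp_fasta(c("syn-mir-1" = "ccUGAGGUAGUaaa",
                          "syn-mir-2" = "ggUGAGGUAGUccc",
                          "syn-mir-3" = "aaUGAGGUAGUAcc"))
  ref <- build_reference(mature_fasta = mat, hairpin_fasta = hp)
  expect_equal(sum(ref$targets$kind == "mature"), 2L)
  expect_equal(sum(ref$targets$kind == "precursor"), 3L)
  expect_equal(nrow(ref$nested_pairs), 1L)
  expect_equal(ref$nested_pairs$short_target, "syn-mir-1-5p")
  # masked precursors contain N runs
  expect_true(all(grepl("N", ref$targets$sequence[ref$targets$kind ==
                                                    "precursor"])))
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_reference(ref, fa, tsv)
  ref2 <- read_reference(fa, tsv)
  expect_equal(ref2$targets$target_name, ref$targets$target_name)
  expect_equal(ref2$targets$sequence, ref$targets$sequence)
  expect_equal(ref2$nested_pairs, ref$nested_pairs)
  expect_equal(lapply(ref2$targets$member_genes, identity),
               lapply(ref$targets$member_genes, identity))
})

test_that("generated reference structure matches the generator's truth", {
  cfg <- simulation_config(n_mature_genes = 80, n_shared_families = 4,
                           shared_family_size = 3, n_nested_pairs = 5)
  sim <- generate_reference(cfg, seed = 3)
  ref <- build_reference(matures = sim$mature, precursors = sim$hairpin)
  # family registry
  multi <- ref$targets$member_genes[lengths(ref$targets$member_genes) > 1]
  expect_equal(length(multi), 4L)
  expect_setequal(vapply(multi, paste, character(1), collapse = ","),
                  vapply(sim$truth$families, function(f)
                    paste(sort(f, method = "radix"), collapse = ","),
                    character(1)))
  # nested registry
  expect_equal(nrow(ref$nested_pairs), 5L)
  expect_setequal(
    paste(ref$nested_pairs$short_target, ref$nested_pairs$long_target),
    paste(sim$truth$nested$short_target, sim$truth$nested$long_target))
  # collapse partition invariant
  mt <- ref$targets[ref$targets$kind == "mature", ]
  expect_equal(sum(lengths(mt$member_genes)), nrow(sim$mature))
})
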