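# Independent oracles and small fixture builders.

# Brute-force ungapped <=1-mismatch mapper: scans every target and every
# offset, computing Hamming distance directly (target N never matches).
# Completely independent of the seeded k-mer index implementation.
brute_force_align <- function(seq, targets) {
  L <- nchar(seq)
  r <- strsplit(seq, "")[[1]]
  out <- list()
  for (i in seq_len(nrow(targets))) {
    t <- strsplit(targets$sequence[i], "")[[1]]
    TL <- length(t)
    if (TL < L) next
    for (off in 0:(TL - L)) {
      w <- t[(off + 1):(off + L)]
      mm <- sum(w != r | w == "N")
      if (mm <= 1)
        out[[length(out) + 1]] <- data.frame(
          target_name = targets$target_name[i], offset = off,
          mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(target_name = character(0), offset = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$target_name, res$offset), , drop = FALSE]
}

# Exhaustive two-sided Wilcoxon rank-sum p-value by enumerating all
# choose(n, n_a) assignments of the pooled ranks to group a.
wilcoxon_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# minimal reference directly from target sequences (no precursors)
toy_reference <- function(seqs, kinds = rep("mature", length(seqs)),
                          names = sprintf("t%02d", seq_along(seqs)),
                          nested_pairs = NULL) {
  targets <- data.frame(target_name = names, sequence = seqs, kind = kinds,
                        stringsAsFactors = FALSE)
  targets$member_genes <- I(as.list(names))
  np <- if (is.null(nested_pairs))
    data.frame(short_target = character(0), long_target = character(0),
               stringsAsFactors = FALSE) else nested_pairs
  partner <- setNames(rep(NA_character_, nrow(targets)),
                      targets$target_name)
  partner[np$short_target] <- np$long_target
  partner[np$long_target] <- np$short_target
  targets$nested_partner <- unname(partner)
  structure(list(targets = targets, nested_pairs = np),
            class = "mirna_reference")
}

# collapsed-read table straight from sequences
ur_table <- function(seqs, mult = rep(1L, length(seqs))) {
  data.frame(sequence = seqs, multiplicity = as.integer(mult),
             stringsAsFactors = FALSE)
}

write_tmp_fasta <- function(named_seqs, path = tempfile(fileext = ".fa")) {
  lines <- if (length(named_seqs))
    paste0(">", names(named_seqs), "\n", unname(named_seqs))
  else character(0)
  writeLines(lines, path)
  path
}
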