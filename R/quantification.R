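#' Assign mapped reads to targets under the priority counting rules
#'
#' For each collapsed read (weighted by its multiplicity):
#' 1. if any perfect (0-mismatch) placement exists, all 1-mismatch
#'    placements are discarded;
#' 2. precursor placements are discarded when any mature placement remains,
#'    so precursor counts comprise reads mapping exclusively to precursors;
#' 3. if the remaining placements name a single target, the read counts
#'    there;
#' 4. if they name exactly the two members of a registered nested pair, the
#'    read counts toward the longer target's total and is flagged as shared
#'    (to be redistributed by [nested_subtraction()]);
#' 5. otherwise the read is ambiguous and counted toward no target.
#' Reads counted via a 1-mismatch placement also increment the mismatch
#' subcount.
#'
#' @param unique_reads data.frame from [collapse_reads()].
#' @param hits data.frame from [align_reads()].
#' @param ref The `mirna_reference` the hits refer to.
#' @return list with `counts` (data.frame `target_name`, `total`,
#'   `mismatch` over all reference targets), `shared` (per nested pair:
#'   `short_target`, `long_target`, `shared_total`, `shared_mismatch`),
#'   `ambiguous`, `unmapped`, `mapped_total` (all multiplicity-weighted).
#' @export
assign_counts <- function(unique_reads, hits, ref) {
  tn <- ref$targets$target_name
  if (!all(hits$target_name %in% tn))
    stop("hit references unknown target: ",
         setdiff(hits$target_name, tn)[1L])
  total <- setNames(numeric(length(tn)), tn)
  mism <- total
  np <- ref$nested_pairs
  pair_key <- if (nrow(np))
    paste(pmin(np$short_target, np$long_target),
          pmax(np$short_target, np$long_target)) else character(0)
  shared_total <- setNames(numeric(nrow(np)), pair_key)
  shared_mism <- shared_total
  ambiguous <- 0
  mapped_total <- 0

  ht <- data.table::as.data.table(hits)
  groups <- if (nrow(ht)) split(ht, by = "sequence") else list()
  mapped_seqs <- names(groups)
  for (g in groups) {
    mult <- g$multiplicity[1L]
    mapped_total <- mapped_total + mult
    if (any(g$mismatches == 0L)) g <- g[g$mismatches == 0L]
    if (any(g$target_kind == "mature")) g <- g[g$target_kind == "mature"]
    tu <- unique(g$target_name)
    via_mm <- min(g$mismatches)  # uniform after perfect-priority filter
    if (length(tu) == 1L) {
      total[tu] <- total[tu] + mult
      if (via_mm == 1L) mism[tu] <- mism[tu] + mult
    } else if (length(tu) == 2L &&
               paste(min(tu), max(tu)) %in% pair_key) {
      key <- paste(min(tu), max(tu))
      long <- np$long_target[match(key, pair_key)]
      total[long] <- total[long] + mult
      shared_total[key] <- shared_total[key] + mult
      if (via_mm == 1L) {
        mism[long] <- mism[long] + mult
        shared_mism[key] <- shared_mism[key] + mult
      }
    } else {
      ambiguous <- ambiguous + mult
    }
  }
  unmapped <- sum(unique_reads$multiplicity) - mapped_total

  shared <- np
  if (nrow(np)) {
    shared$shared_total <- unname(shared_total[pair_key])
    shared$shared_mismatch <- unname(shared_mism[pair_key])
  } else {
    shared <- data.frame(short_target = character(0),
                         long_target = character(0),
                         shared_total = numeric(0),
                         shared_mismatch = numeric(0))
  }
  list(counts = data.frame(target_name = tn, total = unname(total),
                           mismatch = unname(mism),
                           stringsAsFactors = FALSE),
       shared = shared, ambiguous = ambiguous, unmapped = unmapped,
       mapped_total = mapped_total)
}

#' Redistribute nested-pair counts by the subtraction rule
#'
#' For each registered nested pair, reads of the shorter sequence map to
#' both members and were provisionally counted toward the longer target.
#' The shorter target's count is the total mapping to the longer target
#' minus the reads mapping uniquely to it; the longer target keeps its
#' unique mappings. Pair totals are conserved.
#'
#' @param assignment Result of [assign_counts()].
#' @return The assignment with `counts` adjusted (shared totals moved to
#'   the short member, mismatch subcounts treated identically).
#' @export
nested_subtraction <- function(assignment) {
  counts <- assignment$counts
  sh <- assignment$shared
  rownames(counts) <- counts$target_name
  for (i in seq_len(nrow(sh))) {
    s <- sh$short_target[i]; l <- sh$long_target[i]
    unique_long <- counts[l, "total"] - sh$shared_total[i]
    if (unique_long < 0)
      stop("nested subtraction produced a negative count for ", l,
           " (accounting bug)")
    counts[s, "total"] <- counts[s, "total"] + sh$shared_total[i]
    counts[l, "total"] <- unique_long
    mm_unique <- counts[l, "mismatch"] - sh$shared_mismatch[i]
    if (mm_unique < 0)
      stop("nested subtraction produced a negative mismatch count for ", l)
    counts[s, "mismatch"] <- counts[s, "mismatch"] + sh$shared_mismatch[i]
    counts[l, "mismatch"] <- mm_unique
  }
  rownames(counts) <- NULL
  assignment$counts <- counts
  assignment
}

#' Build a multi-library count table
#'
#' @param assignments Named list (by library label) of
#'   [nested_subtraction()] / [assign_counts()] results.
#' @param ref The shared `mirna_reference`.
#' @return Object of class `mirna_count_table`: list with `targets`
#'   (reference target metadata), `libraries`, `total` and `mismatch`
#'   (targets x libraries matrices), `mapped_total`, `ambiguous`,
#'   `unmapped` (per-library vectors).
#' @export
build_count_table <- function(assignments, ref) {
  stopifnot(length(assignments) >= 1L, !is.null(names(assignments)))
  tn <- ref$targets$target_name
  libs <- names(assignments)
  total <- matrix(0, length(tn), length(libs),
                  dimnames = list(tn, libs))
  mism <- total
  mt <- setNames(numeric(length(libs)), libs)
  amb <- mt; unm <- mt
  for (lib in libs) {
    a <- assignments[[lib]]
    idx <- match(a$counts$target_name, tn)
    if (anyNA(idx)) stop("library ", lib, " counts unknown targets")
    total[idx, lib] <- a$counts$total
    mism[idx, lib] <- a$counts$mismatch
    mt[lib] <- a$mapped_total
    amb[lib] <- a$ambiguous
    unm[lib] <- a$unmapped
  }
  structure(list(targets = ref$targets[, c("target_name", "kind")],
                 member_genes = vapply(ref$targets$member_genes, paste,
                                       character(1), collapse = ","),
                 libraries = libs, total = total, mismatch = mism,
                 mapped_total = mt, ambiguous = amb, unmapped = unm),
            class = "mirna_count_table")
}

#' @export
print.mirna_count_table <- function(x, ...) {
  cat("mirna_count_table:", nrow(x$total), "targets x",
      ncol(x$total), "libraries;",
      format(sum(x$total), big.mark = ","), "assigned reads\n")
  invisible(x)
}

#' Write / read a count table as TSV
#'
#' Columns: `target`, `kind`, `member_genes`, then `<lib>_total` and
#' `<lib>_mismatch` per library; a trailing `#mapped_total` comment row
#' carries per-library mapped totals so the table round-trips losslessly.
#'
#' @param ct A `mirna_count_table`.
#' @param path TSV file path.
#' @export
write_count_table <- function(ct, path) {
  df <- data.frame(target = rownames(ct$total), kind = ct$targets$kind,
                   member_genes = ct$member_genes,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (lib in ct$libraries) {
    df[[paste0(lib, "_total")]] <- ct$total[, lib]
    df[[paste0(lib, "_mismatch")]] <- ct$mismatch[, lib]
  }
  foot <- data.frame(target = "#mapped_total", kind = "", member_genes = "",
                     stringsAsFactors = FALSE)
  for (lib in ct$libraries) {
    foot[[paste0(lib, "_total")]] <- ct$mapped_total[lib]
    foot[[paste0(lib, "_mismatch")]] <- ct$ambiguous[lib]
  }
  utils::write.table(rbind(df, foot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  foot <- df$target == "#mapped_total"
  meta <- df[foot, , drop = FALSE]
  df <- df[!foot, , drop = FALSE]
  libs <- sub("_total$", "", grep("_total$", names(df), value = TRUE))
  total <- as.matrix(df[, paste0(libs, "_total"), drop = FALSE])
  mism <- as.matrix(df[, paste0(libs, "_mismatch"), drop = FALSE])
  dimnames(total) <- dimnames(mism) <- list(df$target, libs)
  mt <- setNames(as.numeric(meta[1L, paste0(libs, "_total")]), libs)
  amb <- setNames(as.numeric(meta[1L, paste0(libs, "_mismatch")]), libs)
  structure(list(targets = data.frame(target_name = df$target,
                                      kind = df$kind,
                                      stringsAsFactors = FALSE),
                 member_genes = df$member_genes, libraries = libs,
                 total = total, mismatch = mism, mapped_total = mt,
                 ambiguous = amb,
                 unmapped = setNames(rep(NA_real_, length(libs)), libs)),
            class = "mirna_count_table")
}

#' Counts-per-million and percent-abundance normalization
#'
#' Each library is scaled by its total counted miRNA reads (the sum of
#' per-target assigned counts, not the raw read number), giving counts per
#' million and percent abundance.
#'
#' @param ct A `mirna_count_table`.
#' @return Object of class `mirna_abundance`: list with `cpm` and
#'   `percent` matrices (targets x libraries), plus target metadata.
#' @export
cpm_normalize <- function(ct) {
  denom <- colSums(ct$total)
  if (any(denom == 0))
    stop("zero-count library: ", paste(ct$libraries[denom == 0],
                                       collapse = ", "))
  cpm <- sweep(ct$total, 2L, denom, "/") * 1e6
  pct <- sweep(ct$total, 2L, denom, "/") * 100
  structure(list(targets = ct$targets, libraries = ct$libraries,
                 cpm = cpm, percent = pct),
            class = "mirna_abundance")
}

#' Highly expressed target subset
#'
#' Targets whose expression exceeds `threshold` counts per million
#' (strictly) in at least `min_libraries` libraries.
#'
#' @param abundance A `mirna_abundance`.
#' @param threshold CPM threshold (default 100).
#' @param min_libraries Minimum number of libraries above threshold.
#' @return Character vector of target names.
#' @export
filter_highly_expressed <- function(abundance, threshold = 100,
                                    min_libraries = 1L) {
  n_over <- rowSums(abundance$cpm > threshold)
  rownames(abundance$cpm)[n_over >= min_libraries]
}

#' Pooling feasibility: correlation of individual-library means with a
#' pooled library
#'
#' Pearson product-moment correlation between the per-target mean count of
#' individually sequenced replicate libraries and the counts of the pooled
#' library built from the same samples, over a given target subset.
#'
#' @param individual_counts Matrix (targets x replicate libraries) of
#'   counts, rownames = target names.
#' @param pooled_counts Named numeric vector of pooled-library counts.
#' @param subset Character vector of target names to correlate over.
#' @return list with `r_squared`, `r`, `p_value`, `n`.
#' @export
pooling_correlation <- function(individual_counts, pooled_counts, subset) {
  stopifnot(ncol(individual_counts) >= 2L)
  subset <- intersect(subset, rownames(individual_counts))
  subset <- intersect(subset, names(pooled_counts))
  x <- rowMeans(individual_counts[subset, , drop = FALSE])
  y <- pooled_counts[subset]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("pooling_correlation: constant vector")
  ct <- cor.test(x, y, method = "pearson")
  list(r_squared = unname(ct$estimate^2), r = unname(ct$estimate),
       p_value = ct$p.value, n = length(subset))
}
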