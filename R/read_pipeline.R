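#' Read a FASTQ file into a raw-read table
#'
#' Standard 4-line FASTQ (Sanger Phred+33 qualities assumed but not
#' interpreted); gzip-transparent. An optional `barcode` is taken from a
#' trailing `#<index>` or `:<index>` token in the read id when present.
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with `read_id`, `sequence`, `qualities`, `barcode`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      qualities = character(0), barcode = character(0),
                      stringsAsFactors = FALSE))
  id <- sub("^@", "", lines[seq(1L, by = 4L, length.out = n)])
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(nchar(seq) != nchar(qual)))
    stop("malformed FASTQ (sequence/quality length mismatch): ", path)
  bc <- rep(NA_character_, n)
  m <- regmatches(id, regexpr("[#:]([ACGTN]+)$", id))
  has <- grepl("[#:]([ACGTN]+)$", id)
  bc[has] <- sub("^[#:]", "", m)
  data.frame(read_id = id, sequence = seq, qualities = qual, barcode = bc,
             stringsAsFactors = FALSE)
}

#' Read an Illumina qseq file into a raw-read table
#'
#' Tab-separated 11-column Illumina qseq dialect (machine, run, lane, tile,
#' x, y, index, read number, sequence, quality, filter flag). Uncalled
#' bases `.` are converted to `N`; the index column provides the barcode.
#'
#' @param path qseq file (optionally gzipped).
#' @return data.frame with `read_id`, `sequence`, `qualities`, `barcode`.
#' @export
read_qseq <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(x) == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      qualities = character(0), barcode = character(0),
                      stringsAsFactors = FALSE))
  if (ncol(x) != 11L)
    stop("malformed qseq (expected 11 columns, got ", ncol(x), "): ", path)
  seq <- chartr(".", "N", toupper(x[[9]]))
  id <- do.call(paste, c(x[1:6], sep = ":"))
  bc <- chartr(".", "N", toupper(x[[7]]))
  bc[!nzchar(bc)] <- NA_character_
  data.frame(read_id = id, sequence = seq, qualities = x[[10]],
             barcode = bc, stringsAsFactors = FALSE)
}

#' Demultiplex reads by exact barcode match
#'
#' A read is assigned to a library if and only if its barcode equals that
#' library's index exactly; all other reads (including one-mismatch
#' barcodes and missing barcodes) are unassigned.
#'
#' @param reads Raw-read data.frame with a `barcode` column.
#' @param barcode_map Named character vector, `index -> library label`.
#' @return list with `libraries` (named list of read data.frames, one per
#'   library) and `unassigned` (count).
#' @export
demultiplex <- function(reads, barcode_map) {
  if (anyDuplicated(names(barcode_map)))
    stop("duplicate index in barcode map")
  if (length(unique(nchar(names(barcode_map)))) > 1L)
    stop("barcodes in map must all have equal length")
  libs <- setNames(vector("list", length(barcode_map)),
                   unname(barcode_map))
  assigned <- match(reads$barcode, names(barcode_map))
  for (i in seq_along(barcode_map)) {
    libs[[unname(barcode_map)[i]]] <-
      reads[!is.na(assigned) & assigned == i, , drop = FALSE]
  }
  list(libraries = libs, unassigned = sum(is.na(assigned)))
}

#' Clip the 3' sequencing adapter from reads
#'
#' Truncates each read at the leftmost position where either a full
#' occurrence of the adapter begins or a prefix of the adapter of length
#' at least `min_overlap` runs exactly to the end of the read. Reads with
#' no such match are returned unchanged (the length filter then removes
#' untrimmed full-length reads).
#'
#' @param sequences Character vector of read sequences.
#' @param adapter 3' adapter sequence (default: Illumina TruSeq small-RNA).
#' @param min_overlap Minimum adapter-prefix overlap at the read end.
#' @return Character vector of trimmed sequences.
#' @export
trim_adapter <- function(sequences,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         min_overlap = 3L) {
  stopifnot(nzchar(adapter), min_overlap >= 1L)
  n <- length(sequences)
  if (n == 0L) return(sequences)
  len <- nchar(sequences)
  cut <- rep(NA_integer_, n)   # number of bases kept
  full <- regexpr(adapter, sequences, fixed = TRUE)
  cut[full > 0L] <- full[full > 0L] - 1L
  klim <- min(nchar(adapter) - 1L, max(len))
  if (klim >= min_overlap) {
    for (k in seq(klim, min_overlap)) {    # descending: longest overlap first
      pref <- substr(adapter, 1L, k)
      m <- endsWith(sequences, pref) & len >= k
      if (any(m)) {
        cand <- len[m] - k
        cur <- cut[m]
        cut[m] <- ifelse(is.na(cur), cand, pmin(cur, cand))
      }
    }
  }
  keep <- is.na(cut)
  out <- sequences
  out[!keep] <- substr(sequences[!keep], 1L, cut[!keep])
  out
}

#' Retain reads within the small-RNA length window
#'
#' @param sequences Character vector of trimmed read sequences.
#' @param min_len,max_len Inclusive length bounds (defaults 18 and 30 nt).
#' @return The subset of `sequences` with lengths in `[min_len, max_len]`.
#' @export
length_filter <- function(sequences, min_len = 18L, max_len = 30L) {
  len <- nchar(sequences)
  sequences[len >= min_len & len <= max_len]
}

#' Collapse identical reads
#'
#' @param sequences Character vector of filtered read sequences.
#' @return data.frame with `sequence` and `multiplicity` (number of
#'   identical raw reads), ordered by decreasing multiplicity then
#'   sequence; multiplicities sum to `length(sequences)`.
#' @export
collapse_reads <- function(sequences) {
  if (!length(sequences))
    return(data.frame(sequence = character(0), multiplicity = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab),
                    multiplicity = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$multiplicity, out$sequence, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write collapsed reads as FASTA with multiplicity-encoding headers
#'
#' Headers follow the `>seq<i>_x<multiplicity>` convention used by the
#' mirDeep collapse script.
#'
#' @param unique_reads data.frame from [collapse_reads()].
#' @param path Output FASTA path.
#' @export
write_collapsed_fasta <- function(unique_reads, path) {
  hdr <- paste0(">seq", seq_len(nrow(unique_reads)), "_x",
                unique_reads$multiplicity)
  writeLines(paste0(hdr, "\n", unique_reads$sequence), path)
  invisible(path)
}

#' Read a collapsed-read FASTA back into a table
#' @param path FASTA with `>seq<i>_x<multiplicity>` headers.
#' @return data.frame with `sequence`, `multiplicity`.
#' @export
read_collapsed_fasta <- function(path) {
  x <- read_fasta_dna(path)
  data.frame(sequence = x$sequence,
             multiplicity = as.integer(sub("^.*_x", "", x$gene_name)),
             stringsAsFactors = FALSE)
}

# ---- mapping ---------------------------------------------------------------

RAW_N <- as.raw(78L)  # 'N'

#' Build a k-mer seed index over reference targets
#'
#' Indexes every k-mer of every target for pigeonhole-seeded one-mismatch
#' mapping: a read with at most one mismatch has one exact half, so either
#' its first or its last k bases occur exactly in the target. k defaults to
#' 9, half the minimum read length of 18 nt.
#'
#' @param ref A `mirna_reference`.
#' @param k Seed length; must satisfy `k <= floor(min_read_len / 2)`.
#' @return An object of class `mirna_index`.
#' @export
build_alignment_index <- function(ref, k = 9L) {
  t <- ref$targets
  n <- nrow(t)
  env <- new.env(parent = emptyenv(), size = max(64L, 4L * n))
  for (i in seq_len(n)) {
    s <- t$sequence[i]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    for (p in seq_along(kmers)) {
      km <- kmers[p]
      hit <- env[[km]]
      env[[km]] <- if (is.null(hit)) c(i, starts[p]) else c(hit, i, starts[p])
    }
  }
  structure(list(env = env, k = k,
                 target_name = t$target_name,
                 target_kind = t$kind,
                 target_len = nchar(t$sequence),
                 target_raw = lapply(t$sequence, charToRaw)),
            class = "mirna_index")
}

#' Map a read to the reference with at most one mismatch, ungapped
#'
#' Reports every end-to-end placement of the read within a target at
#' Hamming distance 0 or 1. A masked (`N`) target base never matches any
#' read base, so reads overlapping two or more masked positions cannot hit.
#' Candidate placements come from exact seed lookups of the read's first
#' and last k bases (pigeonhole over the two read halves guarantees
#' completeness at one mismatch); each candidate is verified by full
#' Hamming comparison.
#'
#' @param seq Read sequence (18-30 nt).
#' @param index A `mirna_index` from [build_alignment_index()].
#' @return data.frame of hits: `target_name`, `offset` (0-based), and
#'   `mismatches` (0 or 1); zero rows when unmapped.
#' @export
align_read <- function(seq, index) {
  h <- align_read_internal(seq, index)
  data.frame(target_name = index$target_name[h[["tgt"]]],
             offset = h[["off"]], mismatches = h[["mm"]],
             stringsAsFactors = FALSE)
}

# returns list(tgt = integer target index, off = 0-based offset, mm)
align_read_internal <- function(seq, index) {
  k <- index$k
  L <- nchar(seq)
  env <- index$env
  none <- list(tgt = integer(0), off = integer(0), mm = integer(0))
  if (L < 2L * k) stop("read shorter than 2k; rebuild index with smaller k")
  c1 <- env[[substr(seq, 1L, k)]]
  c2 <- env[[substr(seq, L - k + 1L, L)]]
  nc <- (if (is.null(c1)) 0L else length(c1) %/% 2L) +
        (if (is.null(c2)) 0L else length(c2) %/% 2L)
  if (nc == 0L) return(none)
  tgt <- integer(nc); off <- integer(nc)   # off: 1-based start in target
  j <- 0L
  if (!is.null(c1)) {
    m <- length(c1) %/% 2L
    idx <- seq_len(m) * 2L
    tgt[seq_len(m)] <- c1[idx - 1L]
    off[seq_len(m)] <- c1[idx]
    j <- m
  }
  if (!is.null(c2)) {
    m <- length(c2) %/% 2L
    idx <- seq_len(m) * 2L
    tgt[j + seq_len(m)] <- c2[idx - 1L]
    off[j + seq_len(m)] <- c2[idx] - (L - k)
    j <- j + m
  }
  ok <- off >= 1L & off + L - 1L <= index$target_len[tgt]
  tgt <- tgt[ok]; off <- off[ok]
  if (!length(tgt)) return(none)
  dup <- duplicated(tgt * 1e6 + off)
  tgt <- tgt[!dup]; off <- off[!dup]
  r <- charToRaw(seq)
  mm <- integer(length(tgt))
  keep <- logical(length(tgt))
  for (i in seq_along(tgt)) {
    w <- index$target_raw[[tgt[i]]][off[i]:(off[i] + L - 1L)]
    d <- sum(w != r | w == RAW_N)
    if (d <= 1L) { keep[i] <- TRUE; mm[i] <- d }
  }
  o <- order(tgt[keep], off[keep])
  list(tgt = tgt[keep][o], off = off[keep][o] - 1L, mm = mm[keep][o])
}

#' Map a table of collapsed reads
#'
#' @param unique_reads data.frame from [collapse_reads()].
#' @param index A `mirna_index`.
#' @return data.frame of hits with `sequence`, `multiplicity`,
#'   `target_name`, `offset`, `mismatches` (one row per placement; reads
#'   with no placement are absent).
#' @export
align_reads <- function(unique_reads, index) {
  n <- nrow(unique_reads)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    h <- align_read_internal(unique_reads$sequence[i], index)
    if (length(h$tgt))
      res[[i]] <- data.table(sequence = unique_reads$sequence[i],
                             multiplicity = unique_reads$multiplicity[i],
                             target_name = index$target_name[h$tgt],
                             target_kind = index$target_kind[h$tgt],
                             offset = h$off, mismatches = h$mm)
  }
  out <- rbindlist(res)
  if (!nrow(out))
    out <- data.table(sequence = character(0), multiplicity = integer(0),
                      target_name = character(0), target_kind = character(0),
                      offset = integer(0), mismatches = integer(0))
  as.data.frame(out)
}

#' Multiplicity-weighted mapping rate
#'
#' @param unique_reads data.frame from [collapse_reads()].
#' @param hits data.frame from [align_reads()].
#' @return Fraction in `[0, 1]` of reads (weighted by multiplicity) with at
#'   least one hit.
#' @export
mapping_rate <- function(unique_reads, hits) {
  tot <- sum(unique_reads$multiplicity)
  if (tot == 0L) stop("mapping_rate: zero reads")
  mapped <- unique_reads$sequence %in% unique(hits$sequence)
  sum(unique_reads$multiplicity[mapped]) / tot
}
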