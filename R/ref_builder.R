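#' @importFrom data.table data.table setDT setkey := .N .SD rbindlist fread fwrite
#' @importFrom stats prcomp median rmultinom rlnorm runif binom.test wilcox.test cor.test setNames
#' @importFrom utils head packageVersion
NULL

# Sort helper: byte-order (C locale) so collapsed-group naming is
# platform-independent.
sort_c <- function(x) sort(x, method = "radix")

#' Parse miRBase-style mature and hairpin FASTA files
#'
#' Reads mature and precursor (hairpin) miRNA sequences, converts the RNA
#' alphabet to DNA (U to T), and resolves which mature sequences are excised
#' from which hairpin. miRBase FASTA headers do not encode the mature/hairpin
#' relation explicitly, so the relation is derived from the naming convention
#' in which a mature name extends its hairpin name (e.g. `mir-1-5p` from
#' hairpin `mir-1`), case-insensitively; an explicit two-column mapping can
#' override this.
#'
#' @param mature_fasta Path to the mature miRNA FASTA (sequences may use U).
#' @param hairpin_fasta Path to the hairpin (precursor) FASTA.
#' @param child_map Optional data.frame (or path to a two-column TSV) with
#'   columns `mature` and `hairpin` giving explicit mature-to-hairpin
#'   assignments that override the name convention.
#' @return A list with elements `matures` (data.frame: `gene_name`,
#'   `sequence`) and `precursors` (data.frame: `gene_name`, `sequence`, and
#'   list-column `mature_children` of mature gene names).
#' @export
parse_mirbase_fasta <- function(mature_fasta, hairpin_fasta, child_map = NULL) {
  matures <- read_fasta_dna(mature_fasta)
  precursors <- read_fasta_dna(hairpin_fasta)
  if (anyDuplicated(matures$gene_name))
    stop("duplicate mature gene_name: ",
         matures$gene_name[duplicated(matures$gene_name)][1L])
  if (anyDuplicated(precursors$gene_name))
    stop("duplicate hairpin gene_name: ",
         precursors$gene_name[duplicated(precursors$gene_name)][1L])

  children <- resolve_children(matures$gene_name, precursors$gene_name,
                               child_map)
  precursors$mature_children <- children[precursors$gene_name]
  list(matures = matures, precursors = precursors)
}

# FASTA -> data.frame(gene_name, sequence) with U->T and upper-casing.
# First whitespace-delimited token of the header is the gene name.
read_fasta_dna <- function(path) {
  if (file.exists(path) && isTRUE(file.size(path) == 0))
    return(data.frame(gene_name = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  nm <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("malformed FASTA record (non-ACGTUN characters) in ", path, ": ",
         nm[bad][1L])
  if (any(!nzchar(seqs)))
    stop("empty sequence in ", path, ": ", nm[!nzchar(seqs)][1L])
  data.frame(gene_name = nm, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

# mature -> hairpin by name-extension convention, with optional explicit map.
# Returns a list keyed by hairpin name, each element a character vector of
# mature children (possibly empty).
resolve_children <- function(mature_names, hairpin_names, child_map = NULL) {
  children <- setNames(vector("list", length(hairpin_names)), hairpin_names)
  for (h in hairpin_names) children[[h]] <- character(0)

  explicit <- character(0)
  if (!is.null(child_map)) {
    if (is.character(child_map) && length(child_map) == 1L)
      child_map <- utils::read.delim(child_map, header = TRUE,
                                     stringsAsFactors = FALSE)
    stopifnot(all(c("mature", "hairpin") %in% names(child_map)))
    for (i in seq_len(nrow(child_map))) {
      h <- child_map$hairpin[i]
      if (!h %in% hairpin_names)
        stop("child map references unknown hairpin: ", h)
      children[[h]] <- c(children[[h]], child_map$mature[i])
    }
    explicit <- child_map$mature
  }

  lo_h <- tolower(hairpin_names)
  lo_m <- tolower(mature_names)
  for (i in seq_along(mature_names)) {
    if (mature_names[i] %in% explicit) next
    hit <- lo_h == lo_m[i] | startsWith(lo_m[i], paste0(lo_h, "-"))
    if (any(hit)) {
      # prefer the longest matching hairpin name (most specific)
      j <- which(hit)[which.max(nchar(hairpin_names[hit]))]
      children[[j]] <- c(children[[j]], mature_names[i])
    }
  }
  children
}

#' Collapse identical mature sequences into single reference targets
#'
#' Several miRNA genes can give rise to the same mature sequence; reads
#' cannot distinguish them, so each distinct mature sequence becomes one
#' reference target. The target is named after the byte-order-first member
#' gene and all member genes are recorded.
#'
#' @param matures data.frame with `gene_name` and `sequence` (DNA alphabet).
#' @return data.frame with `target_name`, `sequence`, `kind` ("mature") and
#'   list-column `member_genes`.
#' @export
collapse_identical_matures <- function(matures) {
  if (nrow(matures) == 0L)
    return(data.frame(target_name = character(0), sequence = character(0),
                      kind = character(0),
                      member_genes = I(list()), stringsAsFactors = FALSE))
  groups <- split(matures$gene_name, matures$sequence)
  groups <- lapply(groups, sort_c)
  target_name <- vapply(groups, `[`, character(1), 1L)
  out <- data.frame(target_name = unname(target_name),
                    sequence = names(groups),
                    kind = "mature",
                    stringsAsFactors = FALSE)
  out$member_genes <- I(unname(groups))
  # stable order: by target name
  out <- out[order(out$target_name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mask mature sequences inside their own precursors
#'
#' Replaces every occurrence of each precursor's own mature children within
#' the precursor sequence by a run of `N` of the same length, so that
#' mature-length reads cannot map both to the mature target and to its
#' precursor; precursor counts then comprise reads mapping exclusively to
#' precursor sequences. Matures annotated to other hairpins are not searched.
#'
#' @param precursors data.frame from [parse_mirbase_fasta()] (with
#'   `mature_children`).
#' @param matures data.frame with `gene_name`, `sequence`.
#' @return `precursors` with masked `sequence` (same lengths as input).
#' @export
mask_matures_in_precursors <- function(precursors, matures) {
  if (nrow(precursors) == 0L) return(precursors)
  seq_of <- setNames(matures$sequence, matures$gene_name)
  out <- precursors
  for (i in seq_len(nrow(out))) {
    kids <- out$mature_children[[i]]
    s <- out$sequence[i]
    for (kid in kids) {
      ks <- seq_of[[kid]]
      if (is.null(ks)) {
        warning("child mature ", kid, " not present in mature set; ",
                "precursor ", out$gene_name[i], " left unmasked for it")
        next
      }
      if (!grepl(ks, s, fixed = TRUE)) {
        warning("mature ", kid, " not found within precursor ",
                out$gene_name[i], "; left unmasked for it")
        next
      }
      s <- gsub(ks, strrep("N", nchar(ks)), s, fixed = TRUE)
    }
    stopifnot(nchar(s) == nchar(out$sequence[i]))
    out$sequence[i] <- s
  }
  out
}

#' Detect nested mature pairs differing by one terminal base
#'
#' Finds ordered pairs of mature targets where the shorter sequence is a
#' contiguous substring of the longer and the lengths differ by exactly one.
#' Reads of the shorter sequence map to both targets, while reads of the
#' longer map uniquely, which motivates the count-subtraction rule applied
#' in [nested_subtraction()]. Containments with length difference of two or
#' more are reported as a warning but not registered.
#'
#' @param targets data.frame of collapsed mature targets
#'   ([collapse_identical_matures()]).
#' @return data.frame with columns `short_target`, `long_target`.
#' @export
detect_nested_pairs <- function(targets) {
  empty <- data.frame(short_target = character(0),
                      long_target = character(0), stringsAsFactors = FALSE)
  n <- nrow(targets)
  if (n < 2L) return(empty)
  len <- nchar(targets$sequence)
  pairs <- list()
  deeper <- 0L
  for (i in seq_len(n)) {
    cand <- which(len > len[i])
    if (!length(cand)) next
    hit <- cand[vapply(cand, function(j)
      grepl(targets$sequence[i], targets$sequence[j], fixed = TRUE),
      logical(1))]
    for (j in hit) {
      if (len[j] - len[i] == 1L) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(short_target = targets$target_name[i],
                     long_target = targets$target_name[j],
                     stringsAsFactors = FALSE)
      } else {
        deeper <- deeper + 1L
      }
    }
  }
  if (deeper > 0L)
    warning(deeper, " containment(s) with length difference >= 2 detected; ",
            "not registered as nested pairs")
  if (!length(pairs)) return(empty)
  out <- rbindlist(pairs)
  setkey(out, short_target, long_target)
  as.data.frame(out)
}

#' Build the full mapping reference
#'
#' Composes parsing, mature collapsing, precursor masking and nested-pair
#' detection into a single reference object used by the mapper and counter.
#'
#' @param matures,precursors Parsed records as returned by
#'   [parse_mirbase_fasta()], or `NULL` to parse from the FASTA paths.
#' @param mature_fasta,hairpin_fasta,child_map Passed to
#'   [parse_mirbase_fasta()] when `matures` is `NULL`.
#' @return An object of class `mirna_reference`: a list with `targets`
#'   (data.frame: `target_name`, `sequence`, `kind`, `member_genes`,
#'   `nested_partner`) and `nested_pairs` (data.frame: `short_target`,
#'   `long_target`).
#' @export
build_reference <- function(matures = NULL, precursors = NULL,
                            mature_fasta = NULL, hairpin_fasta = NULL,
                            child_map = NULL) {
  if (is.null(matures)) {
    parsed <- parse_mirbase_fasta(mature_fasta, hairpin_fasta, child_map)
    matures <- parsed$matures
    precursors <- parsed$precursors
  }
  mt <- collapse_identical_matures(matures)
  masked <- mask_matures_in_precursors(precursors, matures)
  np <- detect_nested_pairs(mt)

  pt <- data.frame(target_name = masked$gene_name,
                   sequence = masked$sequence,
                   kind = rep("precursor", nrow(masked)),
                   stringsAsFactors = FALSE)
  pt$member_genes <- I(as.list(masked$gene_name))
  targets <- rbind(mt, pt)
  if (anyDuplicated(targets$target_name))
    stop("target name collision between mature and precursor sets")
  partner <- setNames(rep(NA_character_, nrow(targets)), targets$target_name)
  partner[np$short_target] <- np$long_target
  partner[np$long_target] <- np$short_target
  targets$nested_partner <- unname(partner)
  rownames(targets) <- NULL
  structure(list(targets = targets, nested_pairs = np),
            class = "mirna_reference")
}

#' @export
print.mirna_reference <- function(x, ...) {
  k <- table(x$targets$kind)
  multi <- sum(lengths(x$targets$member_genes) > 1L)
  cat("mirna_reference:",
      sum(x$targets$kind == "mature"), "mature targets (",
      multi, "multi-gene ),",
      sum(x$targets$kind == "precursor"), "precursor targets,",
      nrow(x$nested_pairs), "nested pairs\n")
  invisible(x)
}

#' Write / read a reference as FASTA plus metadata TSV
#'
#' The FASTA carries every target sequence (masked precursors included);
#' the TSV records `target_name`, `kind`, `length`, comma-joined
#' `member_genes` and `nested_partner`, which together reconstruct the
#' reference exactly.
#'
#' @param ref A `mirna_reference`.
#' @param fasta,tsv Output (or input) file paths.
#' @return `write_reference` returns the paths invisibly; `read_reference`
#'   returns a `mirna_reference`.
#' @export
write_reference <- function(ref, fasta, tsv) {
  t <- ref$targets
  writeLines(paste0(">", t$target_name, "\n", t$sequence), fasta)
  meta <- data.frame(target_name = t$target_name, kind = t$kind,
                     length = nchar(t$sequence),
                     member_genes = vapply(t$member_genes, paste,
                                           character(1), collapse = ","),
                     nested_partner = ifelse(is.na(t$nested_partner), "",
                                             t$nested_partner),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta, tsv) {
  seqs <- read_fasta_dna(fasta)
  meta <- utils::read.delim(tsv, stringsAsFactors = FALSE,
                            colClasses = "character")
  stopifnot(identical(seqs$gene_name, meta$target_name))
  targets <- data.frame(target_name = meta$target_name,
                        sequence = seqs$sequence,
                        kind = meta$kind, stringsAsFactors = FALSE)
  targets$member_genes <- I(strsplit(meta$member_genes, ",", fixed = TRUE))
  targets$nested_partner <- ifelse(nzchar(meta$nested_partner),
                                   meta$nested_partner, NA_character_)
  short <- meta$target_name[nzchar(meta$nested_partner) &
                              meta$kind == "mature"]
  np <- data.frame(short_target = character(0), long_target = character(0),
                   stringsAsFactors = FALSE)
  if (length(short)) {
    len <- setNames(as.integer(meta$length), meta$target_name)
    partner <- setNames(targets$nested_partner, targets$target_name)
    is_short <- len[short] < len[partner[short]]
    np <- data.frame(short_target = short[is_short],
                     long_target = unname(partner[short][is_short]),
                     stringsAsFactors = FALSE)
    np <- np[order(np$short_target, method = "radix"), , drop = FALSE]
    rownames(np) <- NULL
  }
  structure(list(targets = targets, nested_pairs = np),
            class = "mirna_reference")
}
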