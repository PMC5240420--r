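#' Configuration for the synthetic Four Core Genotypes experiment generator
#'
#' Defaults emulate the study design: a miRBase-like reference with
#' multi-gene families sharing one mature sequence, hairpins embedding
#' their matures, seven 1-nt-nested mature pairs, heavy-tailed (log-normal)
#' baseline expression shared across libraries, multiplicative planted
#' gonadal-sex / sex-chromosome / diet effects per condition, TruSeq-style
#' adapter-contaminated reads with uniform substitution errors, and a
#' non-miRNA contaminant fraction that brings the mapping rate into the
#' 80-90 percent range observed for real small-RNA libraries.
#'
#' @param n_mature_genes Number of mature miRNA gene records.
#' @param n_shared_families Families of genes sharing one mature sequence.
#' @param shared_family_size Genes per shared family.
#' @param n_nested_pairs Mature pairs differing by one terminal base.
#' @param mature_len_range Inclusive mature sequence length range.
#' @param precursor_flank_range Inclusive hairpin flank length range.
#' @param two_mature_fraction Fraction of hairpins carrying both a -5p and
#'   a -3p mature.
#' @param depth Reads per library.
#' @param error_rate Per-base substitution error probability.
#' @param read_length Raw read length before trimming.
#' @param adapter 3' adapter appended to every insert.
#' @param dispersion Log-normal sigma of baseline expression (log scale).
#' @param precursor_fraction Fraction of reads drawn from unmasked
#'   precursor fragments.
#' @param other_rna_fraction Fraction of reads from non-miRNA small RNAs
#'   (degradation products etc.) that should not map.
#' @param replicate_sigma Log-normal sigma of between-replicate expression
#'   variation (used for pooled-vs-individual library emulation).
#' @param effects Planted multiplicative effects, a list keyed by
#'   condition (`intact_chow`, `GDX_chow`, `GDX_HFD`), each holding
#'   `sex = c(effect, fraction)` (log2 effect applied to gonadally male
#'   libraries for the affected miRNA subset; negative values produce a
#'   female bias) and `chromosome = c(effect, fraction)` (applied to XY
#'   libraries), plus `diet = c(effect, fraction)` applied with random
#'   per-miRNA sign to high-fat-diet libraries.
#' @param seed Default seed used by the generator entry points.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_mature_genes = 300L,
                              n_shared_families = 20L,
                              shared_family_size = 3L,
                              n_nested_pairs = 7L,
                              mature_len_range = c(18L, 24L),
                              precursor_flank_range = c(18L, 28L),
                              two_mature_fraction = 0.3,
                              depth = 1e5,
                              error_rate = 0.01,
                              read_length = 36L,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              dispersion = 2.5,
                              precursor_fraction = 0.01,
                              other_rna_fraction = 0.12,
                              replicate_sigma = 0.3,
                              effects = default_effects(),
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_mature_genes > 0L, n_shared_families >= 0L,
            shared_family_size >= 2L, n_nested_pairs >= 0L,
            depth > 0, error_rate >= 0, error_rate <= 1,
            precursor_fraction >= 0, other_rna_fraction >= 0,
            precursor_fraction + other_rna_fraction < 1)
  n_family_genes <- n_shared_families * shared_family_size
  if (n_family_genes + 2L * n_nested_pairs > n_mature_genes)
    stop("infeasible config: families and nested pairs need more genes ",
         "than n_mature_genes provides")
  structure(cfg, class = "sim_config")
}

#' Planted effect sizes emulating the study's qualitative pattern
#'
#' Male-biased miRNA profile in gonadally intact chow-fed mice, a slight
#' female bias after gonadectomy, a combined male and XY bias under high
#' fat diet, and a strong diet effect that dominates library covariance.
#' Effects are log2 multiplicative sizes paired with the fraction of
#' miRNAs affected.
#'
#' @return Nested list of condition effects (see [simulation_config()]).
#' @export
default_effects <- function() {
  list(intact_chow = list(sex = c(effect = 1.0, fraction = 0.6),
                          chromosome = c(effect = 0, fraction = 0)),
       GDX_chow = list(sex = c(effect = -0.4, fraction = 0.6),
                       chromosome = c(effect = 0, fraction = 0)),
       GDX_HFD = list(sex = c(effect = 0.8, fraction = 0.6),
                      chromosome = c(effect = 0.8, fraction = 0.6)),
       diet = c(effect = 1.5, fraction = 0.5))
}

BASES <- c("A", "C", "G", "T")

# sample() treats a length-1 numeric as 1:x; this keeps degenerate ranges
# (e.g. a fixed mature length) literal
sample_from <- function(x, n, replace = TRUE) {
  x[sample.int(length(x), n, replace = replace)]
}

rand_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(L) paste(sample(BASES, L, replace = TRUE),
                                collapse = ""), character(1))
}

# any containment (substring) relations among sequences, as index pairs
containments <- function(seqs) {
  n <- length(seqs)
  len <- nchar(seqs)
  out <- list()
  for (i in seq_len(n)) {
    cand <- which(len >= len[i])
    cand <- cand[cand != i]
    hit <- cand[grepl(seqs[i], seqs[cand], fixed = TRUE)]
    if (length(hit))
      out[[length(out) + 1L]] <- cbind(i, hit)
  }
  if (!length(out)) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

#' Generate a synthetic miRBase-style reference with known structure
#'
#' Emits mature and hairpin records containing planted multi-gene
#' families (identical mature sequences), hairpins embedding their mature
#' children within random flanks (a configurable fraction carry both a
#' -5p and a -3p mature), and exactly the configured number of 1-nt
#' 3'-nested mature pairs; all other sequences are verified free of
#' accidental containment. Also draws the expression truth shared by all
#' libraries of an experiment: log-normal baseline abundances, unmasked
#' precursor fragment windows, and the planted per-condition affected
#' miRNA subsets.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer; when given, seeds the RNG (otherwise the
#'   current RNG state is used, as when called from
#'   [generate_fcg_experiment()]).
#' @return A list of class `sim_reference` with `mature` and `hairpin`
#'   record data.frames (DNA alphabet), and `truth` (families, nested
#'   pairs at collapsed-target level, fragment windows, baseline
#'   expression, affected subsets).
#' @export
generate_reference <- function(config = simulation_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_fam_genes <- config$n_shared_families * config$shared_family_size
  n_distinct <- config$n_mature_genes - (n_fam_genes -
                                           config$n_shared_families)
  lr <- config$mature_len_range

  # distinct mature sequences: free + nested (long = short + 1 terminal nt)
  n_free <- n_distinct - 2L * config$n_nested_pairs
  for (attempt in 1:100) {
    free <- rand_dna(n_free, sample_from(lr[1]:lr[2], n_free))
    shorts <- rand_dna(config$n_nested_pairs,
                       sample_from(lr[1]:max(lr[1], lr[2] - 1L),
                                   config$n_nested_pairs))
    longs <- paste0(shorts, sample(BASES, config$n_nested_pairs,
                                   replace = TRUE))
    seqs <- c(free, shorts, longs)
    if (anyDuplicated(seqs)) next
    cont <- containments(seqs)
    planted <- cbind(n_free + seq_len(config$n_nested_pairs),
                     n_free + config$n_nested_pairs +
                       seq_len(config$n_nested_pairs))
    ok <- nrow(cont) == nrow(planted) &&
      all(paste(cont[, 1], cont[, 2]) %in% paste(planted[, 1], planted[, 2]))
    if (ok) break
    if (attempt == 100L) stop("could not generate containment-free reference")
  }
  is_nested_short <- seq_along(seqs) %in% planted[, 1]
  is_nested_long <- seq_along(seqs) %in% planted[, 2]

  # assign sequences to genes: families replicate free sequences
  fam_seq_idx <- head(which(!is_nested_short & !is_nested_long),
                      config$n_shared_families)
  gene_seq_idx <- c(rep(fam_seq_idx, each = config$shared_family_size),
                    setdiff(seq_along(seqs), fam_seq_idx))
  n_genes <- length(gene_seq_idx)
  stopifnot(n_genes == config$n_mature_genes)

  # hairpin layout: family genes and nested genes get single-mature
  # hairpins; a fraction of the remaining genes pair up as -5p/-3p
  n_protected <- config$n_shared_families * config$shared_family_size +
    2L * config$n_nested_pairs
  gene_id <- seq_len(n_genes)
  protected <- c(seq_len(n_fam_genes),
                 n_genes - 2L * config$n_nested_pairs + seq_len(
                   2L * config$n_nested_pairs))
  pairable <- setdiff(gene_id, protected)
  n_pairs <- floor(length(pairable) * config$two_mature_fraction / 2)
  paired <- if (n_pairs > 0) matrix(pairable[seq_len(2L * n_pairs)],
                                    ncol = 2L, byrow = TRUE)
            else matrix(integer(0), 0, 2)
  singles <- setdiff(gene_id, as.vector(paired))

  hp_id <- 0L
  mature_rows <- vector("list", n_genes)
  hairpin_rows <- list()
  children_rows <- list()
  fr <- config$precursor_flank_range
  make_hp_name <- function(i) sprintf("syn-mir-%03d", i)
  add_hairpin <- function(children_idx, arms) {
    hp_id <<- hp_id + 1L
    hp <- make_hp_name(hp_id)
    mnames <- paste0(hp, "-", arms)
    mseqs <- seqs[gene_seq_idx[children_idx]]
    f5 <- rand_dna(1L, sample_from(fr[1]:fr[2], 1L))
    f3 <- rand_dna(1L, sample_from(fr[1]:fr[2], 1L))
    body <- if (length(mseqs) == 2L)
      paste0(mseqs[1L], rand_dna(1L, sample(8:15, 1L)), mseqs[2L])
    else mseqs[1L]
    hairpin_rows[[hp_id]] <<- data.frame(
      gene_name = hp, sequence = paste0(f5, body, f3),
      stringsAsFactors = FALSE)
    children_rows[[hp_id]] <<- mnames
    for (k in seq_along(children_idx))
      mature_rows[[children_idx[k]]] <<- data.frame(
        gene_name = mnames[k], sequence = mseqs[k],
        stringsAsFactors = FALSE)
  }
  for (g in singles) add_hairpin(g, sample(c("5p", "3p"), 1L))
  for (r in seq_len(nrow(paired))) add_hairpin(paired[r, ], c("5p", "3p"))

  mature <- do.call(rbind, mature_rows)
  hairpin <- do.call(rbind, hairpin_rows)
  hairpin$mature_children <- I(children_rows)

  # truth at collapsed-target level (names as ref_builder will assign them)
  collapsed <- collapse_identical_matures(mature)
  seq_to_target <- setNames(collapsed$target_name, collapsed$sequence)
  families <- lapply(which(lengths(collapsed$member_genes) > 1L),
                     function(i) collapsed$member_genes[[i]])
  nested <- data.frame(
    short_target = unname(seq_to_target[seqs[planted[, 1]]]),
    long_target = unname(seq_to_target[seqs[planted[, 2]]]),
    stringsAsFactors = FALSE)

  # unmasked fragment window per hairpin (start of the 3' flank), the
  # source of precursor-exclusive reads
  frag <- character(nrow(hairpin))
  for (i in seq_len(nrow(hairpin))) {
    s <- hairpin$sequence[i]
    kids <- hairpin$mature_children[[i]]
    last_end <- max(vapply(kids, function(k) {
      ms <- mature$sequence[mature$gene_name == k]
      regexpr(ms, s, fixed = TRUE) + nchar(ms) - 1L
    }, numeric(1)))
    flen <- min(nchar(s) - last_end, sample(19:22, 1L))
    frag[i] <- substr(s, last_end + 1L, last_end + flen)
  }
  names(frag) <- hairpin$gene_name

  baseline <- setNames(rlnorm(nrow(collapsed), meanlog = 0,
                              sdlog = config$dispersion),
                       collapsed$target_name)
  precursor_expr <- setNames(rlnorm(nrow(hairpin), 0, 2.0),
                             hairpin$gene_name)

  # planted effects spare the top decile of baseline abundance: the
  # dominant species stay sex-stable (overall composition is preserved,
  # as observed in real adipose libraries) and CPM renormalization of the
  # planted shifts stays mild
  affected <- list()
  tgt <- collapsed$target_name
  n_top <- ceiling(0.1 * length(tgt))
  eligible <- names(sort(baseline, decreasing = TRUE))[-seq_len(n_top)]
  pick <- function(frac) sample(eligible,
                                min(round(frac * length(tgt)),
                                    length(eligible)))
  for (cond in c("intact_chow", "GDX_chow", "GDX_HFD")) {
    eff <- config$effects[[cond]]
    affected[[cond]] <- list(
      sex = pick(eff$sex[["fraction"]]),
      chromosome = pick(eff$chromosome[["fraction"]]))
  }
  diet_set <- pick(config$effects$diet[["fraction"]])
  affected$diet <- setNames(sample(c(-1, 1), length(diet_set),
                                   replace = TRUE), diet_set)

  structure(list(mature = mature, hairpin = hairpin,
                 truth = list(families = families, nested = nested,
                              collapsed = collapsed, fragments = frag,
                              baseline = baseline,
                              precursor_expr = precursor_expr,
                              affected = affected),
                 config = config),
            class = "sim_reference")
}

# condition key used in config$effects / truth$affected
condition_key <- function(condition) {
  paste(condition$gonadal_state, condition$diet, sep = "_")
}

# per-library expected expression weights over mature targets
library_expression <- function(sim, genotype, condition,
                               baseline = NULL) {
  tr <- sim$truth
  cfg <- sim$config
  w <- if (is.null(baseline)) tr$baseline else baseline
  key <- condition_key(condition)
  eff <- cfg$effects[[key]]
  if (is.null(eff)) stop("no planted effects for condition ", key)
  if (genotype$gonadal_sex == "M" && eff$sex[["effect"]] != 0) {
    a <- tr$affected[[key]]$sex
    w[a] <- w[a] * 2^eff$sex[["effect"]]
  }
  if (genotype$chromosomes == "XY" && eff$chromosome[["effect"]] != 0) {
    a <- tr$affected[[key]]$chromosome
    w[a] <- w[a] * 2^eff$chromosome[["effect"]]
  }
  if (condition$diet == "HFD" && cfg$effects$diet[["effect"]] != 0) {
    d <- tr$affected$diet
    w[names(d)] <- w[names(d)] * 2^(d * cfg$effects$diet[["effect"]])
  }
  w
}

# vectorized uniform substitution errors; distinct positions per read
mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  L <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), L, error_rate)
  one <- which(nerr == 1L)
  if (length(one)) {
    pos <- 1L + floor(runif(length(one)) * L[one])
    cur <- substr(seqs[one], pos, pos)
    shift <- sample.int(3L, length(one), replace = TRUE)
    newb <- BASES[(match(cur, BASES) - 1L + shift) %% 4L + 1L]
    substr(seqs[one], pos, pos) <- newb
  }
  multi <- which(nerr >= 2L)
  for (i in multi) {
    pos <- sample.int(L[i], nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      newb <- sample(setdiff(BASES, cur), 1L)
      substr(seqs[i], p, p) <- newb
    }
  }
  seqs
}

#' Generate one synthetic sequencing library
#'
#' Draws reads multinomially at the configured depth from the per-library
#' expected expression (baseline times the planted multiplicative effects
#' for this genotype and condition, plus precursor fragments and unmapped
#' contaminant RNAs), appends the 3' adapter, truncates to the raw read
#' length, applies uniform substitution errors, and attaches the library
#' barcode.
#'
#' @param sim A `sim_reference` from [generate_reference()].
#' @param genotype list with `gonadal_sex` ("F"/"M") and `chromosomes`
#'   ("XX"/"XY").
#' @param condition list with `gonadal_state` ("intact"/"GDX") and `diet`
#'   ("chow"/"HFD").
#' @param label Library label (used in read ids).
#' @param barcode Library index sequence.
#' @param expression Optional named expression override (mature targets),
#'   e.g. a replicate-perturbed baseline.
#' @param depth,error_rate Optional overrides of the config values.
#' @return list with `reads` (data.frame `read_id`, `sequence`,
#'   `qualities`, `barcode`), `truth_counts` (named; mature targets,
#'   precursors, and `__other__`), `genotype`, `condition`.
#' @export
generate_library <- function(sim, genotype, condition, label = "lib",
                             barcode = "ATCACG", expression = NULL,
                             depth = NULL, error_rate = NULL) {
  cfg <- sim$config
  if (is.null(depth)) depth <- cfg$depth
  if (is.null(error_rate)) error_rate <- cfg$error_rate
  tr <- sim$truth
  w_mat <- library_expression(sim, genotype, condition, expression)
  w_mat <- w_mat / sum(w_mat) *
    (1 - cfg$precursor_fraction - cfg$other_rna_fraction)
  w_pre <- tr$precursor_expr / sum(tr$precursor_expr) *
    cfg$precursor_fraction
  w <- c(w_mat, w_pre, `__other__` = cfg$other_rna_fraction)
  counts <- as.vector(rmultinom(1L, size = depth, prob = w))
  names(counts) <- names(w)

  src_seq <- c(setNames(tr$collapsed$sequence, tr$collapsed$target_name),
               tr$fragments)
  n_other <- counts[["__other__"]]
  inserts <- c(rep(src_seq[names(w_mat)], counts[names(w_mat)]),
               rep(src_seq[names(w_pre)], counts[names(w_pre)]),
               if (n_other > 0) rand_dna(n_other, sample(20:24, n_other,
                                                         replace = TRUE)))
  inserts <- sample(inserts)             # shuffle read order
  full <- substr(paste0(inserts, cfg$adapter,
                        strrep("A", cfg$read_length)),
                 1L, cfg$read_length)
  full <- mutate_reads(full, error_rate)
  reads <- data.frame(
    read_id = paste0(label, ":", seq_along(full), "#", barcode),
    sequence = full,
    qualities = strrep("I", nchar(full)),
    barcode = barcode, stringsAsFactors = FALSE)
  list(reads = reads, truth_counts = counts, genotype = genotype,
       condition = condition, label = label)
}

FCG_GENOTYPES <- data.frame(
  gonadal_sex = c("F", "M", "F", "M"),
  chromosomes = c("XX", "XX", "XY", "XY"),
  stringsAsFactors = FALSE)

FCG_CONDITIONS <- data.frame(
  gonadal_state = c("intact", "GDX", "GDX"),
  diet = c("chow", "chow", "HFD"),
  stringsAsFactors = FALSE)

TRUSEQ_INDICES <- c("ATCACG", "CGATGT", "TTAGGC", "TGACCA", "ACAGTG",
                    "GCCAAT", "CAGATC", "ACTTGA", "GATCAG", "TAGCTT",
                    "GGCTAC", "CTTGTA")

#' Generate a full synthetic Four Core Genotypes experiment
#'
#' One library per genotype (XX-F, XX-M, XY-F, XY-M) in each of the three
#' conditions (gonadally intact on chow, gonadectomized on chow,
#' gonadectomized on high fat diet): twelve libraries with a design sheet
#' and complete ground truth, fully determined by the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return list of class `fcg_experiment` with `sim` (the
#'   `sim_reference`), `libraries` (named list from
#'   [generate_library()]), `design` (12-row design sheet), and
#'   `planted_directions` (expected majority group per contrast and
#'   condition).
#' @export
generate_fcg_experiment <- function(config = simulation_config(),
                                    seed = config$seed) {
  set.seed(seed)
  sim <- generate_reference(config)
  libs <- list()
  design <- list()
  i <- 0L
  for (c_i in seq_len(nrow(FCG_CONDITIONS))) {
    for (g_i in seq_len(nrow(FCG_GENOTYPES))) {
      i <- i + 1L
      genotype <- as.list(FCG_GENOTYPES[g_i, ])
      condition <- as.list(FCG_CONDITIONS[c_i, ])
      label <- paste0(condition$gonadal_state, "_", condition$diet, "_",
                      genotype$chromosomes, genotype$gonadal_sex)
      libs[[label]] <- generate_library(sim, genotype, condition,
                                        label = label,
                                        barcode = TRUSEQ_INDICES[i])
      design[[i]] <- data.frame(library = label,
                                gonadal_sex = genotype$gonadal_sex,
                                chromosomes = genotype$chromosomes,
                                gonadal_state = condition$gonadal_state,
                                diet = condition$diet,
                                barcode = TRUSEQ_INDICES[i],
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(sim = sim, libraries = libs,
                 design = do.call(rbind, design),
                 planted_directions = planted_directions(config)),
            class = "fcg_experiment")
}

#' Expected majority-bias direction per contrast and condition
#'
#' Derived from the signs of the planted effect sizes: a positive sex
#' effect raises expression in gonadally male libraries, so the majority
#' of affected miRNAs have negative female/male log2 ratios (male
#' direction); likewise for the chromosome effect and the XY direction.
#'
#' @param config A [simulation_config()].
#' @return data.frame with `condition`, `contrast`, `direction` (the
#'   favoured group label, or `NA` when no effect is planted).
#' @export
planted_directions <- function(config = simulation_config()) {
  out <- list()
  for (cond in c("intact_chow", "GDX_chow", "GDX_HFD")) {
    eff <- config$effects[[cond]]
    s <- eff$sex[["effect"]]
    k <- eff$chromosome[["effect"]]
    out[[length(out) + 1L]] <- data.frame(
      condition = cond, contrast = "F_vs_M",
      direction = if (s > 0) "M" else if (s < 0) "F" else NA_character_,
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      condition = cond, contrast = "XX_vs_XY",
      direction = if (k > 0) "XY" else if (k < 0) "XX" else NA_character_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate individual replicate libraries and their pooled counterpart
#'
#' Emulates the pooling-feasibility assessment: replicate libraries are
#' drawn from replicate-perturbed copies of the baseline expression
#' (log-normal perturbation of sigma `replicate_sigma`), and the pooled
#' library from the mean of those replicate expression profiles at the
#' same depth.
#'
#' @param sim A `sim_reference`.
#' @param n_individual Number of replicate libraries.
#' @param genotype,condition Genotype and condition of the replicates.
#' @param depth,error_rate Optional config overrides.
#' @return list with `individual` (list of library objects) and `pooled`
#'   (one library object).
#' @export
generate_pooled_set <- function(sim, n_individual = 3L,
                                genotype = list(gonadal_sex = "F",
                                                chromosomes = "XX"),
                                condition = list(gonadal_state = "GDX",
                                                 diet = "HFD"),
                                depth = NULL, error_rate = NULL) {
  cfg <- sim$config
  base <- sim$truth$baseline
  reps <- lapply(seq_len(n_individual), function(i)
    base * rlnorm(length(base), 0, cfg$replicate_sigma))
  individual <- lapply(seq_len(n_individual), function(i)
    generate_library(sim, genotype, condition,
                     label = paste0("ind", i),
                     barcode = TRUSEQ_INDICES[i],
                     expression = reps[[i]], depth = depth,
                     error_rate = error_rate))
  pooled_expr <- Reduce(`+`, reps) / n_individual
  pooled <- generate_library(sim, genotype, condition, label = "pooled",
                             barcode = TRUSEQ_INDICES[n_individual + 1L],
                             expression = pooled_expr, depth = depth,
                             error_rate = error_rate)
  list(individual = individual, pooled = pooled)
}

#' Write a synthetic experiment to disk
#'
#' Emits `mature.fa` and `hairpin.fa` (RNA alphabet, miRBase style), one
#' FASTQ per library, `design.tsv`, and `truth.json`.
#'
#' @param experiment An `fcg_experiment`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- experiment$sim
  writeLines(paste0(">", sim$mature$gene_name, "\n",
                    chartr("T", "U", sim$mature$sequence)),
             file.path(dir, "mature.fa"))
  writeLines(paste0(">", sim$hairpin$gene_name, "\n",
                    chartr("T", "U", sim$hairpin$sequence)),
             file.path(dir, "hairpin.fa"))
  for (label in names(experiment$libraries)) {
    r <- experiment$libraries[[label]]$reads
    writeLines(paste0("@", r$read_id, "\n", r$sequence, "\n+\n",
                      r$qualities),
               file.path(dir, paste0(label, ".fastq")))
  }
  utils::write.table(experiment$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    truth_counts = lapply(experiment$libraries, function(l)
      as.list(l$truth_counts)),
    nested = experiment$sim$truth$nested,
    families = experiment$sim$truth$families,
    planted_directions = experiment$planted_directions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
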