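#' Validate a Four Core Genotypes design sheet
#'
#' @param design data.frame with columns `library`, `gonadal_sex` (F/M),
#'   `chromosomes` (XX/XY), `gonadal_state` (intact/GDX), `diet`
#'   (chow/HFD).
#' @return The design, with columns checked and coerced to character.
#' @export
validate_design <- function(design) {
  need <- c("library", "gonadal_sex", "chromosomes", "gonadal_state", "diet")
  if (!all(need %in% names(design)))
    stop("design sheet must have columns: ", paste(need, collapse = ", "))
  design[need] <- lapply(design[need], as.character)
  stopifnot(all(design$gonadal_sex %in% c("F", "M")),
            all(design$chromosomes %in% c("XX", "XY")),
            all(design$gonadal_state %in% c("intact", "GDX")),
            all(design$diet %in% c("chow", "HFD")))
  if (anyDuplicated(design$library)) stop("duplicate library labels")
  design
}

#' Per-miRNA log2 group expression ratios for one contrast and condition
#'
#' For the female-vs-male contrast the numerator is the mean CPM of the two
#' gonadally female libraries (XX-F and XY-F) of the condition and the
#' denominator the mean of the two male libraries; for XX-vs-XY the groups
#' are the two XX and the two XY libraries. miRNAs whose numerator or
#' denominator group mean is zero receive a pseudocount added to both group
#' means and are flagged.
#'
#' @param abundance A `mirna_abundance`.
#' @param design A validated design sheet ([validate_design()]).
#' @param contrast `"F_vs_M"` or `"XX_vs_XY"`.
#' @param condition list or named vector with `gonadal_state` and `diet`.
#' @param subset Target names over which to compute ratios (typically the
#'   highly expressed set); defaults to all targets.
#' @param pseudocount CPM added to both group means when either is zero.
#' @return Object of class `ratio_profile`: list with `contrast`,
#'   `condition`, `log2_ratios` (named numeric), `pseudocounted` (logical
#'   flags), and group library labels.
#' @export
group_log2_ratio <- function(abundance, design, contrast = c("F_vs_M",
                                                             "XX_vs_XY"),
                             condition, subset = NULL, pseudocount = 0.5) {
  contrast <- match.arg(contrast)
  design <- validate_design(design)
  cond <- as.list(condition)
  sel <- design$gonadal_state == cond$gonadal_state & design$diet == cond$diet
  d <- design[sel, , drop = FALSE]
  if (nrow(d) != 4L)
    stop("condition (", cond$gonadal_state, ", ", cond$diet,
         ") does not have exactly the four genotype libraries")
  grp_var <- if (contrast == "F_vs_M") "gonadal_sex" else "chromosomes"
  num_lvl <- if (contrast == "F_vs_M") "F" else "XX"
  num_libs <- d$library[d[[grp_var]] == num_lvl]
  den_libs <- d$library[d[[grp_var]] != num_lvl]
  if (length(num_libs) != 2L || length(den_libs) != 2L)
    stop("missing genotype library for contrast ", contrast)
  cpm <- abundance$cpm
  if (is.null(subset)) subset <- rownames(cpm)
  stopifnot(all(subset %in% rownames(cpm)))
  num <- rowMeans(cpm[subset, num_libs, drop = FALSE])
  den <- rowMeans(cpm[subset, den_libs, drop = FALSE])
  flag <- num == 0 | den == 0
  num[flag] <- num[flag] + pseudocount
  den[flag] <- den[flag] + pseudocount
  structure(list(contrast = contrast, condition = cond,
                 log2_ratios = log2(num / den), pseudocounted = flag,
                 numerator_libraries = num_libs,
                 denominator_libraries = den_libs),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat("ratio_profile", x$contrast, "in (", x$condition$gonadal_state, ",",
      x$condition$diet, "):", length(x$log2_ratios), "miRNAs, median",
      signif(median(x$log2_ratios), 3), "\n")
  invisible(x)
}

#' Bin log2 ratios into a fixed-width histogram
#'
#' Bins are half-open `[a, a + width)` intervals spanning `[-clamp,
#' clamp]`; values below `-clamp` fall in the first bin and values of
#' `clamp` or above in the last.
#'
#' @param profile A `ratio_profile` (or numeric vector of log2 ratios).
#' @param width Bin width (default 0.5).
#' @param clamp Half-range of the histogram (default 4).
#' @return data.frame with `bin_lower`, `bin_upper`, `count`; counts sum
#'   to the profile length.
#' @export
bin_ratios <- function(profile, width = 0.5, clamp = 4) {
  x <- if (inherits(profile, "ratio_profile")) profile$log2_ratios
       else as.numeric(profile)
  breaks <- seq(-clamp, clamp, by = width)
  nbin <- length(breaks) - 1L
  idx <- findInterval(x, breaks)        # 0 below, nbin+1 at/above clamp
  idx[idx < 1L] <- 1L
  idx[idx > nbin] <- nbin
  data.frame(bin_lower = breaks[-length(breaks)], bin_upper = breaks[-1L],
             count = tabulate(idx, nbins = nbin))
}

#' Exact binomial test for sign bias of a ratio distribution
#'
#' Tests whether the numbers of positively and negatively sex-biased
#' miRNAs depart from the 50:50 split expected without a group effect.
#' Ratios exactly zero are excluded. Two-sided exact binomial test.
#'
#' @param profile A `ratio_profile` (or numeric vector of log2 ratios).
#' @return list with `n_positive`, `n_negative`, `p_value`, `direction`
#'   (`"positive"` = numerator group higher for the majority of miRNAs,
#'   `"negative"` = denominator group higher, `"none"` on a tie) and
#'   `majority_group` (the design label favoured, when the input is a
#'   `ratio_profile`).
#' @export
sign_bias_test <- function(profile) {
  x <- if (inherits(profile, "ratio_profile")) profile$log2_ratios
       else as.numeric(profile)
  npos <- sum(x > 0)
  nneg <- sum(x < 0)
  if (npos + nneg == 0L) stop("sign_bias_test: all ratios are zero")
  bt <- binom.test(npos, npos + nneg, p = 0.5, alternative = "two.sided")
  direction <- if (npos > nneg) "positive" else if (nneg > npos)
    "negative" else "none"
  majority <- NA_character_
  if (inherits(profile, "ratio_profile") && direction != "none") {
    lab <- if (profile$contrast == "F_vs_M") c("F", "M") else c("XX", "XY")
    majority <- if (direction == "positive") lab[1L] else lab[2L]
  }
  list(n_positive = npos, n_negative = nneg, p_value = bt$p.value,
       direction = direction, majority_group = majority)
}

#' Wilcoxon rank-sum comparison of two ratio distributions
#'
#' Two-sided unpaired Wilcoxon rank-sum test of a distributional shift
#' between two ratio profiles of the same contrast (e.g. gonadally intact
#' versus gonadectomized). Exact when both samples have at most 20
#' untied observations, normal approximation with continuity correction
#' and tie-corrected variance otherwise.
#'
#' @param profile_a,profile_b `ratio_profile` objects (or numeric vectors).
#' @return Two-sided p-value.
#' @export
compare_conditions <- function(profile_a, profile_b) {
  a <- if (inherits(profile_a, "ratio_profile")) profile_a$log2_ratios
       else as.numeric(profile_a)
  b <- if (inherits(profile_b, "ratio_profile")) profile_b$log2_ratios
       else as.numeric(profile_b)
  if (!length(a) || !length(b)) stop("compare_conditions: empty profile")
  if (inherits(profile_a, "ratio_profile") &&
      inherits(profile_b, "ratio_profile") &&
      !identical(profile_a$contrast, profile_b$contrast))
    stop("profiles have different contrasts")
  exact <- max(length(a), length(b)) <= 20L &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  wt$p.value
}

#' Median of a ratio profile
#'
#' Sample median of the log2 ratios (mean of the central pair for even n).
#'
#' @param profile A `ratio_profile` (or numeric vector).
#' @return Numeric median.
#' @export
median_ratio <- function(profile) {
  x <- if (inherits(profile, "ratio_profile")) profile$log2_ratios
       else as.numeric(profile)
  if (!length(x)) stop("median_ratio: empty profile")
  median(x)
}

#' Principal component analysis of sequencing libraries
#'
#' Libraries are observations and miRNAs features. The default transform
#' is `log2(CPM + 1)` followed by feature centering (no unit-variance
#' scaling). Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param abundance A `mirna_abundance`.
#' @param subset Target names used as features (typically the highly
#'   expressed set).
#' @param transform `"log2cpm"` (default), `"cpm"`, or `"percent"`.
#' @param n_components Number of components to return (default all).
#' @return list with `scores` (libraries x components),
#'   `variance_fraction` (per component, sums to 1 over all components),
#'   `loadings` (features x components).
#' @export
pca_libraries <- function(abundance, subset = NULL,
                          transform = c("log2cpm", "cpm", "percent"),
                          n_components = NULL) {
  transform <- match.arg(transform)
  if (is.null(subset)) subset <- rownames(abundance$cpm)
  nlib <- length(abundance$libraries)
  if (nlib < 3L) stop("pca_libraries: need at least 3 libraries")
  x <- switch(transform,
              log2cpm = log2(abundance$cpm[subset, , drop = FALSE] + 1),
              cpm = abundance$cpm[subset, , drop = FALSE],
              percent = abundance$percent[subset, , drop = FALSE])
  x <- t(x)  # libraries x features
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  if (is.null(n_components)) n_components <- ncol(p$x)
  if (n_components > ncol(p$x))
    stop("fewer libraries than requested components")
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, "*")[, seq_len(n_components), drop = FALSE]
  loadings <- sweep(p$rotation, 2L, flip, "*")[, seq_len(n_components),
                                               drop = FALSE]
  list(scores = scores, variance_fraction = vf, loadings = loadings)
}

#' Full sex-difference statistics for a quantified experiment
#'
#' Convenience wrapper computing, for every condition present in the
#' design, the F-vs-M and XX-vs-XY ratio profiles over the highly
#' expressed set, their sign-bias tests, medians and binned histograms,
#' plus all within-contrast condition comparisons and the library PCA.
#'
#' @param abundance A `mirna_abundance`.
#' @param design A design sheet.
#' @param cpm_threshold,min_libraries Passed to
#'   [filter_highly_expressed()].
#' @param pseudocount Passed to [group_log2_ratio()].
#' @return list with `highly_expressed`, `profiles` (named by
#'   `<contrast>.<state>_<diet>`), `sign_tests`, `medians`,
#'   `condition_tests` (pairwise Wilcoxon p-values), `pca`.
#' @export
sex_difference_stats <- function(abundance, design, cpm_threshold = 100,
                                 min_libraries = 1L, pseudocount = 0.5) {
  design <- validate_design(design)
  he <- filter_highly_expressed(abundance, cpm_threshold, min_libraries)
  if (!length(he)) stop("highly expressed set is empty at CPM threshold ",
                        cpm_threshold)
  conds <- unique(design[, c("gonadal_state", "diet")])
  profiles <- list()
  for (ct in c("F_vs_M", "XX_vs_XY")) {
    for (i in seq_len(nrow(conds))) {
      cond <- as.list(conds[i, ])
      nm <- paste0(ct, ".", cond$gonadal_state, "_", cond$diet)
      profiles[[nm]] <- group_log2_ratio(abundance, design, ct, cond,
                                         subset = he,
                                         pseudocount = pseudocount)
    }
  }
  sign_tests <- lapply(profiles, sign_bias_test)
  medians <- vapply(profiles, median_ratio, numeric(1))
  condition_tests <- list()
  for (ct in c("F_vs_M", "XX_vs_XY")) {
    nms <- names(profiles)[startsWith(names(profiles), ct)]
    if (length(nms) >= 2L) {
      cmb <- utils::combn(nms, 2L)
      for (j in seq_len(ncol(cmb))) {
        key <- paste(cmb[1L, j], "vs", cmb[2L, j])
        condition_tests[[key]] <-
          compare_conditions(profiles[[cmb[1L, j]]], profiles[[cmb[2L, j]]])
      }
    }
  }
  pca <- pca_libraries(abundance, subset = he)
  list(highly_expressed = he, profiles = profiles,
       sign_tests = sign_tests, medians = medians,
       condition_tests = condition_tests, pca = pca)
}
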