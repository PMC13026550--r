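# Length/GC summaries, two-way ANOVA with Tukey-Kramer HSD, insertion-site
# sequence logos and the per-family feature bubble matrix.

#' GC content of a nucleotide sequence, in percent
#'
#' `N` is excluded from the denominator. An all-N (or empty after exclusion)
#' sequence is undefined and returns `NA` with a warning.
#'
#' @param sequence RNA or DNA string.
#' @return Percent GC in `[0, 100]`.
#' @export
gc_content <- function(sequence) {
  v <- seq_chars(dna_to_rna(sequence))
  v <- v[v != "N"]
  if (!length(v)) {
    warning("GC content undefined: no non-N bases")
    return(NA_real_)
  }
  100 * sum(v %in% c("G", "C")) / length(v)
}

#' AT/AU content of a nucleotide sequence, in percent
#' @inheritParams gc_content
#' @export
at_content <- function(sequence) {
  v <- seq_chars(dna_to_rna(sequence))
  v <- v[v != "N"]
  if (!length(v)) {
    warning("AT content undefined: no non-N bases")
    return(NA_real_)
  }
  100 * sum(v %in% c("A", "U")) / length(v)
}

#' Two-way ANOVA with Tukey-Kramer HSD post hoc comparisons
#'
#' Fits `value ~ A * B` with both factors fixed and reports Type-II sums of
#' squares (appropriate for the unbalanced cohorts this is used on), F and p
#' per main effect and interaction, followed by Tukey-Kramer HSD on the
#' non-empty cell means (standard error per pair from the residual mean square
#' and the harmonic mean of the pair's cell sizes). If a factor has a single
#' level the model is reduced to a one-way ANOVA with a warning.
#'
#' @param values Numeric response (e.g. intron length or GC percent).
#' @param factorA First factor (e.g. intron lineage).
#' @param factorB Second factor (e.g. organellar compartment).
#' @param conf_level Confidence level for Tukey intervals (default 0.95).
#' @return List with `anova` (data.frame: effect, df, SS, F, p), `tukey`
#'   (data.frame of pairwise cell comparisons: diff, lwr, upr, p_adj),
#'   `cell_means` and the fitted `model`.
#' @export
two_way_anova_tukey <- function(values, factorA, factorB, conf_level = 0.95) {
  A <- factor(factorA)
  B <- factor(factorB)
  stopifnot(length(values) == length(A), length(values) == length(B))
  one_way <- nlevels(A) < 2L || nlevels(B) < 2L
  if (nlevels(A) < 2L && nlevels(B) < 2L) {
    stop("both factors have a single level", call. = FALSE)
  }
  dat <- data.frame(y = values, A = A, B = B)
  if (one_way) {
    warning("a factor has a single level; reduced to one-way ANOVA")
    f <- if (nlevels(A) >= 2L) "A" else "B"
    fit <- lm(stats::reformulate(f, "y"), data = dat)
    av <- car::Anova(fit, type = 2)
    cells <- interaction(dat[[f]], drop = TRUE, sep = ":")
  } else {
    fit <- lm(y ~ A * B, data = dat)
    av <- car::Anova(fit, type = 2)
    cells <- interaction(A, B, drop = TRUE, sep = ":")
  }
  av_df <- data.frame(
    effect = rownames(av),
    df = av$Df,
    SS = av$`Sum Sq`,
    F = av$`F value`,
    p = av$`Pr(>F)`,
    stringsAsFactors = FALSE
  )

  mse <- sum(fit$residuals^2) / fit$df.residual
  df_err <- fit$df.residual
  means <- tapply(dat$y, cells, mean)
  ns <- tapply(dat$y, cells, length)
  k <- length(means)
  pairs <- combn(names(means), 2)
  qcrit <- qtukey(conf_level, nmeans = k, df = df_err)
  tukey <- data.frame(
    pair = apply(pairs, 2, paste, collapse = " - "),
    diff = NA_real_, lwr = NA_real_, upr = NA_real_, p_adj = NA_real_,
    stringsAsFactors = FALSE
  )
  for (c_i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, c_i]; g2 <- pairs[2, c_i]
    diff <- means[[g1]] - means[[g2]]
    se <- sqrt(mse / 2 * (1 / ns[[g1]] + 1 / ns[[g2]])) # Tukey-Kramer
    tukey$diff[c_i] <- diff
    tukey$lwr[c_i] <- diff - qcrit * se
    tukey$upr[c_i] <- diff + qcrit * se
    tukey$p_adj[c_i] <- ptukey(abs(diff) / se, nmeans = k, df = df_err,
                               lower.tail = FALSE)
  }
  list(anova = av_df, tukey = tukey,
       cell_means = data.frame(cell = names(means), n = as.integer(ns),
                               mean = as.numeric(means)),
       model = fit)
}

#' Insertion-site sequence logo profile
#'
#' From aligned fixed-width windows centered on the splice junction (position
#' 0), computes per-position base frequencies and information content
#' IC = 2 - H (Shannon entropy in bits). By default no small-sample correction
#' is applied, so an invariant column scores exactly 2 bits and a uniform
#' column exactly 0; set `small_sample_correction` to subtract the e(n) =
#' 3/(2 ln 2 n) approximation.
#'
#' @param windows Character vector of equal-length nucleotide windows, or a
#'   character matrix (rows = sites).
#' @param center Column index of the junction (position 0); defaults to the
#'   middle column of an odd-width window.
#' @param small_sample_correction Apply the e(n) correction (default FALSE).
#' @return A `logo_profile`: list with `freq` (4 x width matrix), `ic`
#'   (numeric vector, bits) and `positions` (junction-relative coordinates).
#' @export
insertion_site_logo <- function(windows, center = NULL,
                                small_sample_correction = FALSE) {
  if (!is.matrix(windows)) {
    if (length(unique(nchar(windows))) != 1L) {
      stop("windows differ in length", call. = FALSE)
    }
    windows <- do.call(rbind, strsplit(toupper(windows), "", fixed = TRUE))
  } else {
    windows <- toupper(windows)
  }
  windows[windows == "T"] <- "U"
  n <- nrow(windows)
  w <- ncol(windows)
  if (is.null(center)) center <- (w + 1L) %/% 2L
  counts <- apply(windows, 2L, function(col) {
    tabulate(factor(col, levels = RNA_BASES), nbins = 4L)
  })
  rownames(counts) <- RNA_BASES
  tot <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(tot, 1L), "/")
  H <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- 2 - H
  if (small_sample_correction) ic <- pmax(0, ic - 3 / (2 * log(2) * n))
  positions <- seq_len(w) - center
  structure(list(freq = freq, ic = ic, positions = positions, n = n),
            class = "logo_profile")
}

#' Feature bubble matrix: per-family percentage of members with each feature
#'
#' Mirrors the bubble-matrix summary of the occurrence and integrity of key
#' structural elements: for each intron family and each logical feature
#' column, the percentage of assessable members carrying the feature, rounded
#' to one decimal. Members with `NA` for a feature are counted in a separate
#' `not assessable` denominator note.
#'
#' @param feature_table data.frame with one row per intron: an `intron_id`
#'   column, logical feature columns, and either a `family` column or a `key`
#'   column resolvable through `assignments`.
#' @param assignments Optional family assignment: a named character vector
#'   (names = intron keys) or the data.frame from [assign_families()]
#'   (`$assignments`), used when `feature_table` lacks a `family` column.
#' @param features Character vector of feature column names (default: all
#'   logical columns).
#' @return A `bubble_matrix`: list with `percent` (family x feature matrix),
#'   `family_size` (named integer) and `not_assessable` (family x feature
#'   counts of NA members).
#' @export
bubble_matrix <- function(feature_table, assignments = NULL, features = NULL) {
  stopifnot(is.data.frame(feature_table))
  if (!"family" %in% names(feature_table)) {
    if (is.null(assignments)) {
      stop("feature_table needs a 'family' column or 'assignments'", call. = FALSE)
    }
    if (is.data.frame(assignments)) {
      assignments <- setNames(assignments$family, assignments$key)
    }
    feature_table$family <- unname(assignments[feature_table$key])
    feature_table <- feature_table[!is.na(feature_table$family), , drop = FALSE]
  }
  if (is.null(features)) {
    features <- names(feature_table)[vapply(feature_table, is.logical, logical(1L))]
  }
  fams <- sort(unique(feature_table$family))
  pct <- matrix(NA_real_, length(fams), length(features),
                dimnames = list(fams, features))
  nas <- matrix(0L, length(fams), length(features),
                dimnames = list(fams, features))
  sizes <- setNames(integer(length(fams)), fams)
  for (f in fams) {
    rows <- feature_table[feature_table$family == f, , drop = FALSE]
    sizes[[f]] <- nrow(rows)
    for (ft in features) {
      x <- rows[[ft]]
      nas[f, ft] <- sum(is.na(x))
      k <- sum(x, na.rm = TRUE)
      denom <- sum(!is.na(x))
      pct[f, ft] <- if (denom) round(100 * k / denom, 1) else NA_real_
    }
  }
  structure(list(percent = pct, family_size = sizes, not_assessable = nas),
            class = "bubble_matrix")
}
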