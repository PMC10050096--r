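#' Normalize morphometric traits to [0, 1] within species
#'
#' Linearly rescales each trait within each species so the species minimum
#' maps to 0 and the maximum to 1 — the cross-species normalization used
#' before ordination. A trait constant within a species is set to 0 with a
#' warning.
#'
#' @param table data.frame with a species column and numeric trait columns.
#' @param trait_cols names of the trait columns (default: all numeric
#'   columns except `species_col`).
#' @param species_col name of the species column (default "species").
#' @return the table with trait columns rescaled.
#' @export
normalize_traits <- function(table, trait_cols = NULL, species_col = "species") {
  if (is.null(trait_cols))
    trait_cols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                          species_col)
  if (any(sapply(table[trait_cols], function(x) any(x < 0, na.rm = TRUE))))
    stop("negative measurements")
  for (sp in unique(table[[species_col]])) {
    rows <- table[[species_col]] == sp
    for (tr in trait_cols) {
      x <- table[rows, tr]
      rng <- range(x, na.rm = TRUE)
      if (diff(rng) == 0) {
        warning("trait '", tr, "' constant within species '", sp,
                "'; set to 0")
        table[rows, tr] <- 0
      } else {
        table[rows, tr] <- (x - rng[1]) / diff(rng)
      }
    }
  }
  table
}

#' Size-match two groups by iterative exclusion of extremes
#'
#' Repeatedly removes one extreme individual at a time — from the group
#' whose mean deviates more from the pooled mean, dropping that group's
#' maximum if its mean is above the pooled mean and its minimum otherwise —
#' re-testing the group means after each removal, until they no longer
#' differ significantly. This reproduces the "exclude the largest of the
#' large group and the smallest of the small group" matching procedure.
#'
#' @param a,b numeric vectors (e.g. body lengths of the two morphs).
#' @param alpha significance threshold (default 0.05).
#' @param test "t" (Welch two-sample t-test on means, default) or
#'   "wilcoxon".
#' @return list with `excluded_a`, `excluded_b` (indices into the inputs),
#'   `matched_a`, `matched_b`, `p` (final test p-value) and `n_steps`.
#' @export
size_match <- function(a, b, alpha = 0.05, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(length(a) >= 3, length(b) >= 3)
  n_a0 <- length(a); n_b0 <- length(b)
  idx_a <- seq_along(a); idx_b <- seq_along(b)
  pval <- function(x, y) {
    if (test == "t") stats::t.test(x, y)$p.value else
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
  p <- pval(a, b); steps <- 0L
  while (p < alpha) {
    if (length(a) <= 2 || length(b) <= 2)
      stop("groups exhausted before means matched")
    pooled <- mean(c(a, b))
    dev_a <- abs(mean(a) - pooled); dev_b <- abs(mean(b) - pooled)
    from_a <- if (dev_a != dev_b) dev_a > dev_b else
      (mean(a) > mean(b) && steps %% 2 == 0) ||
      (mean(a) < mean(b) && steps %% 2 == 1)
    if (from_a) {
      drop <- if (mean(a) > pooled) which.max(a) else which.min(a)
      a <- a[-drop]; idx_a <- idx_a[-drop]
    } else {
      drop <- if (mean(b) > pooled) which.max(b) else which.min(b)
      b <- b[-drop]; idx_b <- idx_b[-drop]
    }
    steps <- steps + 1L
    p <- pval(a, b)
  }
  list(excluded_a = setdiff(seq_len(n_a0), idx_a),
       excluded_b = setdiff(seq_len(n_b0), idx_b),
       matched_a = a, matched_b = b, p = p,
       n_steps = steps, kept_a = idx_a, kept_b = idx_b)
}

#' Percent difference of group means
#'
#' `100 * (mean(a) / mean(b) - 1)`: how much longer (in percent) group `a`
#' is than group `b` on average.
#'
#' @param a,b numeric vectors.
#' @param digits decimal places (default 1).
#' @return numeric scalar.
#' @export
percent_mean_difference <- function(a, b, digits = 1) {
  if (!length(a) || !length(b)) stop("empty group")
  if (mean(b) == 0) stop("zero denominator mean")
  round(100 * (mean(a) / mean(b) - 1), digits)
}

#' Principal components of a normalized trait table
#'
#' Covariance-based PCA (no re-standardization: the 0-1 normalization
#' already equalizes trait ranges). Returns scores, loadings and
#' explained-variance fractions.
#'
#' @param x numeric matrix or data.frame of normalized traits
#'   (individuals x traits), no missing values.
#' @return list with `scores`, `loadings`, `explained` (fractions summing
#'   to 1), `sdev`.
#' @export
pca_project <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 individuals")
  if (anyNA(x)) stop("missing values in trait table")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(scores = pc$x, loadings = pc$rotation,
       explained = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev)
}

#' Summarize raiding-assay tables per scout genotype
#'
#' @param raids data.frame with one row per raid: `colony` (colony id),
#'   `scout` (genotype of the initiating scout), and optionally numeric
#'   participant-count columns named `participants_<genotype>`.
#' @param n_colonies number of colonies assayed (default: number of
#'   distinct colony ids observed).
#' @param genotypes scout genotypes to summarize (default: those observed);
#'   pass explicitly to report zeroes for genotypes that initiated no raid.
#' @return data.frame per scout genotype: `n_raids`, `raids_per_colony`,
#'   `mean_participants` (NA without participant columns), plus attribute
#'   `participant_fraction` (named vector over genotypes) when counts are
#'   present.
#' @export
raid_summary <- function(raids, n_colonies = length(unique(raids$colony)),
                         genotypes = sort(unique(raids$scout))) {
  if (n_colonies < 1) stop("need >= 1 colony")
  genos <- genotypes
  part_cols <- grep("^participants_", names(raids), value = TRUE)
  out <- do.call(rbind, lapply(genos, function(g) {
    sub <- raids[raids$scout == g, , drop = FALSE]
    total_part <- if (length(part_cols))
      rowSums(sub[, part_cols, drop = FALSE]) else NULL
    data.frame(scout = g, n_raids = nrow(sub),
               raids_per_colony = nrow(sub) / n_colonies,
               mean_participants = if (is.null(total_part)) NA_real_ else
                 if (!length(total_part)) 0 else mean(total_part),
               stringsAsFactors = FALSE)
  }))
  if (length(part_cols)) {
    totals <- colSums(raids[, part_cols, drop = FALSE])
    attr(out, "participant_fraction") <-
      stats::setNames(totals / sum(totals),
                      sub("^participants_", "", part_cols))
  }
  rownames(out) <- NULL
  out
}
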