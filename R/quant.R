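#' Taxon-wise protein fractions
#'
#' Normalizes protein intensities within each taxon: a protein's "fraction" is
#' its intensity divided by the summed intensity of all proteins assigned to
#' the same taxon, separately within every condition x replicate. Fractions
#' per taxon therefore sum to 1 and are invariant to per-taxon global
#' intensity scaling (e.g. channel loading differences).
#'
#' @param table data.frame with columns `protein_id`, `taxon_id`,
#'   `condition`, `replicate`, `intensity` (non-negative, finite).
#' @return The input with an added `fraction` column.
#' @export
taxon_fractions <- function(table) {
  need <- c("protein_id", "taxon_id", "condition", "replicate", "intensity")
  if (!all(need %in% names(table)))
    stop("missing columns: ", paste(setdiff(need, names(table)), collapse = ", "))
  if (any(!is.finite(table$intensity)) || any(table$intensity < 0))
    stop("intensities must be finite and non-negative")
  key <- interaction(table$taxon_id, table$condition, table$replicate,
                     drop = TRUE)
  totals <- tapply(table$intensity, key, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero))
    stop("zero total intensity for taxon x condition x replicate: ",
         paste(zero, collapse = ", "))
  table$fraction <- table$intensity / as.vector(totals[as.character(key)])
  table
}

#' Log2 fold change of protein fractions between two conditions
#'
#' Averages fractions across replicates within each group, per protein x
#' taxon, then reports `log2(treatment / control)`. Proteins with a zero
#' control fraction have an undefined ratio: they are excluded from the output
#' with a warning (listed in the `excluded` attribute) unless a `pseudocount`
#' is supplied, in which case it is added to both group means.
#'
#' @param fractions output of [taxon_fractions()].
#' @param treatment,control condition labels.
#' @param pseudocount optional non-negative value added to both means
#'   (default 0 = off).
#' @return data.frame `protein_id`, `taxon_id`, `log2fc`, `n_treat`,
#'   `n_ctrl`, with excluded zero-control records in `attr(, "excluded")`.
#' @export
log2_fold_change <- function(fractions, treatment, control, pseudocount = 0) {
  stopifnot("fraction" %in% names(fractions))
  if (pseudocount < 0) stop("'pseudocount' must be non-negative")
  sub <- fractions[fractions$condition %in% c(treatment, control), ]
  if (nrow(sub) == 0L) stop("no rows for the requested conditions")
  agg <- stats::aggregate(fraction ~ protein_id + taxon_id + condition,
                          data = sub, FUN = mean)
  cnt <- stats::aggregate(fraction ~ protein_id + taxon_id + condition,
                          data = sub, FUN = length)
  names(cnt)[4] <- "n"
  wide <- merge(
    merge(agg[agg$condition == treatment, c(1, 2, 4)],
          agg[agg$condition == control, c(1, 2, 4)],
          by = c("protein_id", "taxon_id"),
          suffixes = c("_treat", "_ctrl")),
    merge(cnt[cnt$condition == treatment, c(1, 2, 4)],
          cnt[cnt$condition == control, c(1, 2, 4)],
          by = c("protein_id", "taxon_id"),
          suffixes = c("_treat", "_ctrl")),
    by = c("protein_id", "taxon_id"))
  wide$fraction_treat <- wide$fraction_treat + pseudocount
  wide$fraction_ctrl <- wide$fraction_ctrl + pseudocount
  undef <- wide$fraction_ctrl == 0
  excluded <- wide[undef, c("protein_id", "taxon_id")]
  if (nrow(excluded))
    warning(nrow(excluded),
            " protein(s) with zero control fraction excluded")
  wide <- wide[!undef, ]
  out <- data.frame(protein_id = wide$protein_id,
                    taxon_id = wide$taxon_id,
                    log2fc = log2(wide$fraction_treat / wide$fraction_ctrl),
                    n_treat = wide$n_treat, n_ctrl = wide$n_ctrl,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Significance star buckets
#'
#' The five-level convention used in the figures: `ns` for p > .05, `*` for
#' .01 < p <= .05, `**` for 1e-3 < p <= .01, `***` for 1e-4 < p <= 1e-3 and
#' `****` for p <= 1e-4.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = TRUE) |>
    as.character()
}

#' Two-sided Mann-Whitney-Wilcoxon comparison with Bonferroni correction
#'
#' Rank-sum test between two samples (e.g. the gene-level and protein-level
#' values of a protein family), Bonferroni-adjusted for `n_comparisons`
#' simultaneous tests, with the star-bucket label of [significance_stars()]
#' computed on the adjusted p-value. If all pooled values are identical the
#' p-value is 1 by convention.
#'
#' @param values_a,values_b numeric samples (both nonempty).
#' @param n_comparisons number of simultaneous comparisons.
#' @return List with `statistic`, `p_value`, `p_adjusted`, `stars`, `n_a`,
#'   `n_b`.
#' @export
compare_group_distributions <- function(values_a, values_b, n_comparisons = 1) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both samples must be nonempty")
  if (n_comparisons < 1) stop("'n_comparisons' must be >= 1")
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    w <- length(values_a) * length(values_b) / 2
    p <- 1
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              alternative = "two.sided"))
    w <- unname(ht$statistic)
    p <- ht$p.value
  }
  p_adj <- min(1, p * n_comparisons)
  list(statistic = w, p_value = p, p_adjusted = p_adj,
       stars = significance_stars(p_adj),
       n_a = length(values_a), n_b = length(values_b))
}

#' One-sample Wilcoxon signed-rank test against zero
#'
#' Two-sided test of whether a sample (e.g. log2 fold changes of ribosomal
#' proteins) is centred at 0. All-zero samples give p = 1 by convention.
#'
#' @param values numeric sample (nonempty).
#' @return List with `statistic`, `p_value`, `stars`, `n`.
#' @export
one_sample_sign_test <- function(values) {
  if (length(values) == 0L) stop("'values' must be nonempty")
  nonzero <- values[values != 0]
  if (length(nonzero) == 0L) {
    v <- 0; p <- 1
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values, mu = 0,
                                              alternative = "two.sided"))
    v <- unname(ht$statistic)
    p <- ht$p.value
  }
  list(statistic = v, p_value = p, stars = significance_stars(p),
       n = length(values))
}
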