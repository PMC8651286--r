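# Cohort-level statistics for longitudinal immune-cfDNA studies: balanced
# intra/inter-individual coefficients of variation, baseline fold change,
# seroconversion-based responder classification, empirical ROC curves,
# nonparametric group tests and cfDNA/count ratios.
#
# Longitudinal tables are long-format data.frames with columns
# donor_id, timepoint, source (cfDNA / whole_blood / CBC), analyte
# (cell type), value (>= 0), and optionally units.

.check_long_table <- function(table) {
  need <- c("donor_id", "timepoint", "source", "analyte", "value")
  .check(all(need %in% names(table)),
         "long table needs columns %s", paste(need, collapse = ", "))
  key <- paste(table$donor_id, table$timepoint, table$source, table$analyte)
  .check(!any(duplicated(key)), "duplicate (donor, timepoint, source, analyte) rows")
  .check(all(is.na(table$value) | table$value >= 0), "values must be non-negative")
  invisible(table)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean.
#' Undefined (NA) when the mean is zero or fewer than two values remain.
#'
#' @param values Numeric vector.
#' @return CV, or NA when undefined.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  stats::sd(values) / m
}

# donors x timepoints value matrix for one analyte/source
.donor_time_matrix <- function(table, analyte, source) {
  sub <- table[table$analyte == analyte & table$source == source, , drop = FALSE]
  .check(nrow(sub) > 0, "no rows for analyte %s, source %s", analyte, source)
  donors <- sort(unique(sub$donor_id))
  tps <- unique(sub$timepoint)
  m <- matrix(NA_real_, nrow = length(donors), ncol = length(tps),
              dimnames = list(donors, as.character(tps)))
  m[cbind(match(sub$donor_id, donors), match(sub$timepoint, tps))] <- sub$value
  m
}

#' Mean intra-individual coefficient of variation
#'
#' Computes each donor's CV across that donor's timepoints and averages over
#' donors; donors with an undefined CV are excluded with a message.
#'
#' @param table Long-format table (see module description).
#' @param analyte,source Selectors.
#' @return A list: `intra_cv` (mean over donors), `per_donor` (named vector),
#'   `n_donors`.
#' @export
intra_cv <- function(table, analyte, source) {
  .check_long_table(table)
  m <- .donor_time_matrix(table, analyte, source)
  cvs <- apply(m, 1, coefficient_of_variation)
  drop <- is.na(cvs)
  if (any(drop)) {
    message(sprintf("intra_cv: dropping %d donor(s) with undefined CV", sum(drop)))
  }
  cvs <- cvs[!drop]
  .check(length(cvs) > 0, "no donor with a defined CV")
  list(intra_cv = mean(cvs), per_donor = cvs, n_donors = length(cvs))
}

#' Balanced mean inter-individual coefficient of variation
#'
#' The inter-individual CV is computed across donors at each timepoint. To
#' remove the bias from comparing CVs at different sample sizes (e.g. six
#' timepoints per donor but 15 donors), the across-donor CV is computed on
#' every donor subset of size `group_size` — per timepoint, then averaged
#' across timepoints — and averaged over subsets. Subsets are enumerated
#' exhaustively when their number does not exceed `exact_cap`, otherwise
#' sampled uniformly with `n_sample` draws under `seed`.
#'
#' @param table Long-format table.
#' @param analyte,source Selectors.
#' @param group_size Donors per subset (default 6).
#' @param time_averaged Compute CVs on per-donor time-averaged values
#'   instead of per timepoint (alternative reading; default FALSE).
#' @param exact_cap Maximum number of subsets enumerated exactly (1e6).
#' @param n_sample Subsets sampled beyond the cap (1e5).
#' @param seed Seed for subset sampling.
#' @return A list: `inter_cv`, `n_subsets`, `exact`, `group_size`,
#'   `n_donors`.
#' @export
inter_cv_balanced <- function(table, analyte, source, group_size = 6,
                              time_averaged = FALSE, exact_cap = 1e6,
                              n_sample = 1e5, seed = 1L) {
  .check_long_table(table)
  m <- .donor_time_matrix(table, analyte, source)
  nd <- nrow(m)
  .check(group_size <= nd, "group_size (%d) exceeds number of donors (%d)",
         group_size, nd)
  if (time_averaged) m <- matrix(rowMeans(m, na.rm = TRUE), ncol = 1)
  n_comb <- choose(nd, group_size)
  exact <- n_comb <= exact_cap
  subsets <- if (exact) {
    utils::combn(nd, group_size)
  } else {
    .with_seed(seed, replicate(n_sample, sort(sample.int(nd, group_size))))
  }
  per_subset <- apply(subsets, 2, function(rows) {
    cvs <- apply(m[rows, , drop = FALSE], 2, coefficient_of_variation)
    mean(cvs, na.rm = TRUE)
  })
  list(inter_cv = mean(per_subset, na.rm = TRUE),
       n_subsets = ncol(subsets), exact = exact,
       group_size = group_size, n_donors = nd)
}

#' Fold change from baseline
#'
#' Each donor's values are divided by that donor's value at the baseline
#' timepoint, per analyte and source. Donors whose baseline is zero or
#' missing are excluded for that analyte (no pseudo-count) with a message.
#'
#' @param table Long-format table.
#' @param baseline_timepoint Baseline label (default "D0").
#' @return The table restricted to eligible rows with an added
#'   `fold_change` column.
#' @export
fold_change_from_baseline <- function(table, baseline_timepoint = "D0") {
  .check_long_table(table)
  .check(baseline_timepoint %in% table$timepoint,
         "baseline timepoint %s absent from table", baseline_timepoint)
  base <- table[table$timepoint == baseline_timepoint, , drop = FALSE]
  bkey <- paste(base$donor_id, base$source, base$analyte)
  key <- paste(table$donor_id, table$source, table$analyte)
  bval <- base$value[match(key, bkey)]
  ok <- !is.na(bval) & bval > 0
  n_excl <- length(unique(key[!ok]))
  if (n_excl > 0) {
    message(sprintf(
      "fold_change_from_baseline: %d donor/analyte series excluded (baseline zero or missing)",
      n_excl))
  }
  out <- table[ok, , drop = FALSE]
  out$fold_change <- table$value[ok] / bval[ok]
  rownames(out) <- NULL
  out
}

#' Classify vaccination responders from HI titers
#'
#' Hemagglutination-inhibition titers are reciprocal serum dilutions; 1:40
#' is the conventional positivity cut-off. Strains with baseline titer below
#' `cutoff` are "eligible" (no pre-existing antibodies). A donor with no
#' eligible strain (antibodies against all strains at baseline) is excluded;
#' a responder has post-vaccination titer strictly above `cutoff` on at
#' least one eligible strain; otherwise non-responder. Donors whose eligible
#' strains all lack a post titer are excluded.
#'
#' @param titers data.frame with columns `donor_id`, `strain`,
#'   `baseline_titer`, `post_titer`.
#' @param cutoff Positivity cut-off (default 40).
#' @return data.frame: `donor_id`, `status` (responder / non_responder /
#'   excluded), `reason`.
#' @export
classify_responders <- function(titers, cutoff = 40) {
  need <- c("donor_id", "strain", "baseline_titer", "post_titer")
  .check(all(need %in% names(titers)), "titer table needs columns %s",
         paste(need, collapse = ", "))
  .check(all(is.na(titers$baseline_titer) | titers$baseline_titer > 0) &&
           all(is.na(titers$post_titer) | titers$post_titer > 0),
         "titers must be positive")
  rows <- lapply(split(titers, titers$donor_id), function(d) {
    eligible <- !is.na(d$baseline_titer) & d$baseline_titer < cutoff
    if (!any(eligible)) {
      status <- "excluded"; reason <- "antibodies against all strains at baseline"
    } else {
      post <- d$post_titer[eligible]
      if (all(is.na(post))) {
        status <- "excluded"; reason <- "no post titer on eligible strains"
      } else if (any(post > cutoff, na.rm = TRUE)) {
        status <- "responder"; reason <- ""
      } else {
        status <- "non_responder"; reason <- ""
      }
    }
    data.frame(donor_id = d$donor_id[1], status = status, reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical ROC curve and AUC
#'
#' Ties are handled by the rank convention, so the trapezoid AUC equals
#' U/(n1*n2) from the Mann-Whitney statistic on the same data.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Logical or 0/1 vector; TRUE/1 = case.
#' @return A list: `auc` and `curve` (data.frame `threshold`, `fpr`, `tpr`;
#'   thresholds descending, with the (0,0) and (1,1) endpoints).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  .check(n1 > 0 && n0 > 0, "both classes must be non-empty")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(auc = auc, curve = curve)
}

#' Nonparametric group comparisons
#'
#' Two-group comparisons use the two-tailed Mann-Whitney (Wilcoxon rank-sum)
#' test; multi-group comparisons use Kruskal-Wallis; `pearson` gives the
#' Pearson correlation of two paired series. Exact rank-sum p-values are
#' used at small n without ties (the default behaviour of the underlying
#' routine), normal approximation with tie correction otherwise.
#'
#' @param groups A list of numeric vectors (2 for `rank_sum_2` and
#'   `pearson`, >= 2 for `kruskal_wallis`).
#' @param method One of `"rank_sum_2"`, `"kruskal_wallis"`, `"pearson"`.
#' @return A list: `statistic`, `p_value`, `method` (plus `estimate` for
#'   pearson).
#' @export
group_compare <- function(groups, method = c("rank_sum_2", "kruskal_wallis",
                                             "pearson")) {
  method <- match.arg(method)
  stopifnot(is.list(groups))
  if (method == "rank_sum_2") {
    .check(length(groups) == 2, "rank_sum_2 needs exactly 2 groups")
    ht <- stats::wilcox.test(groups[[1]], groups[[2]], alternative = "two.sided")
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = method)
  } else if (method == "kruskal_wallis") {
    .check(length(groups) >= 2, "kruskal_wallis needs >= 2 groups")
    ht <- stats::kruskal.test(groups)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = method)
  } else {
    .check(length(groups) == 2 && length(groups[[1]]) == length(groups[[2]]),
           "pearson needs 2 paired series")
    ht <- stats::cor.test(groups[[1]], groups[[2]], method = "pearson")
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         estimate = unname(ht$estimate), method = method)
  }
}

#' Per-donor cfDNA / blood-count ratio
#'
#' Ratio between the cfDNA percentage of a cell type and the percentage of
#' that population in blood (CBC), per donor and analyte; zero denominators
#' give NA with a flag.
#'
#' @param table Long-format table containing both sources.
#' @param num_source,den_source Source labels (default cfDNA over CBC).
#' @param timepoint Optional timepoint selector.
#' @return data.frame: `donor_id`, `analyte`, `numerator`, `denominator`,
#'   `ratio`, `flag`.
#' @export
cfdna_count_ratio <- function(table, num_source = "cfDNA", den_source = "CBC",
                              timepoint = NULL) {
  .check_long_table(table)
  if (!is.null(timepoint)) table <- table[table$timepoint == timepoint, , drop = FALSE]
  num <- table[table$source == num_source, , drop = FALSE]
  den <- table[table$source == den_source, , drop = FALSE]
  key_n <- paste(num$donor_id, num$timepoint, num$analyte)
  key_d <- paste(den$donor_id, den$timepoint, den$analyte)
  hit <- match(key_n, key_d)
  ok <- !is.na(hit)
  .check(any(ok), "no matched %s/%s pairs", num_source, den_source)
  out <- data.frame(donor_id = num$donor_id[ok], analyte = num$analyte[ok],
                    numerator = num$value[ok], denominator = den$value[hit[ok]],
                    stringsAsFactors = FALSE)
  zero <- out$denominator == 0
  out$ratio <- ifelse(zero, NA_real_, out$numerator / out$denominator)
  out$flag <- ifelse(zero, "zero_denominator", "")
  rownames(out) <- NULL
  out
}

#' Median/MAD outlier flags
#'
#' Transparent substitute for proprietary multi-outlier detection: flags
#' points further than `k` median absolute deviations from the median.
#' Off by default in all pipelines; callers opt in explicitly.
#'
#' @param values Numeric vector.
#' @param k MAD multiplier (default 5).
#' @return Logical vector, TRUE = outlier.
#' @export
mad_outliers <- function(values, k = 5) {
  med <- stats::median(values, na.rm = TRUE)
  madv <- stats::mad(values, na.rm = TRUE)
  if (is.na(madv) || madv == 0) return(rep(FALSE, length(values)))
  !is.na(values) & abs(values - med) > k * madv
}
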