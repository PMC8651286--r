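# Marker discovery from a reference methylation atlas.
#
# The atlas is a 450K-array style beta-value matrix: rows are CpG sites with
# genomic coordinates, columns are tissues / sorted cell types. Cell-type
# specific markers are CpGs strongly hypomethylated in the target cell type
# and methylated nearly everywhere else, lying in locally CpG-dense regions
# so that a short amplicon captures several co-methylated sites.

#' Construct a methylation atlas object
#'
#' @param cpg_ids Character vector of unique CpG identifiers.
#' @param chrom Character vector of chromosome names, one per CpG.
#' @param pos Integer vector of 1-based probe positions.
#' @param betas Numeric matrix of methylation fractions in \[0,1\] (NA for
#'   missing); rows = CpGs, columns = atlas samples.
#' @param groups Optional character vector, one per column, giving the
#'   cell-type/tissue group of each column. Defaults to the column names, so
#'   each column is its own group.
#'
#' @return An object of class `methylation_atlas`: a list with elements
#'   `cpg_ids`, `chrom`, `pos`, `betas` (rownames = cpg_ids), `samples`,
#'   `groups`, sorted by (chrom, pos).
#' @export
methylation_atlas <- function(cpg_ids, chrom, pos, betas, groups = NULL) {
  betas <- as.matrix(betas)
  n <- length(cpg_ids)
  .check(nrow(betas) == n && length(chrom) == n && length(pos) == n,
         "atlas fields have inconsistent lengths")
  .check(ncol(betas) >= 2, "an atlas needs at least 2 columns")
  dup <- duplicated(cpg_ids)
  .check(!any(dup), "duplicate cpg_id: %s", paste(unique(cpg_ids[dup]), collapse = ", "))
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value outside [0,1] at CpG %s (column %d)",
                 cpg_ids[bad[1, 1]], bad[1, 2]), call. = FALSE)
  }
  if (is.null(colnames(betas))) colnames(betas) <- paste0("S", seq_len(ncol(betas)))
  if (is.null(groups)) groups <- colnames(betas)
  .check(length(groups) == ncol(betas), "one group label per atlas column required")
  ord <- order(chrom, pos)
  betas <- betas[ord, , drop = FALSE]
  rownames(betas) <- cpg_ids[ord]
  structure(list(cpg_ids = cpg_ids[ord], chrom = chrom[ord],
                 pos = as.integer(pos[ord]), betas = betas,
                 samples = colnames(betas), groups = as.character(groups)),
            class = "methylation_atlas")
}

#' @export
print.methylation_atlas <- function(x, ...) {
  cat(sprintf("methylation_atlas: %d CpGs x %d columns (%d groups)\n",
              length(x$cpg_ids), ncol(x$betas), length(unique(x$groups))))
  invisible(x)
}

#' Load a methylation atlas from a delimited file
#'
#' Expects a header line and columns `cpg_id`, `chrom`, `pos` followed by one
#' numeric beta column per atlas sample. Missing betas (empty or NA) are
#' tolerated and flagged.
#'
#' @param path Path to a TSV/CSV file (delimiter auto-detected from the
#'   extension; `.csv` means comma, anything else tab).
#' @param groups Optional named character vector mapping sample column names
#'   to group labels, for atlases with several columns per cell type.
#' @return A [methylation_atlas()].
#' @export
load_atlas <- function(path, groups = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("cpg_id", "chrom", "pos")
  .check(all(need %in% names(df)), "atlas file must have columns %s",
         paste(need, collapse = ", "))
  samp_cols <- setdiff(names(df), need)
  betas <- as.matrix(df[, samp_cols, drop = FALSE])
  storage.mode(betas) <- "double"
  g <- NULL
  if (!is.null(groups)) {
    .check(all(samp_cols %in% names(groups)),
           "groups must name every sample column")
    g <- unname(groups[samp_cols])
  }
  methylation_atlas(df$cpg_id, df$chrom, df$pos, betas, groups = g)
}

#' Write a methylation atlas to a TSV file
#'
#' Inverse of [load_atlas()] (group labels are not stored in the file).
#'
#' @param atlas A [methylation_atlas()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "methylation_atlas"))
  df <- data.frame(cpg_id = atlas$cpg_ids, chrom = atlas$chrom,
                   pos = atlas$pos, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(atlas$betas, row.names = NULL))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Marker selection criteria
#'
#' Thresholds for cell-type-specific hypomethylated marker discovery. The
#' defaults implement the standard rule: mean beta below 0.3 in the target
#' cell type, beta above 0.8 in over 90% of the remaining atlas columns,
#' and at least `min_cpgs_in_window` (i.e. more than five) CpG sites within
#' a `window_bp` window so an amplicon can read a co-methylated block; the
#' top `top_k` CpGs per cell type are kept.
#'
#' @param beta_target_max Maximum mean beta in the target cell type (0.3).
#' @param beta_other_min Betas above this count as methylated-elsewhere (0.8).
#' @param other_pass_fraction Fraction of non-target columns that must exceed
#'   `beta_other_min`, strictly (0.90).
#' @param window_bp Window width centred on the candidate (150).
#' @param min_cpgs_in_window Minimum atlas CpGs inside the window, candidate
#'   included (6, i.e. "more than five").
#' @param top_k Markers retained per cell type (10).
#' @param max_missing_fraction CpGs with more than this fraction of missing
#'   betas are excluded from consideration (0.2).
#' @return A list of class `marker_criteria`.
#' @export
marker_criteria <- function(beta_target_max = 0.3, beta_other_min = 0.8,
                            other_pass_fraction = 0.90, window_bp = 150,
                            min_cpgs_in_window = 6, top_k = 10,
                            max_missing_fraction = 0.2) {
  .check(beta_target_max >= 0 && beta_target_max < beta_other_min &&
           beta_other_min <= 1, "need 0 <= beta_target_max < beta_other_min <= 1")
  .check(window_bp > 0, "window_bp must be positive")
  .check(min_cpgs_in_window >= 1, "min_cpgs_in_window must be >= 1")
  .check(top_k >= 1, "top_k must be >= 1")
  structure(list(beta_target_max = beta_target_max,
                 beta_other_min = beta_other_min,
                 other_pass_fraction = other_pass_fraction,
                 window_bp = window_bp,
                 min_cpgs_in_window = min_cpgs_in_window,
                 top_k = top_k,
                 max_missing_fraction = max_missing_fraction),
            class = "marker_criteria")
}

#' Find candidate cell-type-specific hypomethylated CpGs
#'
#' A CpG is a candidate for `target` when its mean beta over the target
#' columns is strictly below `beta_target_max` and the fraction of non-target
#' columns with beta strictly above `beta_other_min` is strictly greater than
#' `other_pass_fraction`. Multiple columns of the target group are averaged
#' per CpG first; missing betas are dropped from means and denominators, and
#' CpGs missing in more than `max_missing_fraction` of columns are skipped.
#'
#' @param atlas A [methylation_atlas()].
#' @param target Cell-type group label (must match `atlas$groups`).
#' @param criteria A [marker_criteria()].
#' @return A data.frame of candidates: `cpg_id`, `chrom`, `pos`,
#'   `target_cell_type`, `beta_target`, `mean_other`, `fraction_other_above`,
#'   `margin` (mean_other - beta_target), `n_cpgs_in_window` (NA until
#'   [density_filter()] runs).
#' @export
find_candidate_cpgs <- function(atlas, target, criteria = marker_criteria()) {
  stopifnot(inherits(atlas, "methylation_atlas"))
  .check(target %in% atlas$groups, "unknown target cell type: %s", target)
  tcols <- atlas$groups == target
  b <- atlas$betas
  miss_frac <- rowMeans(is.na(b))
  eligible <- miss_frac <= criteria$max_missing_fraction
  if (any(!eligible)) {
    message(sprintf("find_candidate_cpgs: %d CpGs skipped for missingness > %g",
                    sum(!eligible), criteria$max_missing_fraction))
  }
  bt <- rowMeans(b[, tcols, drop = FALSE], na.rm = TRUE)
  bo <- b[, !tcols, drop = FALSE]
  n_other_obs <- rowSums(!is.na(bo))
  frac_above <- rowSums(bo > criteria$beta_other_min, na.rm = TRUE) / n_other_obs
  mean_other <- rowMeans(bo, na.rm = TRUE)
  keep <- eligible & !is.nan(bt) & n_other_obs > 0 &
    bt < criteria$beta_target_max &
    frac_above > criteria$other_pass_fraction
  keep[is.na(keep)] <- FALSE
  data.frame(cpg_id = atlas$cpg_ids[keep],
             chrom = atlas$chrom[keep],
             pos = atlas$pos[keep],
             target_cell_type = rep(target, sum(keep)),
             beta_target = unname(bt[keep]),
             mean_other = unname(mean_other[keep]),
             fraction_other_above = unname(frac_above[keep]),
             margin = unname(mean_other[keep] - bt[keep]),
             n_cpgs_in_window = rep(NA_integer_, sum(keep)),
             stringsAsFactors = FALSE)
}

#' Filter candidates by local CpG density
#'
#' Keeps candidates whose `window_bp` window, centred on the candidate and
#' inclusive of it, contains at least `min_cpgs_in_window` atlas CpGs. With
#' the defaults (150 bp, >= 6) this is the "more than five CpG sites within
#' 150 bp" rule that guarantees an amplicon can read a co-methylated block.
#'
#' @param candidates Output of [find_candidate_cpgs()].
#' @param atlas The atlas the candidates came from.
#' @param criteria A [marker_criteria()].
#' @return The retained rows with `n_cpgs_in_window` populated.
#' @export
density_filter <- function(candidates, atlas, criteria = marker_criteria()) {
  stopifnot(inherits(atlas, "methylation_atlas"))
  if (nrow(candidates) == 0) return(candidates)
  .check(all(candidates$cpg_id %in% atlas$cpg_ids),
         "candidate absent from atlas: %s",
         paste(utils::head(setdiff(candidates$cpg_id, atlas$cpg_ids)), collapse = ", "))
  half <- criteria$window_bp / 2
  n_in <- integer(nrow(candidates))
  for (ch in unique(candidates$chrom)) {
    apos <- sort(atlas$pos[atlas$chrom == ch])
    idx <- which(candidates$chrom == ch)
    cp <- candidates$pos[idx]
    # count atlas CpGs with |pos - cp| <= window/2 via sorted interval lookup
    lo <- findInterval(cp - half - 0.5, apos)
    hi <- findInterval(cp + half + 0.5 - 1e-9, apos)
    n_in[idx] <- hi - lo
  }
  out <- candidates[n_in >= criteria$min_cpgs_in_window, , drop = FALSE]
  out$n_cpgs_in_window <- n_in[n_in >= criteria$min_cpgs_in_window]
  rownames(out) <- NULL
  out
}

#' Select the top-k markers per cell type
#'
#' Ranks candidates within each cell type by `margin` (mean beta of
#' non-target columns minus target beta) descending, breaking ties by
#' `fraction_other_above` then genomic coordinate, and keeps at most `top_k`
#' per cell type. Deterministic for a fixed input.
#'
#' @param candidates Candidate data.frame (possibly several cell types).
#' @param criteria A [marker_criteria()].
#' @return The selected rows, ordered by cell type then rank.
#' @export
select_top_k <- function(candidates, criteria = marker_criteria()) {
  if (nrow(candidates) == 0) return(candidates)
  pieces <- lapply(split(candidates, candidates$target_cell_type), function(d) {
    ord <- order(-d$margin, -d$fraction_other_above, d$chrom, d$pos)
    d <- d[ord, , drop = FALSE]
    if (nrow(d) < criteria$top_k) {
      .warnf("cell type %s: only %d candidates (top_k = %d)",
             d$target_cell_type[1], nrow(d), criteria$top_k)
    }
    utils::head(d, criteria$top_k)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Discover markers for several cell types in one call
#'
#' Runs [find_candidate_cpgs()], [density_filter()] and [select_top_k()] for
#' each target cell type and combines the results.
#'
#' @param atlas A [methylation_atlas()].
#' @param targets Character vector of cell-type group labels.
#' @param criteria A [marker_criteria()].
#' @return Selected marker data.frame across all targets.
#' @export
discover_markers <- function(atlas, targets, criteria = marker_criteria()) {
  cand <- do.call(rbind, lapply(targets, function(tt) {
    density_filter(find_candidate_cpgs(atlas, tt, criteria), atlas, criteria)
  }))
  if (is.null(cand)) return(data.frame())
  select_top_k(cand, criteria)
}
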