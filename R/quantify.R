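# Conversion of per-marker unmethylated fractions into calibrated
# per-cell-type fractions and absolute genome equivalents per ml plasma.

#' Sample metadata
#'
#' @param sample_id,donor_id,timepoint,group Labels.
#' @param cfdna_conc Total cfDNA concentration in ng per ml plasma (Qubit).
#' @return A list of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, donor_id = sample_id, timepoint = NA,
                        group = NA, cfdna_conc = NA_real_) {
  .check(is.na(cfdna_conc) || cfdna_conc >= 0, "cfdna_conc must be >= 0")
  structure(list(sample_id = sample_id, donor_id = donor_id,
                 timepoint = timepoint, group = group,
                 cfdna_conc = cfdna_conc), class = "sample_meta")
}

#' Calibration table
#'
#' Per-cell-type divisors applied to raw unmethylated fractions. The default
#' carries the published neutrophil coefficient: the neutrophil-derived
#' cfDNA fraction is the raw methylation fraction divided by 0.69, derived
#' from spike-in calibration curves. All other cell types default to 1.0
#' (their coefficients are not published).
#'
#' @param coefficients Named numeric vector of divisors (> 0); cell types
#'   absent from the table implicitly get 1.0.
#' @param notes Optional named character vector of provenance notes.
#' @return A data.frame of class `calibration_table` with columns
#'   `cell_type`, `coefficient`, `note`.
#' @export
calibration_table <- function(coefficients = c(neutrophil = 0.69),
                              notes = NULL) {
  .check(all(coefficients > 0), "calibration coefficients must be > 0")
  ct <- names(coefficients)
  .check(!is.null(ct) && all(nzchar(ct)), "coefficients must be named by cell type")
  note <- if (is.null(notes)) rep("", length(ct)) else {
    out <- rep("", length(ct)); out[match(names(notes), ct)] <- notes; out
  }
  structure(data.frame(cell_type = ct, coefficient = unname(coefficients),
                       note = note, stringsAsFactors = FALSE),
            class = c("calibration_table", "data.frame"))
}

#' Combine a cell type's marker fractions
#'
#' The assay reports one value per cell type from its 2-3 markers; the
#' combiner is an unweighted mean of the defined per-marker fractions
#' (default) or a read-weighted pooled fraction.
#'
#' @param fractions Per-marker unmethylated fractions (NA = undefined).
#' @param n_retained Retained read counts, needed for `weighted = TRUE`.
#' @param weighted Pool counts across markers instead of averaging fractions.
#' @return A list: `raw_fraction` (NA when every marker is undefined),
#'   `n_markers_used`, `flag` ("", "some_markers_missing", "all_missing").
#' @export
aggregate_cell_type <- function(fractions, n_retained = NULL, weighted = FALSE) {
  def <- !is.na(fractions)
  if (!any(def)) {
    return(list(raw_fraction = NA_real_, n_markers_used = 0L, flag = "all_missing"))
  }
  if (weighted) {
    .check(!is.null(n_retained), "weighted aggregation needs n_retained")
    raw <- sum(fractions[def] * n_retained[def]) / sum(n_retained[def])
  } else {
    raw <- mean(fractions[def])
  }
  list(raw_fraction = raw, n_markers_used = sum(def),
       flag = if (all(def)) "" else "some_markers_missing")
}

#' Apply spike-in calibration to a raw fraction
#'
#' Corrected fraction = raw fraction / coefficient. Cell types without a
#' coefficient use 1.0. Corrected values above 1 are kept but flagged.
#'
#' @param raw_fraction Raw unmethylated-molecule fraction.
#' @param cell_type Cell-type label.
#' @param table A [calibration_table()].
#' @return A list: `corrected_fraction`, `coefficient`, `flag`.
#' @export
apply_calibration <- function(raw_fraction, cell_type,
                              table = calibration_table()) {
  i <- match(cell_type, table$cell_type)
  coef <- if (is.na(i)) 1.0 else table$coefficient[i]
  .check(coef > 0, "calibration coefficient for %s must be > 0", cell_type)
  corrected <- raw_fraction / coef
  list(corrected_fraction = corrected, coefficient = coef,
       flag = if (!is.na(corrected) && corrected > 1) "corrected_gt_1" else "")
}

#' Convert a cfDNA fraction to genome equivalents per ml
#'
#' GE/ml = fraction x cfDNA concentration (ng/ml) x 303, since a haploid
#' genome weighs ~3.3 pg. Exactly linear in both arguments.
#'
#' @param corrected_fraction Calibrated cell-type fraction.
#' @param cfdna_conc cfDNA concentration in ng/ml (or a [sample_meta()]).
#' @return GE/ml (NA with a message when the concentration is missing).
#' @export
to_genome_equivalents <- function(corrected_fraction, cfdna_conc) {
  if (inherits(cfdna_conc, "sample_meta")) cfdna_conc <- cfdna_conc$cfdna_conc
  corrected_fraction * cfdna_conc * .GE_PER_NG
}

#' Quantify one sample's cell-type cfDNA
#'
#' Aggregates marker fractions per cell type, applies calibration, and
#' converts to GE/ml. Fractions from different cell types are independent
#' assays: no renormalisation across cell types is performed.
#'
#' @param marker_counts `counts` data.frame from [tally_sample()].
#' @param panel An [amplicon_panel()].
#' @param meta A [sample_meta()].
#' @param calibration A [calibration_table()].
#' @param weighted Use read-weighted marker pooling.
#' @return data.frame: one row per panel cell type with `sample_id`,
#'   `cell_type`, `raw_fraction`, `corrected_fraction`, `ge_per_ml`,
#'   `n_markers_used`, `flags`.
#' @export
quantify_sample <- function(marker_counts, panel, meta,
                            calibration = calibration_table(),
                            weighted = FALSE) {
  cts <- panel_cell_types(panel)
  rows <- lapply(cts, function(ct) {
    mk <- panel$cell_type_groups[[ct]]
    sub <- marker_counts[marker_counts$marker %in% mk, , drop = FALSE]
    if (nrow(sub) == 0) {
      agg <- list(raw_fraction = NA_real_, n_markers_used = 0L, flag = "all_missing")
    } else {
      agg <- aggregate_cell_type(sub$fraction, sub$n_retained, weighted)
    }
    cal <- apply_calibration(agg$raw_fraction, ct, calibration)
    ge <- if (is.na(cal$corrected_fraction)) NA_real_ else
      to_genome_equivalents(cal$corrected_fraction, meta)
    flags <- paste(Filter(nzchar, c(agg$flag, cal$flag,
                                    if (is.na(meta$cfdna_conc)) "no_cfdna_conc")),
                   collapse = ";")
    data.frame(sample_id = meta$sample_id, cell_type = ct,
               raw_fraction = agg$raw_fraction,
               corrected_fraction = cal$corrected_fraction,
               ge_per_ml = ge, n_markers_used = agg$n_markers_used,
               flags = flags, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
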