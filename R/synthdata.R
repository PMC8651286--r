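# Synthetic-data generators: methylation atlases with planted markers,
# bisulfite amplicon reads from cell-type mixtures, and cohort tables for
# healthy / vaccination / EoE / lymphoma scenarios. All generators are pure
# functions of (parameters, seed).

.IMMUNE_CELL_TYPES <- c("neutrophil", "monocyte", "eosinophil", "bcell",
                        "tcell", "cd8", "treg")

#' Synthetic 16-marker immune panel
#'
#' A deterministic synthetic stand-in for the published 16-named-marker
#' panel (NEUT1-3, MONO1-2, EOSI2-3, B-CELL1-3, T-CELL1-2, CD8A/B,
#' TREG1-2) covering seven immune cell types. Sequences are randomly
#' generated (fixed internal seed), 100-140 bp, each containing several CpG
#' sites and non-CpG cytosines for conversion QC; they are synthetic and
#' share no homology with the real marker loci. Two markers use the
#' allow-one-exception unmethylated-call rule to exercise that code path.
#'
#' @return An [amplicon_panel()].
#' @export
synthetic_panel <- function() {
  defs <- list(
    c("NEUT1", "neutrophil"), c("NEUT2", "neutrophil"), c("NEUT3", "neutrophil"),
    c("MONO1", "monocyte"), c("MONO2", "monocyte"),
    c("EOSI2", "eosinophil"), c("EOSI3", "eosinophil"),
    c("B-CELL1", "bcell"), c("B-CELL2", "bcell"), c("B-CELL3", "bcell"),
    c("T-CELL1", "tcell"), c("T-CELL2", "tcell"),
    c("CD8A", "cd8"), c("CD8B", "cd8"),
    c("TREG1", "treg"), c("TREG2", "treg"))
  .with_seed(104729, {
    amps <- lapply(seq_along(defs), function(i) {
      nm <- defs[[i]][1]; ct <- defs[[i]][2]
      len <- sample(100:140, 1)
      repeat {
        seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                            prob = c(0.3, 0.2, 0.25, 0.25)), collapse = "")
        ncpg <- length(.find_cpg_offsets(seq))
        nqc <- length(.noncpg_c_offsets(seq))
        if (ncpg >= 4 && ncpg <= 8 && nqc >= 8) break
      }
      rule <- if (nm %in% c("NEUT2", "B-CELL2")) "allow_one_exception" else "strict"
      exempt <- if (nm == "B-CELL2") 1L else integer()
      start <- i * 100000L
      amplicon_def(nm, ct, paste0("chr", (i %% 5) + 1), start, start + len,
                   seq, unmeth_rule = rule, exempt_cpgs = exempt)
    })
    amplicon_panel(amps)
  })
}

#' Read-simulation configuration
#'
#' Defaults emulate a well-run bisulfite amplicon assay: 99% bisulfite
#' conversion (probability that an unmethylated or non-CpG cytosine reads as
#' T), 0.3% per-base substitution error, and a small rate (0.2%) of
#' methylated CpG cytosines reading as T (inappropriate conversion).
#'
#' @param depth Reads per marker.
#' @param conversion_rate Conversion probability for unmethylated / non-CpG
#'   cytosines.
#' @param sequencing_error Per-base substitution error probability.
#' @param meth_fail Probability a methylated CpG cytosine converts anyway.
#' @param frac_reverse Fraction of reads emitted reverse-complemented.
#' @param seed RNG seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(depth = 1000, conversion_rate = 0.99,
                            sequencing_error = 0.003, meth_fail = 0.002,
                            frac_reverse = 0, seed = 1L) {
  .check(depth >= 1, "depth must be >= 1")
  for (p in c(conversion_rate, sequencing_error, meth_fail, frac_reverse)) {
    .check(p >= 0 && p <= 1, "probabilities must lie in [0,1]")
  }
  structure(list(depth = as.integer(depth), conversion_rate = conversion_rate,
                 sequencing_error = sequencing_error, meth_fail = meth_fail,
                 frac_reverse = frac_reverse, seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate bisulfite amplicon reads from a cell-type mixture
#'
#' Each read of each marker is drawn from a source cell type in proportion
#' to `mixture`; its methylation pattern comes from `patterns` (default: a
#' cell type is fully unmethylated at its own markers and fully methylated
#' everywhere else; mixture components that are not panel cell types, e.g. a
#' HEK-293 background, are methylated everywhere). Bisulfite conversion,
#' conversion failure, inappropriate conversion of methylated CpGs and
#' substitution sequencing errors are then applied; qualities are constant
#' Q37 with error sites downgraded to Q14.
#'
#' @param panel An [amplicon_panel()].
#' @param mixture Named per-source fractions summing to 1.
#' @param config A [read_sim_config()].
#' @param patterns Optional nested list `patterns[[source]][[marker]]` of
#'   per-CpG "U"/"M" states overriding the default.
#' @param fastq Optional path; when given the reads are also written as
#'   FASTQ.
#' @return A list: `reads` (data.frame `id`, `seq`, `qual`), `truth`
#'   (data.frame `read_id`, `marker`, `source`, `unmeth_pattern` = whether
#'   the source pattern at this marker is all-unmethylated).
#' @export
simulate_reads <- function(panel, mixture, config = read_sim_config(),
                           patterns = NULL, fastq = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"))
  .check(abs(sum(mixture) - 1) <= 1e-9, "mixture must sum to 1")
  .check(!is.null(names(mixture)) && all(nzchar(names(mixture))),
         "mixture must be named by source")
  sources <- names(mixture)
  get_pattern <- function(src, amp) {
    if (!is.null(patterns) && !is.null(patterns[[src]]) &&
        !is.null(patterns[[src]][[amp$name]])) {
      return(patterns[[src]][[amp$name]])
    }
    if (identical(src, amp$cell_type)) {
      rep("U", length(amp$cpg_offsets))
    } else {
      rep("M", length(amp$cpg_offsets))
    }
  }
  .with_seed(config$seed, {
    pieces <- lapply(panel$amplicons, function(amp) {
      L <- nchar(amp$ref_seq)
      nd <- config$depth
      src <- sample(sources, nd, replace = TRUE, prob = mixture)
      M <- matrix(rep(.seq_to_int(amp$ref_seq), nd), nrow = L)
      # bisulfite conversion of non-CpG cytosines
      for (q in amp$noncpg_c_offsets) {
        conv <- stats::runif(nd) < config$conversion_rate
        M[q + 1L, conv] <- .INT_T
      }
      # CpG cytosines according to the source pattern
      pat <- vapply(sources, function(s)
        paste(get_pattern(s, amp), collapse = ""), character(1))
      for (k in seq_along(amp$cpg_offsets)) {
        st <- substr(pat[src], k, k)
        u <- st == "U"
        flip <- logical(nd)
        flip[u] <- stats::runif(sum(u)) < config$conversion_rate
        flip[!u] <- stats::runif(sum(!u)) < config$meth_fail
        M[amp$cpg_offsets[k] + 1L, flip] <- .INT_T
      }
      # substitution sequencing errors
      Q <- matrix(70L, nrow = L, ncol = nd)  # Q37
      nerr <- stats::rbinom(1, L * nd, config$sequencing_error)
      if (nerr > 0) {
        pos <- sample.int(L * nd, nerr)
        alt <- c(.INT_A, .INT_C, .INT_G, .INT_T)
        repl <- alt[(match(M[pos], alt) + sample(1:3, nerr, replace = TRUE) - 1L) %% 4L + 1L]
        M[pos] <- repl
        Q[pos] <- 47L  # Q14
      }
      seqs <- apply(M, 2, .int_to_seq)
      quals <- apply(Q, 2, .int_to_seq)
      # orientation flags are always drawn so that the molecular content is
      # identical for any frac_reverse under the same seed
      fl <- stats::runif(nd) < config$frac_reverse
      {
        if (any(fl)) {
          seqs[fl] <- .revcomp_chr(seqs[fl])
          quals[fl] <- vapply(quals[fl], function(s)
            .int_to_seq(rev(.seq_to_int(s))), character(1), USE.NAMES = FALSE)
        }
      }
      ids <- sprintf("%s_%06d_%s", amp$name, seq_len(nd), src)
      unmeth_truth <- !grepl("M", pat[src], fixed = TRUE)
      list(reads = data.frame(id = ids, seq = seqs, qual = quals,
                              stringsAsFactors = FALSE),
           truth = data.frame(read_id = ids, marker = amp$name, source = src,
                              unmeth_pattern = unmeth_truth,
                              stringsAsFactors = FALSE))
    })
    reads <- do.call(rbind, lapply(pieces, `[[`, "reads"))
    truth <- do.call(rbind, lapply(pieces, `[[`, "truth"))
    rownames(reads) <- rownames(truth) <- NULL
    if (!is.null(fastq)) write_fastq(reads, fastq)
    list(reads = reads, truth = truth)
  })
}

#' Simulate a methylation atlas with planted markers
#'
#' Background CpGs are methylated everywhere (betas 0.85-1.0, spaced 1 kb so
#' they never form dense windows). For each immune cell type,
#' `planted_per_type` marker CpGs are planted: hypomethylated (beta < 0.15)
#' in that cell type and 0.9-1.0 elsewhere, each surrounded by
#' `satellites_per_marker` additional CpGs within 75 bp (beta 0.5 in the
#' target so they never qualify themselves, high elsewhere) so the density
#' filter passes for planted CpGs only.
#'
#' @param cell_types Immune cell type column labels.
#' @param n_other_tissues Number of non-immune tissue columns (default 25,
#'   giving a 32-column atlas with the 7 immune types).
#' @param planted_per_type Qualifying markers planted per cell type.
#' @param n_background_cpgs Background (non-marker) CpGs.
#' @param satellites_per_marker Density satellites per planted marker.
#' @param seed RNG seed.
#' @return A list: `atlas` ([methylation_atlas()]) and `truth` (data.frame
#'   `cpg_id`, `role` in planted/satellite/background, `cell_type`).
#' @export
simulate_atlas <- function(cell_types = .IMMUNE_CELL_TYPES,
                           n_other_tissues = 25, planted_per_type = 12,
                           n_background_cpgs = 500,
                           satellites_per_marker = 5, seed = 1L) {
  .check(planted_per_type >= 0, "planted_per_type must be >= 0")
  cols <- c(cell_types, sprintf("tissue%02d", seq_len(n_other_tissues)))
  ncol_ <- length(cols)
  .with_seed(seed, {
    rows <- list(); ids <- character(); chrom <- character(); pos <- integer()
    roles <- character(); role_ct <- character()
    # background: methylated everywhere, 1 kb apart
    if (n_background_cpgs > 0) {
      bg <- matrix(stats::runif(n_background_cpgs * ncol_, 0.85, 1.0),
                   ncol = ncol_)
      rows <- c(rows, list(bg))
      ids <- c(ids, sprintf("bg%05d", seq_len(n_background_cpgs)))
      chrom <- c(chrom, rep("chr1", n_background_cpgs))
      pos <- c(pos, 1000000L + 1000L * seq_len(n_background_cpgs))
      roles <- c(roles, rep("background", n_background_cpgs))
      role_ct <- c(role_ct, rep(NA_character_, n_background_cpgs))
    }
    sat_d <- c(-60L, -40L, -20L, 20L, 40L, 60L, -70L, 70L)
    cluster <- 0L
    for (ti in seq_along(cell_types)) {
      tt <- cell_types[ti]
      for (j in seq_len(planted_per_type)) {
        cluster <- cluster + 1L
        centre_pos <- 10000000L + cluster * 1000L
        b <- stats::runif(ncol_, 0.9, 1.0)
        b[ti] <- stats::runif(1, 0, 0.15)
        rows <- c(rows, list(matrix(b, nrow = 1)))
        ids <- c(ids, sprintf("pl_%s_%02d", tt, j))
        chrom <- c(chrom, "chr2"); pos <- c(pos, centre_pos)
        roles <- c(roles, "planted"); role_ct <- c(role_ct, tt)
        for (s in seq_len(satellites_per_marker)) {
          bs <- stats::runif(ncol_, 0.9, 1.0)
          bs[ti] <- 0.5  # dense neighbour, but never a candidate itself
          rows <- c(rows, list(matrix(bs, nrow = 1)))
          ids <- c(ids, sprintf("sat_%s_%02d_%d", tt, j, s))
          chrom <- c(chrom, "chr2"); pos <- c(pos, centre_pos + sat_d[s])
          roles <- c(roles, "satellite"); role_ct <- c(role_ct, tt)
        }
      }
    }
    betas <- do.call(rbind, rows)
    colnames(betas) <- cols
    truth <- data.frame(cpg_id = ids, role = roles, cell_type = role_ct,
                        stringsAsFactors = FALSE)
    list(atlas = methylation_atlas(ids, chrom, pos, betas), truth = truth)
  })
}

#' Cohort scenario parameters
#'
#' Bundles the generative parameters of one cohort scenario. Healthy
#' baseline cfDNA means (GE/ml) are the published healthy-population values:
#' neutrophils 390, monocytes 101, eosinophils 38, T-cells 30, B-cells 17,
#' CD8 T-cells 8, Tregs 2. Blood counts have per-donor set points
#' (donor-level lognormal, sdlog 0.3) with small within-donor noise (sdlog
#' 0.08); cfDNA is generated from the turnover relation (cell number /
#' lifespan, folded into the baseline mean) with large shared lognormal
#' noise (sdlog 0.8) and no donor set point. Scenario effects: vaccination
#' raises B-cell cfDNA at day 3, peaks at day 7 and returns by day 28, with
#' larger peaks in responders, while B-cell counts rise only modestly from
#' day 7; EoE elevates eosinophil cfDNA in the active group (mean 115 vs 34
#' in controls) with counts unchanged; lymphoma elevates B-cell cfDNA (mean
#' 264.4 vs 18.3) while B-cell counts drop (0.079 vs 0.162 x 10^9/l).
#'
#' @param scenario One of "healthy", "vaccination", "eoe", "lymphoma".
#' @return A list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(scenario = c("healthy", "vaccination", "eoe",
                                         "lymphoma")) {
  scenario <- match.arg(scenario)
  base <- list(
    scenario = scenario,
    cell_types = .IMMUNE_CELL_TYPES,
    cf_baseline = c(neutrophil = 390, monocyte = 101, eosinophil = 38,
                    tcell = 30, bcell = 17, cd8 = 8, treg = 2),
    count_mean = c(neutrophil = 4.0, monocyte = 0.5, eosinophil = 0.2,
                   tcell = 1.5, bcell = 0.162, cd8 = 0.45, treg = 0.05),
    lifespan_rel = c(neutrophil = 1, monocyte = 0.6, eosinophil = 1,
                     tcell = 20, bcell = 15, cd8 = 20, treg = 10),
    count_set_sdlog = 0.30, count_within_sdlog = 0.08, cf_sdlog = 0.80,
    n_donors = 15, timepoints = sprintf("W%d", 1:6))
  extra <- switch(scenario,
    healthy = list(),
    vaccination = list(
      n_donors = 92, timepoints = c("D0", "D3", "D7", "D28"),
      responder_rate = 0.8,
      cf_fold_responder = c(D0 = 1, D3 = 2.5, D7 = 3.5, D28 = 1),
      cf_fold_nonresponder = c(D0 = 1, D3 = 1.3, D7 = 1.4, D28 = 1),
      count_fold = c(D0 = 1, D3 = 1, D7 = 1.2, D28 = 1.15),
      strains = c("H1N1", "H3", "YAMA", "VIC")),
    eoe = list(
      timepoints = "T1",
      group_sizes = c(active = 21, inactive = 24, control = 14),
      eos_cf_mean = c(active = 115, inactive = 36, control = 34)),
    lymphoma = list(
      timepoints = "T1",
      group_sizes = c(lymphoma = 17, control = 23),
      b_cf_mean = c(lymphoma = 264.4, control = 18.3),
      b_count_mean = c(lymphoma = 0.079, control = 0.162)))
  structure(c(base[setdiff(names(base), names(extra))], extra),
            class = "cohort_scenario")
}

#' Simulate a longitudinal cohort
#'
#' Generates matched cfDNA (GE/ml), CBC (10^9 cells/l) and whole-blood
#' methylation (cell-type fraction of counts) tables under a
#' [cohort_scenario()]. Counts fluctuate around per-donor set points; cfDNA
#' has population-level variability only, so by construction counts show
#' intra < inter individual variation while cfDNA varies similarly within
#' and between individuals. Deterministic per seed.
#'
#' @param scenario A [cohort_scenario()] or scenario name.
#' @param n_donors Optional override of the scenario's donor count.
#' @param timepoints Optional override of the scenario's timepoints.
#' @param seed RNG seed.
#' @return A list: `table` (long data.frame `donor_id`, `timepoint`,
#'   `source`, `analyte`, `value`, `units`), `titers` (vaccination only),
#'   `truth` (data.frame per donor: `donor_id`, `group`, `responder`, plus
#'   count set points as `sp_<cell type>` columns).
#' @export
simulate_cohort <- function(scenario = "healthy", n_donors = NULL,
                            timepoints = NULL, seed = 1L) {
  if (is.character(scenario)) scenario <- cohort_scenario(scenario)
  stopifnot(inherits(scenario, "cohort_scenario"))
  sc <- scenario
  cts <- sc$cell_types
  if (is.null(timepoints)) timepoints <- sc$timepoints
  .with_seed(seed, {
    # donors and groups
    if (!is.null(sc$group_sizes)) {
      groups <- rep(names(sc$group_sizes), sc$group_sizes)
      if (!is.null(n_donors)) groups <- rep(names(sc$group_sizes),
                                            length.out = n_donors)
      nd <- length(groups)
    } else {
      nd <- if (is.null(n_donors)) sc$n_donors else n_donors
      groups <- rep(sc$scenario, nd)
    }
    donors <- sprintf("donor%03d", seq_len(nd))
    responder <- rep(NA, nd)
    if (sc$scenario == "vaccination") {
      responder <- stats::runif(nd) < sc$responder_rate
      responder[1] <- NA  # donor with baseline antibodies to all strains
    }
    # per-donor, per-cell-type means (group effects applied to the means)
    cf_mean <- matrix(rep(sc$cf_baseline[cts], each = nd), nrow = nd,
                      dimnames = list(donors, cts))
    ct_mean <- matrix(rep(sc$count_mean[cts], each = nd), nrow = nd,
                      dimnames = list(donors, cts))
    if (sc$scenario == "eoe") {
      cf_mean[, "eosinophil"] <- sc$eos_cf_mean[groups]
    }
    if (sc$scenario == "lymphoma") {
      cf_mean[, "bcell"] <- sc$b_cf_mean[groups]
      ct_mean[, "bcell"] <- sc$b_count_mean[groups]
    }
    # count set points: donor-level lognormal around the (group) mean
    sp <- ct_mean * exp(matrix(stats::rnorm(nd * length(cts),
                                            -sc$count_set_sdlog^2 / 2,
                                            sc$count_set_sdlog), nrow = nd))
    nt <- length(timepoints)
    grid <- expand.grid(d = seq_len(nd), t = seq_len(nt), ct = seq_along(cts))
    within <- exp(stats::rnorm(nrow(grid), -sc$count_within_sdlog^2 / 2,
                               sc$count_within_sdlog))
    counts <- sp[cbind(grid$d, grid$ct)] * within
    if (sc$scenario == "vaccination") {
      isb <- cts[grid$ct] == "bcell"
      counts[isb] <- counts[isb] * sc$count_fold[timepoints[grid$t[isb]]]
    }
    # cfDNA: turnover link (instantaneous count / lifespan) scaled to the
    # group baseline mean, with large population-level lognormal noise and
    # no donor set point beyond what the count link carries
    cf_noise <- exp(stats::rnorm(nrow(grid), -sc$cf_sdlog^2 / 2, sc$cf_sdlog))
    cf <- cf_mean[cbind(grid$d, grid$ct)] *
      (counts / ct_mean[cbind(grid$d, grid$ct)]) * cf_noise
    if (sc$scenario == "vaccination") {
      isb <- cts[grid$ct] == "bcell"
      fold <- ifelse(is.na(responder[grid$d]) | responder[grid$d],
                     sc$cf_fold_responder[timepoints[grid$t]],
                     sc$cf_fold_nonresponder[timepoints[grid$t]])
      cf[isb] <- cf[isb] * fold[isb]
    }
    # whole-blood methylation: cell-type fraction of total counts
    tot <- tapply(counts, list(grid$d, grid$t), sum)
    wb <- counts / tot[cbind(grid$d, grid$t)] *
      exp(stats::rnorm(nrow(grid), 0, 0.03))
    long <- rbind(
      data.frame(donor_id = donors[grid$d], timepoint = timepoints[grid$t],
                 source = "cfDNA", analyte = cts[grid$ct], value = cf,
                 units = "GE/ml", stringsAsFactors = FALSE),
      data.frame(donor_id = donors[grid$d], timepoint = timepoints[grid$t],
                 source = "CBC", analyte = cts[grid$ct], value = counts,
                 units = "1e9/l", stringsAsFactors = FALSE),
      data.frame(donor_id = donors[grid$d], timepoint = timepoints[grid$t],
                 source = "whole_blood", analyte = cts[grid$ct], value = wb,
                 units = "fraction", stringsAsFactors = FALSE))
    rownames(long) <- NULL
    titers <- NULL
    if (sc$scenario == "vaccination") {
      ns <- length(sc$strains)
      titers <- expand.grid(donor_id = donors, strain = sc$strains,
                            stringsAsFactors = FALSE)
      titers$baseline_titer <- 20
      titers$baseline_titer[titers$donor_id == donors[1]] <- 80
      titers$post_titer <- 20
      for (d in which(!is.na(responder) & responder)) {
        s <- sample(sc$strains, 1)
        titers$post_titer[titers$donor_id == donors[d] & titers$strain == s] <- 160
      }
      titers$post_titer[titers$donor_id == donors[1]] <- 160
    }
    truth <- data.frame(donor_id = donors, group = groups,
                        responder = responder, stringsAsFactors = FALSE)
    colnames(sp) <- paste0("sp_", cts)
    truth <- cbind(truth, as.data.frame(sp, row.names = NULL))
    list(table = long, titers = titers, truth = truth)
  })
}
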