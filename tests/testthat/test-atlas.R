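# Marker discovery from the methylation atlas.

test_that("load_atlas parses, validates bounds and ids, loads 32 columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(cpg_id = c("cg1", "cg2"), chrom = "chr1", pos = c(100, 200),
                   a = 0.5, b = 0.5, c = 0.5)
  make_atlas_file(df, f)
  at <- load_atlas(f)
  expect_s3_class(at, "methylation_atlas")
  expect_equal(dim(at$betas), c(2L, 3L))

  df_bad <- df; df_bad$b[2] <- 1.2
  make_atlas_file(df_bad, f)
  expect_error(load_atlas(f), "cg2")

  df_dup <- df; df_dup$cpg_id <- c("cg1", "cg1")
  make_atlas_file(df_dup, f)
  expect_error(load_atlas(f), "duplicate")

  # a 32-column atlas (7 immune types + 25 tissues) round-trips
  sim <- simulate_atlas(n_background_cpgs = 20, planted_per_type = 1, seed = 3)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(sim$atlas, f2)
  at2 <- load_atlas(f2)
  expect_length(at2$samples, 32L)
  expect_equal(at2$betas, sim$atlas$betas)
})

test_that("candidate thresholds behave exactly at the 0.3 / 0.8 / 90% rule", {
  # 1 target column + 31 others
  mk_row <- function(bt, n_hi, hi = 0.95, lo = 0.5) c(bt, rep(hi, n_hi), rep(lo, 31 - n_hi))
  betas <- rbind(extreme = mk_row(0.0, 31, hi = 1.0),
                 pass = mk_row(0.29, 29),    # 29/31 = 93.5% > 90%
                 failfrac = mk_row(0.29, 27), # 27/31 = 87.1%
                 failbeta = mk_row(0.31, 31))
  at <- methylation_atlas(rownames(betas), rep("chr1", 4), (1:4) * 1000, betas,
                          groups = c("target", paste0("o", 1:31)))
  cand <- find_candidate_cpgs(at, "target")
  expect_setequal(cand$cpg_id, c("extreme", "pass"))
  expect_equal(cand$fraction_other_above[cand$cpg_id == "pass"], 29 / 31)
  expect_error(find_candidate_cpgs(at, "nosuch"), "unknown target")
})

test_that("find_candidate_cpgs equals the brute-force oracle on a random atlas", {
  set.seed(41)
  n <- 1000
  groups <- c("target", "target", paste0("o", 1:30))  # 2 target columns
  betas <- matrix(runif(n * 32), ncol = 32)
  # plant clear markers and near-threshold rows so the hit set is
  # non-trivial on both sides of every predicate
  hot <- sample(n, 40)
  betas[hot, 1:2] <- runif(80, 0, 0.4)
  betas[hot[1:20], 3:32] <- runif(20 * 30, 0.82, 1)     # all above 0.8
  betas[hot[21:40], 3:32] <- runif(20 * 30, 0.75, 0.95) # borderline
  at <- methylation_atlas(sprintf("cg%04d", 1:n), rep("chr1", n),
                          seq(1, by = 500, length.out = n), betas, groups)
  crit <- marker_criteria()
  got <- find_candidate_cpgs(at, "target", crit)
  expect_setequal(got$cpg_id, oracle_candidates(at, "target", crit))
  expect_gt(nrow(got), 0)
})

test_that("missing betas are averaged out and over-missing CpGs are skipped", {
  betas <- matrix(0.95, nrow = 2, ncol = 10)
  betas[1, 1] <- 0.1; betas[1, 3:4] <- NA        # 20% missing: kept
  betas[2, 1] <- 0.1; betas[2, 3:5] <- NA        # 30% missing: skipped
  at <- methylation_atlas(c("ok", "gappy"), c("chr1", "chr1"), c(100, 200),
                          betas, groups = c("t", paste0("o", 1:9)))
  expect_message(cand <- find_candidate_cpgs(at, "t"), "skipped")
  expect_equal(cand$cpg_id, "ok")
})

test_that("density_filter applies the >5-CpGs-in-150bp rule and matches brute force", {
  # cluster of 6 CpGs within 150 bp; cluster of 5; an isolated CpG
  pos <- c(1000, 1020, 1040, 1060, 1070, 1075,      # 6 within +-75 of 1040
           5000, 5030, 5060, 5090, 5120,            # 5 within +-75 of 5060
           9000)
  n <- length(pos)
  betas <- matrix(0.95, n, 5)
  betas[, 1] <- 0.1
  at <- methylation_atlas(sprintf("cg%02d", 1:n), rep("chr1", n), pos, betas,
                          groups = c("t", "o1", "o2", "o3", "o4"))
  cand <- find_candidate_cpgs(at, "t")
  kept <- density_filter(cand, at)
  expect_true("cg03" %in% kept$cpg_id)   # centre of the 6-cluster
  expect_false("cg09" %in% kept$cpg_id)  # centre of the 5-cluster
  expect_false("cg12" %in% kept$cpg_id)  # singleton
  expect_equal(kept$n_cpgs_in_window,
               unname(oracle_window_counts(at, kept$cpg_id, 150)))

  # agreement with exhaustive counting on a 200-CpG synthetic chromosome
  set.seed(7)
  pos2 <- sort(sample(1:20000, 200))
  at2 <- methylation_atlas(sprintf("x%03d", 1:200), rep("chr2", 200), pos2,
                           matrix(c(rep(0.05, 200), rep(0.95, 600)), ncol = 4),
                           groups = c("t", "o1", "o2", "o3"))
  cand2 <- find_candidate_cpgs(at2, "t")
  kept2 <- density_filter(cand2, at2)
  counts <- oracle_window_counts(at2, cand2$cpg_id, 150)
  expect_setequal(kept2$cpg_id, cand2$cpg_id[counts >= 6])
  expect_error(density_filter(data.frame(cpg_id = "zz", chrom = "chr2",
                                         pos = 1, target_cell_type = "t"),
                              at2), "absent")
})

test_that("select_top_k ranks by margin, breaks ties by coordinate, warns on shortfall", {
  cand <- data.frame(cpg_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(300, 100, 200), target_cell_type = "t",
                     beta_target = 0.1, mean_other = 0.9,
                     fraction_other_above = 1,
                     margin = c(0.8, 0.8, 0.9), n_cpgs_in_window = 6L)
  crit <- marker_criteria(top_k = 2)
  sel <- select_top_k(cand, crit)
  expect_equal(sel$cpg_id, c("c", "b"))  # margin first, then position
  expect_identical(sel, select_top_k(cand, crit))  # deterministic
  expect_warning(select_top_k(cand, marker_criteria(top_k = 10)), "only 3")
})

test_that("selection is idempotent and monotone in the thresholds", {
  sim <- simulate_atlas(planted_per_type = 12, n_background_cpgs = 200, seed = 11)
  at <- sim$atlas
  crit <- marker_criteria()
  sel <- discover_markers(at, "bcell", crit)
  # idempotence: re-running selection on its own candidate rows is stable
  again <- select_top_k(density_filter(sel, at, crit), crit)
  expect_setequal(again$cpg_id, sel$cpg_id)
  # monotonicity: tightening any threshold never enlarges the candidate set
  base <- find_candidate_cpgs(at, "bcell", crit)
  for (tight in list(marker_criteria(beta_target_max = 0.2),
                     marker_criteria(beta_other_min = 0.9),
                     marker_criteria(other_pass_fraction = 0.95))) {
    expect_true(all(find_candidate_cpgs(at, "bcell", tight)$cpg_id
                    %in% base$cpg_id))
  }
})

test_that("planted atlas yields exactly min(P, top_k) selections per type", {
  sim <- simulate_atlas(planted_per_type = 3, n_background_cpgs = 100, seed = 5)
  suppressWarnings(
    sel <- discover_markers(sim$atlas, c("neutrophil", "treg")))
  expect_equal(as.integer(table(sel$target_cell_type)[c("neutrophil", "treg")]),
               c(3L, 3L))
  sim0 <- simulate_atlas(planted_per_type = 0, n_background_cpgs = 100, seed = 5)
  expect_equal(nrow(find_candidate_cpgs(sim0$atlas, "neutrophil")), 0L)
})
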