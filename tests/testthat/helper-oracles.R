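# Independent oracles used by the property/equivalence tests. These are
# deliberately naive re-implementations (plain loops and string ops) that
# share no code with the package internals they check.

# ---- marker discovery ----

# brute-force per-CpG candidate scan: one loop, literal predicates
oracle_candidates <- function(atlas, target, crit) {
  hits <- character()
  tcols <- which(atlas$groups == target)
  ocols <- which(atlas$groups != target)
  for (i in seq_along(atlas$cpg_ids)) {
    row <- atlas$betas[i, ]
    if (mean(is.na(row)) > crit$max_missing_fraction) next
    bt <- mean(row[tcols], na.rm = TRUE)
    ov <- row[ocols]
    ov <- ov[!is.na(ov)]
    if (length(ov) == 0 || is.nan(bt)) next
    if (bt < crit$beta_target_max &&
        sum(ov > crit$beta_other_min) / length(ov) > crit$other_pass_fraction) {
      hits <- c(hits, atlas$cpg_ids[i])
    }
  }
  hits
}

# exhaustive window counting
oracle_window_counts <- function(atlas, cand_ids, window_bp) {
  vapply(cand_ids, function(id) {
    i <- match(id, atlas$cpg_ids)
    sum(atlas$chrom == atlas$chrom[i] &
          abs(atlas$pos - atlas$pos[i]) <= window_bp / 2)
  }, integer(1))
}

# ---- read interpretation ----

# bisulfite conversion by string substitution (CpG C -> Y, other C -> T)
oracle_convert <- function(seq) {
  gsub("C", "T", gsub("CG", "YG", seq, fixed = TRUE), fixed = TRUE)
}

# naive per-read interpreter implementing the documented pipeline semantics
# position by position
oracle_interpret <- function(seq, qual, panel, min_identity = 80,
                             min_quality = 30, min_conversion = 0.95) {
  if (mean(utf8ToInt(qual) - 33) < min_quality) {
    return(list(marker = NA, reason = "low_quality", unmeth = FALSE))
  }
  ident_at <- function(read, ref) {
    # best ungapped identity over all containment offsets, both given as
    # character vectors; Y in ref matches C or T
    Lr <- length(read); La <- length(ref)
    best <- -1; bestoff <- NA; bestlen <- min(Lr, La)
    offs <- 0:abs(La - Lr)
    for (off in offs) {
      m <- 0
      for (k in seq_len(bestlen)) {
        rb <- if (Lr <= La) read[k] else read[off + k]
        fb <- if (Lr <= La) ref[off + k] else ref[k]
        if (rb == fb || (fb == "Y" && rb %in% c("C", "T"))) m <- m + 1
      }
      idv <- 100 * m / bestlen
      if (idv > best) { best <- idv; bestoff <- if (Lr <= La) off else -off }
    }
    list(identity = best, shift = bestoff)
  }
  rc <- function(x) rev(chartr("ACGT", "TGCA", x))
  rchars <- strsplit(seq, "")[[1]]
  best_id <- -1; best_amp <- NA; best_shift <- NA; best_ori <- NA; nbest <- 0
  for (nm in names(panel$amplicons)) {
    ref <- strsplit(oracle_convert(panel$amplicons[[nm]]$ref_seq), "")[[1]]
    fw <- ident_at(rchars, ref)
    rv <- ident_at(rc(rchars), ref)
    hit <- if (rv$identity > fw$identity) c(rv, ori = "-") else c(fw, ori = "+")
    if (hit$identity > best_id) {
      best_id <- hit$identity; best_amp <- nm
      best_shift <- hit$shift; best_ori <- hit$ori; nbest <- 1
    } else if (hit$identity == best_id) nbest <- nbest + 1
  }
  if (best_id < min_identity) {
    return(list(marker = NA, reason = "low_identity", unmeth = FALSE))
  }
  if (nbest > 1) {
    return(list(marker = NA, reason = "ambiguous_assignment", unmeth = FALSE))
  }
  amp <- panel$amplicons[[best_amp]]
  oriented <- if (best_ori == "-") rc(rchars) else rchars
  L <- length(oriented)
  ref_chars <- strsplit(amp$ref_seq, "")[[1]]
  cpg0 <- which(vapply(seq_len(length(ref_chars) - 1), function(i)
    ref_chars[i] == "C" && ref_chars[i + 1] == "G", logical(1))) - 1L
  calls <- vapply(cpg0, function(p) {
    r <- p - best_shift + 1
    if (r < 1 || r + 1 > L) return("absent")
    d <- paste0(oriented[r], oriented[r + 1])
    if (d == "TG") "U" else if (d == "CG") "M" else "A"
  }, character(1))
  if (any(calls == "absent")) {
    return(list(marker = best_amp, reason = "missing_cpgs", unmeth = FALSE))
  }
  if (sum(calls == "A") > 1) {
    return(list(marker = best_amp, reason = "missing_cpgs", unmeth = FALSE))
  }
  qc0 <- which(ref_chars == "C") - 1L  # all C offsets, 0-based
  qc0 <- qc0[vapply(qc0, function(p)   # keep Cs not followed by G
    p + 2 > length(ref_chars) || ref_chars[p + 2] != "G", logical(1))]
  covered <- qc0[qc0 - best_shift + 1 >= 1 & qc0 - best_shift + 1 <= L]
  if (length(covered) > 0) {
    conv <- mean(oriented[covered - best_shift + 1] == "T")
    if (conv < min_conversion) {
      return(list(marker = best_amp, reason = "poor_conversion", unmeth = FALSE))
    }
  }
  dev <- which(calls != "U")
  unmeth <- if (any(calls == "A")) FALSE
  else if (amp$unmeth_rule == "strict") length(dev) == 0
  else length(dev) == 0 ||
    (length(dev) == 1 &&
       (length(amp$exempt_cpgs) == 0 || dev %in% amp$exempt_cpgs))
  list(marker = best_amp, reason = "none", unmeth = unmeth)
}

# ---- statistics ----

# exact one-sided rank-sum p by enumeration of all group assignments
oracle_ranksum_p_less <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(all_v), n1)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  us <- apply(combos, 2, function(ix) u_of(all_v[ix], all_v[-ix]))
  mean(us <= u_obs)
}

# small helpers for building fixtures
tiny_amplicon <- function(name = "TOY1", cell_type = "toy",
                          seq = "TACGGATCGTTA") {
  amplicon_def(name, cell_type, "chrT", 0, nchar(seq), seq)
}

make_atlas_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
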