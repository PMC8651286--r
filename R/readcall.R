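# Interpretation of demultiplexed bisulfite amplicon reads: assignment to
# panel markers, quality / identity / conversion filters, per-CpG
# methylation calls and the per-marker fraction of fully unmethylated
# molecules.
#
# Matching is ungapped: amplicons are primer-defined so indels are rare, and
# a sliding-offset comparison of the read against each bisulfite-converted
# reference (CpG positions wildcarded to match C or T) in both orientations
# is sufficient and deterministic. Identity = matches / aligned reference
# length, in percent.

#' Read-calling configuration
#'
#' @param min_identity Minimum percent identity to a converted reference for
#'   a read to be assigned (80: reads need at least 80% similarity to a
#'   target sequence).
#' @param min_mean_quality Minimum mean Phred quality (30; the assay filters
#'   on Illumina quality scores without a published threshold, so a common
#'   amplicon QC default is used).
#' @param min_conversion Minimum bisulfite conversion rate, measured on
#'   non-CpG cytosines, when defined (0.95).
#' @param require_all_cpgs Reject reads that do not cover every expected CpG
#'   of their marker (TRUE).
#' @return A list of class `readcall_config`.
#' @export
readcall_config <- function(min_identity = 80, min_mean_quality = 30,
                            min_conversion = 0.95, require_all_cpgs = TRUE) {
  structure(list(min_identity = min_identity,
                 min_mean_quality = min_mean_quality,
                 min_conversion = min_conversion,
                 require_all_cpgs = require_all_cpgs),
            class = "readcall_config")
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file (optionally gzipped).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(ss),
             seq = as.character(ss),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# precompute integer-coded references for matching
.prep_refs <- function(panel) {
  lapply(panel$amplicons, function(a) {
    v <- .seq_to_int(a$converted)
    list(name = a$name, v = v, wild = v == .INT_Y, La = length(v),
         cpg = a$cpg_offsets, noncpg_c = a$noncpg_c_offsets,
         rule = a$unmeth_rule, exempt = a$exempt_cpgs)
  })
}

.comp_table <- function() {
  comp <- integer(96)
  comp[.INT_A] <- .INT_T; comp[.INT_T] <- .INT_A
  comp[.INT_C] <- .INT_G; comp[.INT_G] <- .INT_C
  comp[.INT_N] <- .INT_N
  comp
}

# Align a set of equal-length reads (int matrix L x n) to one reference at
# every valid ungapped offset; returns best identity and the alignment shift
# (ref position of read base 1, 0-based; negative when the read overhangs
# the reference start).
.align_matrix_ref <- function(M, ref) {
  L <- nrow(M); n <- ncol(M)
  best <- numeric(n); shift <- integer(n)
  if (L <= ref$La) {
    for (off in 0:(ref$La - L)) {
      sl <- (off + 1):(off + L)
      eq <- (M == ref$v[sl]) | (ref$wild[sl] & (M == .INT_C | M == .INT_T))
      idv <- 100 * colSums(eq) / L
      upd <- idv > best
      best[upd] <- idv[upd]; shift[upd] <- off
    }
  } else {
    for (off in 0:(L - ref$La)) {
      eq <- (M[(off + 1):(off + ref$La), , drop = FALSE] == ref$v) |
        (ref$wild & (M[(off + 1):(off + ref$La), , drop = FALSE] == .INT_C |
                       M[(off + 1):(off + ref$La), , drop = FALSE] == .INT_T))
      idv <- 100 * colSums(eq) / ref$La
      upd <- idv > best
      best[upd] <- idv[upd]; shift[upd] <- -off
    }
  }
  list(identity = best, shift = shift)
}

# Vectorised assignment of reads to a panel. Returns one row per read:
# marker index (NA if none), identity of best match, shift, orientation,
# and reason ("none", "low_identity", "ambiguous_assignment").
.assign_reads <- function(seqs, refs, min_identity) {
  n <- length(seqs)
  out <- data.frame(marker = rep(NA_integer_, n), identity = numeric(n),
                    shift = integer(n), orient = rep("+", n),
                    reason = rep("low_identity", n), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  lens <- nchar(seqs)
  na <- length(refs)
  comp <- .comp_table()
  for (L in unique(lens)) {
    idx <- which(lens == L)
    Mf <- matrix(utf8ToInt(paste(seqs[idx], collapse = "")), nrow = L)
    Mr <- matrix(comp[Mf[L:1, , drop = FALSE]], nrow = L)
    idmat <- matrix(-1, nrow = na, ncol = length(idx))
    shmat <- matrix(0L, nrow = na, ncol = length(idx))
    ormat <- matrix("+", nrow = na, ncol = length(idx))
    for (ai in seq_len(na)) {
      fw <- .align_matrix_ref(Mf, refs[[ai]])
      rv <- .align_matrix_ref(Mr, refs[[ai]])
      use_rv <- rv$identity > fw$identity
      idmat[ai, ] <- ifelse(use_rv, rv$identity, fw$identity)
      shmat[ai, ] <- ifelse(use_rv, rv$shift, fw$shift)
      ormat[ai, ] <- ifelse(use_rv, "-", "+")
    }
    bi <- max.col(t(idmat), ties.method = "first")
    sel <- cbind(bi, seq_along(idx))
    bid <- idmat[sel]
    nmax <- colSums(idmat == rep(bid, each = na))
    pass <- bid >= min_identity
    amb <- pass & nmax > 1
    ok <- pass & nmax == 1
    out$identity[idx] <- bid
    out$reason[idx][amb] <- "ambiguous_assignment"
    out$reason[idx][ok] <- "none"
    out$marker[idx][ok] <- bi[ok]
    out$shift[idx][ok] <- shmat[sel][ok]
    out$orient[idx][ok] <- ormat[sel][ok]
  }
  out
}

#' Assign one read to a panel marker
#'
#' Compares the read, in both orientations, against every bisulfite-converted
#' reference of the panel at every ungapped offset; CpG wildcard positions
#' match C or T. The best marker is returned when its identity reaches
#' `min_identity` percent and is uniquely best; equal-best matches give
#' `ambiguous_assignment`.
#'
#' @param seq Read sequence (character).
#' @param panel An [amplicon_panel()].
#' @param min_identity Percent identity threshold (default 80).
#' @return A list: `marker` (name or NA), `identity`, `shift` (0-based ref
#'   position of read base 1; negative = read overhangs the reference),
#'   `orientation` ("+"/"-"), `reason` ("none", "low_identity",
#'   "ambiguous_assignment").
#' @export
assign_read <- function(seq, panel, min_identity = 80) {
  refs <- .prep_refs(panel)
  r <- .assign_reads(toupper(seq), refs, min_identity)
  list(marker = if (is.na(r$marker)) NA_character_ else refs[[r$marker]]$name,
       identity = r$identity, shift = r$shift, orientation = r$orient,
       reason = r$reason)
}

# codes: 0 absent, 1 unmethylated, 2 methylated, 3 ambiguous
.CALL_LABELS <- c("absent", "U", "M", "A")

# per-CpG call codes for a group of oriented reads (int matrix M, common
# alignment shift) against one amplicon; returns ncpg x n integer matrix
.call_codes <- function(M, shift, ref) {
  L <- nrow(M); n <- ncol(M)
  ncpg <- length(ref$cpg)
  codes <- matrix(0L, nrow = ncpg, ncol = n)
  for (k in seq_len(ncpg)) {
    r1 <- ref$cpg[k] - shift + 1L
    if (r1 >= 1 && r1 + 1 <= L) {
      b1 <- M[r1, ]; b2 <- M[r1 + 1, ]
      codes[k, ] <- ifelse(b1 == .INT_T & b2 == .INT_G, 1L,
                           ifelse(b1 == .INT_C & b2 == .INT_G, 2L, 3L))
    }
  }
  codes
}

#' Call CpG methylation states on an assigned read
#'
#' Per CpG of the amplicon: a read dinucleotide `CG` is methylated, `TG` is
#' unmethylated, any other dinucleotide is ambiguous, and CpGs outside the
#' read span are absent.
#'
#' @param seq Read sequence, in reference orientation (reverse-complement it
#'   first if the read was assigned on "-").
#' @param amplicon An [amplicon_def()].
#' @param shift Alignment shift from [assign_read()] (default 0).
#' @return Character vector over the amplicon's CpGs with values
#'   `"U"`, `"M"`, `"A"`, `"absent"`.
#' @export
call_cpgs <- function(seq, amplicon, shift = 0L) {
  ref <- list(cpg = amplicon$cpg_offsets)
  M <- matrix(.seq_to_int(toupper(seq)), ncol = 1)
  codes <- .call_codes(M, as.integer(shift), ref)
  .CALL_LABELS[codes[, 1] + 1L]
}

#' Bisulfite conversion rate of a read
#'
#' Fraction of the reference's non-CpG cytosine positions covered by the
#' read that appear as T. Unmethylated non-CpG cytosines should always
#' convert, so this measures bisulfite conversion efficiency. Undefined (NA)
#' when the read covers no such position.
#'
#' @inheritParams call_cpgs
#' @return A fraction in \[0,1\], or NA when undefined.
#' @export
conversion_rate <- function(seq, amplicon, shift = 0L) {
  v <- .seq_to_int(toupper(seq))
  rows <- amplicon$noncpg_c_offsets - as.integer(shift) + 1L
  rows <- rows[rows >= 1 & rows <= length(v)]
  if (length(rows) == 0) return(NA_real_)
  mean(v[rows] == .INT_T)
}

#' Classify a molecule as fully unmethylated
#'
#' Under the `strict` rule every CpG call must be unmethylated. Under
#' `allow_one_exception` at most one call may deviate; when `exempt` indices
#' are given the deviation must be at an exempt CpG. Any ambiguous call
#' disqualifies the molecule.
#'
#' @param calls Character vector of calls (`"U"`, `"M"`, `"A"`); must contain
#'   no `"absent"` (such reads are rejected upstream).
#' @param rule `"strict"` or `"allow_one_exception"`.
#' @param exempt 1-based indices of exemptable CpGs (empty = any single one).
#' @return TRUE if the molecule counts as fully unmethylated.
#' @export
classify_molecule <- function(calls, rule = c("strict", "allow_one_exception"),
                              exempt = integer()) {
  rule <- match.arg(rule)
  .check(!any(calls == "absent"), "calls contain absent CpGs; read should have been rejected")
  if (any(calls == "A")) return(FALSE)
  dev <- which(calls != "U")
  if (rule == "strict") return(length(dev) == 0)
  length(dev) == 0 ||
    (length(dev) == 1 && (length(exempt) == 0 || dev %in% exempt))
}

#' Tally a sample's reads into per-marker unmethylated-molecule fractions
#'
#' Runs the full read-interpretation pipeline: mean-quality filter, marker
#' assignment (identity filter, both orientations), per-CpG methylation
#' calls, bisulfite-conversion QC on non-CpG cytosines, and molecule
#' classification under each marker's unmethylated-call rule. Every input
#' read ends up retained or in exactly one reject category.
#'
#' @param reads A FASTQ path or a data.frame with columns `id`, `seq` and
#'   optionally `qual`.
#' @param panel An [amplicon_panel()].
#' @param config A [readcall_config()].
#' @param per_read Also return the per-read assessment table (slower; default
#'   FALSE).
#' @return A list with:
#'   * `counts`: data.frame per marker: `marker`, `cell_type`,
#'     `n_total_assigned`, `n_retained`, `n_fully_unmethylated`, `fraction`
#'     (NA when no read retained), `mean_conversion`;
#'   * `summary`: list with `n_reads`, `reject_tallies` (named vector over
#'     reject reasons + "none"), `mean_conversion`;
#'   * `assessments` (if `per_read`): data.frame per read with `read_id`,
#'     `marker`, `identity`, `mean_quality`, `cpg_calls`, `conversion_rate`,
#'     `fully_unmethylated`, `retained`, `reject_reason`.
#' @export
tally_sample <- function(reads, panel, config = readcall_config(),
                         per_read = FALSE) {
  stopifnot(inherits(panel, "amplicon_panel"))
  if (is.character(reads)) reads <- read_fastq(reads)
  .check(all(c("id", "seq") %in% names(reads)), "reads need columns id, seq")
  n <- nrow(reads)
  seqs <- toupper(reads$seq)
  has_qual <- "qual" %in% names(reads) && !all(is.na(reads$qual))

  # mean Phred quality per read
  if (has_qual) {
    mq <- vapply(reads$qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                 USE.NAMES = FALSE)
  } else {
    mq <- rep(Inf, n)
  }

  # collapse duplicate (seq, qual-pass) reads: the pipeline is a pure
  # function of the sequence once the quality filter is decided
  qpass <- mq >= config$min_mean_quality
  key <- paste0(qpass, "\r", seqs)
  first <- !duplicated(key)
  uidx <- which(first)
  map <- match(key, key[first])
  w <- tabulate(map, nbins = length(uidx))
  useq <- seqs[uidx]
  uqpass <- qpass[uidx]

  refs <- .prep_refs(panel)
  na_ <- length(refs)
  u_n <- length(uidx)
  u_marker <- rep(NA_integer_, u_n)
  u_identity <- rep(NA_real_, u_n)
  u_reason <- rep("low_quality", u_n)
  u_conv <- rep(NA_real_, u_n)
  u_calls <- rep(NA_character_, u_n)
  u_unmeth <- rep(FALSE, u_n)

  al_idx <- which(uqpass)
  if (length(al_idx) > 0) {
    al <- .assign_reads(useq[al_idx], refs, config$min_identity)
    u_identity[al_idx] <- al$identity
    u_reason[al_idx] <- al$reason
    u_marker[al_idx] <- al$marker
    assigned <- al_idx[!is.na(al$marker)]
    if (length(assigned) > 0) {
      ai <- al$marker[!is.na(al$marker)]
      ash <- al$shift[!is.na(al$marker)]
      aor <- al$orient[!is.na(al$marker)]
      alen <- nchar(useq[assigned])
      gkey <- paste(ai, aor, ash, alen)
      for (g in unique(gkey)) {
        gi <- which(gkey == g)
        ridx <- assigned[gi]
        ref <- refs[[ai[gi[1]]]]
        L <- alen[gi[1]]
        M <- matrix(utf8ToInt(paste(useq[ridx], collapse = "")), nrow = L)
        if (aor[gi[1]] == "-") M <- matrix(.comp_table()[M[L:1, , drop = FALSE]], nrow = L)
        shift <- ash[gi[1]]
        codes <- .call_codes(M, shift, ref)
        n_absent <- sum(rowSums(codes == 0L) > 0)
        n_ambig <- colSums(codes == 3L)
        n_meth <- colSums(codes == 2L)
        # conversion QC on covered non-CpG C positions
        crow <- ref$noncpg_c - shift + 1L
        crow <- crow[crow >= 1 & crow <= L]
        conv <- if (length(crow) > 0) {
          colMeans(M[crow, , drop = FALSE] == .INT_T)
        } else rep(NA_real_, length(ridx))
        u_conv[ridx] <- conv
        reason <- rep("none", length(ridx))
        if (config$require_all_cpgs && n_absent > 0) {
          reason[] <- "missing_cpgs"
        } else {
          reason[n_ambig > 1] <- "missing_cpgs"
          bad_conv <- !is.na(conv) & conv < config$min_conversion
          reason[reason == "none" & bad_conv] <- "poor_conversion"
        }
        ok <- reason == "none"
        unmeth <- rep(FALSE, length(ridx))
        if (any(ok)) {
          if (ref$rule == "strict") {
            unmeth[ok] <- n_meth[ok] == 0 & n_ambig[ok] == 0
          } else {
            cand <- ok & n_ambig == 0 & n_meth <= 1
            if (length(ref$exempt) > 0 && any(cand & n_meth == 1)) {
              one <- which(cand & n_meth == 1)
              devk <- vapply(one, function(j) which(codes[, j] == 2L)[1], integer(1))
              cand[one] <- devk %in% ref$exempt
            }
            unmeth[ok] <- cand[ok]
          }
        }
        u_reason[ridx] <- reason
        u_unmeth[ridx] <- unmeth
        if (per_read) {
          lab <- matrix(.CALL_LABELS[codes + 1L], nrow = nrow(codes))
          lab[lab == "absent"] <- "."
          u_calls[ridx] <- apply(lab, 2, paste, collapse = "")
        }
      }
    }
  }

  # per-marker counts (weights expand collapsed duplicates)
  mk_names <- vapply(refs, `[[`, character(1), "name")
  counts <- data.frame(
    marker = mk_names,
    cell_type = vapply(panel$amplicons, `[[`, character(1), "cell_type"),
    n_total_assigned = 0L, n_retained = 0L, n_fully_unmethylated = 0L,
    fraction = NA_real_, mean_conversion = NA_real_,
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  retained_u <- u_reason == "none" & !is.na(u_marker)
  for (ai in seq_len(na_)) {
    in_m <- !is.na(u_marker) & u_marker == ai
    counts$n_total_assigned[ai] <- sum(w[in_m])
    ret <- in_m & retained_u
    counts$n_retained[ai] <- sum(w[ret])
    counts$n_fully_unmethylated[ai] <- sum(w[ret & u_unmeth])
    if (counts$n_retained[ai] > 0) {
      counts$fraction[ai] <-
        counts$n_fully_unmethylated[ai] / counts$n_retained[ai]
      cv <- u_conv[ret]
      cw <- w[ret]
      def <- !is.na(cv)
      if (any(def)) counts$mean_conversion[ai] <-
          sum(cv[def] * cw[def]) / sum(cw[def])
    }
  }

  reasons <- c("none", "low_quality", "low_identity", "ambiguous_assignment",
               "missing_cpgs", "poor_conversion")
  tall <- vapply(reasons, function(r) sum(w[u_reason == r]), numeric(1))
  convdef <- !is.na(u_conv)
  res <- list(counts = counts,
              summary = list(n_reads = n, reject_tallies = tall,
                             mean_conversion = if (any(convdef))
                               sum(u_conv[convdef] * w[convdef]) / sum(w[convdef])
                             else NA_real_))
  if (per_read) {
    res$assessments <- data.frame(
      read_id = reads$id,
      marker = ifelse(is.na(u_marker[map]), NA_character_, mk_names[u_marker[map]]),
      identity = u_identity[map],
      mean_quality = mq,
      cpg_calls = u_calls[map],
      conversion_rate = u_conv[map],
      fully_unmethylated = u_unmeth[map],
      retained = u_reason[map] == "none",
      reject_reason = u_reason[map],
      stringsAsFactors = FALSE)
  }
  res
}
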