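# Targeted amplicon panel: marker loci, their CpG structure, per-marker
# unmethylated-call rules, and bisulfite-converted reference sequences.
#
# Coordinates are 0-based half-open (BED convention) internally; the
# sequenced (top) strand only is modelled, reverse-complement handling lives
# in read assignment.

#' Define one amplicon marker
#'
#' @param name Marker name (e.g. "NEUT1", "B-CELL2"); unique within a panel.
#' @param cell_type Cell type the marker reports on.
#' @param chrom,start,end Genomic location, 0-based half-open.
#' @param ref_seq Genomic sequence (uppercase A/C/G/T) of length end-start,
#'   in read orientation.
#' @param cpg_offsets 0-based offsets of CpG cytosines within `ref_seq`;
#'   auto-detected from the sequence when NULL.
#' @param unmeth_rule `"strict"` (every CpG must read unmethylated) or
#'   `"allow_one_exception"` (one CpG may deviate; some markers are more
#'   sensitive when a single CpG is allowed to be methylated differently).
#' @param exempt_cpgs For `allow_one_exception`: 1-based indices of the CpGs
#'   that are allowed to deviate; empty means any single CpG may.
#' @return A list of class `amplicon_def` (includes the precomputed
#'   bisulfite-converted reference and non-CpG cytosine offsets).
#' @export
amplicon_def <- function(name, cell_type, chrom, start, end, ref_seq,
                         cpg_offsets = NULL,
                         unmeth_rule = c("strict", "allow_one_exception"),
                         exempt_cpgs = integer()) {
  unmeth_rule <- match.arg(unmeth_rule)
  ref_seq <- toupper(ref_seq)
  .check(nchar(ref_seq) == end - start,
         "%s: sequence length %d != end - start = %d",
         name, nchar(ref_seq), end - start)
  .check(grepl("^[ACGT]+$", ref_seq), "%s: sequence must be uppercase A/C/G/T", name)
  detected <- .find_cpg_offsets(ref_seq)
  if (is.null(cpg_offsets)) {
    cpg_offsets <- detected
  } else {
    cpg_offsets <- as.integer(sort(cpg_offsets))
    .check(all(cpg_offsets %in% detected),
           "%s: a cpg_offset does not point at 'CG' in ref_seq", name)
  }
  .check(length(cpg_offsets) >= 1, "%s: amplicon has no CpG", name)
  .check(all(diff(cpg_offsets) > 0), "%s: cpg_offsets must be strictly increasing", name)
  .check(all(exempt_cpgs >= 1 & exempt_cpgs <= length(cpg_offsets)),
         "%s: exempt_cpgs out of range", name)
  if (nchar(ref_seq) > 160) {
    .warnf("%s: amplicon length %d exceeds the 160 bp design bound",
           name, nchar(ref_seq))
  }
  structure(list(name = name, cell_type = cell_type, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 ref_seq = ref_seq, cpg_offsets = cpg_offsets,
                 unmeth_rule = unmeth_rule,
                 exempt_cpgs = as.integer(exempt_cpgs),
                 converted = bisulfite_reference(ref_seq),
                 noncpg_c_offsets = .noncpg_c_offsets(ref_seq)),
            class = "amplicon_def")
}

# 0-based offsets of CpG cytosines
.find_cpg_offsets <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m) - 1L
}

# 0-based offsets of cytosines NOT followed by G (bisulfite conversion QC
# positions: these should always read as T)
.noncpg_c_offsets <- function(seq) {
  v <- .seq_to_int(seq)
  is_c <- v == .INT_C
  next_g <- c(v[-1] == .INT_G, FALSE)
  which(is_c & !next_g) - 1L
}

#' Bisulfite-convert a reference sequence
#'
#' Every cytosine outside a CpG context becomes T (full conversion of
#' unmethylated non-CpG cytosines); every CpG cytosine becomes the IUPAC
#' wildcard `Y`, which matches C (methylated) or T (unmethylated) during
#' read comparison. Output length equals input length.
#'
#' @param x An [amplicon_def()] or a character sequence.
#' @return The converted sequence as a character string.
#' @export
bisulfite_reference <- function(x) {
  seq <- if (inherits(x, "amplicon_def")) x$ref_seq else toupper(x)
  v <- .seq_to_int(seq)
  cpg <- .find_cpg_offsets(seq) + 1L
  is_c <- v == .INT_C
  v[is_c] <- .INT_T
  v[cpg] <- .INT_Y
  .int_to_seq(v)
}

#' Build a panel from amplicon definitions
#'
#' @param amplicons A list of [amplicon_def()] objects with unique names;
#'   every cell type must have at least one marker.
#' @return An object of class `amplicon_panel`: list with `amplicons` (named
#'   list) and `cell_type_groups` (cell type -> marker names).
#' @export
amplicon_panel <- function(amplicons) {
  .check(length(amplicons) >= 1, "empty panel")
  stopifnot(all(vapply(amplicons, inherits, logical(1), "amplicon_def")))
  nms <- vapply(amplicons, `[[`, character(1), "name")
  .check(!any(duplicated(nms)), "duplicate marker name: %s",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(amplicons) <- nms
  cts <- vapply(amplicons, `[[`, character(1), "cell_type")
  groups <- split(nms, cts)
  structure(list(amplicons = amplicons, cell_type_groups = groups),
            class = "amplicon_panel")
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("amplicon_panel: %d markers, %d cell types\n",
              length(x$amplicons), length(x$cell_type_groups)))
  invisible(x)
}

#' Cell types covered by a panel
#' @param panel An [amplicon_panel()].
#' @return Character vector of cell-type labels.
#' @export
panel_cell_types <- function(panel) names(panel$cell_type_groups)

#' Load a panel from a BED-like table plus FASTA sequences
#'
#' The table must have columns `name`, `cell_type`, `chrom`, `start`, `end`,
#' `unmeth_rule` and optionally `exempt_cpgs` (comma-separated 1-based CpG
#' indices). Each row needs a FASTA record of matching name and length; CpG
#' offsets are auto-detected from the sequence.
#'
#' @param table_path Path to the TSV table.
#' @param fasta_path Path to the FASTA file of amplicon sequences.
#' @return An [amplicon_panel()].
#' @export
load_panel <- function(table_path, fasta_path) {
  df <- utils::read.table(table_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "cell_type", "chrom", "start", "end", "unmeth_rule")
  .check(all(need %in% names(df)), "panel table must have columns %s",
         paste(need, collapse = ", "))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  amps <- lapply(seq_len(nrow(df)), function(i) {
    nm <- df$name[i]
    .check(nm %in% names(seqs), "no FASTA record for marker %s", nm)
    exempt <- integer()
    if ("exempt_cpgs" %in% names(df) && !is.na(df$exempt_cpgs[i]) &&
        nzchar(df$exempt_cpgs[i])) {
      exempt <- as.integer(strsplit(as.character(df$exempt_cpgs[i]), ",")[[1]])
    }
    amplicon_def(nm, df$cell_type[i], df$chrom[i], df$start[i], df$end[i],
                 as.character(seqs[[nm]]), unmeth_rule = df$unmeth_rule[i],
                 exempt_cpgs = exempt)
  })
  amplicon_panel(amps)
}

#' Write a panel to a BED-like table plus FASTA
#'
#' Inverse of [load_panel()].
#'
#' @param panel An [amplicon_panel()].
#' @param table_path,fasta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(panel, table_path, fasta_path) {
  a <- panel$amplicons
  df <- data.frame(name = names(a),
                   cell_type = vapply(a, `[[`, character(1), "cell_type"),
                   chrom = vapply(a, `[[`, character(1), "chrom"),
                   start = vapply(a, `[[`, integer(1), "start"),
                   end = vapply(a, `[[`, integer(1), "end"),
                   unmeth_rule = vapply(a, `[[`, character(1), "unmeth_rule"),
                   exempt_cpgs = vapply(a, function(x)
                     paste(x$exempt_cpgs, collapse = ","), character(1)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- Biostrings::DNAStringSet(vapply(a, `[[`, character(1), "ref_seq"))
  names(ss) <- names(a)
  Biostrings::writeXStringSet(ss, fasta_path)
  invisible(c(table_path, fasta_path))
}

#' Panel diagnostics
#'
#' Report-only validation: per-marker CpG counts and lengths, length
#' warnings (> 160 bp), and pairwise similarity of the bisulfite-converted
#' references. Pairs whose converted references diverge by less than 20%
#' (identity > 80%, the read-assignment threshold) are flagged as ambiguous
#' since reads could not be assigned uniquely between them.
#'
#' @param panel An [amplicon_panel()].
#' @param ambiguity_identity Identity (%) above which a pair is flagged (80).
#' @return A list with `markers` (data.frame), `ambiguous_pairs`
#'   (data.frame), `n_cell_types`.
#' @export
validate_panel <- function(panel, ambiguity_identity = 80) {
  stopifnot(inherits(panel, "amplicon_panel"))
  a <- panel$amplicons
  markers <- data.frame(
    name = names(a),
    cell_type = vapply(a, `[[`, character(1), "cell_type"),
    length = vapply(a, function(x) nchar(x$ref_seq), integer(1)),
    n_cpgs = vapply(a, function(x) length(x$cpg_offsets), integer(1)),
    n_noncpg_c = vapply(a, function(x) length(x$noncpg_c_offsets), integer(1)),
    unmeth_rule = vapply(a, `[[`, character(1), "unmeth_rule"),
    over_length = vapply(a, function(x) nchar(x$ref_seq) > 160, logical(1)),
    stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  pairs <- data.frame(marker1 = character(), marker2 = character(),
                      identity = numeric(), stringsAsFactors = FALSE)
  nms <- names(a)
  if (length(a) >= 2) {
    refs <- lapply(a, function(x) .seq_to_int(x$converted))
    for (i in seq_len(length(a) - 1)) {
      for (j in (i + 1):length(a)) {
        id <- .pair_identity(refs[[i]], refs[[j]])
        if (id > ambiguity_identity) {
          pairs <- rbind(pairs, data.frame(marker1 = nms[i], marker2 = nms[j],
                                           identity = id))
        }
      }
    }
  }
  list(markers = markers, ambiguous_pairs = pairs,
       n_cell_types = length(panel$cell_type_groups))
}

# best ungapped sliding identity between two converted references
# (Y on either side matches C, T or Y on the other); identity relative to
# the shorter sequence.
.pair_identity <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  La <- length(a); Lb <- length(b)
  best <- 0
  for (off in 0:(Lb - La)) {
    bb <- b[(off + 1):(off + La)]
    eq <- a == bb |
      (a == .INT_Y & (bb == .INT_C | bb == .INT_T)) |
      (bb == .INT_Y & (a == .INT_C | a == .INT_T))
    best <- max(best, 100 * sum(eq) / La)
  }
  best
}
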