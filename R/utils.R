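# Internal helpers shared across modules.

# Haploid human genome mass is ~3.3 pg, so 1 ng of cfDNA contains
# 1000/3.3 ~ 303 genome equivalents. The printed constant 303 is stored
# once here and used everywhere; see ge_per_ng().
.GE_PER_NG <- 303

#' Genome equivalents per nanogram of human DNA
#'
#' Returns the constant used to convert cfDNA concentrations from ng/ml to
#' haploid genome equivalents (GE) per ml: one haploid genome weighs about
#' 3.3 pg, so 1 ng contains roughly 303 genomes. The value 303 (rather than
#' 1000/3.3 = 303.03) is used so that reported numbers match the standard
#' printed arithmetic of the assay.
#'
#' @return A single number, 303.
#' @export
ge_per_ng <- function() .GE_PER_NG

# Integer codes of the DNA alphabet (utf8), used by the vectorised
# read-matching code.
.INT_A <- 65L
.INT_C <- 67L
.INT_G <- 71L
.INT_T <- 84L
.INT_N <- 78L
.INT_Y <- 89L  # IUPAC pyrimidine wildcard: C or T

.seq_to_int <- function(s) utf8ToInt(s)

.int_to_seq <- function(v) intToUtf8(v)

# Reverse complement on integer-coded sequences. N maps to N, Y (C/T) to
# R-equivalent is not needed: wildcards only ever live on references, which
# are matched in a fixed orientation.
.revcomp_int <- function(v) {
  out <- integer(length(v))
  out[v == .INT_A] <- .INT_T
  out[v == .INT_T] <- .INT_A
  out[v == .INT_C] <- .INT_G
  out[v == .INT_G] <- .INT_C
  out[v == .INT_N] <- .INT_N
  rev(out)
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# stopifnot with a formatted message
.check <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
}

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic local RNG: evaluate `expr` under a seed without disturbing
# the caller's RNG stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
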