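# Internal helpers shared across modules. Sequences are handled as plain
# character vectors at the interfaces and converted to Biostrings objects
# where the heavy lifting (matching, letter frequencies) happens.

BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of sequences, computed over unambiguous bases only.
#' @noRd
gc_fraction <- function(x) {
  ss <- Biostrings::DNAStringSet(x)
  gc <- Biostrings::letterFrequency(ss, "GC")
  acgt <- Biostrings::letterFrequency(ss, "ACGT")
  as.numeric(gc) / as.numeric(acgt)
}

# Pooled GC over a set of sequences (one number).
gc_fraction_pooled <- function(x) {
  ss <- Biostrings::DNAStringSet(x)
  sum(Biostrings::letterFrequency(ss, "GC")) /
    sum(Biostrings::letterFrequency(ss, "ACGT"))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Positions at which two equal-length strings differ.
mismatch_positions <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  which(ra != rb)
}

hamming <- function(a, b) length(mismatch_positions(a, b))

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")  # bacterial (table 11) starts

split_codons <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3 == 0)
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

# Rejecting stop codons (AT-rich) when drawing sense codons inflates the
# realized GC; this solves for the input GC whose post-rejection
# expectation equals the target.
orf_gc_adjust <- function(target) {
  realized <- function(g) {
    pt <- (1 - g) / 2; pa <- pt; pg <- g / 2
    p_stop <- pt * pa * (pa + 2 * pg)          # TAA + TAG + TGA
    gc_in_stops <- 2 * pt * pa * pg            # one G each in TAG, TGA
    (3 * g - gc_in_stops) / (3 * (1 - p_stop)) - target
  }
  stats::uniroot(realized, c(1e-3, 1 - 1e-3), tol = 1e-9)$root
}

# Random open reading frame: start codon + sense codons + single stop.
# Sense-codon GC is adjusted so the realized body GC matches `gc`.
random_orf <- function(n_codons, gc = 0.5) {
  stopifnot(n_codons >= 2)
  g_adj <- orf_gc_adjust(gc)
  body <- character(n_codons - 2L)
  for (i in seq_along(body)) {
    repeat {
      cod <- random_dna(3, g_adj)
      if (!cod %in% STOP_CODONS) break
    }
    body[i] <- cod
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

translate_cds <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                     if.fuzzy.codon = "X"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
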