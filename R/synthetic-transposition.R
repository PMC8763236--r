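# Copy-and-paste transposition with AT-biased target choice and
# target-site duplication (TSD) generation.

# AT fraction of every k-bp window of every contig; returns a data.frame
# (contig, pos, at) where pos is the 1-based first base of the window.
window_at_fraction <- function(contigs, k) {
  out <- lapply(names(contigs), function(ct) {
    s <- Biostrings::DNAString(contigs[[ct]])
    if (length(s) < k) return(NULL)
    at <- Biostrings::letterFrequencyInSlidingView(s, k, "AT") / k
    data.frame(contig = ct, pos = seq_len(length(s) - k + 1L),
               at = as.numeric(at), stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Calibrate the AT target bias for a desired mean TSD GC content
#'
#' Insertion sites are drawn with weight proportional to
#' `exp(beta * AT(window))`. This solves for the `beta` whose expected
#' target-window GC equals `target_gc` on the given genome.
#'
#' @param genome An `is_genome` (or list with a `contigs` character vector).
#' @param k TSD length (window size in bp).
#' @param target_gc Desired expected GC fraction of the insertion windows.
#' @return The calibrated `beta` (0 when `target_gc` equals the genome's
#'   unweighted mean window GC).
#' @export
calibrate_target_bias <- function(genome, k = 8, target_gc = 0.27) {
  w <- window_at_fraction(genome$contigs, k)
  gcw <- 1 - w$at
  f <- function(beta) {
    wt <- exp(beta * w$at)
    sum(wt * gcw) / sum(wt) - target_gc
  }
  lo <- f(0)
  if (abs(lo) < 1e-12) return(0)
  stats::uniroot(f, c(-80, 80), tol = 1e-10)$root
}

# Insert `element` at `site` (1-based first TSD base) of `contig` in
# `genome`, duplicating the k-bp target window. Returns the mutated genome
# with gene coordinates shifted past the insertion point.
insert_element <- function(genome, contig, site, element_seq, k,
                           orientation = "+") {
  s <- genome$contigs[[contig]]
  stopifnot(site >= 1, site + k - 1 <= nchar(s))
  elem <- if (orientation == "-") revcomp(element_seq) else element_seq
  tsd <- substr(s, site, site + k - 1)
  new_seq <- paste0(substr(s, 1, site + k - 1), elem,
                    substr(s, site, nchar(s)))
  g <- genome
  g$contigs[[contig]] <- new_seq
  shift <- nchar(elem) + k
  sel <- g$genes$contig == contig & g$genes$start >= site + k
  g$genes$start[sel] <- g$genes$start[sel] + shift
  g$genes$end[sel] <- g$genes$end[sel] + shift
  if (!is.null(g$copies) && nrow(g$copies)) {
    sel <- g$copies$contig == contig & g$copies$start >= site + k
    g$copies$start[sel] <- g$copies$start[sel] + shift
    g$copies$end[sel] <- g$copies$end[sel] + shift
  }
  attr(g, "last_tsd") <- tsd
  g
}

#' Simulate copy-and-paste IS transposition events
#'
#' Each event copies the element from an intact donor copy (the donor is
#' never excised), picks a target site with probability proportional to
#' `exp(beta * AT(window))` over all k-bp windows of the genome, duplicates
#' the k-bp target window as flanking direct repeats, and (optionally)
#' returns the mutated genome carrying the new copy. Events are
#' independent: each mutated genome carries exactly one new insertion, as
#' for independent cells in a population.
#'
#' @param genome An `is_genome` containing at least one intact copy of
#'   `family`.
#' @param family Family label (must exist in `genome$elements`).
#' @param n_events Number of independent insertion events to draw.
#' @param beta AT-preference parameter (0 = uniform targeting; see
#'   [calibrate_target_bias()]).
#' @param seed Integer seed.
#' @param return_genomes If `TRUE` (default when `n_events <= 50`), the
#'   result carries one mutated genome per event; truth rows are returned
#'   regardless.
#' @param avoid_existing If `TRUE` (default), target windows overlapping
#'   an existing element copy (plus a 500 bp margin, about one library
#'   insert size) are excluded: insertions into or right next to a
#'   resident copy are unresolvable by short-read junction evidence
#'   because reads and mates from the new copy multi-map to the resident
#'   one.
#' @return A list with `truth` (data.frame: event, family, donor_gene,
#'   contig, site, orientation, tsd_seq) and `genomes` (list of mutated
#'   `is_genome`s or `NULL`).
#' @export
simulate_transposition <- function(genome, family, n_events = 1, beta = 0,
                                   seed = NULL,
                                   return_genomes = n_events <= 50,
                                   avoid_existing = TRUE) {
  el <- genome$elements[[family]]
  if (is.null(el)) stop("unknown family: ", family)
  donors <- genome$copies[genome$copies$family == family &
                            genome$copies$intact, , drop = FALSE]
  if (!nrow(donors))
    stop("family ", family,
         " has no intact donor copy; a non-autonomous-only family cannot self-mobilize")
  stopifnot(is.finite(beta))
  k <- el$spec$tsd_length
  donor <- donors[1, ]
  donor_seq <- substring(genome$contigs[[donor$contig]], donor$start,
                         donor$end)
  if (donor$strand == "-") donor_seq <- revcomp(donor_seq)
  with_seed(seed, {
    win <- window_at_fraction(genome$contigs, max(k, 1))
    if (avoid_existing && !is.null(genome$copies) &&
        nrow(genome$copies)) {
      bad <- rep(FALSE, nrow(win))
      for (i in seq_len(nrow(genome$copies)))
        bad <- bad | (win$contig == genome$copies$contig[i] &
                        win$pos >= genome$copies$start[i] - 500L &
                        win$pos <= genome$copies$end[i] + 500L)
      win <- win[!bad, , drop = FALSE]
    }
    wt <- exp(beta * win$at)
    idx <- sample.int(nrow(win), n_events, replace = TRUE, prob = wt)
    orient <- sample(c("+", "-"), n_events, replace = TRUE)
    truth <- data.frame(event = seq_len(n_events), family = family,
                        donor_gene = donor$gene_id,
                        contig = win$contig[idx], site = win$pos[idx],
                        orientation = orient,
                        tsd_seq = substring(genome$contigs[win$contig[idx]],
                                            win$pos[idx],
                                            win$pos[idx] + k - 1L),
                        stringsAsFactors = FALSE)
    if (k == 0) truth$tsd_seq <- ""
    genomes <- NULL
    if (return_genomes) {
      genomes <- vector("list", n_events)
      for (i in seq_len(n_events))
        genomes[[i]] <- insert_element(genome, truth$contig[i],
                                       truth$site[i], donor_seq, k,
                                       truth$orientation[i])
    }
    list(truth = truth, genomes = genomes)
  })
}
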