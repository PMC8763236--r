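# Simulation-based validation harness for the insertion caller.

#' Benchmark the insertion caller against simulated truth
#'
#' Runs replicate end-to-end simulations (genome with one resident
#' element copy, a single new copy-and-paste insertion at a known
#' frequency, paired-end reads, junction calling) and summarizes recall,
#' precision and allele-frequency accuracy against the generator's truth.
#' Truth frequencies are drawn uniformly on `freq_range`; a call matches
#' truth when a PASS call sits within 3 bp of the planted site.
#'
#' @param n_replicates Number of independent replicates (one insertion
#'   each).
#' @param depth Sequencing coverage per replicate.
#' @param read_length,insert_size Library geometry in bp.
#' @param error_rate Per-base substitution error rate.
#' @param genome_length Reference length in bp.
#' @param freq_range Range of truth insertion frequencies.
#' @param seed Integer seed (replicate r uses `seed + 10 * r + 0:2`).
#' @return List with `per_insertion` (truth, estimate, site error),
#'   `recall`, `precision`, `mean_abs_freq_error`, `max_abs_freq_error`.
#' @export
caller_benchmark <- function(n_replicates = 20, depth = 250,
                             read_length = 150, insert_size = 400,
                             error_rate = 0.002, genome_length = 1e4,
                             freq_range = c(0.05, 0.95), seed = 1) {
  rows <- list()
  n_pass_total <- 0L
  for (r in seq_len(n_replicates)) {
    s <- seed + 10L * r
    fam <- is_family("ISAm1", element_length = 1200, copy_number = 1,
                     intact_copies = 1, tsd_length = 8)
    g <- generate_genome(contig_lengths = genome_length,
                         family_specs = list(fam), gene_density = 0.3,
                         seed = s)
    tr <- simulate_transposition(g, "ISAm1", n_events = 1, seed = s + 1)
    f <- with_seed(s + 2, stats::runif(1, freq_range[1], freq_range[2]))
    rd <- simulate_reads(list(list(genome = g, weight = 1 - f),
                              list(genome = tr$genomes[[1]], weight = f)),
                         depth = depth, read_length = read_length,
                         insert_size = insert_size,
                         error_rate = error_rate, seed = s + 3)
    jx <- find_junctions(rd$reads, g,
                         c(ISAm1 = g$elements$ISAm1$consensus))
    calls <- call_insertions(jx, g)
    pass <- calls[calls$status == "PASS", , drop = FALSE]
    n_pass_total <- n_pass_total + nrow(pass)
    mhit <- which(pass$contig == tr$truth$contig[1] &
                    abs(pass$site - tr$truth$site[1]) <= 3)
    rows[[r]] <- data.frame(
      replicate = r, truth_freq = f,
      est_freq = if (length(mhit)) pass$frequency[mhit[1]] else NA_real_,
      site_error = if (length(mhit))
        abs(pass$site[mhit[1]] - tr$truth$site[1]) else NA_integer_,
      tsd_ok = if (length(mhit))
        identical(pass$tsd_seq[mhit[1]], tr$truth$tsd_seq[1]) else NA)
  }
  per <- do.call(rbind, rows)
  detected <- !is.na(per$est_freq)
  err <- abs(per$est_freq - per$truth_freq)
  list(per_insertion = per,
       recall = mean(detected),
       precision = if (n_pass_total > 0) sum(detected) / n_pass_total
       else NA_real_,
       mean_abs_freq_error = mean(err, na.rm = TRUE),
       max_abs_freq_error = if (any(detected)) max(err, na.rm = TRUE)
       else NA_real_)
}
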