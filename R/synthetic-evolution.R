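# Serial-transfer Wright-Fisher simulation with new transposition
# mutations and phase-weighted selection.

#' Parameters of a serial-transfer evolution experiment
#'
#' Defaults emulate a 150-fold dilution every cycle (log2(150) ~ 7.23
#' generations per cycle) with a bottleneck scaled to 1e4 cells for
#' desk-scale runs; the experimental bottleneck of 4.5e5 cells can be
#' requested explicitly. Fitness of a genotype over one cycle is
#' `w = (1 + s_e)^g_e * (1 + s_l)^g_l`, applied per generation as
#' `w^(1/g)`; by default the whole cycle is treated as exponential-phase
#' (`g_e = g`, `g_l = 0`) since within-cycle demography is not observed.
#'
#' @param n_cycles Number of transfer cycles to simulate.
#' @param bottleneck_size Cells sampled at each transfer (N_b).
#' @param dilution_factor Fold-dilution D at transfer; generations per
#'   cycle are `log2(D)`.
#' @param transposition_rate New-insertion rate u per genome per
#'   generation.
#' @param s_new Per-phase selection coefficients `c(s_e, s_l)` given to
#'   each new mutant genotype.
#' @param g_e,g_l Generations per cycle assigned to the exponential and
#'   linear phase when weighting fitness (defaults: all exponential).
#' @return A validated list of class `evolution_params`.
#' @export
evolution_params <- function(n_cycles = 57, bottleneck_size = 1e4,
                             dilution_factor = 150,
                             transposition_rate = 0,
                             s_new = c(s_e = 0, s_l = 0),
                             g_e = NULL, g_l = 0) {
  g <- log2(dilution_factor)
  stopifnot(bottleneck_size >= 1, dilution_factor > 1,
            transposition_rate >= 0, n_cycles >= 1)
  if (is.null(g_e)) g_e <- g - g_l
  stopifnot(abs(g_e + g_l - g) < 1e-9)
  structure(list(n_cycles = as.integer(n_cycles),
                 bottleneck_size = as.integer(bottleneck_size),
                 dilution_factor = dilution_factor,
                 generations_per_cycle = g,
                 transposition_rate = transposition_rate,
                 s_new = s_new, g_e = g_e, g_l = g_l),
            class = "evolution_params")
}

cycle_fitness <- function(s_e, s_l, g_e, g_l) {
  (1 + s_e)^g_e * (1 + s_l)^g_l
}

#' Simulate evolution under serial 1:D dilution transfers
#'
#' Each cycle runs `round(log2(D))` discrete generations of multinomial
#' Wright-Fisher reproduction with fitness-weighted expected frequencies,
#' the population doubling each generation from the bottleneck size; new
#' transposition mutant genotypes arise at rate u per genome per
#' generation; the cycle ends with a multinomial bottleneck of N_b cells.
#'
#' @param founder Data frame with one row per founding genotype: columns
#'   `genotype` (label), `freq` (initial frequencies summing to 1) and
#'   optionally `s_e`, `s_l` (default 0).
#' @param params An [evolution_params()] object.
#' @param seed Integer seed.
#' @return List of class `serial_transfer_sim` with `freq` (matrix
#'   cycles+1 x genotypes of post-bottleneck frequencies, cycle 0 = founder),
#'   `genotypes` (data.frame: genotype, parent, s_e, s_l, origin_cycle) and
#'   `params`. New mutant genotypes are labelled `mut_<n>`.
#' @export
simulate_serial_transfer <- function(founder, params, seed = NULL) {
  stopifnot(is.data.frame(founder), all(c("genotype", "freq") %in%
                                          names(founder)))
  stopifnot(abs(sum(founder$freq) - 1) < 1e-9)
  if (is.null(founder$s_e)) founder$s_e <- 0
  if (is.null(founder$s_l)) founder$s_l <- 0
  p <- params
  n_gen <- max(1L, round(p$generations_per_cycle))
  with_seed(seed, {
    geno <- data.frame(genotype = as.character(founder$genotype),
                       parent = NA_character_,
                       s_e = founder$s_e, s_l = founder$s_l,
                       origin_cycle = 0L, stringsAsFactors = FALSE)
    w_gen <- cycle_fitness(geno$s_e, geno$s_l, p$g_e, p$g_l)^(1 / n_gen)
    counts <- stats::rmultinom(1, p$bottleneck_size, founder$freq)[, 1]
    freq_rows <- list(`0` = counts / sum(counts))
    n_mut <- 0L
    for (cycle in seq_len(p$n_cycles)) {
      n <- p$bottleneck_size
      monomorphic <- sum(counts > 0) == 1L && p$transposition_rate == 0
      if (!monomorphic) {
        for (gen in seq_len(n_gen)) {
          n <- min(round(n * 2), round(p$bottleneck_size * p$dilution_factor))
          pr <- counts * w_gen
          counts <- stats::rmultinom(1, n, pr)[, 1]
          if (p$transposition_rate > 0) {
            nm <- stats::rpois(1, p$transposition_rate * n)
            if (nm > 0) {
              parents <- sample.int(length(counts), nm, replace = TRUE,
                                    prob = counts)
              for (pa in parents) {
                if (counts[pa] == 0) next
                n_mut <- n_mut + 1L
                counts[pa] <- counts[pa] - 1L
                counts <- c(counts, 1L)
                geno <- rbind(geno, data.frame(
                  genotype = sprintf("mut_%d", n_mut),
                  parent = geno$genotype[pa],
                  s_e = p$s_new[["s_e"]], s_l = p$s_new[["s_l"]],
                  origin_cycle = cycle, stringsAsFactors = FALSE))
                w_gen <- c(w_gen, cycle_fitness(p$s_new[["s_e"]],
                                                p$s_new[["s_l"]],
                                                p$g_e, p$g_l)^(1 / n_gen))
              }
            }
          }
        }
        counts <- stats::rmultinom(1, p$bottleneck_size, counts)[, 1]
      }
      freq_rows[[as.character(cycle)]] <- counts / sum(counts)
    }
    n_geno <- nrow(geno)
    freq <- matrix(0, nrow = length(freq_rows), ncol = n_geno,
                   dimnames = list(names(freq_rows), geno$genotype))
    for (i in seq_along(freq_rows))
      freq[i, seq_along(freq_rows[[i]])] <- freq_rows[[i]]
    stopifnot(all(abs(rowSums(freq) - 1) < 1e-12))
    structure(list(freq = freq, genotypes = geno, params = p),
              class = "serial_transfer_sim")
  })
}

#' @export
print.serial_transfer_sim <- function(x, ...) {
  cat(sprintf("Serial-transfer simulation: %d cycles, %d genotypes (%d new mutants)\n",
              nrow(x$freq) - 1L, ncol(x$freq),
              sum(!is.na(x$genotypes$parent))))
  invisible(x)
}

#' Per-allele frequencies from a serial-transfer simulation
#'
#' The defining mutation of genotype i is carried by i and all its
#' descendants; the allele frequency at each cycle is the summed genotype
#' frequency over that clade.
#'
#' @param sim A `serial_transfer_sim`.
#' @return Matrix cycles x alleles (same labels as genotypes).
#' @export
allele_frequencies <- function(sim) {
  g <- sim$genotypes
  out <- sim$freq
  # accumulate children into parents; genotypes are ordered by origin
  for (i in rev(seq_len(nrow(g)))) {
    pa <- g$parent[i]
    if (!is.na(pa)) out[, pa] <- out[, pa] + out[, g$genotype[i]]
  }
  out
}
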