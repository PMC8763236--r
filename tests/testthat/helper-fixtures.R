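# Shared fixtures, built once per test run.

# Small genome with one active IS family (the nine-copy, one-intact
# configuration of the ancestral strain).
fixture_nine_copy_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      fam <- is_family("ISAm1", element_length = 1200, copy_number = 9,
                       intact_copies = 1, divergence = 0.005,
                       itr_length = 14, tsd_length = 8)
      g <<- generate_genome(contig_lengths = 6e4, family_specs = list(fam),
                            gene_density = 0.35, seed = 20240901)
    }
    g
  }
})

# Compact caller substrate: 15 kb genome, one single-copy element.
fixture_caller_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      fam <- is_family("ISAm1", element_length = 1200, copy_number = 1,
                       intact_copies = 1, divergence = 0,
                       itr_length = 14, tsd_length = 8)
      g <<- generate_genome(contig_lengths = 1.5e4,
                            family_specs = list(fam),
                            gene_density = 0.3, seed = 424242)
    }
    g
  }
})

random_codon <- function(no_stop = TRUE) {
  repeat {
    cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                 collapse = "")
    if (!no_stop || !cod %in% c("TAA", "TAG", "TGA")) return(cod)
  }
}
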