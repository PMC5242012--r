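# Shared fixtures, built in code at test time.

default_table <- read_codon_table()

## default table with some codon frequencies overridden, w recomputed
tweaked_table <- function(freqs) {
  tab <- as.data.frame(default_table)[, c("codon", "aa", "freq")]
  tab$freq[match(names(freqs), tab$codon)] <- unname(freqs)
  venomlib:::as_codon_table(tab)
}

random_gene <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

write_fasta <- function(headers, seqs) {
  path <- tempfile(fileext = ".faa")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

## small designed-gene fixture shared across assembly/acceptance tests
fixture_designs <- local({
  cache <- NULL
  function(n = 40, seed = 101) {
    if (is.null(cache)) {
      lib <- generate_synthetic_library(n, seed = seed)
      cache <<- design_genes(lib, default_table, seed = seed)
    }
    cache
  }
})
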