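# Shared fixtures, generated in code.  Expensive objects are cached per test
# session in this environment so several test files can reuse them.
fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(fx[[name]])) fx[[name]] <- force(expr)
  fx[[name]]
}

random_seq <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

mutate_seq <- function(seq, rate, seed = 1, mix = c(1, 1, 1) / 3) {
  withr::with_seed(seed, sketchasm:::apply_read_errors(seq, rate, mix)$seq)
}

# small clean genome + error-free reads (cheap, reused widely)
clean_reads_20k <- function() {
  fixture("clean20k", {
    g <- simulate_genome(genome_spec(20000, seed = 101))
    reads <- simulate_reads(g, coverage = 25, error_rate = 0,
                            seed = 102, min_length = 800)
    list(genome = g, reads = reads)
  })
}

# noisy reads over a small genome
noisy_reads_20k <- function() {
  fixture("noisy20k", {
    g <- simulate_genome(genome_spec(20000, seed = 103))
    reads <- simulate_reads(g, coverage = 30, error_rate = 0.10, seed = 104)
    list(genome = g, reads = reads)
  })
}

# true overlap length between two reads by truth coordinates
true_overlap <- function(reads, a, b) {
  ra <- reads[match(a, reads$id), ]
  rb <- reads[match(b, reads$id), ]
  pmax(0, pmin(ra$end, rb$end) - pmax(ra$start, rb$start))
}
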