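# Small in-code fixtures shared across tests.

small_sim_config <- function(seed = 1, ...) {
  args <- list(n_genomes = 12, core_size = 30, ancestral_accessory = 15,
               pool_size = 8, polyphyly_events = 1, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

# Hand-built two-genome hit table exercising coverage filtering, ties and
# reciprocity; gene IDs follow the genome|gene convention.
tiny_hits <- function() {
  rows <- list(
    # qseqid     sseqid     pident len bit  qcov
    c("A|a1", "A|a1", 100, 200, 400, 1.00),
    c("A|a2", "A|a2", 100, 200, 380, 1.00),
    c("A|a3", "A|a3", 100, 200, 360, 1.00),
    c("B|b1", "B|b1", 100, 200, 395, 1.00),
    c("B|b2", "B|b2", 100, 200, 375, 1.00),
    c("B|b3", "B|b3", 100, 200, 355, 1.00),
    c("A|a1", "B|b1", 90, 180, 300, 0.90),
    c("B|b1", "A|a1", 90, 180, 300, 0.90),
    c("A|a2", "B|b2", 88, 170, 280, 0.65),  # below the 0.70 coverage floor
    c("B|b2", "A|a2", 88, 170, 280, 0.90),
    c("A|a3", "B|b3", 80, 150, 200, 0.85),  # a3 -> b3 best...
    c("B|b3", "A|a2", 80, 150, 210, 0.85),  # ...but b3 prefers a2
    c("B|b3", "A|a3", 80, 150, 150, 0.85))
  m <- do.call(rbind, rows)
  hits <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                     pident = as.numeric(m[, 3]), length = as.numeric(m[, 4]),
                     mismatch = 0, gapopen = 0, qstart = 1,
                     qend = as.numeric(m[, 4]), sstart = 1,
                     send = as.numeric(m[, 4]), evalue = 1e-50,
                     bitscore = as.numeric(m[, 5]), qcovs = as.numeric(m[, 6]),
                     stringsAsFactors = FALSE)
  class(hits) <- c("hit_table", "data.frame")
  hits
}
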