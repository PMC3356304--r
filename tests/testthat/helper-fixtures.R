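# Small in-code fixtures shared across test files.

toy_universe <- function(n = 20, len = 5000, mu = 2.7e-6) {
  gene_universe(sprintf("g%02d", seq_len(n)), rep(len, n), mu = mu)
}

# Universe with a 10x length split: `n_short` genes of `short` nt followed
# by `n_long` genes of 10x that length.
split_universe <- function(n_short, n_long, short = 2000, mu = 2.7e-6) {
  gene_universe(sprintf("g%04d", seq_len(n_short + n_long)),
                c(rep(short, n_short), rep(10 * short, n_long)), mu = mu)
}

write_lengths_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

write_gmt_file <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

write_mutation_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}
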