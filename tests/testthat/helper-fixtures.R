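# Small deterministic fixtures shared across test files.

# two-chromosome genome, fast to render
small_genome <- function(seed = 11, het_density = 1 / 3000) {
  simulate_genome(c(chr1 = 6e7, chr2 = 4e7), het_density = het_density,
                  seed = seed)
}

# one-chromosome genome for event-level tests
one_chrom_genome <- function(len = 150e6, seed = 7, het_density = 0) {
  simulate_genome(c(chr1 = len), het_density = het_density, seed = seed)
}

# allelic list for hand-built single-sample tables
allelic_from_df <- function(df) {
  list(sites = df[, c("chrom", "pos")],
       depthA = matrix(df$depthA, dimnames = list(NULL, "s1")),
       depthB = matrix(df$depthB, dimnames = list(NULL, "s1")))
}

# residual switch points of a +/-1 orientation sequence
count_switch_points <- function(ori) sum(diff(ori) != 0)

# default 4-chromosome genome without het sites (classification tests)
default_genome <- function(seed = 7) {
  simulate_genome(het_density = 0, seed = seed)
}
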