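# Independent brute-force oracles used across the suite.

# degeneracy by exhaustive enumeration (independent of the product rule)
enum_degeneracy <- function(seq) length(expand_degenerate(seq))

# Wallace-rule Tm of one concrete oligo
wallace_tm <- function(s) {
  chars <- strsplit(s, "")[[1L]]
  2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C"))
}

# random degenerate sequence over the full 15-letter alphabet
random_degenerate <- function(len) {
  paste(sample(c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N"),
               len, replace = TRUE), collapse = "")
}

# small-sample quadratic surface evaluated directly (oracle for predictions)
quad_surface <- function(b, x, y) {
  b[1] + b[2] * x + b[3] * x^2 + b[4] * y + b[5] * y^2 + b[6] * x * y
}
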