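# coefficient grids shared across tests; chosen to hit every dispatch case of
# the closed formula (a = 1, a = 1/2, other powers of two activating the
# excluded-index blocks, negatives, non-dyadic rationals)
a_grid_small <- c("1", "-1", "2", "-2", "1/2", "3", "1/3", "4", "3/2")
a_grid_full  <- c("1", "-1", "2", "-2", "4", "8", "1/2", "-1/2", "3", "1/3", "3/2", "5")

chr <- function(x) as.character(x)

random_rationals <- function(k, seed) {
  set.seed(seed)
  paste0(sample(-12:12, k, replace = TRUE), "/", sample(1:9, k, replace = TRUE))
}

# direct bitwise convolution sums, the definitional oracle for the AND/XOR/OR
# sequences
bitwise_direct <- function(n, op) {
  f <- switch(op, and = bitwAnd, xor = bitwXor, or = bitwOr)
  if (n < 2) return(0)
  k <- seq_len(n - 1)
  sum(as.numeric(f(k, n - k)))
}
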