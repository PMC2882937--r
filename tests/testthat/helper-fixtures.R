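# Shared fixtures and independent oracles, built in code at test time.

# Exhaustive-enumeration oracle for the upper hypergeometric tail:
# P(overlap >= k) when m genes are drawn from N of which b are marked.
hyper_tail_enum <- function(N, b, m, k) {
  ks <- k:min(b, m)
  sum(choose(b, ks) * choose(N - b, m - ks)) / choose(N, m)
}

# Closed-form upper tail of a chi-square with 4 degrees of freedom,
# independent of stats::pchisq: P(X > x) = (1 + x/2) exp(-x/2).
chisq4_tail <- function(x) (1 + x / 2) * exp(-x / 2)

# Small labelled expression matrix with i.i.d. standard normal entries.
noise_matrix <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("g%04d", seq_len(n)),
                         sprintf("s%03d", seq_len(m))))
}

# Noise matrix with one planted gene-by-sample block shifted by `shift`.
planted_block_matrix <- function(n, m, block_genes, block_samples, shift,
                                 seed = 1) {
  x <- noise_matrix(n, m, seed)
  x[seq_len(block_genes), seq_len(block_samples)] <-
    x[seq_len(block_genes), seq_len(block_samples)] + shift
  x
}

write_tmp_lines <- function(lines) {
  path <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A sharply peaked single-base PWM (probability `p` on `base` everywhere).
single_base_pwm <- function(name, base, length = 6, p = 0.97) {
  probs <- matrix((1 - p) / 3, length, 4)
  probs[, match(base, c("A", "C", "G", "T"))] <- p
  pwm(name, probs)
}
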