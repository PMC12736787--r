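# Independent oracles used to cross-check the package's implementations.
# These deliberately take the naive route (per-residue loops, full
# enumeration, closed-form formulas) rather than reusing package internals.

KD_REF <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

naive_gravy <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  vals <- KD_REF[chars]
  vals <- vals[!is.na(vals)]
  sum(vals) / length(vals)
}

naive_window_mean <- function(sequence, start, width) {
  naive_gravy(substr(sequence, start, start + width - 1))
}

random_aa_seq <- function(len, alphabet = names(KD_REF)) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# group assignments of the pooled tie-free sample; mirrors the convention
# p = min(1, 2 * min(P(U <= u), P(U >= u))).
mwu_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Welch t, Satterthwaite df and two-sided p straight from the formulas
welch_formula <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

write_temp_fasta <- function(text) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(text, path)
  path
}
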