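# Shared fixtures and independent brute-force oracles.

toy_library <- function() {
  fp_library(list(
    A = c(`1` = 2, `2` = 1),
    B = c(`2` = 3),
    C = c(`1` = 1, `3` = 4, `7` = 2)
  ))
}

# Brute-force continuous Tanimoto: explicit double loop over the union of
# fragment keys, no vectorised shortcuts.
bf_tanimoto <- function(fp1, fp2) {
  keys <- union(names(fp1), names(fp2))
  num <- 0; s1 <- 0; s2 <- 0
  for (k in keys) {
    a <- if (k %in% names(fp1)) as.numeric(fp1[[k]]) else 0
    b <- if (k %in% names(fp2)) as.numeric(fp2[[k]]) else 0
    num <- num + a * b
    s1 <- s1 + a^2
    s2 <- s2 + b^2
  }
  if (s1 + s2 - num == 0) return(0)
  num / (s1 + s2 - num)
}

# Brute-force SQB probability: materialise the reference's pure density and
# the compound's rank-1 projector over an explicit basis and take the trace.
bf_sqb_trace <- function(r, c) {
  basis <- union(names(r), names(c))
  d <- pure_density(r, basis)
  S <- projector_onto(c, basis)
  Re(sum(diag(d %*% S)))
}

random_complex_vec <- function(n, basis) {
  v <- complex(real = stats::runif(n), imaginary = stats::runif(n))
  names(v) <- sample(basis, n)
  v
}

random_fp <- function(n_frags, universe = 50) {
  frags <- sort(sample.int(universe, n_frags))
  count_fingerprint(stats::setNames(sample(1:4, n_frags, replace = TRUE), frags))
}

random_library <- function(n_compounds, universe = 50) {
  fps <- lapply(seq_len(n_compounds), function(i) random_fp(sample(2:8, 1), universe))
  names(fps) <- sprintf("M%03d", seq_len(n_compounds))
  fp_library(fps)
}

small_benchmark <- function(seed = 7) {
  spec <- benchmark_spec(
    data.frame(class_id = c("HOM", "HET"),
               n_actives = c(15, 15),
               core_size = c(30, 60),
               core_prob = c(0.85, 0.25)),
    n_decoys = 300, fragment_universe = 256, seed = seed
  )
  generate_benchmark(spec)
}
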