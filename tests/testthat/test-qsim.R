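test_that("subspace probability sums the fragment masses", {
  d <- fragment_distribution(c(a = 0.5, b = 0.5))
  expect_equal(subspace_probability(d, "a"), 0.5)
  expect_equal(subspace_probability(d, c("a", "b")), 1.0)
  d2 <- fragment_distribution(c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(subspace_probability(d2, c("a", "c")), 0.7)
  expect_equal(subspace_probability(d2, character(0)), 0)
  expect_error(fragment_distribution(c(a = 0.4, b = 0.4)), "sum to 1")
})

test_that("mixed-state density operators are diagonal, trace-1, and PSD", {
  d <- fragment_distribution(c(a = 0.5, b = 0.5))
  D <- density_from_distribution(d, c("a", "b"))
  expect_equal(D, diag(as.complex(c(0.5, 0.5)), 2), ignore_attr = TRUE)

  point <- fragment_distribution(c(f = 1))
  P <- density_from_distribution(point, c("g", "f"))
  expect_equal(P, projector_onto(c(f = 1), c("g", "f")))
  expect_true(is_projector(P))

  set.seed(1)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    p <- stats::rgamma(n, 1)
    p <- p / sum(p)
    basis <- paste0("f", seq_len(n))
    D <- density_from_distribution(fragment_distribution(stats::setNames(p, basis)), basis)
    expect_equal(Re(sum(diag(D))), 1, tolerance = 1e-12)
    expect_true(is_density_operator(D))
  }
})

test_that("pure densities are rank-1 Hermitian idempotent operators", {
  e1 <- pure_density(c(f1 = 1), c("f1", "f2"))
  expect_equal(e1[1, 1], 1 + 0i)
  expect_equal(sum(Mod(e1)), 1)

  # phi = (1, i)/sqrt(2) -> [[0.5, -0.5i], [0.5i, 0.5]]
  phi <- c(f1 = 1 + 0i, f2 = 0 + 1i)
  D <- pure_density(phi, c("f1", "f2"))
  expect_equal(D, matrix(c(0.5, 0.5i, -0.5i, 0.5), 2,
                         dimnames = list(c("f1", "f2"), c("f1", "f2"))),
               tolerance = 1e-15)

  set.seed(2)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    basis <- paste0("f", seq_len(n))
    phi <- random_complex_vec(sample(1:n, 1), basis)
    D <- pure_density(phi, basis)
    expect_true(is_density_operator(D, tol = 1e-9))
    expect_true(is_projector(D, tol = 1e-9))
  }
  expect_error(pure_density(c(f1 = 0), "f1"), "zero")
})

test_that("SQB closed form equals the brute-force trace oracle to 1e-12", {
  set.seed(4)
  basis <- paste0("f", 1:8)
  for (i in 1:40) {
    r <- random_complex_vec(sample(2:6, 1), basis)
    cc <- random_complex_vec(sample(2:6, 1), basis)
    expect_equal(sqb_probability(r, cc), bf_sqb_trace(r, cc), tolerance = 1e-12)
  }
})

test_that("SQB probability: self-projection 1, orthogonal 0, zero-norm 0", {
  v <- c(`1` = 1 + 2i, `5` = 0.3 + 0.7i)
  expect_equal(sqb_probability(v, v), 1, tolerance = 1e-15)
  w <- c(`9` = 2 + 1i)
  expect_equal(sqb_probability(v, w), 0)
  expect_warning(z <- sqb_probability(v, complex(0)), "zero-norm")
  expect_equal(z, 0)
})

test_that("SQB probability is symmetric and scalar-invariant, in [0,1]", {
  set.seed(6)
  basis <- paste0("f", 1:8)
  for (i in 1:20) {
    r <- random_complex_vec(4, basis)
    cc <- random_complex_vec(4, basis)
    p <- sqb_probability(r, cc)
    expect_gte(p, 0)
    expect_lte(p, 1 + 1e-12)
    expect_equal(p, sqb_probability(cc, r), tolerance = 1e-12)
    z <- complex(real = stats::rnorm(1), imaginary = stats::rnorm(1))
    if (Mod(z) > 1e-3) {
      expect_equal(sqb_probability(r * z, cc), p, tolerance = 1e-10)
      expect_equal(sqb_probability(r, cc * z), p, tolerance = 1e-10)
    }
  }
})

test_that("continuous Tanimoto: hand values and conventions", {
  expect_equal(tanimoto_continuous(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(tanimoto_continuous(c(1, 1, 0), c(0, 1, 1)), 1 / 3)
  expect_equal(tanimoto_continuous(c(a = 1, b = 1), c(c = 2, d = 5)), 0)
  expect_warning(z <- tanimoto_continuous(numeric(0), numeric(0)), "zero")
  expect_equal(z, 0)
  expect_error(tanimoto_continuous(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("continuous Tanimoto reduces to binary Tanimoto on 0/1 vectors", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    a <- stats::rbinom(n, 1, 0.5)
    b <- stats::rbinom(n, 1, 0.5)
    if (sum(a) + sum(b) == 0) next
    binary <- sum(a & b) / sum(a | b)
    expect_equal(tanimoto_continuous(a, b), binary, tolerance = 1e-15)
  }
})
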