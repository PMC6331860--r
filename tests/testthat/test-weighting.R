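# Frozen expected values below were computed with an independent
# high-precision (30-digit) evaluation of the closed-form expressions.

test_that("global weight matches high-precision values and is decreasing in cf", {
  expect_equal(global_weight(1000, 1000), 7.2353855017067829e-05, tolerance = 1e-12)
  expect_equal(global_weight(10, 1000), 0.66664257281487208, tolerance = 1e-12)
  for (m in c(2, 10, 1000)) {
    expect_gt(global_weight(1, m), global_weight(m, m))
    w <- global_weight(seq_len(m %/% 2), m)
    expect_true(all(diff(w) < 0))
  }
  expect_error(global_weight(0, 10), "cf")
  expect_error(global_weight(11, 10), "cf")
})

test_that("local (tech 1) weight: zero at ff=0, 1/3 at the balanced point, saturating", {
  expect_equal(tech1_weight(0, 5, 5), 0)
  expect_equal(tech1_weight(1, 5, 5), 1 / 3)
  expect_gt(tech1_weight(10, 7, 5), tech1_weight(5, 7, 5))
  ff <- 0:50
  w <- tech1_weight(ff, 3, 4)
  expect_true(all(w >= 0 & w < 1))
  expect_error(tech1_weight(1, 5, 0), "c_avg")
})

test_that("tech 2 weight is exactly the local x global product", {
  set.seed(5)
  for (i in 1:20) {
    m <- sample(10:2000, 1)
    cf <- sample.int(m, 1)
    ff <- sample(0:6, 1)
    c_j <- stats::runif(1, 1, 40)
    c_avg <- stats::runif(1, 5, 30)
    expect_equal(tech2_weight(ff, c_j, c_avg, cf, m),
                 tech1_weight(ff, c_j, c_avg) * global_weight(cf, m),
                 tolerance = 1e-15)
  }
  # ubiquitous fragments are nearly annihilated by the global factor
  expect_equal(tech2_weight(3, 10, 10, 1000, 1000),
               tech1_weight(3, 10, 10) * 7.2353855017067829e-05,
               tolerance = 1e-12)
})

test_that("okapi (tech 3) weight applies the min/max reference-matching factor", {
  t2 <- tech2_weight(4, 12, 10, 7, 100)
  expect_equal(tech3_okapi_weight(4, 4, 12, 10, 7, 100), t2)
  expect_equal(tech3_okapi_weight(4, 0, 12, 10, 7, 100), 0)
  expect_equal(tech3_okapi_weight(0, 0, 12, 10, 7, 100), 0)  # 0/0 convention
  expect_equal(tech3_okapi_weight(2, 6, 12, 10, 7, 100),
               tech2_weight(2, 12, 10, 7, 100) / 3, tolerance = 1e-15)
})

test_that("weight formulas are non-negative and nested: tech3 <= tech2 <= global", {
  set.seed(9)
  for (i in 1:50) {
    m <- sample(5:500, 1)
    cf <- sample.int(m, 1)
    ff <- sample(0:8, 1)
    ffr <- sample(0:8, 1)
    c_j <- stats::runif(1, 0.5, 30)
    c_avg <- stats::runif(1, 2, 25)
    g <- global_weight(cf, m)
    t1 <- tech1_weight(ff, c_j, c_avg)
    t2 <- tech2_weight(ff, c_j, c_avg, cf, m)
    t3 <- tech3_okapi_weight(ff, ffr, c_j, c_avg, cf, m)
    expect_true(all(c(g, t1, t2, t3) >= 0))
    expect_lte(t3, t2 + 1e-15)
    expect_lte(t2, g + 1e-15)
  }
})

test_that("embedding places the global weight in Re and the technique in Im", {
  lib <- toy_library()
  st <- corpus_stats(lib)
  fp <- lib$A

  er <- embed_compound(fp, st, weight_scheme("real"))
  expect_equal(Im(er), rep(0, length(fp)), ignore_attr = TRUE)
  expect_equal(Re(er), unname(global_weight(st$doc_freq[names(fp)], st$n_compounds)),
               ignore_attr = TRUE)

  e1 <- embed_compound(fp, st, weight_scheme("tech1"))
  c_j <- fp_size(fp)
  expect_equal(Im(e1),
               vapply(seq_along(fp),
                      function(k) tech1_weight(as.numeric(fp)[k], c_j, st$avg_size),
                      numeric(1)),
               ignore_attr = TRUE)
  expect_equal(Re(e1), Re(er), ignore_attr = TRUE)

  expect_length(embed_compound(count_fingerprint(), st, weight_scheme("tech2")), 0L)
})

test_that("okapi embedding needs a reference and vanishes outside its support", {
  lib <- toy_library()
  st <- corpus_stats(lib)
  expect_error(embed_compound(lib$A, st, weight_scheme("okapi")), "reference")

  ref <- lib$B                       # support {2}
  e <- embed_compound(lib$A, st, weight_scheme("okapi"), reference = ref)
  outside <- setdiff(names(lib$A), names(ref))
  expect_true(all(Im(e[outside]) == 0))

  # the reference embedded against itself: min/max factor 1 => tech2 values
  eref <- embed_compound(ref, st, weight_scheme("okapi"), reference = ref)
  e2 <- embed_compound(ref, st, weight_scheme("tech2"))
  expect_equal(eref, e2, ignore_attr = TRUE)
})

test_that("real-scheme embedding ignores counts: same support, same vector", {
  lib <- fp_library(list(P = c(`3` = 1, `8` = 5), Q = c(`3` = 4, `8` = 2)))
  st <- corpus_stats(lib)
  eP <- embed_compound(lib$P, st, weight_scheme("real"))
  eQ <- embed_compound(lib$Q, st, weight_scheme("real"))
  expect_equal(eP, eQ, ignore_attr = TRUE)
})
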