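test_that("a candidate identical to the reference ranks first with score 1", {
  lib <- fp_library(list(
    R = c(`1` = 2, `4` = 1),
    TWIN = c(`1` = 2, `4` = 1),
    OTHER = c(`2` = 3, `9` = 1)
  ))
  for (meth in c("tan", "sqb-real", "sqb-tech1", "sqb-tech2", "sqb-okapi")) {
    rk <- rank_library("R", lib, method = meth)
    expect_equal(rk$compound_id[1], "TWIN", info = meth)
    expect_equal(rk$score[1], 1, tolerance = 1e-12, info = meth)
    expect_false("R" %in% rk$compound_id)
    expect_true(all(diff(rk$score) <= 1e-12))
  }
})

test_that("tied scores are ordered by ascending compound id", {
  lib <- fp_library(list(
    Q = c(`1` = 1),
    Zed = c(`2` = 1), Alpha = c(`2` = 1), Mid = c(`2` = 1)
  ))
  rk <- rank_library("Q", lib, method = "tan")
  expect_equal(rk$compound_id, c("Alpha", "Mid", "Zed"))
})

test_that("TAN ranking matches a brute-force pairwise similarity sort", {
  set.seed(13)
  lib <- random_library(10)
  st <- corpus_stats(lib)
  ref <- names(lib)[1]
  rk <- rank_library(ref, lib, st, method = "tan")
  bf <- vapply(setdiff(names(lib), ref),
               function(id) bf_tanimoto(lib[[ref]], lib[[id]]), numeric(1))
  bf_order <- names(bf)[order(-bf, names(bf), method = "radix")]
  expect_equal(rk$compound_id, bf_order)
  expect_equal(rk$score, unname(bf[rk$compound_id]), tolerance = 1e-12)
})

test_that("SQB rankings agree with the scalar embed + probability path", {
  set.seed(14)
  lib <- random_library(8)
  st <- corpus_stats(lib)
  ref <- names(lib)[3]
  for (meth in c("sqb-real", "sqb-tech1", "sqb-tech2", "sqb-okapi")) {
    technique <- sub("^sqb-", "", meth)
    rk <- rank_library(ref, lib, st, method = meth)
    er <- embed_compound(lib[[ref]], st, weight_scheme(technique),
                         reference = lib[[ref]])
    for (id in rk$compound_id) {
      ec <- embed_compound(lib[[id]], st, weight_scheme(technique),
                           reference = lib[[ref]])
      expect_equal(rk$score[rk$compound_id == id], sqb_probability(er, ec),
                   tolerance = 1e-10, info = paste(meth, id))
    }
  }
})

test_that("unknown method tokens are rejected", {
  lib <- toy_library()
  expect_error(rank_library("A", lib, method = "cosine"))
  expect_error(rank_library("ZZZ", lib, method = "tan"), "not in the library")
})

test_that("recall honours the rounded percentage cutoff with floor 1", {
  ranked <- structure(
    data.frame(compound_id = sprintf("M%04d", 1:1000),
               score = seq(1, 0.001, length.out = 1000)),
    reference_id = "REF", method = "tan",
    class = c("ranked_list", "data.frame")
  )
  actives <- c(sprintf("M%04d", c(1, 3, 7, 9, 10)),   # 5 in top 10
               sprintf("M%04d", 900:914))             # 15 far down
  expect_equal(recall_at(ranked, actives, 0.01), 25)
  expect_equal(recall_at(ranked, sprintf("M%04d", 1:10), 0.01), 100)
  expect_equal(recall_at(ranked, sprintf("M%04d", 990:999), 0.01), 0)
  # floor: a 30-compound list at 1% still inspects one position
  small <- structure(ranked[1:30, ], reference_id = "REF", method = "tan",
                     class = c("ranked_list", "data.frame"))
  expect_equal(recall_at(small, "M0001", 0.01), 100)
  expect_error(recall_at(ranked, "REF", 0.01), "actives")
  expect_error(recall_at(ranked, actives, 1.2), "fraction")
})

test_that("recall is monotone in the cutoff fraction and reaches 100", {
  set.seed(15)
  lib <- random_library(60)
  rk <- rank_library(names(lib)[1], lib, method = "sqb-tech2")
  actives <- names(lib)[seq(2, 20, 2)]
  fr <- c(0.01, 0.05, 0.1, 0.25, 0.5, 0.999)
  rec <- vapply(fr, function(f) recall_at(rk, actives, f), numeric(1))
  expect_true(all(diff(rec) >= 0))
  expect_equal(rec[length(rec)], 100)
})

test_that("evaluation reduces to a single recall call for one class/method/reference", {
  bench <- small_benchmark()
  res <- evaluate_screening(bench$library, bench$labels["HOM"],
                            references_per_class = 1, methods = "tan",
                            fractions = 0.05, seed = 99)
  ref <- res[[1]]$references$HOM
  direct <- recall_at(
    suppressWarnings(rank_library(ref, bench$library, method = "tan")),
    bench$labels$HOM, 0.05
  )
  expect_equal(unname(res[[1]]$table["HOM", "tan"]), direct)
})

test_that("evaluation is seed-reproducible and aggregates consistently", {
  bench <- small_benchmark()
  run <- function() {
    evaluate_screening(bench$library, bench$labels, references_per_class = 3,
                       methods = c("tan", "sqb-okapi"), seed = 5)
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1, r2)
  for (res in r1) {
    expect_equal(res$mean_row, colMeans(res$table), tolerance = 1e-12)
    expect_true(all(res$table >= 0 & res$table <= 100))
    s <- summarize_table(res$table)
    expect_equal(res$shaded_cells, s$shaded_cells)
    expect_gte(sum(res$shaded_cells), nrow(res$table))
  }
  expect_error(
    evaluate_screening(bench$library, bench$labels, references_per_class = 100,
                       seed = 1),
    "too small"
  )
})

test_that("table summaries reproduce the published DS1 top-1% aggregate rows", {
  tab <- published_recall_table("mddr_ds1", 0.01)
  s <- summarize_table(tab)
  expect_equal(unname(s$mean_row["sqb_tech3"]), 22.01, tolerance = 0.005)
  expect_equal(unname(s$shaded_cells),
               c(2L, 1L, 5L, 0L, 3L))
})

test_that("table summaries handle degenerate shapes and ties", {
  one <- matrix(41.5, 1, 1, dimnames = list("K", "m"))
  s <- summarize_table(one)
  expect_equal(unname(s$mean_row), 41.5)
  expect_equal(unname(s$shaded_cells), 1L)

  const <- matrix(10, 4, 3, dimnames = list(paste0("K", 1:4), c("a", "b", "c")))
  expect_equal(unname(summarize_table(const)$shaded_cells), c(4L, 4L, 4L))

  bad <- matrix(c(1, NA), 1, 2)
  expect_error(summarize_table(bad), "missing")
})
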