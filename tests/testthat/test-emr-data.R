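test_that("parsing handles empty files, duplicate codes and onset annotations", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# header comment", ""), empty)
  expect_equal(nrow(parse_emr_file(empty)), 0)

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tBlack\t45\tfemale\t401.9;789.00@63;401.9", f)
  rec <- parse_emr_file(f)
  expect_equal(rec$icd9_codes[[1]], c("401.9", "789.00"))
  expect_equal(rec$age_years, 45L)
  expect_equal(rec$gender, "female")
})

test_that("malformed lines are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tBlack\t45\tfemale\t401.9",
               "p2\tWhite\t30\tmale\t",
               "# a comment",
               "p3-missing-fields",
               "p4\tOther\t62\ttrans\t250.00",
               "p5\tHispanic\t51\tfemale\t"), f)
  expect_error(parse_emr_file(f), "line 4")
})

test_that("unknown gender tokens error and list the allowed set", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tBlack\t45\tnonbinary2\t401.9", f)
  expect_error(parse_emr_file(f), "male, female, trans, other, unknown")
})

test_that("continuous ages are floored to integer categories", {
  rec <- emr_records("p1", "White", 45.9, "male", list("401.9"))
  expect_identical(rec$age_years, 45L)
})

test_that("writing and re-parsing round-trips records exactly", {
  recs <- tiny_records()
  path <- tiny_emr_file(recs)
  back <- parse_emr_file(path)
  expect_equal(back, recs)
})

test_that("vocabulary enumerates codes, observed ages and the five genders", {
  two <- emr_records(c("a", "b"), c("White", "Black"), c(30, 45),
                     c("female", "male"), list("401.9", "401.9"))
  v <- build_vocabulary(two)
  expect_length(v$feature_names, 1 + 2 + 5)

  lone <- emr_records("a", "Other", 70, "unknown", list(character()))
  expect_length(build_vocabulary(lone)$feature_names, 6)

  expect_error(build_vocabulary(two[0, ]), "zero records")
})

test_that("vocabulary order is deterministic under record shuffling", {
  recs <- tiny_records()
  v1 <- build_vocabulary(recs)
  v2 <- build_vocabulary(recs[c(3, 1, 4, 2), ])
  expect_identical(v1, v2)
  # bijection: contiguous unique indices
  expect_equal(sort(unname(v1$index_of)), seq_along(v1$feature_names))
  expect_false(anyDuplicated(v1$feature_names) > 0)
})

test_that("encoding sets exactly code + age + gender bits per patient", {
  recs <- tiny_records()
  v <- build_vocabulary(recs)
  b <- encode_batch(recs, v)
  expect_equal(unname(Matrix::rowSums(b$matrix)),
               lengths(recs$icd9_codes) + 2)
  # p2: one code, one age, one gender
  on <- which(b$matrix[2, ] == 1)
  expect_setequal(names(on), c("gender_male", "age_30", "401.9"))
  expect_true(all(b$matrix@x == 1))
})

test_that("unseen test-time codes are dropped with a logged count", {
  train <- tiny_records()
  v <- build_vocabulary(train)
  test <- emr_records("q1", "unknown", 45, "female", list(c("999.99", "888.8")))
  expect_message(b <- encode_batch(test, v), "dropped 2")
  expect_equal(sum(b$matrix), 2)  # age + gender only
  expect_equal(b$n_unseen, 2L)
  expect_true(is.na(b$labels))
})

test_that("encoding is batch-invariant under row partitioning", {
  g <- generate_cohort(cohort_spec(80, n_background_features = 20, seed = 3))
  v <- build_vocabulary(g$records)
  whole <- encode_batch(g$records, v)$matrix
  parts <- withr::with_seed(9, split(seq_len(80), sample(1:3, 80, replace = TRUE)))
  stacked <- do.call(rbind, lapply(parts, function(ix)
    encode_batch(g$records[ix, ], v)$matrix))
  expect_equal(as.matrix(stacked[order(unlist(parts)), ]), as.matrix(whole))
})

test_that("fold plans partition patients with near-equal sizes", {
  p <- make_fold_plan(103, 10, seed = 7)
  sizes <- tabulate(p$assignments, 10)
  expect_equal(sum(sizes), 103)
  expect_setequal(unique(sizes), c(10, 11))
  expect_equal(sum(sizes == 11), 3)

  tiny <- make_fold_plan(10, 10, seed = 1)
  expect_equal(unname(tabulate(tiny$assignments, 10)), rep(1, 10))

  expect_error(make_fold_plan(5, 6), "exceeds")
  expect_error(make_fold_plan(10, 1), "k must be")
})

test_that("fold plans are seed-deterministic and splits tile the data", {
  expect_identical(make_fold_plan(103, 10, seed = 7), make_fold_plan(103, 10, seed = 7))
  expect_false(identical(make_fold_plan(103, 10, seed = 7)$assignments,
                         make_fold_plan(103, 10, seed = 8)$assignments))
  p <- make_fold_plan(57, 5, validation_fraction = 0.1, seed = 2)
  tests <- lapply(1:5, function(f) fold_split(p, f)$test)
  expect_equal(sort(unlist(tests)), 1:57)     # tests tile the dataset
  sp <- fold_split(p, 3)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:57)
  expect_equal(length(sp$val), round(0.1 * (57 - length(sp$test))))
})

test_that("masking flips only ones, at the requested rate", {
  g <- generate_cohort(cohort_spec(2000, n_background_features = 50,
                                   background_prevalence = 0.15, seed = 4))
  b <- encode_batch(g$records, build_vocabulary(g$records))
  expect_identical(mask_observations(b, 0, seed = 1), b)

  n_ones <- sum(b$matrix)
  expect_gt(n_ones, 1e4)
  masked <- mask_observations(b, 0.3, seed = 11)
  expect_identical(dim(masked$matrix), dim(b$matrix))
  # never creates ones
  expect_true(all(b$matrix[masked$matrix == 1] == 1))
  removed <- n_ones - sum(masked$matrix)
  bound <- qbinom(c(5e-4, 1 - 5e-4), n_ones, 0.3)
  expect_gte(removed, bound[1])
  expect_lte(removed, bound[2])

  expect_error(mask_observations(b, 1), "rate")
  expect_error(mask_observations(b, -0.1), "rate")
})

test_that("demographic columns can be protected from masking", {
  recs <- tiny_records()
  b <- encode_batch(recs, build_vocabulary(recs))
  masked <- mask_observations(b, 0.9, seed = 3, protect_demographics = TRUE)
  demo <- b$vocab$kind %in% c("gender", "age")
  expect_equal(as.matrix(masked$matrix[, demo]), as.matrix(b$matrix[, demo]))
})

test_that("an all-zero batch is unchanged by masking", {
  recs <- tiny_records()
  b <- encode_batch(recs, build_vocabulary(recs))
  b$matrix <- b$matrix * 0
  expect_equal(sum(mask_observations(b, 0.5, seed = 1)$matrix), 0)
})

test_that("dataset summaries compute counts and one-decimal percentages", {
  single <- emr_records(c("a", "b"), c("White", "White"), c(1, 2),
                        c("male", "male"), list(character(), character()))
  s <- summarize_dataset(single)
  expect_equal(s$percent, c(0, 100, 0, 0))

  even <- class_composition(c(Other = 1, White = 1, Hispanic = 1, Black = 1))
  expect_equal(even$percent, rep(25, 4))
  expect_equal(sum(even$count), 4)
})
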