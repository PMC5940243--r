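# Hand-buildable 2-2-2 network used for arithmetic-by-hand checks.
hand_222 <- function() {
  m <- build_mlp(network_spec(2, c(2), "relu", 0, n_classes = 2), 1)
  m$layers[[1]]$W <- matrix(c(1, 0.5, -1, 2), 2, 2)
  m$layers[[1]]$b <- c(0.5, -1)
  m$layers[[2]]$W <- matrix(c(1, 1, 0, 1), 2, 2)
  m$layers[[2]]$b <- c(0, 0)
  m
}

test_that("references are the forward pass of the zero input", {
  m <- hand_222()
  r <- compute_references(m)
  expect_equal(r$input, c(0, 0))
  expect_equal(r$z[[1]], c(0.5, -1))     # biases only
  expect_equal(r$a[[2]], c(0.5, 0))      # ReLU clips the negative unit
  expect_equal(r$logits, c(0.5, 0))
  expect_equal(r$probs, exp(c(0.5, 0)) / sum(exp(c(0.5, 0))))
  expect_identical(compute_references(m), r)
})

test_that("zero biases and ReLU give zero hidden references and uniform output", {
  m <- toy_model(6, c(4, 3), activation = "relu", seed = 2)
  for (l in seq_along(m$layers)) m$layers[[l]]$b <- m$layers[[l]]$b * 0
  r <- compute_references(m)
  expect_equal(r$a[[2]], rep(0, 4))
  expect_equal(r$a[[3]], rep(0, 3))
  expect_equal(r$probs, rep(0.25, 4))
})

test_that("a sample equal to the reference gets an all-zero decomposition", {
  m <- toy_model(8, c(5, 4), seed = 3)
  r <- compute_references(m)
  s <- deeplift_sample(m, r, numeric(8))
  expect_equal(unname(s$C), matrix(0, 8, 4))
  expect_equal(unname(s$delta), rep(0, 4))
})

test_that("the rescale rule matches a hand-derived single-ReLU calculation", {
  m <- build_mlp(network_spec(2, c(1), "relu", 0, n_classes = 2), 1)
  m$layers[[1]]$W <- matrix(c(1, -2), 2, 1)
  m$layers[[1]]$b <- -0.5
  m$layers[[2]]$W <- matrix(c(2, -1), 1, 2)
  m$layers[[2]]$b <- c(0, 0)
  r <- compute_references(m)
  s <- deeplift_sample(m, r, c(1, 0))
  # z: -0.5 -> 0 at reference, +0.5 -> 0.5 for the sample; multiplier 0.5
  expect_equal(unname(s$C), rbind(c(1, -0.5), c(0, 0)))
  expect_equal(s$delta, c(1, -0.5))
  expect_equal(colSums(s$C), s$delta)
})

test_that("identity-activation networks reproduce the weight-product closed form", {
  m <- toy_model(10, c(6, 5), activation = "prelu", alpha0 = 1, seed = 7)
  w_eff <- effective_weights(m)
  r <- compute_references(m)
  X <- withr::with_seed(8, matrix(rbinom(50, 1, 0.4), 5, 10))
  for (i in 1:5) {
    s <- deeplift_sample(m, r, X[i, ])
    expect_equal(unname(s$C), unname(w_eff * X[i, ]), tolerance = 1e-12)
  }
})

test_that("summation-to-delta holds on random trained networks, both targets", {
  d <- separable_xy(300, n_noise = 8, seed = 14)
  ns <- network_spec(ncol(d$X), c(12, 10), "prelu", 0.3)
  m <- train_mlp(build_mlp(ns, 9), d$X, d$y, d$X[1:60, ], d$y[1:60],
                 train_config(0.01, 64, max_epochs = 10, patience = 10, seed = 9))
  r <- compute_references(m)
  X <- withr::with_seed(15, matrix(rbinom(20 * ncol(d$X), 1, 0.3), 20))
  for (i in 1:20) {
    s <- deeplift_sample(m, r, X[i, ])
    expect_equal(colSums(s$C), s$delta, tolerance = 1e-5)
    sp <- deeplift_sample(m, r, X[i, ], target_layer = "probabilities")
    expect_equal(colSums(sp$C), sp$delta, tolerance = 1e-5)
    expect_equal(unname(sp$delta), unname(predict_proba(m, rbind(X[i, ]))[1, ]) - r$probs,
                 tolerance = 1e-10)
  }
})

test_that("a single active feature's score equals its output perturbation", {
  m <- toy_model(7, c(5, 4), seed = 11)
  r <- compute_references(m)
  for (i in 1:7) {
    x <- numeric(7); x[i] <- 1
    s <- deeplift_sample(m, r, x)
    # exact logit difference via an explicit forward pass, no attribution code
    z1 <- prelu(x %*% m$layers[[1]]$W + rep(m$layers[[1]]$b, each = 1),
                m$layers[[1]]$alpha)
    z2 <- prelu(z1 %*% m$layers[[2]]$W + rep(m$layers[[2]]$b, each = 1),
                m$layers[[2]]$alpha)
    logits <- drop(z2 %*% m$layers[[3]]$W) + m$layers[[3]]$b
    expect_equal(unname(s$C[i, ]), logits - r$logits, tolerance = 1e-10)
  }
})

test_that("batch aggregation sums samples and accumulates across calls", {
  m <- toy_model(9, c(6), seed = 12)
  r <- compute_references(m)
  X <- withr::with_seed(13, matrix(rbinom(90, 1, 0.4), 10, 9))
  singles <- lapply(1:10, function(i) deeplift_sample(m, r, X[i, ]))
  whole <- aggregate_contributions(singles)
  expect_equal(whole$sample_count, 10L)
  expect_equal(whole$scores, Reduce(`+`, lapply(singles, `[[`, "C")))
  # associativity: two halves then combine == all at once
  half <- aggregate_contributions(singles[6:10],
                                  previous = aggregate_contributions(singles[1:5]))
  expect_equal(half, whole)
  # identity and degenerate cases
  expect_equal(aggregate_contributions(singles[1])$scores, singles[[1]]$C)
  expect_error(aggregate_contributions(list()), "empty")
  # the batch driver agrees with the per-sample route
  fast <- deeplift_scores(m, X, check_tol = 1e-5)
  expect_equal(fast$scores, unname(whole$scores), ignore_attr = TRUE)
})

test_that("class orderings sort descending with the canonical tie-break", {
  o <- class_ordering("heartdisease",
                      c(Other = -500, White = -100, Hispanic = 200, Black = 500))
  expect_equal(o$classes, c("Black", "Hispanic", "White", "Other"))
  expect_equal(o$scores, c(500, 200, -100, -500))

  tie <- class_ordering("x", rep(1.5, 4))
  expect_equal(tie$classes, RE_CLASSES)

  expect_error(class_ordering("x", c(1, 2, NaN, 4)), "finite")
})

test_that("frequency orderings use mean-centered per-class presence counts", {
  n_per <- c(Other = 40, White = 40, Hispanic = 40, Black = 40)
  with_code <- c(Other = 10, White = 20, Hispanic = 30, Black = 40)
  cls <- rep(names(n_per), n_per)
  codes <- unlist(lapply(names(n_per), function(cl)
    c(rep(TRUE, with_code[cl]), rep(FALSE, n_per[cl] - with_code[cl]))))
  recs <- emr_records(sprintf("p%03d", seq_along(cls)), cls,
                      rep(50, length(cls)), rep("female", length(cls)),
                      lapply(codes, function(has) if (has) "401.9" else character()))
  b <- encode_batch(recs, build_vocabulary(recs))
  o <- frequency_ordering(b, "401.9")
  expect_equal(unname(attr(o, "counts")), c(10, 20, 30, 40))
  expect_equal(o$scores, c(15, 5, -5, -15))
  expect_equal(o$classes, c("Black", "Hispanic", "White", "Other"))

  o0 <- frequency_ordering(b, "gender_male")   # absent everywhere
  expect_equal(o0$scores, rep(0, 4))
  expect_equal(o0$classes, RE_CLASSES)
  expect_error(frequency_ordering(b, "999.9"), "unknown feature")
})

test_that("frequency and DeepLIFT orderings agree on deterministic markers", {
  det <- data.frame(feature = c("282.60", "088.81"),
                    target_class = c("Black", "White"),
                    prevalence_in_target = 1, prevalence_elsewhere = 0)
  g <- generate_cohort(cohort_spec(2500, markers = det,
                                   n_background_features = 20, seed = 41))
  b <- encode_batch(g$records, build_vocabulary(g$records))
  X <- as.matrix(b$matrix); y <- b$labels
  ns <- network_spec(ncol(X), c(24, 24), "relu", 0.1)
  m <- train_mlp(build_mlp(ns, 2), X[1:2000, ], y[1:2000],
                 X[2001:2250, ], y[2001:2250],
                 train_config(0.005, 128, max_epochs = 30, patience = 5, seed = 2))
  cm <- deeplift_scores(m, X[2251:2500, ])
  for (i in 1:2) {
    f <- det$feature[i]
    dl <- class_ordering(f, cm$scores[f, ])
    fr <- frequency_ordering(b, f)
    expect_equal(dl$classes[1], det$target_class[i])
    expect_equal(fr$classes[1], det$target_class[i])
  }
})

test_that("features are ranked by score range with clamping", {
  scores <- rbind(a = c(-500, -100, 200, 500), b = c(1, 1, 1, 1),
                  c = c(0, 0, 0, 300))
  colnames(scores) <- RE_CLASSES
  cm <- structure(list(scores = scores, sample_count = 1L),
                  class = "contribution_matrix")
  r <- rank_features_by_range(cm, 10)       # top_k beyond feature count: all
  expect_equal(r$feature, c("a", "c", "b"))
  expect_equal(r$range, c(1000, 300, 0))
  expect_equal(nrow(rank_features_by_range(cm, 2)), 2)
})

test_that("orderings export and re-import byte-stably", {
  m <- toy_model(6, c(4), seed = 21)
  cm <- deeplift_scores(m, withr::with_seed(3, matrix(rbinom(30, 1, 0.5), 5, 6)))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  export_orderings(cm, p1)
  tab <- read_orderings(p1)
  expect_equal(nrow(tab), 6)
  # re-export of the re-imported table is byte-identical
  utils::write.table(tab, p2, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  expect_identical(readLines(p1), readLines(p2))
})
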