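# Constructed decoy tables with known tm/score relations.
perfect_table <- function(n_targets = 5L, n_models = 30L, seed = 1L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_targets), function(t) {
    tm <- runif(n_models)
    data.frame(target_id = paste0("T", t),
               model_id = paste0("m", seq_len(n_models)),
               tm = tm, score = -tm, is_native = FALSE,
               stringsAsFactors = FALSE)
  }))
}

test_that("perfect, inverted and random scorers bracket the accuracy scale", {
  tab <- perfect_table()
  acc <- pairwise_accuracy(tab)
  expect_true(all(acc$accuracy[!is.na(acc$accuracy)] == 100))
  inv <- tab; inv$score <- tab$tm
  acc_inv <- pairwise_accuracy(inv)
  expect_true(all(acc_inv$accuracy[!is.na(acc_inv$accuracy)] == 0))

  set.seed(3)
  rnd <- tab; rnd$score <- runif(nrow(tab))
  # with 5 x 30 models the binomial error is wide; just check mid-range
  a <- pairwise_accuracy(rnd)
  overall <- a$accuracy[a$category == "overall"]
  expect_gt(overall, 35); expect_lt(overall, 65)
})

test_that("pairs below the minimum TM difference are not counted", {
  tab <- data.frame(target_id = "T1", model_id = c("a", "b", "c"),
                    tm = c(0.50, 0.55, 0.90), score = c(-1, -2, -3),
                    is_native = FALSE)
  acc <- pairwise_accuracy(tab, min_delta_tm = 0.1)
  # (a,b) differs by 0.05: dropped; (a,c) and (b,c) count
  expect_equal(acc$n_pairs[acc$category == "overall"], 2L)
  two <- data.frame(target_id = "T1", model_id = c("a", "b"),
                    tm = c(0.9, 0.5), score = c(-10, -5), is_native = FALSE)
  a2 <- pairwise_accuracy(two)
  expect_equal(a2$accuracy[a2$category == "near_native"], 100)
  expect_equal(a2$n_pairs[a2$category == "overall"], 1L)
})

test_that("accuracy and rank correlations are invariant under monotone transforms", {
  tab <- perfect_table(4L, 25L, seed = 9)
  set.seed(10)
  tab$score <- rnorm(nrow(tab)) - 2 * tab$tm
  mono <- tab; mono$score <- exp(3 * tab$score + 1)
  expect_equal(pairwise_accuracy(mono)$accuracy,
               pairwise_accuracy(tab)$accuracy)
  c1 <- per_target_correlations(tab)
  c2 <- per_target_correlations(mono)
  expect_equal(c2$spearman, c1$spearman, tolerance = 1e-12)
  expect_equal(c2$kendall, c1$kendall, tolerance = 1e-12)

  cube <- tab; cube$score <- -tab$tm^3
  c3 <- per_target_correlations(cube)
  expect_equal(c3$spearman, 1); expect_equal(c3$kendall, 1)
  expect_lt(c3$pearson, 1)
  perf <- per_target_correlations(perfect_table())
  expect_equal(perf$pearson, 1)
  expect_equal(perf$spearman, 1)
  expect_equal(perf$kendall, 1)
})

test_that("independent scores correlate near zero", {
  set.seed(12)
  tab <- perfect_table(30L, 50L, seed = 12)
  tab$score <- runif(nrow(tab))
  cc <- per_target_correlations(tab)
  expect_lt(abs(cc$pearson), 0.1)
  expect_lt(abs(cc$spearman), 0.1)
})

test_that("average predicted ranks behave for perfect, inverted and random scorers", {
  tab <- perfect_table(6L, 50L, seed = 20)
  # perfect scorer: rank of each model equals its tm-rank from the top
  r_direct <- unlist(lapply(split(tab, tab$target_id), function(d) {
    r <- rank(-d$tm)
    r[quality_category(d$tm) == "near_native"]
  }))
  expect_equal(average_predicted_rank(tab, "near_native"), mean(r_direct))
  inv <- tab; inv$score <- tab$tm
  expect_equal(average_predicted_rank(inv, "near_native"),
               nrow(tab) / 6 + 1 - mean(r_direct))
  # single-category table under random scores: mean rank ~ (n+1)/2
  set.seed(21)
  one <- data.frame(target_id = rep(paste0("T", 1:40), each = 20),
                    model_id = rep(paste0("m", 1:20), 40),
                    tm = runif(800, 0.85, 1), score = runif(800),
                    is_native = FALSE)
  expect_equal(average_predicted_rank(one, "near_native"), 10.5,
               tolerance = 0.08)
  expect_true(is.na(average_predicted_rank(one, "poor")))
})

test_that("compare_scorers runs a paired Wilcoxon with sensible edges", {
  a <- rep(c(1, 0), 50)
  expect_false(compare_scorers(a, a)$significant)
  expect_identical(compare_scorers(a, a)$n_discordant, 0L)
  set.seed(30)
  a2 <- rbinom(1000, 1, 0.9); b2 <- rbinom(1000, 1, 0.5)
  expect_true(compare_scorers(a2, b2)$significant)
  a3 <- c(rep(1, 10)); b3 <- c(rep(1, 9), 0)
  expect_gt(compare_scorers(a3, b3)$p_value, 0.05)
})

test_that("class subsetting preserves the pair partition", {
  tab <- perfect_table(6L, 20L, seed = 33)
  set.seed(34)
  tab$score <- runif(nrow(tab))
  labs <- c(T1 = "a", T2 = "a", T3 = "b", T4 = "b", T5 = "b", T6 = "a")
  by_cls <- subset_by_class(tab, labs)
  glob <- pairwise_accuracy(tab)
  n_by <- sapply(by_cls, function(r)
    r$accuracy$n_pairs[r$accuracy$category == "overall"])
  expect_equal(sum(n_by), glob$n_pairs[glob$category == "overall"])
  # single class reproduces the global result
  one <- subset_by_class(tab, setNames(rep("x", 6), paste0("T", 1:6)))
  expect_equal(one$x$accuracy, glob)
  expect_warning(subset_by_class(tab, labs[1:4]), "unlabeled")
})

test_that("decoy table validation catches malformed input", {
  expect_error(as_decoy_table(data.frame(target_id = 1)), "lacks columns")
  bad <- data.frame(target_id = "T1", model_id = c("a", "a"),
                    tm = c(0.5, 0.6), score = c(1, 2))
  expect_error(as_decoy_table(bad), "unique")
  nat <- data.frame(target_id = "T1", model_id = c("a", "b"),
                    tm = c(0.5, 0.6), score = c(1, 2),
                    is_native = c(TRUE, FALSE))
  expect_error(as_decoy_table(nat), "tm = 1")
})
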