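test_that("collect_pairs applies the separation and cutoff filters", {
  two <- project(ca_only_chain(rbind(c(0, 0, 0), c(1, 0, 0))),
                 representation_spec("CA"))
  expect_equal(nrow(collect_pairs(two, 15, 3L)), 0L)  # separation 1 < 3

  far <- ca_only_chain(rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0),
                             c(10, 0, 0)))
  s <- project(far, representation_spec("CA"))
  p <- collect_pairs(s, 15, 3L)   # only (1,4), separation 3, d = 10
  expect_equal(nrow(p), 1L)
  expect_equal(p$distance, 10)

  # 5 collinear CA sites spaced 3.8 A: brute-force over all 10 pairs leaves
  # (1,4) 11.4, (1,5) 15.2, (2,5) 11.4 under min_sep 3 and cutoff 17
  lin <- ca_only_chain(cbind((0:4) * 3.8, 0, 0))
  s <- project(lin, representation_spec("CA"))
  p <- collect_pairs(s, 17, 3L)
  expect_equal(nrow(p), 3L)
  expect_equal(sort(p$distance), c(11.4, 11.4, 15.2), tolerance = 1e-12)
})

test_that("scott_bandwidth implements the 1-D Scott rule", {
  set.seed(1)
  x <- rnorm(100)
  x <- (x - mean(x)) / sd(x)          # exact unit sd
  expect_equal(scott_bandwidth(x), 100^(-0.2), tolerance = 1e-12)
  expect_error(scott_bandwidth(1), "at least 2")
  expect_error(scott_bandwidth(rep(2, 5)), "variance")
  y <- rnorm(50)
  expect_equal(scott_bandwidth(3 * y), 3 * scott_bandwidth(y),
               tolerance = 1e-12)
})

test_that("fit_distribution recovers the mode and handles degenerate samples", {
  cfg <- training_config()
  set.seed(11)
  x <- rnorm(10000, 8, 1)
  x <- x[x > 0 & x <= 17]
  d <- fit_distribution(x, 17, cfg)
  expect_equal(sum(d$probs), 1, tolerance = 1e-9)
  centers <- (seq_along(d$probs) - 0.5) * 0.5
  expect_true(abs(centers[which.max(d$probs)] - 8) <= 0.25)

  e <- fit_distribution(numeric(0), 17, cfg)
  expect_true(e$low_confidence)
  expect_equal(e$probs, rep(1 / 34, 34), tolerance = 1e-9)

  one <- fit_distribution(rep(7.1, 20), 17, cfg)  # zero variance fallback
  expect_equal(which.max(one$probs), 15L)          # bin [7.0, 7.5)
  expect_gt(max(one$probs), 0.999)
  expect_true(all(one$probs >= cfg$probability_floor * (1 - 1e-6)))
})

test_that("training produces normalized per-class models with the right prior", {
  chains <- make_training_set(20L, 40L, seed = 8)
  cfg <- training_config()
  m <- train_potential(chains, representation_spec("CB"), cfg)
  expect_lte(length(m$conditional),
             enumerate_pair_classes(representation_spec("CB")))
  sums <- vapply(m$conditional, function(d) sum(d$probs), 0)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(sum(m$reference$probs), 1, tolerance = 1e-9)
  # all-atom prior pools far more observations than the CB projection
  expect_gt(m$provenance$n_reference_observations, m$provenance$n_observations)

  m2 <- train_potential(chains,
                        representation_spec("CB", reference_mode = "representation_prior"),
                        cfg)
  expect_equal(m2$provenance$n_reference_observations,
               m2$provenance$n_observations)
  expect_equal(m2$reference$n_samples, m2$provenance$n_observations)
})

test_that("model serialization round-trips bit-exactly", {
  chains <- make_training_set(5L, 30L, seed = 3)
  m <- train_potential(chains, representation_spec("CB"), training_config())
  path <- tempfile(fileext = ".pot")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(back$reference$probs, m$reference$probs)
  expect_identical(names(back$conditional), names(m$conditional))
  k <- names(m$conditional)[1L]
  expect_identical(back$conditional[[k]]$probs, m$conditional[[k]]$probs)
  probe <- make_chain(30L, "random", "mixed", seed = 77)
  expect_identical(score_pmf(back, probe)$total, score_pmf(m, probe)$total)
  expect_identical(score_tig(back, probe)$total, score_tig(m, probe)$total)
})

test_that("PMF and TIG equal the brute-force oracle on hand-built models", {
  # chain: 4 ALA CA sites; pairs (1,4) d in bin 1, plus (1,5),(2,5) style
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0), c(4.5, 0, 0),
               c(8.2, 0, 0))
  ch <- ca_only_chain(xyz)
  model <- hand_model(list("ALA:CA|ALA:CA" = c(0.3, 0.7)), c(0.6, 0.4))
  for (f in c("pmf", "tig")) {
    oracle <- brute_force_score(model, ch, f)
    got <- if (f == "pmf") score_pmf(model, ch) else score_tig(model, ch)
    expect_equal(got$n_pairs, oracle$n_pairs)
    expect_equal(got$total, oracle$total, tolerance = 1e-12)
  }
  # hand arithmetic for the two-pair sub-case: sites 1,4 (d=4.5, bin 1) and
  # 1,5 (d=8.2, bin 2) and 2,5 (d=6.2, bin 2)
  expected_pmf <- -log(0.3 / 0.6) - 2 * log(0.7 / 0.4)
  expect_equal(score_pmf(model, ch)$total, expected_pmf, tolerance = 1e-12)
  expected_tig <- -(0.3 / 0.6 - 1) - 2 * (0.7 / 0.4 - 1)
  expect_equal(score_tig(model, ch)$total, expected_tig, tolerance = 1e-12)
})

test_that("identical conditional and reference models give exactly zero", {
  ch <- make_chain(20L, "ALA", "helix")
  p <- c(0.25, 0.75)
  model <- hand_model(list("ALA:CA|ALA:CA" = p, "ALA:CB|ALA:CB" = p,
                           "ALA:CA|ALA:CB" = p), p,
                      spec = representation_spec("CA_CB"))
  expect_identical(score_pmf(model, ch)$total, 0)
  expect_identical(score_tig(model, ch)$total, 0)
})

test_that("TIG arithmetic and the information-gain identity hold", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0), c(3.0, 0, 0))
  ch <- ca_only_chain(xyz)               # single pair (1,4), d = 3, bin 1
  model <- hand_model(list("ALA:CA|ALA:CA" = c(0.2, 0.8)), c(0.1, 0.9))
  expect_equal(score_tig(model, ch)$total, -1, tolerance = 1e-12)
  expect_equal(information_gain(3, "ALA:CA|ALA:CA", model), log(2),
               tolerance = 1e-12)
  expect_equal(information_gain(3, "ALA:CA|ALA:CA",
                                hand_model(list("ALA:CA|ALA:CA" = c(0.1, 0.9)),
                                           c(0.1, 0.9))), 0)
  # -sum(dI) == PMF total on an arbitrary trained model and fixture
  chains <- make_training_set(10L, 40L, seed = 21)
  m <- train_potential(chains, representation_spec("CB"), training_config())
  probe <- make_chain(40L, "random", "mixed", seed = 31)
  sites <- project(probe, m$spec)
  pairs <- collect_pairs(sites, m$config$score_cutoff, m$config$min_separation)
  di <- information_gain(pairs$distance, pairs$key, m)
  expect_equal(score_pmf(m, probe)$total, -sum(di), tolerance = 1e-9)
})

test_that("scores are invariant under rigid motion and atom reordering", {
  chains <- make_training_set(10L, 40L, seed = 13)
  m <- train_potential(chains, representation_spec("CB"), training_config())
  probe <- make_chain(40L, "random", "mixed", seed = 14)
  base <- score_pmf(m, probe)$total
  set.seed(15)
  moved <- transform_chain(probe, random_rotation(), c(12, -3, 40))
  expect_equal(score_pmf(m, moved)$total, base, tolerance = 1e-9)
  shuffled <- probe
  set.seed(16)
  shuffled$atoms <- shuffled$atoms[sample(nrow(shuffled$atoms)), ]
  expect_equal(score_pmf(m, shuffled)$total, base, tolerance = 1e-9)
})

test_that("unseen pair classes score through the floored-uniform conditional", {
  model <- hand_model(list("ALA:CA|ALA:CA" = c(0.3, 0.7)), c(0.5, 0.5))
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0), c(3, 0, 0))
  ch <- ca_only_chain(xyz, res_type = c("GLY", "GLY", "GLY", "GLY"))
  res <- score_pmf(model, ch)
  expect_equal(res$n_unknown_classes, 1L)
  expect_equal(res$total, -log((1 / 2) / 0.5), tolerance = 1e-12)
})

test_that("a chain with no scorable pairs is flagged with score zero", {
  ch <- ca_only_chain(rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0),
                            c(300, 0, 0)))
  model <- hand_model(list("ALA:CA|ALA:CA" = c(0.3, 0.7)), c(0.5, 0.5))
  res <- score_pmf(model, ch)
  expect_true(res$flagged)
  expect_identical(res$n_pairs, 0L)
  expect_identical(res$total, 0)
})
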