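eval_tax <- data.frame(
  host_id = c("h1", "h2", "h3", "h4"),
  strain = c("h1", "h2", "h3", "h4"),
  species = c("s1", "s2", "s3", "s4"),
  genus = c("gA", "gA", "gB", "NA"),
  family = c("fA", "fA", "fB", "fB"),
  order = c("oA", "oA", "oA", "oA"),
  class = c("cA", "cA", "cA", "cA"),
  phylum = c("pA", "pA", "pA", "pA"),
  stringsAsFactors = FALSE)

test_that("rank-level correctness follows the lineage, NA never matches", {
  expect_true(correct_at_rank("h1", "h2", "genus", eval_tax))
  expect_false(correct_at_rank("h1", "h3", "genus", eval_tax))
  expect_true(correct_at_rank("h1", "h3", "phylum", eval_tax))
  expect_true(correct_at_rank("h1", "h3", "order", eval_tax))
  # unknown genus on either side scores as incorrect, even vs itself
  expect_false(correct_at_rank("h4", "h4", "genus", eval_tax))
  expect_true(correct_at_rank("h4", "h4", "family", eval_tax))
  expect_error(correct_at_rank("hX", "h1", "genus", eval_tax),
               "unknown host")
})

test_that("accuracy, PCP and coverage follow their definitions", {
  pred <- data.frame(phage_id = paste0("p", 1:4),
                     host_id = c("h1", "h2", "h3", "h3"),
                     stringsAsFactors = FALSE)
  truth <- data.frame(phage_id = paste0("p", 1:4),
                      host_id = c("h1", "h1", "h1", "h3"),
                      stringsAsFactors = FALSE)
  res <- evaluate_predictions(pred, truth, eval_tax)
  g <- res[res$rank == "genus", ]
  expect_equal(g$n_correct, 3)         # p1, p2 same genus; p4 exact
  expect_equal(g$accuracy, 75)
  expect_equal(g$pcp, 75)
  expect_equal(g$coverage, 100)

  # 10 phages, 5 predictions, 4 correct -> 40 / 80 / 50
  pred2 <- data.frame(phage_id = paste0("p", 1:10),
                      host_id = c("h1", "h2", "h1", "h3", "h3",
                                  rep(NA_character_, 5)),
                      stringsAsFactors = FALSE)
  truth2 <- data.frame(phage_id = paste0("p", 1:10),
                       host_id = c("h1", "h1", "h1", "h1", "h3",
                                   rep("h1", 5)),
                       stringsAsFactors = FALSE)
  res2 <- evaluate_predictions(pred2, truth2, eval_tax)
  g2 <- res2[res2$rank == "genus", ]
  expect_equal(g2$accuracy, 40)
  expect_equal(g2$pcp, 80)
  expect_equal(g2$coverage, 50)

  # zero predictions: accuracy 0, coverage 0, PCP undefined
  pred3 <- data.frame(phage_id = paste0("p", 1:3),
                      host_id = NA_character_, stringsAsFactors = FALSE)
  truth3 <- truth[1:3, ]
  res3 <- evaluate_predictions(pred3, truth3, eval_tax)
  expect_true(all(res3$accuracy == 0))
  expect_true(all(res3$coverage == 0))
  expect_true(all(is.na(res3$pcp)))

  expect_error(evaluate_predictions(
    data.frame(phage_id = "px", host_id = "h1"),
    truth, eval_tax), "missing from truth")
})

test_that("accuracy = pcp x coverage / 100 and order does not matter", {
  set.seed(71)
  n <- 30
  pred <- data.frame(phage_id = paste0("p", 1:n),
                     host_id = ifelse(runif(n) < 0.7,
                                      sample(eval_tax$host_id, n, TRUE),
                                      NA_character_),
                     stringsAsFactors = FALSE)
  truth <- data.frame(phage_id = paste0("p", 1:n),
                      host_id = sample(eval_tax$host_id, n, TRUE),
                      stringsAsFactors = FALSE)
  res <- evaluate_predictions(pred, truth, eval_tax)
  for (i in seq_len(nrow(res)))
    if (!is.na(res$pcp[i]))
      expect_equal(res$accuracy[i],
                   res$pcp[i] * res$coverage[i] / 100,
                   tolerance = 1e-9)
  shuf <- pred[sample(n), ]
  res2 <- evaluate_predictions(shuf, truth, eval_tax)
  expect_equal(res[, -1], res2[, -1], tolerance = 1e-12)
})

test_that("accuracy is monotone from genus up to phylum", {
  set.seed(72)
  sim <- simulate_bundle(sim_config(seed = 14, n_phyla = 2,
                                    genera_per_phylum = 2,
                                    hosts_per_genus = 2,
                                    host_len = 3000, phage_len = 1200,
                                    n_train_phages = 16,
                                    n_test_phages = 8,
                                    shared_fragment_len = 300,
                                    test_mutation_rate = 0.1))
  # deliberately noisy caller: random subset called, random errors
  pred <- data.frame(phage_id = sim$test$phage_id,
                     host_id = ifelse(runif(8) < 0.3,
                                      sample(sim$bundle$host_ids, 8,
                                             TRUE),
                                      sim$test$host_id),
                     stringsAsFactors = FALSE)
  pred$host_id[sample(8, 2)] <- NA
  res <- evaluate_predictions(pred, sim$test, sim$bundle$taxonomy)
  acc <- setNames(res$accuracy, res$rank)
  expect_true(all(diff(acc[c("genus", "family", "order", "class",
                             "phylum")]) >= 0))
})

test_that("threshold sweeps are monotone and consistent with evaluate", {
  sim <- simulate_bundle(sim_config(seed = 15, n_phyla = 2,
                                    genera_per_phylum = 2,
                                    hosts_per_genus = 2,
                                    host_len = 3000, phage_len = 1200,
                                    n_train_phages = 16,
                                    n_test_phages = 10,
                                    shared_fragment_len = 300,
                                    test_mutation_rate = 0.08))
  sweep <- threshold_sweep("blast_phage", c(1e-2, 1e-4, 1e-6),
                           sim$test_phages, sim$bundle, sim$test)
  expect_error(threshold_sweep("blast_phage", c(1e-6, 1e-2),
                               sim$test_phages, sim$bundle, sim$test),
               "descending")
  cov_by_e <- sweep$coverage[sweep$rank == "genus"]
  expect_true(all(diff(cov_by_e) <= 0))    # tighter e, fewer calls
  # a one-point sweep equals a direct evaluate of that predictor
  one <- threshold_sweep("blast_phage", 1e-4, sim$test_phages,
                         sim$bundle, sim$test)
  pred <- data.frame(
    phage_id = names(sim$test_phages),
    host_id = vapply(seq_along(sim$test_phages), function(i)
      blast_phage_predict(sim$test_phages[i], sim$bundle,
                          1e-4)$predicted_host_id, character(1)),
    stringsAsFactors = FALSE)
  direct <- evaluate_predictions(pred, sim$test, sim$bundle$taxonomy)
  expect_equal(one$accuracy, direct$accuracy, tolerance = 1e-9)
  expect_equal(one$coverage, direct$coverage, tolerance = 1e-9)
})
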