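# One moderately sized simulated benchmark shared across the cascade
# tests (fit once; predictions are cheap afterwards).
ens_sim <- simulate_bundle(sim_config(seed = 88, n_phyla = 3,
                                      genera_per_phylum = 2,
                                      hosts_per_genus = 2,
                                      host_len = 6000,
                                      phage_len = 2000,
                                      n_train_phages = 24,
                                      n_test_phages = 12,
                                      shared_fragment_len = 400))
ens_fit <- host_ensemble(ens_sim$bundle, algorithm = "lr", k = 4,
                         seed = 3)

# A second, deliberately small reference set: with few short references
# a query can genuinely share no seed word with any of them, which is
# what the no-signal tests need.
tiny_sim <- simulate_bundle(sim_config(seed = 96, n_phyla = 2,
                                       genera_per_phylum = 1,
                                       hosts_per_genus = 2,
                                       host_len = 1500, phage_len = 600,
                                       n_train_phages = 6,
                                       n_test_phages = 3,
                                       shared_fragment_len = 200))
tiny_fit <- host_ensemble(tiny_sim$bundle, algorithm = "lr", k = 3)

dark_query <- local({
  set.seed(92)
  repeat {
    q <- rseq(900)
    ok <- TRUE
    for (t in as.character(tiny_sim$bundle$phages))
      if (longest_shared_word(q, t, 11)) { ok <- FALSE; break }
    if (ok) for (t in as.character(tiny_sim$bundle$hosts))
      if (longest_shared_word(q, t, 11)) { ok <- FALSE; break }
    if (ok) for (t in tiny_fit$spacer_db$spacer_seq)
      if (longest_shared_word(q, t, 10)) { ok <- FALSE; break }
    if (ok) break
  }
  dss(c(dark = q))
})

test_that("an exact copy of a training phage short-circuits at stage one", {
  q <- ens_sim$bundle$phages[1]
  names(q) <- "query"
  pred <- predict_hosts(ens_fit, q)
  expect_identical(pred$stage, "blast_phage")
  expect_identical(pred$host_id, ens_sim$bundle$training$host_id[1])
  expect_lte(pred$score, ens_fit$cascade$e_blast_phage)
})

test_that("a phage whose only signal is a protospacer falls through to CRISPR", {
  set.seed(91)
  db <- ens_fit$spacer_db
  expect_gt(nrow(db), 0)
  sp <- db[1, ]
  repeat {   # random phage with no alignment signal to the references
    q <- rseq(1500)
    ok <- TRUE
    for (t in as.character(ens_sim$bundle$phages))
      if (longest_shared_word(q, t, 16)) { ok <- FALSE; break }
    if (ok) for (t in as.character(ens_sim$bundle$hosts))
      if (longest_shared_word(q, t, 16)) { ok <- FALSE; break }
    if (ok) break
  }
  substr(q, 301, 300 + nchar(sp$spacer_seq)) <- sp$spacer_seq
  pred <- predict_hosts(ens_fit, dss(c(orphan = q)))
  expect_identical(pred$stage, "crispr")
  expect_identical(pred$host_id, sp$host_id)
})

test_that("no signal at all yields an explicit no-prediction unless forced", {
  # zero phage-phage row -> no support host -> the hybrid score cannot
  # reach 0.6, so the cascade falls through all four stages
  pred <- predict_hosts(tiny_fit, dark_query)
  expect_identical(pred$stage, "none")
  expect_true(is.na(pred$host_id))

  forced <- predict_hosts(tiny_fit, dark_query,
                          cascade = cascade_config(force_call = TRUE))
  expect_identical(forced$stage, "hybrid")
  expect_false(is.na(forced$host_id))
})

test_that("cascade coverage dominates every single stage", {
  pred <- predict_hosts(ens_fit, ens_sim$test_phages)
  cov <- mean(!is.na(pred$host_id))
  b <- ens_sim$bundle
  single <- c(
    blast_phage = mean(vapply(seq_along(ens_sim$test_phages),
      function(i) !is.na(blast_phage_predict(ens_sim$test_phages[i], b,
        ens_fit$cascade$e_blast_phage)$predicted_host_id), logical(1))),
    blast_host = mean(vapply(seq_along(ens_sim$test_phages),
      function(i) !is.na(blast_host_predict(ens_sim$test_phages[i], b,
        ens_fit$cascade$e_blast_host)$predicted_host_id), logical(1))),
    crispr = mean(vapply(seq_along(ens_sim$test_phages),
      function(i) !is.na(crispr_predict(ens_sim$test_phages[i],
        ens_fit$spacer_db,
        ens_fit$cascade$e_crispr)$predicted_host_id), logical(1))))
  for (s in names(single)) expect_gte(cov, single[[s]])
})

test_that("relaxing thresholds never loses coverage", {
  strict <- predict_hosts(ens_fit, ens_sim$test_phages,
                          cascade = cascade_config(
                            e_blast_phage = 1e-50, e_blast_host = 1e-50,
                            e_crispr = 1e-6, p_hybrid = 0.9))
  loose <- predict_hosts(ens_fit, ens_sim$test_phages,
                         cascade = cascade_config(
                           e_blast_phage = 1e-5, e_blast_host = 1e-5,
                           e_crispr = 1e-1, p_hybrid = 0.3))
  expect_gte(sum(!is.na(loose$host_id)), sum(!is.na(strict$host_id)))
})

test_that("identical inputs give byte-identical prediction files", {
  p1 <- predict_hosts(ens_fit, ens_sim$test_phages)
  p2 <- predict_hosts(ens_fit, ens_sim$test_phages)
  f1 <- tempfile(); f2 <- tempfile()
  write_predictions(p1, f1)
  write_predictions(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(f1)[1], "phage_id\thost_id\tstage\tscore")
})

test_that("interaction mode confirms the predicted host by alignment", {
  q <- ens_sim$test_phages[1]
  truth <- ens_sim$test$host_id[1]
  # the true reference host itself interacts
  res <- predict_interaction(ens_fit, q, ens_sim$bundle$hosts[truth])
  expect_true(res$interacting)
  expect_identical(res$predicted_host_id, truth)

  # a 2% diverged strain of the same host still interacts
  set.seed(93)
  near <- mutate_sequence(ens_sim$bundle$hosts[[truth]], 0.02)
  res2 <- predict_interaction(ens_fit, q,
                              dss(c(strainX = as.character(near))))
  expect_true(res2$interacting)

  # no host call means no interaction claim
  res3 <- predict_interaction(tiny_fit, dark_query,
                              tiny_sim$bundle$hosts[1])
  expect_false(res3$interacting)
  expect_identical(res3$evidence, "no host call")
})

test_that("phage-for-host mode looks up the phage of the top-hit host", {
  b <- ens_sim$bundle
  # the reference host itself: its (smallest-ID) training phage
  res <- predict_phage_for_host(b, b$hosts["h001"])
  expect_identical(res$via_host_id, "h001")
  cand <- sort(b$training$phage_id[b$training$host_id == "h001"])
  expect_identical(res$phage_id, cand[1])

  # a bacterium unrelated to every reference host: no suggestion
  set.seed(95)
  repeat {
    dark <- rseq(1500)
    ok <- TRUE
    for (t in as.character(b$hosts))
      if (longest_shared_word(dark, t, 16)) { ok <- FALSE; break }
    if (ok) break
  }
  res2 <- predict_phage_for_host(b, dss(c(dark = dark)))
  expect_true(is.na(res2$phage_id))
})

test_that("the predict method dispatches all three application modes", {
  pred <- predict(ens_fit, ens_sim$test_phages[1])
  expect_s3_class(pred, "staged_predictions")
  res <- predict(ens_fit, ens_sim$test_phages[1], type = "interaction",
                 bacterium = ens_sim$bundle$hosts[1])
  expect_type(res$interacting, "logical")
  res2 <- predict(ens_fit, type = "phage_for_host",
                  bacterium = ens_sim$bundle$hosts[1])
  expect_identical(res2$via_host_id, "h001")
})
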