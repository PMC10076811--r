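# Shared two-host scaffold: a bundle small enough to hand-check, plus
# constructed similarity matrices (the hybrid combination operates on
# matrices and probability vectors, so fixtures can be exact).
hyb_bundle <- local({
  set.seed(61)
  phages <- dss(c(p1 = rseq(300), p2 = rseq(300), p3 = rseq(300)))
  hosts <- dss(c(h1 = rseq(500), h2 = rseq(500)))
  taxonomy <- data.frame(host_id = c("h1", "h2"),
                         strain = c("h1", "h2"), species = c("s1", "s2"),
                         genus = c("g1", "g2"), family = c("f1", "f2"),
                         order = c("o1", "o2"), class = c("c1", "c2"),
                         phylum = c("P1", "P2"), stringsAsFactors = FALSE)
  training <- data.frame(phage_id = c("p1", "p2", "p3"),
                         host_id = c("h1", "h2", "h1"),
                         stringsAsFactors = FALSE)
  new_bundle(phages, hosts, taxonomy, training)
})

sim_mat <- function(m, kind, normalized = FALSE)
  structure(m, kind = kind, normalized = normalized,
            class = "sim_matrix")

fake_model <- function(bundle)
  structure(list(host_checksum = bundle$host_checksum,
                 host_ids = bundle$host_ids),
            class = "host_classifier")

test_that("the support host is the host of the most similar phage", {
  pp <- sim_mat(matrix(c(1, 5, 2), 1, 3,
                       dimnames = list("q", c("p1", "p2", "p3"))),
                "phage_phage")
  expect_identical(support_host("q", pp, hyb_bundle), "h2")

  zero <- sim_mat(matrix(0, 1, 3,
                         dimnames = list("q", c("p1", "p2", "p3"))),
                  "phage_phage")
  expect_true(is.na(support_host("q", zero, hyb_bundle)))

  # tie between p1 (h1) and p2 (h2): smaller phage ID wins
  tie <- sim_mat(matrix(c(7, 7, 1), 1, 3,
                        dimnames = list("q", c("p2", "p1", "p3"))),
                 "phage_phage")
  expect_identical(support_host("q", tie, hyb_bundle), "h1")
})

test_that("the convex combination reproduces the worked example", {
  # Pr_b=[0.7,0.3], SIM_PH=[0.2,0.8], SIM_HH(h_s)=[0.5,0.5],
  # alpha=0.9, gamma=0.6 -> pro=[0.562,0.438]
  sims <- list(
    pp = sim_mat(matrix(c(1, 0, 0), 1, 3,
                        dimnames = list("q", c("p1", "p2", "p3"))),
                 "phage_phage"),           # support host = h1
    ph = sim_mat(matrix(c(0.2, 0.8), 1, 2,
                        dimnames = list("q", c("h1", "h2"))),
                 "phage_host", normalized = TRUE),
    hh = sim_mat(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2,
                        dimnames = list(c("h1", "h2"), c("h1", "h2"))),
                 "host_host", normalized = TRUE))
  q <- dss(c(q = rseq(100)))
  hs <- hybrid_score(q, fake_model(hyb_bundle), sims,
                     hybrid_weights(alpha = 0.9, gamma = 0.6),
                     hyb_bundle, prb = c(h1 = 0.7, h2 = 0.3))
  expect_equal(unname(hs$pro), c(0.562, 0.438), tolerance = 1e-12)
  expect_identical(hs$argmax_host, "h1")
  expect_equal(hs$argmax_score, 0.562, tolerance = 1e-12)
  expect_identical(hs$support_host, "h1")

  # gamma = 0 reduces to the base model exactly
  hs0 <- hybrid_score(q, fake_model(hyb_bundle), sims,
                      hybrid_weights(alpha = 0.3, gamma = 0),
                      hyb_bundle, prb = c(h1 = 0.7, h2 = 0.3))
  expect_equal(unname(hs0$pro), c(0.7, 0.3))

  # gamma = 1, alpha = 1 is the pure host-host row of the support host
  hs1 <- hybrid_score(q, fake_model(hyb_bundle), sims,
                      hybrid_weights(alpha = 1, gamma = 1),
                      hyb_bundle, prb = c(h1 = 0.7, h2 = 0.3))
  expect_equal(unname(hs1$pro), c(0.5, 0.5))
})

test_that("scores match a literal brute-force evaluation on random inputs", {
  set.seed(62)
  for (rep in 1:40) {
    M <- sample(2:10, 1)
    prb <- runif(M); prb <- prb / sum(prb)
    simph <- runif(M); simhh <- runif(M)
    a <- runif(1); g <- runif(1)
    got <- phagehost:::combine_scores(prb, simph, simhh, a, g)
    want <- vapply(seq_len(M), function(i)
      (1 - g) * prb[i] + g * ((1 - a) * simph[i] + a * simhh[i]),
      numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("each host's score is monotone in its base probability", {
  set.seed(63)
  for (rep in 1:20) {
    M <- 5
    prb <- runif(M); simph <- runif(M); simhh <- runif(M)
    a <- runif(1); g <- runif(1)
    base <- phagehost:::combine_scores(prb, simph, simhh, a, g)
    prb2 <- prb; prb2[3] <- prb2[3] + runif(1, 0, 1 - prb2[3])
    up <- phagehost:::combine_scores(prb2, simph, simhh, a, g)
    expect_gte(up[3], base[3])
    expect_equal(up[-3], base[-3])
  }
})

test_that("grid search covers the full 11x11 grid and finds planted optima", {
  tax <- hyb_bundle$taxonomy
  hosts <- c("h1", "h2")
  # noise-similarity fixture: the base model is one-hot correct, the
  # similarity rows are noise -> gamma = 0 wins (ties go to smaller
  # gamma, and gamma > 0.5 flips calls)
  set.seed(64)
  n <- 20
  truth <- sample(hosts, n, replace = TRUE)
  prb <- t(vapply(truth, function(h) setNames(as.numeric(hosts == h),
                                              hosts), numeric(2)))
  rownames(prb) <- sprintf("q%02d", 1:n)
  noise <- matrix(runif(2 * n), n, 2, dimnames = dimnames(prb))
  w <- weight_grid_search(prb, noise, noise[, 2:1], truth, tax,
                          rank = "genus", grid_step = 0.1)
  expect_equal(w$gamma, 0)
  expect_equal(nrow(w$grid), 121)
  expect_equal(w$cv_accuracy, 100)

  # misleading-base fixture: the base model is confidently wrong and
  # the phage-host similarity is (narrowly) right, the host-host row
  # is wrong -> only gamma = 1, alpha = 0 classifies everything
  prb2 <- 1 - prb                          # probability 1 on the wrong host
  simph <- t(vapply(truth, function(h)
    setNames(ifelse(hosts == h, 1, 0.96), hosts), numeric(2)))
  rownames(simph) <- rownames(prb)
  simhh_rows <- t(vapply(truth, function(h)
    setNames(as.numeric(hosts != h), hosts), numeric(2)))
  rownames(simhh_rows) <- rownames(prb)
  w2 <- weight_grid_search(prb2, simph, simhh_rows, truth, tax,
                           rank = "genus", grid_step = 0.1)
  expect_equal(w2$gamma, 1)
  expect_equal(w2$alpha, 0)
})

test_that("bundle-level grid search returns valid tuned weights", {
  sims <- list(
    pp = build_similarity_matrix("phage_phage", hyb_bundle,
                                 backend = "internal"),
    ph = build_similarity_matrix("phage_host", hyb_bundle,
                                 backend = "internal"),
    hh = build_similarity_matrix("host_host", hyb_bundle,
                                 backend = "internal"))
  m <- train_host_classifier(hyb_bundle, "lr", k = 2)
  w <- grid_search_weights(hyb_bundle, m, sims, grid_step = 0.5)
  expect_s3_class(w, "hybrid_weights")
  expect_true(w$alpha %in% seq(0, 1, 0.5))
  expect_true(w$gamma %in% seq(0, 1, 0.5))
  expect_equal(nrow(w$grid), 9)
  # audit trail round trip
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_weights(w, jp, tp)
  expect_equal(jsonlite::read_json(jp)$alpha, w$alpha)
  expect_equal(nrow(read.table(tp, header = TRUE)), 9)
  # similarity matrices round-trip with kind and normalization flags
  sp <- tempfile(fileext = ".tsv")
  write_similarity_matrix(normalize_similarity(sims$hh), sp)
  back <- read_similarity_matrix(sp)
  expect_equal(unclass(back), unclass(normalize_similarity(sims$hh)),
               tolerance = 1e-9)
  expect_identical(attr(back, "kind"), "host_host")
  expect_true(attr(back, "normalized"))
})
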