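test_that("embed_config enforces its invariants", {
  cfg <- embed_config(dim = 8, window = 3, epochs = 10, seed = 2)
  expect_s3_class(cfg, "embed_config")
  expect_equal(cfg$epochs, 10L)
  expect_error(embed_config(dim = 1), "dim")
  expect_error(embed_config(window = 0), "window")
  expect_error(embed_config(lr_start = 0.001, lr_end = 0.01), "lr_start")
})

test_that("analytic point gradient matches central finite differences", {
  set.seed(11)
  for (rep in 1:3) {
    d <- rnorm(10); uw <- rnorm(10); un <- matrix(rnorm(5 * 10), 5)
    g <- pvdbow_point_grad(d, uw, un)
    h <- 1e-6
    fd <- function(f, x) {
      sapply(seq_along(x), function(i) {
        (f(replace(x, i, x[i] + h)) - f(replace(x, i, x[i] - h))) / (2 * h)
      })
    }
    expect_lt(max(abs(fd(function(x) pvdbow_point_loss(x, uw, un), d) -
                        g$doc)), 1e-6)
    expect_lt(max(abs(fd(function(x) pvdbow_point_loss(d, x, un), uw) -
                        g$word)), 1e-6)
    num_n <- matrix(NA_real_, nrow(un), ncol(un))
    for (k in seq_len(nrow(un))) {
      for (j in seq_len(ncol(un))) {
        up <- un; up[k, j] <- up[k, j] + h
        dn <- un; dn[k, j] <- dn[k, j] - h
        num_n[k, j] <- (pvdbow_point_loss(d, uw, up) -
                          pvdbow_point_loss(d, uw, dn)) / (2 * h)
      }
    }
    expect_lt(max(abs(num_n - g$neg)), 1e-6)
  }
})

test_that("identical documents embed closer than a shuffled-vocabulary doc", {
  sent <- c("reading", "this", "story", "made", "everyone", "quietly",
            "happy", "today")
  docs <- doc_tbl(sent, sent, sample(c("zeta", "kappa", "theta", "iota",
                                       "rho", "phi", "chi", "psi")))
  m <- train_pvdbow(docs, embed_config(dim = 8, window = 3, epochs = 2000,
                                       seed = 1))
  s <- sim_matrix(similarity_matrix(m))
  expect_gt(s["MT_1_discussion", "MT_2_discussion"],
            s["MT_1_discussion", "MT_3_discussion"])
})

test_that("training is bit-reproducible under a fixed seed and config", {
  docs <- doc_tbl(rep(c("a", "b", "c", "d"), 8), rep(c("c", "d", "e"), 8))
  cfg <- embed_config(dim = 12, window = 2, epochs = 150, seed = 77)
  m1 <- train_pvdbow(docs, cfg)
  m2 <- train_pvdbow(docs, cfg)
  expect_identical(m1$doc_vectors, m2$doc_vectors)
  expect_identical(m1$word_vectors, m2$word_vectors)
  expect_identical(m1$epoch_loss, m2$epoch_loss)
  m3 <- train_pvdbow(docs, embed_config(dim = 12, window = 2, epochs = 150,
                                        seed = 78))
  expect_false(identical(m1$doc_vectors, m3$doc_vectors))
})

test_that("the training objective decreases over early epochs", {
  cfg <- synth_config(seed = 5, n_groups = 1, sessions_per_group = 3,
                      vocab_size = 100, topic_size = 15,
                      text_length = 80, discussion_length = 150)
  corp <- make_corpus(cfg)
  docs <- clean_corpus(corp$transcripts, corp$segments)
  m <- train_pvdbow(docs, embed_config(dim = 16, window = 5, epochs = 400,
                                       seed = 3))
  early <- m$epoch_loss[1:40] # first 10% of epochs
  expect_lt(early[40], early[1])
  slope <- unname(coef(lm(early ~ seq_along(early)))[2])
  expect_lt(slope, 0)
  expect_true(all(is.finite(m$epoch_loss)))
})

test_that("similarity matrices are cosine: identity, symmetry, rescaling", {
  docs <- doc_tbl(rep(c("a", "b"), 10), rep(c("b", "c"), 10),
                  rep(c("c", "d"), 10))
  m <- train_pvdbow(docs, embed_config(dim = 8, window = 2, epochs = 100,
                                       seed = 4))
  s <- similarity_matrix(m)
  M <- sim_matrix(s)
  expect_equal(unname(diag(M)), rep(1, 3), tolerance = 1e-12)
  expect_equal(M, t(M), tolerance = 1e-12)
  expect_error(similarity_matrix(m, rows = "nope"), "unknown")
  # affine display map
  s01 <- similarity_matrix(m, rescale01 = TRUE)
  expect_equal(s01$similarity, (s$similarity + 1) / 2)
  # hand-built orthogonal vectors: raw 0, rescaled 0.5
  fake <- m
  fake$doc_vectors <- rbind(x = c(1, 0, 0, 0, 0, 0, 0, 0),
                            y = c(0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(sim_matrix(similarity_matrix(fake))["x", "y"], 0)
  expect_equal(sim_matrix(similarity_matrix(fake,
                                            rescale01 = TRUE))["x", "y"],
               0.5)
  # scale invariance
  scaled <- m
  scaled$doc_vectors <- m$doc_vectors * 3.7
  expect_equal(similarity_matrix(scaled)$similarity, s$similarity,
               tolerance = 1e-12)
})

test_that("documents from planted topics embed within-topic closer", {
  set.seed(30)
  vocabs <- list(sprintf("a%02d", 1:20), sprintf("b%02d", 1:20),
                 sprintf("c%02d", 1:20))
  results <- sapply(1:3, function(sd) {
    docs_list <- lapply(1:30, function(i) {
      sample(vocabs[[(i - 1) %/% 10 + 1]], 40, replace = TRUE)
    })
    docs <- do.call(doc_tbl, docs_list)
    m <- train_pvdbow(docs, embed_config(dim = 16, window = 5,
                                         epochs = 300, seed = sd))
    M <- sim_matrix(similarity_matrix(m))
    topic <- rep(1:3, each = 10)
    same <- outer(topic, topic, "==") & upper.tri(M)
    diff <- outer(topic, topic, "!=") & upper.tri(M)
    mean(M[same]) > mean(M[diff])
  })
  expect_true(all(results))
})

test_that("text-discussion similarity pairs sessions and aggregates", {
  cfg <- synth_config(seed = 9, n_groups = 1, sessions_per_group = 3,
                      vocab_size = 100, topic_size = 15,
                      text_length = 80, discussion_length = 150,
                      overlap = 0.8)
  corp <- make_corpus(cfg)
  docs <- clean_corpus(corp$transcripts, corp$segments)
  m <- train_pvdbow(docs, embed_config(dim = 16, window = 5, epochs = 400,
                                       seed = 2))
  ts <- text_discussion_similarity(m, docs)
  expect_equal(nrow(ts$sessions), 3)
  expect_equal(ts$groups$n_sessions, 3L)
  expect_equal(ts$groups$mean_similarity, mean(ts$sessions$similarity))
  # a discussion identical to its text is (near) the row maximum
  docs2 <- docs
  docs2$lemmas[[which(docs2$kind == "discussion" & docs2$session == 1)]] <-
    docs2$lemmas[[which(docs2$kind == "text" & docs2$session == 1)]]
  m2 <- train_pvdbow(docs2, embed_config(dim = 16, window = 5,
                                         epochs = 400, seed = 2))
  M <- sim_matrix(similarity_matrix(m2))
  row <- M["MT_1_discussion", colnames(M) != "MT_1_discussion"]
  expect_equal(unname(which.max(row)),
               unname(which(names(row) == "MT_1_text")))
  # unpaired sessions error
  expect_error(text_discussion_similarity(m, docs[docs$kind ==
                                                    "discussion", ]),
               "unpaired")
})

test_that("models persist to text artefacts and restore equivalently", {
  docs <- doc_tbl(rep(c("a", "b", "c"), 10), rep(c("b", "c", "d"), 10))
  m <- train_pvdbow(docs, embed_config(dim = 6, window = 2, epochs = 50,
                                       seed = 6))
  dir <- withr::local_tempdir()
  write_pvdbow(m, dir)
  m2 <- read_pvdbow(dir)
  expect_equal(m2$doc_vectors, m$doc_vectors, tolerance = 1e-12)
  expect_equal(m2$config$epochs, m$config$epochs)
  expect_equal(m2$vocab$lemma, m$vocab$lemma)
  g <- glance(m)
  expect_equal(g$n_docs, 2L)
  expect_equal(g$final_loss, m$final_loss)
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 6)
})
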