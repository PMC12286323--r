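test_that("stratified split reproduces the study marginals and partitions", {
  labs <- data.frame(
    trial_id = sprintf("T%03d", 1:274),
    label = rep(c("understood", "not_understood"), c(174, 100)))
  sp <- make_split(labs, seed = 99)
  tr <- labs$label[labs$trial_id %in% sp$train_ids]
  te <- labs$label[labs$trial_id %in% sp$test_ids]
  expect_equal(sum(tr == "understood"), 122L)    # printed strategy-3 marginals
  expect_equal(sum(te == "understood"), 52L)
  expect_equal(sum(tr == "not_understood"), 70L)
  expect_equal(sum(te == "not_understood"), 30L)
  # partition: union = all, intersection empty
  expect_setequal(c(sp$train_ids, sp$test_ids), labs$trial_id)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  # determinism
  expect_identical(make_split(labs, seed = 99), sp)
  expect_false(identical(make_split(labs, seed = 100)$train_ids, sp$train_ids))
  # strategy-1 marginals 174/74 and 141/61
  labs1 <- data.frame(trial_id = sprintf("S%03d", 1:450),
                      label = rep(c("understood", "not_understood"), c(248, 202)))
  sp1 <- make_split(labs1, seed = 1)
  expect_equal(sum(labs1$label[labs1$trial_id %in% sp1$train_ids] == "understood"), 174L)
  expect_equal(sum(labs1$label[labs1$trial_id %in% sp1$train_ids] == "not_understood"), 141L)
  expect_error(make_split(data.frame(trial_id = c("a", "b"),
                                     label = c("x", "y")), 1),
               ">= 2 trials")
})

test_that("knn prediction agrees with hand-enumerated fixtures", {
  # query coincides with a training point
  x <- matrix(c(0, 0, 5, 5, -3, 1), ncol = 2, byrow = TRUE)
  y <- factor(c("neg", "pos", "neg"), levels = c("neg", "pos"))
  m1 <- knn_fit(x, y, k = 1, positive = "pos")
  p <- predict(m1, c(5, 5))
  expect_equal(as.character(p$label), "pos")
  expect_equal(p$score, 1)
  # 2D fixture: three nearest to the origin are +,+,- with k=3
  x2 <- rbind(c(1, 0), c(0, 1), c(2, 0), c(9, 9), c(0, 8))
  y2 <- factor(c("pos", "pos", "neg", "neg", "neg"), levels = c("neg", "pos"))
  p2 <- predict(knn_fit(x2, y2, k = 3, positive = "pos"), c(0, 0))
  expect_equal(as.character(p2$label), "pos")
  expect_equal(p2$score, 2 / 3)
  expect_error(predict(m1, c(1, 2, 3)), "dimension")
  expect_error(knn_fit(x, y, k = 9), "k must be")
})

test_that("knn agrees with an exhaustive brute-force oracle on 200 points", {
  set.seed(20)
  xtr <- matrix(rnorm(150 * 4), ncol = 4)
  ytr <- factor(sample(c("neg", "pos"), 150, TRUE), levels = c("neg", "pos"))
  xq <- matrix(rnorm(200 * 4), ncol = 4)
  for (k in c(1L, 5L, 12L)) {
    model <- knn_fit(xtr, ytr, k = k, positive = "pos")
    got <- predict(model, xq)
    for (i in seq_len(200)) {
      d <- sqrt(colSums((t(xtr) - xq[i, ])^2))   # O(n^2) oracle
      nn <- order(d)[seq_len(k)]
      votes <- table(ytr[nn])
      expect_equal(got$score[i], mean(ytr[nn] == "pos"))
      if (votes["pos"] != votes["neg"])
        expect_equal(as.character(got$label[i]),
                     names(votes)[which.max(votes)])
    }
  }
})

test_that("knn with k = n_train on balanced data scores every query 0.5", {
  set.seed(21)
  x <- matrix(rnorm(40), ncol = 2)
  y <- factor(rep(c("neg", "pos"), 10), levels = c("neg", "pos"))
  p <- predict(knn_fit(x, y, k = 20, positive = "pos"),
               matrix(rnorm(10), ncol = 2))
  expect_true(all(p$score == 0.5))
})

test_that("duplicating feature dimensions leaves the ranking unchanged", {
  set.seed(22)
  x <- matrix(rnorm(60 * 3), ncol = 3)
  y <- factor(sample(c("neg", "pos"), 60, TRUE), levels = c("neg", "pos"))
  q <- matrix(rnorm(20 * 3), ncol = 3)
  a <- predict(knn_fit(x, y, k = 7, positive = "pos"), q)
  b <- predict(knn_fit(cbind(x, x), y, k = 7, positive = "pos"), cbind(q, q))
  expect_identical(a, b)
})

test_that("tune_k maximizes CV accuracy with smallest-k tie-breaking", {
  set.seed(23)
  # perfectly separable blobs: every k works, tie-break gives 1
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 8), ncol = 2))
  y <- factor(rep(c("a", "b"), each = 30))
  expect_equal(as.integer(tune_k(x, y, seed = 5)), 1L)
  expect_equal(as.integer(tune_k(x, y, k_range = 3, seed = 5)), 3L)
  # label noise: k = 1 overfits, selected k is larger
  set.seed(24)
  x2 <- rbind(matrix(rnorm(300, 0, 1.5), ncol = 2),
              matrix(rnorm(300, 2, 1.5), ncol = 2))
  y2 <- factor(rep(c("a", "b"), each = 150))
  flip <- sample(300, 60)
  y2[flip] <- ifelse(y2[flip] == "a", "b", "a")
  expect_gt(as.integer(tune_k(x2, y2, seed = 6)), 1L)
})

test_that("channel combination enumeration matches binomial sums", {
  combos <- enumerate_channel_combos(20, 4)
  expect_length(combos, 6195L)                   # study count
  expect_length(enumerate_channel_combos(3, 2), 6L)
  set.seed(25)
  for (n in sample(4:12, 3)) {
    m <- sample.int(n, 1)
    expect_length(enumerate_channel_combos(n, m),
                  sum(choose(n, seq_len(m))))
  }
  # deterministic order: sizes ascending, lexicographic within size
  expect_identical(combos[[1]], 1L)
  expect_identical(combos[[21]], c(1L, 2L))
  expect_identical(combos[[length(combos)]], c(17L, 18L, 19L, 20L))
})

make_combo_fixture <- function(n_trials = 60, n_channels = 3, informative = 2,
                               sep = 3, seed = 30) {
  set.seed(seed)
  label <- rep(c("not_understood", "understood"), each = n_trials / 2)
  ids <- sprintf("T%03d", seq_len(n_trials))
  inst <- data.frame(trial_id = rep(ids, each = 3),
                     label = rep(label, each = 3))
  feats <- lapply(seq_len(n_channels), function(ch) {
    shift <- if (ch == informative) sep * (inst$label == "understood") else 0
    matrix(rnorm(nrow(inst) * 2) + shift, ncol = 2,
           dimnames = list(NULL, c("kurtosis", "std")))
  })
  list(features = feats, instances = inst,
       labeled = data.frame(trial_id = ids, label = label))
}

test_that("combo_search ranks informative channels on top, deterministically", {
  fx <- make_combo_fixture()
  sp <- make_split(fx$labeled, seed = 7)
  res <- combo_search(fx$features, fx$instances, sp, k_range = c(1, 3, 5),
                      positive = "understood", seed = 7)
  expect_equal(nrow(res), 7L)                    # C(3,1)+C(3,2)+C(3,3)
  # every top-ranked combo contains the informative channel 2
  top <- res[res$test_ca == max(res$test_ca), "combo"]
  expect_true(all(grepl("2", top)))
  # confusion counts sum to the test-set size for every combo
  expect_true(all(res$tp + res$fn + res$tn + res$fp == length(sp$test_ids)))
  # repeat with the same seed: identical table
  res2 <- combo_search(fx$features, fx$instances, sp, k_range = c(1, 3, 5),
                       positive = "understood", seed = 7)
  expect_identical(res, res2)
  # single channel, single combo
  res1 <- combo_search(fx$features[2], fx$instances, sp,
                       combos = list(1L), k_range = 3,
                       positive = "understood", seed = 7)
  expect_equal(nrow(res1), 1L)
})
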