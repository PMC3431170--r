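# Small labeled feature tables built in code; column names drawn from the
# real feature vocabulary so pool filtering is exercised.
noise_table <- function(n, seed, strong = NULL) {
  set.seed(seed)
  cols <- c(lesionsnake:::texture_feature_names(),
            lesionsnake:::morphology_feature_names())
  tab <- as.data.frame(matrix(rnorm(n * length(cols)), n,
                              dimnames = list(NULL, cols)))
  tab$label <- rep(c("benign", "malignant"), length.out = n)
  if (!is.null(strong))
    tab[[strong]] <- ifelse(tab$label == "malignant", 4, 0) + rnorm(n, sd = 0.3)
  tibble::as_tibble(tab)
}

test_that("a dominant feature is selected first and duplicates never co-enter", {
  tab <- noise_table(40, 1, strong = "entropy")
  sel <- stepwise_select(tab)
  expect_equal(sel[1], "entropy")

  tab2 <- tab
  tab2$contrast <- tab2$entropy     # exact duplicate of the signal column
  sel2 <- stepwise_select(tab2)
  expect_true(sum(c("entropy", "contrast") %in% sel2) == 1)
})

test_that("the feature pool restricts candidates to one family", {
  tab <- noise_table(40, 2, strong = "p2_spiculation")
  sel_m <- stepwise_select(tab, stepwise_config(feature_pool = "morphology"))
  expect_true(all(sel_m %in% lesionsnake:::morphology_feature_names()))
  sel_t <- stepwise_select(tab, stepwise_config(feature_pool = "texture"))
  expect_true(all(sel_t %in% lesionsnake:::texture_feature_names()))
  expect_false("p2_spiculation" %in% sel_t)
})

test_that("null-data selection behaves like the entry threshold dictates", {
  # with 21 independent noise features, the chance that at least one clears
  # the entry threshold is 1 - (1 - p)^21 under the null; check the observed
  # entry rate over 200 replicates against a generous binomial band
  reps <- 200
  entered <- logical(reps)
  for (i in seq_len(reps))
    entered[i] <- length(stepwise_select(noise_table(24, 1000 + i))) > 0
  expected <- 1 - (1 - 0.10)^21
  se <- sqrt(expected * (1 - expected) / reps)
  expect_lt(abs(mean(entered) - expected), 5 * se)
})

test_that("stepwise selection is deterministic and row-order invariant", {
  tab <- noise_table(36, 3, strong = "p5_solidity")
  sel <- stepwise_select(tab)
  set.seed(99)
  for (i in 1:3) {
    perm <- tab[sample(nrow(tab)), ]
    expect_identical(stepwise_select(perm), sel)
  }
})

test_that("the discriminant reduces to the midpoint rule in one dimension", {
  set.seed(4)
  tab <- tibble::tibble(
    entropy = c(rnorm(200, 0), rnorm(200, 10)),
    label = rep(c("benign", "malignant"), each = 200))
  fit <- fit_lda(tab, "entropy")
  # score zero-crossing near 5
  boundary <- -fit$intercept / fit$weights[["entropy"]]
  expect_lt(abs(boundary - 5), 0.5)
})

test_that("discriminant weights equal the closed form pooled-covariance solution", {
  set.seed(5)
  n <- 60
  tab <- tibble::tibble(
    entropy = rnorm(n), p2_spiculation = rnorm(n),
    label = rep(c("benign", "malignant"), each = n / 2))
  tab$entropy <- tab$entropy + (tab$label == "malignant") * 1.5
  fit <- fit_lda(tab, c("entropy", "p2_spiculation"))
  X <- as.matrix(tab[, 1:2])
  Xb <- X[tab$label == "benign", ]; Xm <- X[tab$label == "malignant", ]
  Sp <- (cov(Xb) * (nrow(Xb) - 1) + cov(Xm) * (nrow(Xm) - 1)) / (n - 2)
  w_hand <- solve(Sp) %*% (colMeans(Xm) - colMeans(Xb))
  expect_equal(unname(fit$weights), as.numeric(w_hand), tolerance = 1e-10)
})

test_that("flipped-label duplication cancels the discriminant signal", {
  set.seed(6)
  half <- tibble::tibble(entropy = rnorm(30), contrast = rnorm(30),
                         label = rep(c("benign", "malignant"), 15))
  flipped <- half
  flipped$label <- ifelse(half$label == "benign", "malignant", "benign")
  both <- dplyr::bind_rows(half, flipped)
  fit <- fit_lda(both, c("entropy", "contrast"))
  expect_lt(max(abs(fit$weights)), 1e-10)
})

test_that("leave-one-out runs one fold per lesion and ranks separable data perfectly", {
  tab <- noise_table(24, 7, strong = "entropy")
  sc <- loocv_scores(tab)
  expect_equal(nrow(sc), 24)
  expect_equal(sc$label, as.character(tab$label))
  roc <- roc_analysis(sc$score, sc$label)
  expect_equal(roc$auc, 1)
})

test_that("tidiers return the advertised shapes", {
  tab <- noise_table(30, 8, strong = "entropy")
  fit <- fit_lda(tab, c("entropy", "contrast"))
  td <- generics::tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(nrow(td), 3)  # two features + intercept
  roc <- roc_analysis(rnorm(30), tab$label)
  expect_s3_class(generics::tidy(roc), "tbl_df")
  expect_equal(nrow(generics::glance(roc)), 1)
})

test_that("ROC analysis matches the pair-counting statistic exactly, with ties", {
  set.seed(9)
  for (i in 1:10) {
    n <- 30
    labels <- sample(c("benign", "malignant"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(-2, 2, 0.5), n, replace = TRUE)  # many ties
    roc <- roc_analysis(scores, labels)
    expect_equal(roc$auc, auc_pair_oracle(scores, labels), tolerance = 1e-12)
    rev <- roc_analysis(-scores, labels)
    expect_equal(rev$auc, 1 - roc$auc, tolerance = 1e-12)
  }
})

test_that("perfect scores give a perfect operating point", {
  labels <- rep(c("benign", "malignant"), each = 10)
  scores <- as.numeric(labels == "malignant")
  roc <- roc_analysis(scores, labels)
  expect_equal(roc$auc, 1)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
  expect_equal(roc$accuracy, 1)
  expect_error(roc_analysis(scores, rep("malignant", 20)), "both classes")
})

test_that("DeLong comparison is sane at the extremes and matches pROC", {
  set.seed(10)
  labels <- rep(c("benign", "malignant"), each = 12)
  s1 <- rnorm(24) + (labels == "malignant") * 1.2
  same <- compare_auc(roc_analysis(s1, labels), roc_analysis(s1, labels))
  expect_equal(same$p_value, 1)

  s_perfect <- as.numeric(labels == "malignant")
  s_rand <- rnorm(24)
  extreme <- compare_auc(roc_analysis(s_perfect, labels),
                         roc_analysis(s_rand, labels))
  expect_lt(extreme$p_value, 0.05)

  skip_if_not_installed("pROC")
  s2 <- rnorm(24) + (labels == "malignant") * 0.6
  got <- compare_auc(roc_analysis(s1, labels), roc_analysis(s2, labels))
  ref <- pROC::roc.test(
    pROC::roc(labels, s1, levels = c("benign", "malignant"), direction = "<",
              quiet = TRUE),
    pROC::roc(labels, s2, levels = c("benign", "malignant"), direction = "<",
              quiet = TRUE),
    method = "delong")
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
})
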