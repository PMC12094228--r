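# Component PLRs, PCA selection, stacking, locking and application.

sep_block <- function(n = 100, p = 6, delta = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[y == 1, ] <- x[y == 1, ] + delta
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

test_that("a separable block yields high out-of-fold AUC", {
  b <- sep_block()
  fit <- fit_component_plr(b$x, b$y, seed = 2)
  expect_gte(roc_auc(b$y, fit$oof), 0.95)
})

test_that("label permutation collapses AUC to chance", {
  b <- sep_block(n = 200, delta = 2, seed = 3)
  set.seed(4)
  y_perm <- sample(b$y)
  fit <- fit_component_plr(b$x, y_perm, seed = 4)
  auc <- roc_auc(y_perm, fit$oof)
  expect_gte(auc, 0.35)
  expect_lte(auc, 0.65)
})

test_that("fitting is deterministic under a fixed seed", {
  b <- sep_block(seed = 5)
  f1 <- fit_component_plr(b$x, b$y, seed = 11)
  f2 <- fit_component_plr(b$x, b$y, seed = 11)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$oof, f2$oof)
})

test_that("single-class labels are an error", {
  b <- sep_block()
  expect_error(fit_component_plr(b$x, rep(1, nrow(b$x))),
               class = "cfmonitor_single_class")
  expect_error(fit_artemis_ensemble(matrix(runif(10), 10, 1), rep(0, 10)),
               class = "cfmonitor_single_class")
})

test_that("PCA component count follows the explained-variance target", {
  set.seed(6)
  n <- 80
  # rank-2 signal: two latent directions + labels from the first
  z1 <- rnorm(n); z2 <- rnorm(n)
  load1 <- runif(20); load2 <- runif(20)
  x <- outer(z1, load1) + outer(z2, load2)
  colnames(x) <- paste0("ratio_%02d" |> sprintf(1:20))
  y <- as.integer(z1 > 0)
  fit <- fit_fragmentation_pc_plr(x, y, var_explained = 0.95, seed = 7)
  expect_equal(fit$n_components, 2)

  # eigen-decomposition oracle on isotropic noise
  x2 <- matrix(rnorm(n * 20), n, 20)
  colnames(x2) <- colnames(x)
  ev <- eigen(stats::cov(x2), only.values = TRUE)$values
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.95)[1]
  fit2 <- fit_fragmentation_pc_plr(x2, y, var_explained = 0.95, seed = 8)
  expect_equal(fit2$n_components, k_oracle)

  fit_all <- fit_fragmentation_pc_plr(x2, y, var_explained = 1, seed = 9)
  expect_equal(fit_all$n_components, 20)
})

test_that("missing ratios are mean-imputed from the training cohort", {
  b <- sep_block(n = 60, p = 8, seed = 10)
  colnames(b$x) <- sprintf("ratio_%02d", 1:8)
  x_na <- b$x
  x_na[1, 3] <- NA
  fit <- fit_fragmentation_pc_plr(x_na, b$y, seed = 10)
  expect_equal(fit$impute_means[[3]], mean(x_na[, 3], na.rm = TRUE))
  # application tolerates missing values too
  s <- cfmonitor:::score_pc_plr(fit, x_na)
  expect_true(all(is.finite(s)))
})

test_that("training the full ensemble is deterministic and locked", {
  panel <- cached_panel()
  feats <- panel$training[, -(1:3)]
  m1 <- cached_model()
  m2 <- train_artemis_delfi(feats, panel$training$label, seed = 301)
  expect_identical(m1$training_scores, m2$training_scores)
  expect_identical(m1$checksum, m2$checksum)

  # re-scoring the training matrix reproduces stored scores
  sc <- apply_locked_model(m1, feats)
  expect_lt(max(abs(sc$score - m1$training_scores)), 1e-9)
  expect_true(all(sc$score > 0 & sc$score < 1))

  # tampering with a locked model is caught
  m_bad <- m1
  m_bad$final_stacker$coefficients[1] <-
    m_bad$final_stacker$coefficients[1] + 1
  expect_error(apply_locked_model(m_bad, feats), "checksum")
})

test_that("application errors on missing panel features, naming them", {
  m <- cached_model()
  feats <- cached_panel()$training[, -(1:3)]
  broken <- feats[, setdiff(names(feats), "armz_8q")]
  expect_error(apply_locked_model(m, broken), "armz_8q")
})

test_that("an all-zero feature vector scores as the chained inverse-logit of intercepts", {
  m <- cached_model()
  feats <- cached_panel()$training[, -(1:3)]
  zero <- feats[1, ]
  zero[1, ] <- 0
  got <- apply_locked_model(m, zero)

  comp <- vapply(m$components, function(pl) plogis(pl$intercept),
                 numeric(1))
  artemis <- plogis(m$artemis_stacker$intercept +
                      sum(m$artemis_stacker$coefficients * comp))
  x0 <- rep(0, length(m$ratio_model$features))
  pc_scores <- as.numeric((x0 - m$ratio_model$center) %*%
                            m$ratio_model$rotation)
  ratio_pc <- plogis(m$ratio_model$plr$intercept +
                       sum(m$ratio_model$plr$coefficients * pc_scores))
  armz <- plogis(m$armz_model$intercept)
  final <- plogis(m$final_stacker$intercept +
                    sum(m$final_stacker$coefficients *
                          c(artemis, ratio_pc, armz)))
  expect_equal(got$score, final, tolerance = 1e-12)
})

test_that("synthetic tumor samples outscore matched non-cancer samples", {
  m <- cached_model()
  cfg <- sim_config(seed = 301, fragments_per_sample = 20000,
                    n_reference_healthy = 8, n_training_per_class = 30)
  wins <- 0
  for (i in 1:100) {
    fc <- simulate_sample_features(0.3, cfg, seed = 40000 + i)
    fn <- simulate_sample_features(0, cfg, seed = 50000 + i)
    s <- apply_locked_model(m, dplyr::bind_rows(fc, fn))$score
    wins <- wins + (s[1] > s[2])
  }
  expect_gte(wins, 95)
})

test_that("responder on-treatment scores drop below baseline scores", {
  m <- cached_model()
  cfg <- sim_config(seed = 301, fragments_per_sample = 20000,
                    n_reference_healthy = 8, n_training_per_class = 30)
  baseline <- purrr::map(1:20, function(i) {
    simulate_sample_features(0.05, cfg, seed = 60000 + i)
  }) |> purrr::list_rbind()
  on_tx <- purrr::map(1:20, function(i) {
    simulate_sample_features(0.004, cfg, seed = 70000 + i)
  }) |> purrr::list_rbind()
  s_base <- apply_locked_model(m, baseline)$score
  s_on <- apply_locked_model(m, on_tx)$score
  expect_lt(median(s_on), median(s_base))
})

test_that("JSON serialization round-trips the locked model", {
  m <- cached_model()
  feats <- cached_panel()$training[, -(1:3)]
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble_model(m, path)
  m2 <- read_ensemble_model(path)
  expect_identical(m2$checksum, m$checksum)
  s1 <- apply_locked_model(m, feats)$score
  s2 <- apply_locked_model(m2, feats)$score
  expect_lt(max(abs(s1 - s2)), 1e-9)
})

test_that("tidy and glance summarize the locked model", {
  m <- cached_model()
  td <- tidy(m)
  expect_true(all(c("component", "term", "estimate") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n_components, 6L)
  expect_equal(gl$n_features, length(m$panel))
})
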