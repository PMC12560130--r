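# small labelled fingerprint matrix built directly (no simulator)
make_fm <- function(vals, labels, ids = labels) {
  fm <- data.frame(sample_id = ids, class_label = labels,
                   replicate = 1L, time_s = 30, status = "ok",
                   stringsAsFactors = FALSE)
  vals <- matrix(vals, nrow = length(labels), ncol = 24,
                 dimnames = list(NULL, sensor_columns()))
  fm[sensor_columns()] <- vals
  class(fm) <- c("fingerprint_matrix", "data.frame")
  fm
}

test_that("row standardisation removes per-row constants and is idempotent", {
  fm <- make_fm(rep(2.5, 24 * 3), c("a", "b", "c"))
  cm <- row_standardize(fm)
  expect_true(all(fingerprint_values(cm) == 0))
  expect_equal(cm$row_mean, rep(2.5, 3))
  # hand-computed case: row (1..24)/10 loses its mean 1.25
  fm2 <- make_fm(rep((1:24) / 10, each = 1), "a")
  fm2[sensor_columns()] <- matrix((1:24) / 10, nrow = 1)
  cm2 <- row_standardize(fm2)
  expect_equal(as.numeric(fingerprint_values(cm2)), (1:24) / 10 - 1.25)
  # shift-invariance and idempotence
  fm3 <- fm2
  fm3[sensor_columns()] <- fm2[sensor_columns()] + 17
  expect_equal(fingerprint_values(row_standardize(fm3)),
               fingerprint_values(cm2))
  twice <- row_standardize(cm2)
  expect_equal(fingerprint_values(twice), fingerprint_values(cm2))
  expect_equal(twice$row_mean, cm2$row_mean)  # log preserved
  # rows must sum to zero within 1e-9
  expect_true(all(abs(rowSums(fingerprint_values(cm2))) < 1e-9))
  fm_bad <- fm2; fm_bad$s05 <- NA_real_
  expect_error(row_standardize(fm_bad), "missing")
})

test_that("PCA is deterministic, sign-fixed and explains rank-1 data", {
  withr::with_seed(12, {
    scale_f <- stats::rnorm(30, 2, 1)
    fm <- make_fm(outer(scale_f, (1:24) / 24), rep("a", 30))
  })
  p <- run_pca(fm, n_components = 3)
  expect_equal(p$variance_fraction[1], 1.0, tolerance = 1e-12)
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
  # two well-separated clusters land apart on PC1
  withr::with_seed(13, {
    a <- matrix(stats::rnorm(15 * 24, 0, 0.1), 15)
    b <- matrix(stats::rnorm(15 * 24, 0, 0.1), 15)
    b[, 1:12] <- b[, 1:12] + 5
    fm2 <- make_fm(rbind(a, b), rep(c("a", "b"), each = 15))
  })
  p2 <- run_pca(fm2, 2)
  sa <- p2$scores[1:15, 1]; sb <- p2$scores[16:30, 1]
  expect_true(max(sa) < min(sb) || min(sa) > max(sb))
  expect_error(run_pca(make_fm(rep(0, 24), "a")), "2 rows")
})

test_that("PCA scores on row-standardised data ignore global constants", {
  fm <- run_session(tiny_catalog(), default_chemistries(1),
                    response_model(), seed = 2, replicates = 1)
  cm <- row_standardize(fm)
  shifted <- fm
  shifted[sensor_columns()] <- fm[sensor_columns()] + 3.7
  cm_sh <- row_standardize(shifted)
  expect_equal(run_pca(cm)$scores, run_pca(cm_sh)$scores, tolerance = 1e-9)
})

test_that("stratified split is balanced, disjoint and exhaustive", {
  fm <- make_fm(stats::rnorm(44 * 24), rep(c("a", "b"), c(30, 14)),
                ids = rep(c("s1", "s2", "s3", "s4"), c(15, 15, 11, 3)))
  sp <- stratified_split(fm, "sample_id", 0.5, seed = 1)
  expect_equal(nrow(sp$train) + nrow(sp$validation), 44)
  expect_equal(sum(sp$train$sample_id == "s1"), 8)       # odd 15 -> 8/7
  expect_equal(sum(sp$validation$sample_id == "s1"), 7)
  expect_equal(sum(sp$train$sample_id == "s3"), 6)       # odd 11 -> 6/5
  expect_equal(sum(sp$validation$sample_id == "s3"), 5)
  # disjoint/exhaustive and seed-deterministic, for several seeds
  for (s in 1:5) {
    spx <- stratified_split(fm, "sample_id", 0.5, seed = s)
    key <- function(d) paste(d$sample_id, round(d$s01, 9))
    expect_length(intersect(key(spx$train), key(spx$validation)), 0)
    expect_setequal(c(key(spx$train), key(spx$validation)), key(fm))
  }
  expect_identical(stratified_split(fm, "sample_id", seed = 3),
                   stratified_split(fm, "sample_id", seed = 3))
  fm_single <- make_fm(stats::rnorm(3 * 24), c("a", "a", "b"),
                       ids = c("s1", "s1", "s2"))
  fm_single <- fm_single[-3, ]
  expect_error(stratified_split(rbind(fm_single,
                                      make_fm(stats::rnorm(24), "b", "s2")),
                                "sample_id"), "singleton")
})

test_that("lda_classify matches MASS::lda on well-conditioned data", {
  withr::with_seed(14, {
    n <- 60
    x <- rbind(matrix(stats::rnorm(n * 24, 0), n),
               matrix(stats::rnorm(n * 24, 1.0), n),
               matrix(stats::rnorm(n * 24, -1.5), n))
    fm <- make_fm(x, rep(c("a", "b", "c"), each = n))
  })
  sp <- stratified_split(fm, "class_label", 0.5, seed = 2)
  rep_own <- lda_classify(sp$train, sp$validation, shrinkage = 0)
  oracle <- MASS::lda(fingerprint_values(sp$train),
                      grouping = sp$train$class_label)
  pred <- stats::predict(oracle, fingerprint_values(sp$validation))$class
  expect_equal(rep_own$predicted, as.character(pred))
  expect_equal(rep_own$accuracy,
               mean(pred == sp$validation$class_label))
  # report invariants
  expect_equal(sum(rep_own$confusion), nrow(sp$validation))
  expect_equal(rowSums(rep_own$confusion),
               table(factor(sp$validation$class_label,
                            rep_own$label_set)),
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(rep_own$confusion_pct)), rep(100, 3))
})

test_that("LDA separates separable classes and fails fast otherwise", {
  # linearly separable classes: 100% for every seed in a 10-seed sweep
  withr::with_seed(15, {
    x <- rbind(matrix(stats::rnorm(40 * 24, 0, 0.2), 40),
               matrix(stats::rnorm(40 * 24, 3, 0.2), 40))
    fm <- make_fm(x, rep(c("a", "b"), each = 40))
  })
  for (s in 1:10) {
    sp <- stratified_split(fm, "class_label", 0.5, seed = s)
    expect_equal(lda_classify(sp$train, sp$validation)$accuracy, 1.0)
  }
  # identical generators: accuracy near chance
  withr::with_seed(16, {
    x <- matrix(stats::rnorm(400 * 24), 400)
    fm2 <- make_fm(x, rep(c("a", "b"), each = 200))
  })
  sp2 <- stratified_split(fm2, "class_label", 0.5, seed = 1)
  acc <- lda_classify(sp2$train, sp2$validation)$accuracy
  expect_gt(acc, 0.3); expect_lt(acc, 0.7)
  # label coverage errors
  tr <- fm2[fm2$class_label == "a", ]
  expect_error(lda_classify(tr, fm2), "at least 2 labels")
  tr2 <- fm2[1:250, ]
  va2 <- fm2[251:400, ]
  expect_no_error(lda_classify(tr2, va2))
  va_new <- va2; va_new$class_label[1] <- "zzz"
  expect_error(lda_classify(tr2, va_new), "absent in train")
})

test_that("two-way HCA merges identical rows first and clusters chemistries", {
  withr::with_seed(17, {
    x <- matrix(stats::rnorm(10 * 24), 10)
    x[2, ] <- x[1, ]  # duplicate row
    fm <- make_fm(x, rep("a", 10))
  })
  h <- two_way_hca(fm)
  expect_equal(min(h$row_tree$height), 0)
  first <- sort(-h$row_tree$merge[which.min(h$row_tree$height), ])
  expect_equal(first, c(1, 2))
  # columns driven by identical affinity patterns co-cluster
  withr::with_seed(18, {
    base <- matrix(stats::rnorm(40 * 24, 0, 0.05), 40)
    driver <- stats::rnorm(40, 0, 2)
    base[, 7] <- base[, 7] + driver
    base[, 19] <- base[, 19] + driver
    fm2 <- make_fm(base, rep("a", 40))
  })
  h2 <- two_way_hca(fm2)
  # the driven pair separates jointly from the 22 noise-only columns
  cl <- stats::cutree(h2$col_tree, k = 2)
  expect_equal(cl[[7]], cl[[19]])
  expect_equal(sum(cl == cl[[7]]), 2)
  expect_error(two_way_hca(fm2[1:2, ]), "3 rows")
})

test_that("config files round-trip with defaults spelled out", {
  path <- file.path(withr::local_tempdir(), "cfg.yaml")
  write_default_config(path)
  cfg <- read_config(path)
  expect_s3_class(cfg$layout, "chip_layout")
  expect_equal(cfg$model$bulk_sensitivity, 250)
  expect_equal(cfg$session$seed, 1L)
  expect_length(cfg$catalog, 36)
  # partial config: overrides merge over defaults
  writeLines("response_model:\n  dip_fwhm: 60\nsession:\n  seed: 9", path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$model$dip_fwhm, 60)
  expect_equal(cfg2$model$dip_depth, 0.5)
  expect_equal(cfg2$session$seed, 9)
})
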