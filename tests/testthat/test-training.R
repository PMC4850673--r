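# synthetic labeled instances with a tunable signal: `signal` shifts the
# quality distribution of erroneous positions downward
fake_instances <- function(n_error, n_correct, seed = 1) {
  set.seed(seed)
  n <- n_error + n_correct
  tibble::tibble(
    fwd_pos = sample(0:249, n, replace = TRUE),
    fwd_homopolymer = sample(0:3, n, replace = TRUE),
    fwd_qual = c(sample(5:25, n_error, TRUE), sample(20:40, n_correct, TRUE)),
    rev_pos = sample(0:249, n, replace = TRUE),
    rev_qual = c(sample(5:25, n_error, TRUE), sample(20:40, n_correct, TRUE)),
    overlap = factor(sample(c("NOT_OVERLAP", "MATCH"), n, TRUE),
                     levels = c("NOT_OVERLAP", "MATCH", "CONFLICT", "UNKNOWN")),
    label = factor(c(rep("ERROR", n_error), rep("CORRECT", n_correct)),
                   levels = c("ERROR", "CORRECT")))
}

test_that("the learning subset respects the 1:3 ratio within rounding", {
  inst <- fake_instances(1000, 9000)
  b <- suppressWarnings(build_training_bundle(inst, ratio_a = "1:3", seed = 3))
  nE <- sum(b$a$label == "ERROR"); nC <- sum(b$a$label == "CORRECT")
  expect_equal(nC, 3L * nE)
  expect_gt(nE, 0)
})

test_that("the validation subset is balanced and subsets are disjoint", {
  inst <- fake_instances(800, 4000)
  b <- suppressWarnings(build_training_bundle(inst, seed = 4))
  expect_equal(sum(b$b$label == "ERROR"), sum(b$b$label == "CORRECT"))
  sig <- function(d) do.call(paste, d)
  expect_length(intersect(sig(b$a), sig(b$b)), 0L)
  expect_length(intersect(sig(b$a), sig(b$c)), 0L)
  expect_length(intersect(sig(b$b), sig(b$c)), 0L)
})

test_that("bundles are reproducible under a seed and capped with a warning", {
  inst <- fake_instances(500, 3000)
  suppressWarnings({
    b1 <- build_training_bundle(inst, seed = 5)
    b2 <- build_training_bundle(inst, seed = 5)
  })
  expect_identical(b1$a, b2$a)
  expect_identical(b1$b, b2$b)
  expect_identical(b1$c, b2$c)
  expect_warning(build_training_bundle(inst, seed = 5), "cap")
})

test_that("single-class input is a hard error", {
  inst <- fake_instances(0, 100)
  expect_error(build_training_bundle(inst), "both classes")
})

test_that("a perfect class correlate is selected alone", {
  set.seed(81)
  n <- 600
  label <- factor(sample(c("ERROR", "CORRECT"), n, TRUE),
                  levels = c("ERROR", "CORRECT"))
  inst <- tibble::tibble(
    copy = as.numeric(label == "ERROR"),
    noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
    label = label)
  expect_equal(select_features(inst, seed = 7), "copy")
})

test_that("duplicated informative features are penalized", {
  set.seed(82)
  n <- 900
  signal <- rnorm(n)
  label <- factor(ifelse(signal + rnorm(n, sd = 0.4) > 0, "ERROR", "CORRECT"),
                  levels = c("ERROR", "CORRECT"))
  inst <- tibble::tibble(f1 = signal, f2 = signal, noise = rnorm(n),
                         label = label)
  sel <- select_features(inst, seed = 8)
  expect_lte(sum(sel %in% c("f1", "f2")), 1L)
})

test_that("all-noise features select at most one low-merit feature", {
  set.seed(83)
  n <- 1000
  inst <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                         label = factor(sample(c("ERROR", "CORRECT"), n, TRUE),
                                        levels = c("ERROR", "CORRECT")))
  expect_lte(length(select_features(inst, seed = 9)), 1L)
})
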