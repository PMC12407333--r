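worked_expr <- function() {
  tibble::tibble(
    gene = c("up_over", "up_insuf", "dn_over", "dn_insuf", "flat"),
    MEF      = c(5, 5, 5, 8, 6),
    pre_iPSC = c(8, 5, 2, 8, 6),
    iPSC     = c(5, 8, 5, 5, 6),
    ESC      = c(5, 8, 5, 5, 6)
  )
}

test_that("the four magnitude rules classify the worked examples", {
  calls <- classify_barriers(worked_expr(), delta = 1)
  expect_equal(as.character(calls$class),
               c("over_up", "insufficient_up", "over_down",
                 "insufficient_down", "none"))
})

test_that("classification is invariant to a global expression shift", {
  expr <- worked_expr()
  shifted <- expr
  shifted[, -1] <- shifted[, -1] + 3.7
  expect_equal(classify_barriers(expr)$class, classify_barriers(shifted)$class)
})

test_that("negating expression mirrors over_up <-> over_down and the pair", {
  expr <- worked_expr()
  neg <- expr
  neg[, -1] <- -neg[, -1]
  mirror <- c(over_up = "over_down", over_down = "over_up",
              insufficient_up = "insufficient_down",
              insufficient_down = "insufficient_up", none = "none")
  a <- as.character(classify_barriers(expr)$class)
  b <- as.character(classify_barriers(neg)$class)
  expect_equal(b, unname(mirror[a]))
})

test_that("exactly-at-threshold differences do not trigger a call", {
  expr <- tibble::tibble(gene = "g", MEF = 5, pre_iPSC = 6, iPSC = 5, ESC = 5)
  expect_equal(as.character(classify_barriers(expr, delta = 1)$class), "none")
})

test_that("inputs are validated", {
  expect_error(classify_barriers(worked_expr()[, -2]), "Missing column")
  bad <- worked_expr(); bad$MEF[1] <- NA
  expect_error(classify_barriers(bad), "finite")
  expect_error(classify_barriers(worked_expr(), delta = 0), "delta")
})

test_that("planted classes are recovered perfectly without noise", {
  sim <- simulate_state_expression(n_per_class = 50, n_none = 200,
                                   effect = 3, noise_sd = 0, seed = 1)
  calls <- classify_barriers(sim$expr)
  expect_equal(as.character(calls$class), sim$truth$class)
})

test_that("recovery stays >= 95% at noise sd of a quarter delta", {
  sim <- simulate_state_expression(n_per_class = 250, n_none = 0,
                                   effect = 3, noise_sd = 0.25, seed = 2)
  calls <- classify_barriers(sim$expr, delta = 1)
  acc <- mean(as.character(calls$class) == sim$truth$class)
  expect_gte(acc, 0.95)
})

test_that("a sub-noise planted effect is flagged to the user", {
  expect_warning(
    simulate_state_expression(n_per_class = 5, effect = 0.1, noise_sd = 1),
    "noise floor")
})

test_that("hypergeometric enrichment matches a manual choose() oracle", {
  calls <- tibble::tibble(
    gene = sprintf("g%02d", 1:20),
    class = factor(c(rep("over_up", 5), rep("none", 15)),
                   levels = BARRIER_CLASSES)
  )
  targets <- tibble::tibble(tf = "TF1", gene = sprintf("g%02d", c(1:4, 10:13)))
  enr <- target_enrichment(calls, targets)
  row <- enr[enr$class == "over_up" & enr$tf == "TF1", ]
  expect_equal(row$n_class, 5)
  expect_equal(row$n_in_targets, 4)
  expect_equal(row$fraction, 4 / 5)
  # P(X >= 4) drawing 5 from 8 targets / 12 non-targets
  p_manual <- sum(vapply(4:5, function(k) {
    choose(8, k) * choose(12, 5 - k) / choose(20, 5)
  }, numeric(1)))
  expect_equal(row$p_hyper, p_manual)
})

test_that("empty barrier classes give NA enrichment, not errors", {
  calls <- tibble::tibble(
    gene = c("a", "b"),
    class = factor(c("none", "none"), levels = BARRIER_CLASSES)
  )
  targets <- tibble::tibble(tf = "TF1", gene = "a")
  enr <- target_enrichment(calls, targets)
  expect_true(all(is.na(enr$fraction)))
  expect_true(all(is.na(enr$p_hyper)))
  expect_equal(nrow(enr), 4)
})

test_that("target_set lists are accepted as the target universe", {
  calls <- classify_barriers(worked_expr())
  ts <- target_set("TF1", up = c("up_over", "dn_over"), down = "flat")
  enr <- target_enrichment(calls, list(ts))
  row <- enr[enr$class == "over_up", ]
  expect_equal(row$n_in_targets, 1)
  expect_equal(row$fraction, 1)
})
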