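make_meas <- function(tau, cyc, noise = 0) {
  dna <- dna_content(tau, cyc) + rnorm(length(tau), 0, noise)
  tibble::tibble(label = seq_along(tau), dna = dna,
                 area = 100 * (1 + tau / cyc$total), tau = tau)
}

test_that("ordering recovers a monotone map of cycle position exactly", {
  cyc <- reference_cycle()
  tau <- seq(0, cyc$total - 0.01, length.out = 50)
  meas <- make_meas(tau, cyc)
  meas$pos <- tau # a feature that IS the cycle position
  out <- order_cells(meas, features = c("pos", "area"))
  expect_equal(cor(out$ordering, tau, method = "spearman"), 1)
})

test_that("ordering is invariant to rescaling any feature", {
  cyc <- reference_cycle()
  tau <- seq(0.1, cyc$total - 0.1, length.out = 60)
  meas <- make_meas(tau, cyc)
  a <- order_cells(meas, features = c("dna", "area"))
  meas2 <- meas
  meas2$area <- meas2$area * 1000
  b <- order_cells(meas2, features = c("dna", "area"))
  expect_equal(a$ordering, b$ordering)
})

test_that("degenerate features are dropped; all-degenerate errors", {
  cyc <- reference_cycle()
  tau <- seq(0.1, cyc$total - 0.1, length.out = 30)
  meas <- make_meas(tau, cyc)
  meas$flat <- 5
  expect_message(order_cells(meas, features = c("dna", "area", "flat")),
                 "zero-range")
  meas$flat2 <- 1
  expect_error(
    suppressMessages(order_cells(meas, features = c("flat", "flat2"))),
    "degenerate")
})

test_that("image-derived ordering tracks true cycle position", {
  fx <- run_imaging_fixture(seed = 31)
  m <- fx$meas[!is.na(fx$meas$truth_label), ]
  rho <- cor(m$ordering, m$tau, method = "spearman")
  expect_gte(rho, 0.9) # positive: orientation fixed by the DNA check
})

test_that("staging requires a bimodal DNA distribution", {
  cyc <- reference_cycle()
  set.seed(101)
  tau <- runif(100, 0, cyc$t_g1 - 0.1) # G1 only: all 2N
  meas <- make_meas(tau, cyc, noise = 0.02)
  meas <- order_cells(meas, features = c("dna", "area"))
  expect_error(assign_stages(meas), "unimodal|peak pair")
})

test_that("stage-group assignment agrees with simulation truth >= 90%", {
  fx <- run_imaging_fixture(seed = 31)
  m <- fx$meas[!is.na(fx$meas$truth_label), ]
  acc <- mean(as.character(m$region) == truth_group(m$phase))
  expect_gte(acc, 0.9)
})

test_that("the earliest G1 cells are excluded as early G1", {
  fx <- run_imaging_fixture(seed = 31)
  m <- fx$res$measurements
  g1 <- m[m$region == "G1", ]
  first <- g1[which.min(g1$ordering), ]
  expect_equal(as.character(first$stage), "excluded")
})

test_that("stages appear in canonical order along the ordering", {
  fx <- run_imaging_fixture(seed = 31)
  m <- fx$res$measurements
  kept <- m[m$stage != "excluded", ]
  med <- tapply(kept$ordering, droplevels(kept$stage), median)
  med <- med[c("G1M", "G1L", "SE", "SML", "G2EM", "G2L")]
  expect_false(anyNA(med))
  expect_true(all(diff(med) > 0))
})

test_that("FUCCI G1 gating overrides the DNA-based region", {
  fx <- run_imaging_fixture(seed = 31)
  m <- fx$meas[!is.na(fx$meas$truth_label), ]
  staged <- assign_stages(m, fucci_thresholds = c(100, 100))
  gated <- gate_fucci(staged, 100, 100)
  g1_gated <- gated[gated$fucci_gate == "G1", ]
  expect_true(all(g1_gated$region == "G1"))
  expect_false(any(g1_gated$stage %in% c("G2EM", "G2L")))
})

test_that("a constant mark/DNA ratio gives a flat normalized profile", {
  fx <- run_imaging_fixture(seed = 31)
  m <- fx$res$measurements
  m$mark_const <- 3 * m$dna
  prof <- stage_profile(m, "const")
  expect_equal(prof$norm_ratio[prof$ok], rep(1, sum(prof$ok)))
  expect_equal(attr(prof, "auc"), sum(prof$ok) - 1)
})

test_that("slow marks peak in late G1 and decline into S; fast marks stay flat", {
  fx <- run_imaging_fixture(seed = 31)
  slow <- stage_profile(fx$res$measurements, "H3K27me3", min_cells = 10L)
  ok <- slow[slow$ok, ]
  expect_equal(as.character(ok$stage[which.max(ok$norm_ratio)]), "G1L")
  g1l <- ok$norm_ratio[ok$stage == "G1L"]
  se <- ok$norm_ratio[ok$stage == "SE"]
  sml <- ok$norm_ratio[ok$stage == "SML"]
  expect_gt(g1l, se)
  expect_gt(se, sml)
  fast <- stage_profile(fx$res$measurements, "H3K4me3", min_cells = 10L)
  okf <- fast[fast$ok, ]
  expect_lte(max(okf$norm_ratio) / min(okf$norm_ratio), 1.05)
})

test_that("profile AUC follows the trapezoid rule and is linear in shifts", {
  expect_equal(cyclemark:::.trapz_unit(rep(1, 6)), 5)
  expect_equal(cyclemark:::.trapz_unit(c(1, 2)), 1.5)
  y <- c(1, 0.8, 1.2, 0.9, 1.1, 1)
  expect_equal(cyclemark:::.trapz_unit(y + 2), cyclemark:::.trapz_unit(y) + 10)
})

test_that("profiles fail loudly when too few stages are filled", {
  fx <- run_imaging_fixture(seed = 31)
  m <- fx$res$measurements
  expect_error(stage_profile(m, "H3K27me3", min_cells = 1e6), "Fewer than 4")
})

test_that("compare_profiles renormalizes on the common stage support", {
  fx <- run_imaging_fixture(seed = 31)
  p <- stage_profile(fx$res$measurements, "H3K27me3", min_cells = 10L)
  self <- compare_profiles(p, p)
  expect_equal(self$auc_a, self$auc_b)
  expect_equal(self$range_a, self$range_b)
  expect_equal(self$n_common, sum(p$ok))
})
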