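test_that("target sets validate and derive from perturbation contrasts", {
  expect_error(target_set("X", c("a", "b"), c("b")), "disjoint")
  expect_error(target_set("X"), "empty")
  contrast <- tibble::tibble(
    gene = c("u1", "u2", "d1", "flat"),
    base = c(5, 5, 5, 5),
    perturbed = c(7, 6.5, 3, 5.4)
  )
  ts <- derive_target_set(contrast, "KLF4", fc_threshold = 1)
  expect_setequal(ts$up, c("u1", "u2"))
  expect_equal(ts$down, "d1")
  none <- derive_target_set(contrast, "KLF4", fc_threshold = 10)
  expect_equal(length(none$up) + length(none$down), 0)
  expect_error(derive_target_set(contrast[c(1, 1, 2), ], "X"), "Duplicate")
})

test_that("activity score is mean(up) - mean(down) with empty sides as 0", {
  expr <- c(g1 = 2, g2 = 4, g3 = 1)
  expect_equal(activity_score(expr, target_set("X", c("g1", "g2"), "g3")), 2)
  expect_equal(activity_score(expr, target_set("X", up = c("g1", "g2"))), 3)
  expect_equal(activity_score(expr, target_set("X", down = "g3")), -1)
  expect_true(is.na(activity_score(expr, target_set("X", up = "absent"))))
})

test_that("activity score scales linearly with expression", {
  set.seed(7)
  expr <- setNames(rnorm(10, 5), paste0("g", 1:10))
  ts <- target_set("X", paste0("g", 1:4), paste0("g", 5:8))
  expect_equal(activity_score(3 * expr, ts), 3 * activity_score(expr, ts))
  # and is invariant to replicating a target (size invariance via means)
  ts2 <- target_set("X", paste0("g", c(1, 1, 2, 3, 4)), paste0("g", 5:8))
  expect_equal(activity_score(expr, ts2), activity_score(expr, ts))
})

test_that("planted pseudotime effects give a strictly rising trajectory", {
  fx <- simulate_pseudotime_cells(n_cells = 400, noise_sd = 0.1, seed = 3)
  traj <- activity_trajectory(fx$cells_a, fx$target_sets$OCT4, n_bins = 10)
  expect_equal(nrow(traj), 10)
  expect_equal(cor(traj$bin, traj$mean, method = "spearman"), 1)
  # equal-occupancy bins: counts differ by at most 1
  expect_lte(diff(range(traj$n)), 1)
})

test_that("enhanced-system targets rise faster than baseline", {
  fx <- simulate_pseudotime_cells(n_cells = 400, slope_b = 1.5, seed = 4)
  ta <- activity_trajectory(fx$cells_a, fx$target_sets$SOX2)
  tb <- activity_trajectory(fx$cells_b, fx$target_sets$SOX2)
  slope_a <- coef(lm(mean ~ pseudotime, ta))[2]
  slope_b <- coef(lm(mean ~ pseudotime, tb))[2]
  expect_gt(slope_b, slope_a)
})

test_that("the NR route shows stronger last-factor activity", {
  fx <- simulate_pseudotime_cells(n_cells = 600, nr_frac = 0.3,
                                  nr_slope_factor = 2, seed = 5)
  traj <- activity_trajectory(fx$cells_a, fx$target_sets$KLF4,
                              n_bins = 5, by_route = TRUE)
  late <- traj[traj$bin == 5, ]
  expect_gt(late$mean[late$route == "NR"],
            late$mean[late$route == "reprogramming"])
  # and excluding NR cells removes the route entirely
  no_nr <- activity_trajectory(fx$cells_a, fx$target_sets$KLF4,
                               n_bins = 5, by_route = TRUE, exclude_nr = TRUE)
  expect_false("NR" %in% no_nr$route)
})

test_that("sparse bins are flagged rather than silently summarised", {
  fx <- simulate_pseudotime_cells(n_cells = 12, seed = 6)
  expect_warning(
    traj <- activity_trajectory(fx$cells_a, fx$target_sets$OCT4, n_bins = 10),
    "fewer than 3")
  expect_true(any(traj$low_n))
})

test_that("T/NT/Control groups partition the gene universe", {
  set.seed(11)
  day2 <- tibble::tibble(
    gene = sprintf("g%03d", 1:200),
    expr_a = rnorm(200, 5),
    expr_b = rnorm(200, 5)
  )
  chip <- sprintf("g%03d", 1:60)
  grp <- classify_groups(day2, chip)
  counts <- table(grp$group)
  expect_equal(sum(counts), 200)
  higher <- day2$expr_a - day2$expr_b > 0
  expect_equal(unname(counts["T"] + counts["NT"]), sum(higher))
  expect_true(all(grp$gene[grp$group == "T"] %in% chip))
  expect_false(any(grp$gene[grp$group == "NT"] %in% chip))
})

test_that("group fractions reproduce the half-up printed-percentage style", {
  groups <- tibble::tibble(
    gene = sprintf("g%05d", 1:(1672 + 2919)),
    group = factor(c(rep("T", 1672), rep("NT", 2919)),
                   levels = c("T", "NT", "Control"))
  )
  flags <- tibble::tibble(
    gene = groups$gene,
    higher = c(rep(TRUE, 335), rep(FALSE, 1672 - 335),
               rep(TRUE, 1801), rep(FALSE, 2919 - 1801))
  )
  out <- group_fraction_higher(flags, groups)
  expect_equal(out$percentage[out$group == "T"], 20.04)
  expect_equal(out$percentage[out$group == "NT"], 61.70)
  expect_equal(out$n_total[out$group == "Control"], 0)
  expect_true(is.na(out$percentage[out$group == "Control"]))
  # half-up rounding, not banker's rounding
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("flagged genes outside the group universe are rejected", {
  flags <- tibble::tibble(gene = "x", higher = TRUE)
  groups <- tibble::tibble(gene = "y",
                           group = factor("T", levels = c("T", "NT", "Control")))
  expect_error(group_fraction_higher(flags, groups), "cover")
})

test_that("favorability calls follow the ESC-direction rule", {
  genes <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e"),
    direction = c("higher", "higher", "lower", "lower", "higher"),
    day2 = c(5, 5, 5, 5, 5),
    ESC = c(7, 3, 3, 7, 5),
    pre_iPSC = c(6, 2, 4, 8, 5)
  )
  out <- favorability_call(genes)
  expect_equal(as.character(out$call),
               c("favors", "disfavors", "favors", "disfavors", "neutral"))
  expect_equal(out$pre_ipsc_below_esc, c(TRUE, TRUE, FALSE, FALSE, FALSE))
})
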