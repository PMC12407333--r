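test_that("colony counting applies the threshold/size particle rule", {
  expect_equal(count_colonies(matrix(10, 128, 128)), 0L)
  big <- simulate_colony_plate(5, colony_area = 600, seed = 1)
  expect_equal(count_colonies(big$image), 5L)
  small <- simulate_colony_plate(5, colony_area = 400, seed = 2)
  expect_equal(count_colonies(small$image), 0L)
  expect_equal(count_colonies(small$image, min_size = 300), 5L)
})

test_that("counts are monotone non-increasing in the size filter", {
  mix <- simulate_colony_plate(8, colony_area = c(300, 500, 700, 900),
                               seed = 3)
  sizes <- c(100, 300, 500, 700, 900)
  n <- vapply(sizes, function(s) count_colonies(mix$image, min_size = s),
              integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("connectivity changes what counts as one particle", {
  img <- matrix(0, 64, 64)
  img[10:40, 10:40] <- 100
  img[41:60, 41:60] <- 100 # touches only diagonally at (40,40)/(41,41)
  expect_equal(count_colonies(img, min_size = 100, connectivity = 8), 1L)
  expect_equal(count_colonies(img, min_size = 100, connectivity = 4), 2L)
})

test_that("normalization divides by the control mean", {
  counts <- tibble::tibble(
    gene = rep(c("siNC", "gA", "gB", "gC"), each = 2),
    count = c(20, 20, 30, 30, 10, 10, 0, 0)
  )
  eff <- normalize_counts(counts)
  expect_equal(eff$efficiency[eff$gene == "gA"], 1.5)
  expect_equal(eff$efficiency[eff$gene == "gB"], 0.5)
  expect_equal(eff$efficiency[eff$gene == "gC"], 0)
  expect_equal(eff$efficiency[eff$gene == "siNC"], 1)
  expect_error(normalize_counts(counts[counts$gene != "siNC", ]),
               "Control gene not found")
  zero <- tibble::tibble(gene = "siNC", count = 0)
  expect_error(normalize_counts(zero), "> 0")
})

test_that("hit classes follow the efficiency/trend rules and are exclusive", {
  screen <- tibble::tibble(
    gene = c("a", "b", "c", "d", "e"),
    efficiency = c(0.4, 1.7, 0.4, 1.7, 1.0),
    trend = c("up", "down", "down", "up", "up"),
    diff_flag = c("higher", "ns", "higher", "ns", "higher")
  )
  out <- classify_hits(screen)
  expect_equal(as.character(out$hit_class),
               c("class1", "class2", "none", "none", "none"))
  expect_equal(out$enhanced_candidate, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # boundary: exactly at 1 +/- delta is not a hit
  edge <- tibble::tibble(gene = c("x", "y"), efficiency = c(0.7, 1.3),
                         trend = c("up", "down"))
  expect_true(all(classify_hits(edge, delta = 0.3)$hit_class == "none"))
})

test_that("a planted 112-gene screen is recovered with precision/recall >= 0.9", {
  sim <- simulate_screen(seed = 17)
  eff <- normalize_counts(sim$counts)
  screen <- dplyr::inner_join(eff, sim$trends, by = "gene")
  out <- classify_hits(screen)
  joined <- dplyr::inner_join(out, sim$truth, by = "gene",
                              suffix = c("_called", "_true"))
  called <- joined$hit_class_called != "none"
  planted <- joined$hit_class_true != "none"
  tp <- sum(called & planted &
              as.character(joined$hit_class_called) == joined$hit_class_true)
  precision <- tp / sum(called)
  recall <- tp / sum(planted)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

test_that("stage matrix scores direction consistency against whole-stage", {
  eff <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 4),
    stage = rep(c("whole", "early", "mid", "late"), 2),
    efficiency = c(0.5, 0.6, 0.7, 1.4, # g1: 2 of 3 agree (below control)
                   1.5, 1.2, 1.3, 1.1) # g2: 3 of 3 agree (above control)
  )
  wide <- stage_matrix(eff)
  expect_equal(wide$consistency[wide$gene == "g1"], 2 / 3)
  expect_equal(wide$consistency[wide$gene == "g2"], 1)
  only_whole <- tibble::tibble(gene = "g", stage = "whole", efficiency = 0.5)
  expect_warning(w <- stage_matrix(only_whole), "no single-stage")
  expect_true(is.na(w$consistency))
  expect_error(stage_matrix(only_whole[0, ]), "whole-stage")
})
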