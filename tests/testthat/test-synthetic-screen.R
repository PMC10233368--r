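test_that("config validation enforces capacity and fraction invariants", {
  # 512 preys x 3 tech reps fill a 32 x 48 grid exactly in rowmajor layout
  cfg <- screen_config(n_preys = 512, layout = "rowmajor")
  expect_equal(cfg$n_preys * cfg$n_tech_reps, cfg$grid_rows * cfg$grid_cols)
  # quadrant layout holds one prey per 2x2 block: 384 on a 32 x 48 grid
  expect_error(screen_config(n_preys = 512, layout = "quadrant"),
               "capacity exceeded")
  expect_error(screen_config(n_preys = 385, layout = "quadrant"),
               "capacity exceeded")
  expect_error(screen_config(category_fractions = c(null = 0.6, equal = 0.3,
                                                    prefers_A = 0.1,
                                                    prefers_B = 0.1)),
               "sum to 1")
  expect_error(screen_config(true_fold_change = 1), "true_fold_change")
  expect_silent(screen_config(true_fold_change = 1,
                              category_fractions = c(null = 0.5, equal = 0.5,
                                                     prefers_A = 0,
                                                     prefers_B = 0)))
  expect_error(screen_config(read_noise_sd = -1), ">= 0")
})

test_that("every prey occupies n_tech_reps positions on every membrane", {
  scr <- generate_screen(tiny_config())
  pm <- scr$plate_map
  expect_equal(length(scr$images), 2L * 3L)         # 2 baits x 3 bio reps
  for (mid in names(scr$images)) {
    sub <- pm[pm$membrane_id == mid, ]
    expect_equal(nrow(sub), 96L * 3L)
    expect_true(all(table(sub$prey_id) == 3L))
    expect_false(anyDuplicated(paste(sub$row, sub$col)) > 0)
  }
  # quadrant layout: a prey's replicates are adjacent within one 2x2 block
  one <- pm[pm$membrane_id == names(scr$images)[1L], ]
  spread <- tapply(seq_len(nrow(one)), one$prey_id, function(i)
    max(diff(range(one$row[i])), diff(range(one$col[i]))))
  expect_true(all(spread <= 1))
})

test_that("identical configs generate byte-identical screens", {
  a <- generate_screen(tiny_config(seed = 7))
  b <- generate_screen(tiny_config(seed = 7))
  expect_identical(a, b)
  c <- generate_screen(tiny_config(seed = 8))
  expect_false(identical(a$images, c$images))
})

test_that("planted category counts follow the configured fractions", {
  scr <- generate_screen(tiny_config())
  tab <- table(scr$truth$preys$category)
  # counts are the rounded fractions, with the largest class absorbing the
  # rounding drift so the partition is exact
  expect_true(all(abs(tab[c("null", "equal", "prefers_A", "prefers_B")] -
                        round(c(0.5, 0.3, 0.1, 0.1) * 96)) <= 1))
  expect_equal(unname(tab[c("prefers_A", "prefers_B")]), c(10L, 10L),
               ignore_attr = TRUE)
  expect_equal(sum(tab), 96)
  # planted signal ratios honor the configured fold change
  pr <- scr$truth$preys
  a <- pr[pr$category == "prefers_A", ]
  expect_true(all(a$true_signal_A / a$true_signal_B == 4))
  eq <- pr[pr$category == "equal", ]
  expect_true(all(eq$true_signal_A == eq$true_signal_B))
  nl <- pr[pr$category == "null", ]
  expect_true(all(nl$true_signal_A == 0 & nl$true_signal_B == 0))
})

test_that("zero-noise screens give identical ratios across all 9 replicates", {
  scr <- generate_screen(clean_config())
  td <- scr$truth$dots
  td$bait <- sub("_b[0-9]+$", "", td$membrane_id)
  eq_preys <- scr$truth$preys$prey_id[scr$truth$preys$category == "equal"]
  r <- td[td$prey_id %in% eq_preys & td$bait == "A", ]
  ratio_sd <- tapply(r$signal_integrated / r$control_integrated, r$prey_id,
                     stats::sd)
  expect_equal(max(ratio_sd), 0)
  expect_equal(length(unique(table(r$prey_id))), 1L)
  expect_equal(unique(table(r$prey_id))[[1L]], 9L)
})

test_that("rendered spots integrate to the planted intensity (direct summation)", {
  cfg <- clean_config(background_gradient = 0)
  scr <- generate_screen(cfg)
  img <- scr$images[["B_b2"]]$signal
  td <- scr$truth$dots
  td <- td[td$membrane_id == "B_b2" & td$signal_integrated > 0, ]
  ctr <- planted_centers(cfg, td$row, td$col)
  for (i in seq_len(8)) {              # direct pixel summation oracle
    px <- round(ctr$x[i]) + (-5:5); py <- round(ctr$y[i]) + (-5:5)
    s <- sum(img[py, px] - cfg$background_level)
    expect_lt(abs(s - td$signal_integrated[i]) / td$signal_integrated[i],
              0.02)
  }
})

test_that("generate_sp_set hits its per-position hydropathy targets", {
  # scale maximum: every draw must be Ile
  top <- generate_sp_set(5, 6, list(hi = rep(4.5, 6)), seed = 1)
  expect_true(all(top$hi == "IIIIII"))
  bottom <- generate_sp_set(5, 4, list(lo = rep(-4.5, 4)), seed = 1)
  expect_true(all(bottom$lo == "RRRR"))
  # Monte-Carlo convergence to an interior target
  mid <- generate_sp_set(1000, 3, list(m = rep(0, 3)), seed = 2)
  prof <- group_profile(mid$m, max_len = 3)
  expect_true(all(abs(prof$mean_kd - 0) < 0.2))
  expect_true(all(unlist(strsplit(mid$m, "")) %in% names(kd_scale)))
  expect_error(generate_sp_set(10, 0, list(g = 0)), "length")
  expect_error(generate_sp_set(10, 3, list(g = c(5, 0, 0))),
               "outside the hydropathy scale range")
})

test_that("sp set generation is seed-deterministic", {
  a <- generate_sp_set(20, 8, list(g1 = rep(2, 8), g2 = rep(-2, 8)), seed = 3)
  b <- generate_sp_set(20, 8, list(g1 = rep(2, 8), g2 = rep(-2, 8)), seed = 3)
  expect_identical(a, b)
})
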