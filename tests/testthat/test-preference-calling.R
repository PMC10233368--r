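test_that("normalize_dot returns SA/LC ratios and flags bad controls", {
  expect_equal(normalize_dot(200, 100)$ratio, 2.0)
  expect_equal(normalize_dot(0, 100)$ratio, 0.0)
  zero_ctl <- normalize_dot(200, 0)
  expect_false(zero_ctl$valid)
  expect_true(is.na(zero_ctl$ratio))
  below_floor <- normalize_dot(200, 40, control_floor = 50)
  expect_false(below_floor$valid)
  expect_error(normalize_dot(-1, 100), ">= 0")
})

test_that("replicate aggregation is the median with a count rule", {
  nine <- aggregate_replicates(rep(1.7, 9))
  expect_equal(nine$aggregate, 1.7)
  expect_equal(nine$replicate_sd, 0)
  expect_equal(nine$n_used, 9L)
  robust <- aggregate_replicates(c(rep(1, 8), 10))
  expect_equal(robust$aggregate, 1)        # median shrugs off one outlier
  refused <- aggregate_replicates(c(2, 4), min_replicates = 3)
  expect_true(is.na(refused$aggregate))
  expect_match(refused$reason, "too_few_replicates")
  expect_true(is.na(aggregate_replicates(numeric(0))$aggregate))
  # NA (invalid dot) ratios are dropped before counting
  expect_equal(aggregate_replicates(c(1, 1, 1, NA, NA))$n_used, 3L)
})

test_that("exclusion rules: low-tail Z, one-sidedness, oracle agreement", {
  # each bait group: 19 sets engineered to mean exactly 1.0, SD exactly 0.05,
  # plus one planted outlier -- low (0.4) for bait A, high (2.0) for bait B
  base <- 1 + 0.05 * scale(stats::qnorm(seq(0.05, 0.95,
                                            length.out = 19)))[, 1]
  sets <- data.frame(bait_id = rep(c("A", "B"), each = 20L),
                     prey_id = rep(sprintf("P%02d", 1:20), 2L),
                     aggregate_signal = c(base, 0.4, base, 2.0),
                     replicate_sd = 0.01, n_used = 9L,
                     reason = NA_character_)
  od <- data.frame(strain_id = paste(sets$bait_id, sets$prey_id, sep = ":"),
                   od600 = 1.2)
  out <- apply_exclusions(sets, od, z_threshold = 10, od_floor = 0.05)
  zA <- loo_z_oracle(sets$aggregate_signal[sets$bait_id == "A"])
  zB <- loo_z_oracle(sets$aggregate_signal[sets$bait_id == "B"])
  expect_equal(zA[20L], (0.4 - 1) / 0.05)           # Z = -12
  expect_equal(zB[20L], (2.0 - 1) / 0.05)           # Z = +20
  # the Z = -12 set is excluded with the right reason ...
  expect_true(out$excluded[out$bait_id == "A"][20L])
  expect_equal(out$exclusion_reason[out$bait_id == "A"][20L], "low_z")
  # ... the Z = +20 high outlier is not: the rule is one-sided (low tail)
  expect_false(out$excluded[out$bait_id == "B"][20L])
  # and exclusion agrees with the independent leave-one-out oracle, set for set
  expect_equal(out$excluded, c(zA, zB) < -10)
  expect_equal(out$membrane_z[out$bait_id == "A"], zA, tolerance = 1e-12)
})

test_that("pre-lysis OD rules exclude missing strains and unknown strains", {
  sets <- data.frame(bait_id = "A", prey_id = sprintf("P%02d", 1:12),
                     aggregate_signal = 1, replicate_sd = 0.01,
                     n_used = 9L, reason = NA_character_)
  od <- data.frame(strain_id = paste0("A:", sprintf("P%02d", 1:11)),
                   od600 = c(0.01, rep(1.2, 10)))   # P12 absent from table
  out <- apply_exclusions(sets, od, od_floor = 0.05)
  expect_true(out$excluded[1L])
  expect_equal(out$exclusion_reason[1L], "missing_strain")
  expect_false(out$od_ok[1L])
  expect_true(out$excluded[12L])
  expect_equal(out$exclusion_reason[12L], "no_od")
  expect_true(all(!out$excluded[2:11]))
})

test_that("high replicate SD flags but does not exclude", {
  sets <- data.frame(bait_id = "A", prey_id = sprintf("P%02d", 1:12),
                     aggregate_signal = 1,
                     replicate_sd = c(4, rep(0.1, 11)),
                     n_used = 9L, reason = NA_character_)
  od <- data.frame(strain_id = paste0("A:", sets$prey_id), od600 = 1.2)
  out <- apply_exclusions(sets, od, sd_flag_threshold = 3)
  expect_true(out$sd_flag[1L])
  expect_false(out$excluded[1L])
  expect_equal(sum(out$sd_flag), 1L)
})

test_that("the twofold rule is strict and floor-aware", {
  fl <- 0.1
  expect_equal(as.character(call_preference(2.1, 1.0, 2, fl)$category),
               "prefers_A")
  expect_equal(call_preference(2.1, 1.0, 2, fl)$fold_change, 2.1)
  # boundary: 2.0 is not > 2
  expect_equal(as.character(call_preference(2.0, 1.0, 2, fl)$category),
               "both")
  expect_equal(as.character(call_preference(1.0, 2.1, 2, fl)$category),
               "prefers_B")
  expect_equal(as.character(call_preference(0.01, 0.02, 2, fl)$category),
               "no_interaction")
  # one side at background: fold change against the floor, same strict rule
  one_up <- call_preference(0.5, 0.02, 2, fl)
  expect_equal(as.character(one_up$category), "prefers_A")
  expect_equal(one_up$fold_change, 5)
  expect_equal(as.character(call_preference(0.15, 0.02, 2, fl)$category),
               "both")
  # excluded side propagates
  expect_equal(as.character(call_preference(NA, 1.0, 2, fl)$category),
               "excluded")
  expect_error(call_preference(-1, 1, 2, fl), ">= 0")
})

test_that("screen summaries partition the preys", {
  pairs <- data.frame(prey_id = c("a", "b", "c", "d"),
                      category = c("both", "prefers_A", "no_interaction",
                                   "prefers_A"))
  s <- summarize_screen(pairs)
  expect_equal(sum(s$n), 4L)
  expect_equal(s$n[s$category == "prefers_A"], 2L)
  empty <- summarize_screen(data.frame(prey_id = character(0),
                                       category = character(0)))
  expect_true(all(empty$n == 0L))
  expect_equal(nrow(empty), 5L)
  dup <- data.frame(prey_id = c("a", "a"), category = c("both", "both"))
  expect_error(summarize_screen(dup), "duplicate")
})

test_that("planted preferences are recovered on a small noisy screen", {
  scr <- generate_screen(tiny_config(missing_strain_fraction = 0,
                                     dropout_fraction = 0, seed = 31))
  dots <- quantify_membranes(scr$images, 16, 24)
  sets <- apply_exclusions(build_sets(dots, scr$plate_map), scr$od_table)
  pairs <- call_preferences(sets,
                            detection_floor = detection_floor_auto(dots,
                                                                   scr$plate_map))
  m <- merge(scr$truth$preys, pairs, by = "prey_id")
  pref <- m$category.x %in% c("prefers_A", "prefers_B")
  expect_gte(mean((m$category.x == as.character(m$category.y))[pref]), 0.95)
  called_pref <- as.character(m$category.y) %in% c("prefers_A", "prefers_B")
  expect_lte(mean(called_pref[!pref]), 0.05)
  expect_equal(sum(summarize_screen(pairs)$n), 96L)
  # reproducibility property: replicate SDs stay below the flag level
  expect_lt(max(sets$replicate_sd[!sets$excluded]), 3)
})

test_that("relabeling the baits swaps the preferring categories exactly", {
  scr <- generate_screen(tiny_config(seed = 13))
  dots <- quantify_membranes(scr$images, 16, 24)
  sets <- apply_exclusions(build_sets(dots, scr$plate_map), scr$od_table)
  fl <- detection_floor_auto(dots, scr$plate_map)
  fwd <- summarize_screen(call_preferences(sets, detection_floor = fl))
  rev <- summarize_screen(call_preferences(sets, detection_floor = fl,
                                           baits = c("B", "A")))
  expect_equal(fwd$n[fwd$category == "prefers_A"],
               rev$n[rev$category == "prefers_B"])
  expect_equal(fwd$n[fwd$category == "prefers_B"],
               rev$n[rev$category == "prefers_A"])
  keep <- c("excluded", "no_interaction", "both")
  expect_equal(fwd$n[fwd$category %in% keep], rev$n[rev$category %in% keep])
})
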