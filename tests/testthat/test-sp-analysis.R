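# brute-force oracle: hydropathy means straight from the published table
kd_tab <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
            G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
            H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
            R = -4.5)

test_that("kd_values reproduces the published scale", {
  expect_equal(unname(kd_values("I")), 4.5)
  expect_equal(unname(kd_values("R")), -4.5)
  for (aa in names(kd_tab))
    expect_equal(unname(kd_values(aa)), unname(kd_tab[aa]))
  expect_equal(unname(kd_values("MKI")), unname(kd_tab[c("M", "K", "I")]))
  expect_error(kd_values("MXK"), "unknown residue 'X' at position 2")
  expect_error(kd_values(""), "nonempty")
})

test_that("group profiles match brute-force averages of the scale table", {
  p <- group_profile(c("II", "AA"))
  expect_equal(p$mean_kd[p$position == 1], (4.5 + 1.8) / 2)  # 3.15
  expect_equal(p$mean_kd[p$position == 2], 3.15)
  expect_equal(p$sem_kd[p$position == 1],
               stats::sd(c(4.5, 1.8)) / sqrt(2))
  expect_equal(p$n, c(2, 2))
  # single sequence: SEM reported 0, n flags the convention
  single <- group_profile("MKT")
  expect_equal(single$sem_kd, c(0, 0, 0))
  expect_equal(single$n, c(1, 1, 1))
  # variable lengths: n(p) nonincreasing, short sequences drop out
  var_len <- group_profile(c("IIII", "II"))
  expect_equal(var_len$n, c(2, 2, 1, 1))
  expect_true(all(diff(var_len$n) <= 0))
  expect_error(group_profile(character(0)), "at least one")
})

test_that("profiles of identical sequences round-trip kd_values", {
  p <- group_profile(rep("MKWVT", 7))
  expect_equal(p$mean_kd, unname(kd_values("MKWVT")))
  expect_equal(p$sem_kd, rep(0, 5))
})

test_that("duplicating a group keeps the mean and shrinks the SEM ~sqrt(2)", {
  seqs <- generate_sp_set(50, 10, list(g = rep(1, 10)), seed = 5)$g
  p1 <- group_profile(seqs)
  p2 <- group_profile(c(seqs, seqs))
  expect_equal(p2$mean_kd, p1$mean_kd)
  # sample-SD convention: exact ratio is sqrt((n-1)/(2n-1)), -> 1/sqrt(2)
  n <- 50
  expect_equal(p2$sem_kd / p1$sem_kd, rep(sqrt((n - 1) / (2 * n - 1)), 10),
               tolerance = 1e-10)
  expect_equal(sqrt((n - 1) / (2 * n - 1)), 1 / sqrt(2), tolerance = 0.01)
})

test_that("windowed profiles are available but off by default", {
  p0 <- group_profile(c("IRIRIR"), window = 1)
  expect_equal(p0$mean_kd, unname(kd_values("IRIRIR")))
  p3 <- group_profile(c("IRIRIR"), window = 3)
  expect_equal(p3$mean_kd[2], mean(c(4.5, -4.5, 4.5)))
  expect_error(group_profile("IRIR", window = 2), "odd")
})

test_that("prefix swap is an exact involution", {
  sw <- swap_prefix("MKFAB", "MQRCD", 3)
  expect_equal(unname(sw), c("MQRAB", "MKFCD"))
  # involution
  back <- swap_prefix(sw[["variant1"]], sw[["variant2"]], 3)
  expect_equal(unname(back), c("MKFAB", "MQRCD"))
  # identity at k = 0, length preservation
  expect_equal(unname(swap_prefix("MKFAB", "MQRCD", 0)),
               c("MKFAB", "MQRCD"))
  sw2 <- swap_prefix("MKFABLONG", "MQR", 2)
  expect_equal(nchar(unname(sw2)), c(9L, 3L))
  expect_error(swap_prefix("MK", "MQRCD", 3), "exceeds")
})

test_that("substrate filtering implements (SP or TMD) and not MTS", {
  ann <- data.frame(protein_id = c("p1", "p2", "p3", "p4", "p5"),
                    has_sp = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                    has_tmd = c(FALSE, FALSE, TRUE, FALSE, TRUE),
                    has_mts = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  pairs <- data.frame(prey_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
                      category = c("prefers_A", "prefers_A", "prefers_B",
                                   "both", "both", "no_interaction"))
  out <- filter_substrates(pairs, ann)
  expect_equal(out$candidate[1:5], c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_true(out$annotation_missing[6])
  expect_true(is.na(out$candidate[6]))
  # conservation: candidates + non-candidates + missing = all preys
  expect_equal(sum(out$candidate, na.rm = TRUE) +
                 sum(!out$candidate, na.rm = TRUE) +
                 sum(out$annotation_missing), nrow(pairs))
  cc <- attr(out, "category_counts")
  expect_equal(unname(cc[c("prefers_A", "prefers_B", "both")]),
               c(1L, 1L, 1L), ignore_attr = TRUE)
})

test_that("synthetic SP groups separate at the N terminus beyond 2 pooled SEM", {
  sets <- generate_sp_set(60, 20,
                          list(grpA = c(3.8, 3.8, 3.8, rep(1, 17)),
                               grpB = c(-3.0, -3.0, -3.0, rep(1, 17))),
                          seed = 17)
  pa <- group_profile(sets$grpA, group = "grpA")
  pb <- group_profile(sets$grpB, group = "grpB")
  for (p in 1:3) {
    gap <- abs(pa$mean_kd[p] - pb$mean_kd[p])
    pooled <- sqrt(pa$sem_kd[p]^2 + pb$sem_kd[p]^2)
    expect_gt(gap, 2 * pooled)
  }
})

test_that("reporter constructs inherit the SP donor's planted preference", {
  phobic <- "MIVLAASST"     # hydrophobic start -> planted bait-A preference
  philic <- "MDDKAASST"     # hydrophilic start -> planted bait-B preference
  expect_equal(sp_planted_preference(phobic), "prefers_A")
  expect_equal(sp_planted_preference(philic), "prefers_B")
  rep1 <- build_reporter(phobic, donor_id = "p1")
  expect_s3_class(rep1, "sp_reporter")
  expect_equal(sp_planted_preference(rep1), sp_planted_preference(phobic))
  expect_error(build_reporter(""), "nonempty")
  # swapping the first three residues converts the preference: each variant
  # follows its prefix donor, not its body donor
  sw <- swap_prefix(phobic, philic, 3)
  expect_equal(sp_planted_preference(sw[["variant1"]]), "prefers_B")
  expect_equal(sp_planted_preference(sw[["variant2"]]), "prefers_A")
  expect_equal(sp_planted_preference(build_reporter(sw[["variant1"]])),
               "prefers_B")
})
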