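test_that("candidate pair enumeration covers all ordered pairs", {
  expect_identical(nrow(enumerate_candidate_pairs(sprintf("C%03d", 1:1777))),
                   1777L * 1776L)
  two <- enumerate_candidate_pairs(c("A00", "B00"))
  expect_equal(as.data.frame(two),
               data.frame(d1 = c("A00", "B00"), d2 = c("B00", "A00")))
  expect_identical(nrow(enumerate_candidate_pairs("A00")), 0L)
  ## deterministic lexicographic order, no self-pairs
  p <- enumerate_candidate_pairs(c("Z00", "A00", "M54"))
  expect_identical(p, p[order(d1, d2)])
  expect_true(all(p$d1 != p$d2))
})

test_that("relative risk is Eq.-exact, with an infinite-RR sentinel", {
  expect_identical(relative_risk(10, c(5, 5, 5, 5)), 2)
  expect_identical(relative_risk(7, c(0, 1, 2)), 7)
  expect_identical(relative_risk(3, c(0, 0, 0)), Inf)
  expect_error(relative_risk(0, c(0, 0)), "undefined")
  expect_error(relative_risk(1, numeric(0)), "empty")
  ## rr * mean(controls) recovers c_exposed exactly
  set.seed(21)
  for (i in 1:50) {
    ce <- rpois(1, 20)
    cc <- rpois(sample(1:30, 1), 5)
    if (mean(cc) == 0) next
    expect_equal(relative_risk(ce, cc) * mean(cc), ce, tolerance = 1e-12)
  }
})

test_that("pair significance is the exact binomial tail with half-ties", {
  ## C_exposed beats all 20 controls: P = 0.5^20
  expect_equal(pair_significance(10, rep(0, 20)), 0.5^20)
  ## all ties: successes = N/2, central P-value
  expect_equal(pair_significance(5, rep(5, 20)),
               pbinom(9, 20, 0.5, lower.tail = FALSE))
  ## a tie counts half: 3 wins + 1 tie out of 4 is P(X >= 4) = 0.5^4
  expect_equal(pair_significance(5, c(1, 2, 3, 5)), 0.5^4)
  ## monotone: more wins cannot raise the P-value
  p_seq <- vapply(0:10, function(k)
    pair_significance(1, c(rep(0, k), rep(2, 10 - k))), numeric(1))
  expect_true(all(diff(p_seq) <= 0))
})

test_that("directionality test counts strict orderings inside the window", {
  ## 20 patients, all d1 strictly first: P = 0.5^20
  ev <- data.frame(pid = rep(sprintf("p%02d", 1:20), each = 2),
                   date = rep(c("2000-01-01", "2001-06-01"), 20),
                   code = rep(c("A00", "B00"), 20))
  reg <- tiny_registry(ev)
  d <- directionality_test(reg, "A00", "B00")
  expect_identical(c(d$n_d1_first, d$n_d2_first), c(20L, 0L))
  expect_equal(d$p_direction, 0.5^20)
  ## antisymmetry: reversing every event order swaps the counts exactly
  ev_rev <- ev; ev_rev$code <- rep(c("B00", "A00"), 20)
  d_rev <- directionality_test(tiny_registry(ev_rev), "A00", "B00")
  expect_identical(c(d_rev$n_d1_first, d_rev$n_d2_first), c(0L, 20L))
  ## 10 vs 10 is not significant
  ev_half <- ev
  ev_half$code[1:20] <- rep(c("B00", "A00"), 10)
  d_half <- directionality_test(tiny_registry(ev_half), "A00", "B00")
  expect_identical(c(d_half$n_d1_first, d_half$n_d2_first), c(10L, 10L))
  expect_gt(d_half$p_direction, 0.5)
  ## same-day first occurrences are unusable; none usable -> NA
  same <- tiny_registry(data.frame(pid = c("p1", "p1"), date = "2000-01-01",
                                   code = c("A00", "B00")))
  expect_true(is.na(directionality_test(same, "A00", "B00")$p_direction))
  ## pairs separated by more than the window are unusable
  far <- tiny_registry(data.frame(pid = c("p1", "p1"),
                                  date = c("2000-01-01", "2007-01-01"),
                                  code = c("A00", "B00")))
  expect_true(is.na(directionality_test(far, "A00", "B00")$p_direction))
})

test_that("pre-filter retains planted pairs and drops empty ones", {
  cfg <- simulation_config(
    6000, code_universe = c(A00 = 0.02, B00 = 0.004, C00 = 0.004),
    rules = data.frame(source = "A00", target = "B00", multiplier = 50,
                       lag_mean = 1, lag_sd = 0.8),
    seed = 17)
  reg <- simulate_registry(cfg)
  pre <- prefilter_pairs(reg, threshold_config())
  expect_true(nrow(merge(pre, data.frame(d1 = "A00", d2 = "B00"))) == 1L)
  ## brute-force confirmation of the retained pair's binomial tail: a
  ## patient counts when any B00 event falls within 5y after first A00
  fo <- first_occurrences(reg)
  af <- fo[fo$code == "A00"]; bf <- fo[fo$code == "B00"]
  k <- 0L
  for (pid in af$patient_id) {
    ta <- af$first_date[af$patient_id == pid]
    tb <- reg$events[patient_id == pid & code == "B00", date]
    g <- as.numeric(tb - ta)
    if (any(g > 0 & g <= 5 * 365.25)) k <- k + 1L
  }
  p0 <- nrow(bf) / nrow(reg$patients)
  p_brute <- pbinom(k - 1, nrow(af), p0, lower.tail = FALSE)
  row <- prefilter_pairs(reg, threshold_config(), keep_all = TRUE)
  row <- row[row$d1 == "A00" & row$d2 == "B00"]
  expect_identical(row$n_within, k)
  expect_equal(row$p_cooccurrence, p_brute)
  expect_lt(p_brute, 1.21e-9)
  ## zero co-occurrence means P = 1 and removal
  none <- tiny_registry(data.frame(pid = c("p1", "p2"),
                                   date = c("2000-01-01", "2001-01-01"),
                                   code = c("A00", "B00")))
  all_rows <- prefilter_pairs(none, threshold_config(prefilter_alpha = 0.5),
                              keep_all = TRUE)
  expect_true(all(all_rows$p_cooccurrence == 1))
  expect_identical(nrow(prefilter_pairs(none, threshold_config())), 0L)
})

test_that("timestamp permutation destroys pre-filter retention", {
  cfg <- simulation_config(
    3000, code_universe = c(A00 = 0.02, B00 = 0.006),
    rules = data.frame(source = "A00", target = "B00", multiplier = 40,
                       lag_mean = 1, lag_sd = 0.8),
    seed = 23)
  reg <- simulate_registry(cfg)
  expect_true(nrow(prefilter_pairs(reg, threshold_config())) >= 1L)
  ## redraw every event date uniformly over its patient's at-risk interval:
  ## each patient keeps their codes, but the temporal clustering that makes
  ## windowed co-occurrence excessive is destroyed
  pat <- merge(reg$events[, .(patient_id)], reg$patients, by = "patient_id")
  lo <- as.numeric(pmax(pat$birth_date, reg$window[1]))
  hi <- as.numeric(pmin(data.table::fifelse(is.na(pat$death_date),
                                            reg$window[2], pat$death_date),
                        reg$window[2]))
  set.seed(1)
  hits <- 0L
  for (rep_i in 1:20) {
    ev <- data.table::copy(reg$events)
    ev[, date := as.Date(floor(runif(.N, lo, hi + 1)), origin = "1970-01-01")]
    ev[, week := as.integer(data.table::isoweek(date))]
    reg_p <- new_registry(reg$patients, ev, window = reg$window,
                          validate = FALSE)
    hits <- hits + nrow(prefilter_pairs(reg_p, threshold_config()))
  }
  expect_lte(hits / 20, 0.05)
})

test_that("matched control draws are seeded, bounded and d2-free when d2 absent", {
  cfg <- simulation_config(1500, seed = 4)
  reg <- simulate_registry(cfg)
  m1 <- sample_matched_controls(reg, "I10", "N18", n_controls = 60, seed = 7)
  m2 <- sample_matched_controls(reg, "I10", "N18", n_controls = 60, seed = 7)
  expect_identical(m1$control_counts, m2$control_counts)
  expect_identical(m1$c_exposed, m2$c_exposed)
  expect_length(m1$control_counts, 60L)
  expect_true(all(m1$control_counts >= 0 &
                    m1$control_counts <= m1$n_exposed))
  ## registry where no non-exposed patient ever has d2: all C_i = 0
  ev <- data.frame(pid = c("p1", "p1", "p2", "p3"),
                   date = c("2000-01-01", "2001-01-01",
                            "2000-02-01", "2000-03-01"),
                   code = c("A00", "B00", "C00", "C00"))
  reg0 <- tiny_registry(ev)
  m0 <- sample_matched_controls(reg0, "A00", "B00", n_controls = 25, seed = 1)
  expect_identical(m0$control_counts, rep(0L, 25))
  expect_identical(m0$c_exposed, 1L)
  expect_error(sample_matched_controls(reg0, "Q99", "B00"), "no patient")
})

test_that("exposed count sits centrally in the control ensemble under the null", {
  ## exchangeability isolated by construction: exposure is a label attached
  ## to one uniformly chosen discharge per randomly chosen patient, so the
  ## exposed anchor mechanism is identical to the control pool's; the rank
  ## of C_exposed among the C_i must then be two-sided and centred
  set.seed(77)
  ranks <- vapply(1:30, function(i) {
    cfg <- simulation_config(
      1500, code_universe = c(B00 = 0.03, C00 = 0.05, D00 = 0.05,
                              E00 = 0.05),
      seed = 1000 + i)
    reg <- simulate_registry(cfg)
    ## anchor exposure at uniformly chosen discharges (the pool's own
    ## anchor mechanism), one per exposed patient
    ev <- data.table::copy(reg$events)
    pick <- ev[sample(.N, min(400L, .N))]
    pick <- pick[!duplicated(patient_id)][seq_len(min(250L, .N))]
    pick[, code := "A00"]
    reg2 <- new_registry(reg$patients, rbind(ev, pick),
                         window = reg$window, validate = FALSE)
    mc <- sample_matched_controls(reg2, "A00", "B00", n_controls = 40,
                                  seed = i)
    (sum(mc$control_counts < mc$c_exposed) +
        0.5 * sum(mc$control_counts == mc$c_exposed)) / 40
  }, numeric(1))
  expect_gt(mean(ranks), 0.35)
  expect_lt(mean(ranks), 0.65)
  ## both tails populated, no systematic displacement to one side
  expect_gt(mean(ranks < 0.5), 0.2)
  expect_gt(mean(ranks > 0.5), 0.2)
})

test_that("full mining recovers planted pairs only, never both directions", {
  rules <- data.frame(
    source = c("I10", "I10", "N18"),
    target = c("N18", "E11", "D50"),
    multiplier = c(25, 15, 25),
    lag_mean = c(2, 1.5, 1), lag_sd = 0.8)
  cfg <- simulation_config(8000, rules = rules, seed = 13)
  reg <- simulate_registry(cfg)
  th <- threshold_config(n_controls = 100)
  res <- mine_directional_pairs(reg, th, seed = 5)
  got <- paste(res$pairs$d1, res$pairs$d2)
  expect_true(all(paste(rules$source, rules$target) %in% got))
  ## mutual exclusivity
  expect_identical(
    nrow(merge(res$pairs[, .(d1, d2)], res$pairs[, .(d1 = d2, d2 = d1)],
               by = c("d1", "d2"))), 0L)
  ## stage counts are internally consistent
  sc <- res$stage_counts
  expect_identical(unname(sc["directional"]), nrow(res$pairs))
  expect_true(sc["prefiltered"] <= sc["candidates"])
  expect_true(sc["directional"] <= sc["significant"])
  ## determinism: same registry, thresholds and seed
  res2 <- mine_directional_pairs(reg, th, seed = 5)
  expect_equal(res$pairs, res2$pairs)
})

test_that("lowering alphas never adds pairs (monotonicity)", {
  cfg <- simulation_config(
    5000, code_universe = c(A00 = 0.02, B00 = 0.005, C00 = 0.01),
    rules = data.frame(source = "A00", target = "B00", multiplier = 30,
                       lag_mean = 1.5, lag_sd = 0.8),
    seed = 41)
  reg <- simulate_registry(cfg)
  loose <- threshold_config(prefilter_alpha = 1e-4, pair_alpha = 1e-3,
                            direction_alpha = 0.2, n_controls = 100)
  tight <- threshold_config(prefilter_alpha = 1e-9, pair_alpha = 1e-6,
                            direction_alpha = 0.01, n_controls = 100)
  got_loose <- mine_directional_pairs(reg, loose, seed = 2)$pairs
  got_tight <- mine_directional_pairs(reg, tight, seed = 2)$pairs
  expect_true(all(paste(got_tight$d1, got_tight$d2) %in%
                    paste(got_loose$d1, got_loose$d2)))
})

test_that("sex-specific mining finds sex-restricted effects", {
  ## plant the rule, then erase the target code in females so the
  ## progression only exists in males
  cfg <- simulation_config(
    9000, code_universe = c(A00 = 0.03, B00 = 0.006, C00 = 0.01),
    rules = data.frame(source = "A00", target = "B00", multiplier = 30,
                       lag_mean = 1.5, lag_sd = 0.8),
    seed = 19)
  reg <- simulate_registry(cfg)
  females <- reg$patients[reg$patients$sex == "female", patient_id]
  ev <- reg$events[!(patient_id %in% females & code == "B00")]
  reg_m <- new_registry(reg$patients, ev, window = reg$window,
                        validate = FALSE)
  th <- threshold_config(n_controls = 80)
  male_hit <- mine_directional_pairs(reg_m, th, sex_filter = "male",
                                     seed = 3)$pairs
  female_hit <- mine_directional_pairs(reg_m, th, sex_filter = "female",
                                       seed = 3)$pairs
  expect_true("B00" %in% male_hit$d2[male_hit$d1 == "A00"])
  expect_false("B00" %in% female_hit$d2[female_hit$d1 == "A00"])
})
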