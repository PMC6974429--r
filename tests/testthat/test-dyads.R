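roster9 <- list(p = sprintf("a%02d", 1:9))

test_that("aggregate_dyads tallies directed wins per unordered pair", {
  log <- make_log(c("a01", "a01", "a01", "a02"), c("a02", "a02", "a02", "a01"),
                  roster9)
  tab <- aggregate_dyads(log)
  expect_s3_class(tab, "dyad_table")
  expect_equal(nrow(tab), choose(9, 2))
  rec <- tab[tab$animal_a == "a01" & tab$animal_b == "a02", ]
  expect_equal(c(rec$wins_a, rec$wins_b, rec$difference), c(3, 1, 2))
  expect_equal(sum(tab$total), 4)

  empty <- make_log(character(), character(), roster9)
  tab0 <- aggregate_dyads(empty)
  expect_equal(nrow(tab0), 36)
  expect_true(all(tab0$total == 0))
})

test_that("aggregate_dyads matches a brute-force per-event tally", {
  log <- simulate_pen(generator_config(lambda0 = 0.4), "p1", seed = 11)
  tab <- aggregate_dyads(log)
  ev <- log$events
  for (i in sample(nrow(tab), 20)) {
    a <- tab$animal_a[i]; b <- tab$animal_b[i]
    expect_equal(tab$wins_a[i], sum(ev$winner == a & ev$loser == b))
    expect_equal(tab$wins_b[i], sum(ev$winner == b & ev$loser == a))
  }
  expect_equal(sum(tab$total), nrow(ev))
})

test_that("dyad-level sign test reproduces the exact binomial tail rule", {
  # the classic ladder at alpha = 0.05
  expect_true(dyad_limit_significant(5, 0))
  expect_true(dyad_limit_significant(7, 1))
  expect_false(dyad_limit_significant(4, 0))  # tail 0.5^4 = 0.0625
  expect_false(dyad_limit_significant(6, 1))
  expect_false(dyad_limit_significant(0, 0))
  # symmetry in the two arguments
  expect_equal(dyad_limit_significant(2, 9), dyad_limit_significant(9, 2))
  expect_error(dyad_limit_significant(3, 1, alpha = 1.2), "alpha")
})

test_that("sign-test CI matches the enumeration oracle on random samples", {
  set.seed(402)
  for (rep in 1:100) {
    n <- sample(3:30, 1)
    x <- switch(sample(3, 1),
                rpois(n, 3),                    # discrete with ties
                round(rnorm(n, 2, 1.5), 1),
                sample(0:4, n, replace = TRUE)) # heavy ties
    conf <- sample(c(0.90, 0.95, 0.99), 1)
    got <- sign_test_ci_median(x, conf)
    want <- oracle_sign_ci(x, conf)
    expect_equal(got$lower, want$lower, tolerance = 1e-12)
    expect_equal(got$upper, want$upper, tolerance = 1e-12)
    expect_equal(got$achieved_confidence, want$achieved_confidence, tolerance = 1e-12)
  }
})

test_that("sign-test CI handles constant samples, translation and exact mode", {
  ci <- sign_test_ci_median(rep(3, 9))
  expect_equal(c(ci$lower, ci$upper), c(3, 3))
  x <- c(0, 0, 1, 1, 2, 2, 3, 4, 6)
  ci1 <- sign_test_ci_median(x)
  ci2 <- sign_test_ci_median(x + 10)
  expect_equal(ci2$lower, ci1$lower + 10)
  expect_equal(ci2$upper, ci1$upper + 10)
  exact <- sign_test_ci_median(x, interpolate = FALSE)
  expect_gte(exact$achieved_confidence, 0.95)
  expect_lte(exact$lower, ci1$lower)
  expect_gte(exact$upper, ci1$upper)
  expect_error(sign_test_ci_median(numeric(0)), "empty")
})

test_that("pen limits come from the interacting dyads' difference sample", {
  log <- simulate_pen(generator_config(lambda0 = 0.4), "p1", seed = 7)
  tab <- aggregate_dyads(log)
  lim <- pen_limit(tab)
  d <- tab$difference[tab$total >= 1]
  ci <- sign_test_ci_median(d)
  expect_equal(lim$upper, ci$upper)
  expect_equal(lim$lower, ci$lower)
  expect_equal(lim$n_dyads, length(d))

  # constant difference sample pins the limits
  logc <- make_log(c("a01", "a02", "a03"), c("a02", "a03", "a04"), roster9)
  limc <- pen_limit(aggregate_dyads(logc))
  expect_equal(c(limc$lower, limc$upper), c(1, 1))

  empty <- make_log(character(), character(), roster9)
  expect_error(pen_limit(aggregate_dyads(empty)), "no interacting dyads")
})

test_that("classify_dyads implements the three data-set rules", {
  # every dyad 5:0 -> all significant under DYAD
  init <- rep(c("a01", "a02", "a03"), each = 5)
  recv <- rep(c("a02", "a03", "a01"), each = 5)
  log <- make_log(init, recv, list(p = c("a01", "a02", "a03", "a04")))
  tab <- aggregate_dyads(log)
  lab_d <- classify_dyads(tab, "DYAD")
  inter <- lab_d$total >= 1
  expect_true(all(lab_d$flag[inter] == "significant"))
  expect_true(all(lab_d$flag[!inter] == "unknown"))
  expect_equal(unname(attr(lab_d, "frac_significant")["p"]), 1)

  # ALL flags every interacting dyad
  lab_a <- classify_dyads(tab, "ALL")
  expect_equal(lab_a$flag[inter] == "significant", rep(TRUE, sum(inter)))

  # all differences zero -> nothing exceeds the pen upper limit of 0
  bal_i <- c("a01", "a02", "a01", "a03")
  bal_r <- c("a02", "a01", "a03", "a01")
  logb <- make_log(bal_i, bal_r, roster9)
  lab_p <- classify_dyads(aggregate_dyads(logb), "PEN")
  expect_true(all(lab_p$flag != "significant"))
})

test_that("DYAD false-positive rate under a 50/50 null stays at or below alpha", {
  set.seed(515)
  n_sig <- 0L; n_dyads <- 0L
  for (rep in 1:40) {
    log <- simulate_pen(generator_config(lambda0 = 0.35, kappa = 0, beta = 0),
                        "p1", animals = sprintf("a%02d", 1:9))
    lab <- classify_dyads(aggregate_dyads(log), "DYAD")
    use <- lab$total >= 5
    n_sig <- n_sig + sum(lab$flag[use] == "significant")
    n_dyads <- n_dyads + sum(use)
  }
  expect_gte(n_dyads, 500)
  fp <- n_sig / n_dyads
  se <- sqrt(0.05 * 0.95 / n_dyads)
  expect_lte(fp, 0.05 + 3 * se)
})

test_that("filter_events keeps both directions of significant dyads only", {
  init <- c(rep("a01", 3), "a02", "a03")
  recv <- c(rep("a02", 3), "a01", "a04")
  log <- make_log(init, recv, roster9)
  tab <- aggregate_dyads(log)
  lab <- classify_dyads(tab, "ALL")
  expect_equal(filter_events(log, lab)$events, log$events)  # ALL is identity

  # hand-build labels with a single significant dyad: all 4 of its events stay
  lab2 <- lab
  lab2$flag[!(lab2$animal_a == "a01" & lab2$animal_b == "a02")] <- "not_significant"
  kept <- filter_events(log, lab2)
  expect_equal(nrow(kept$events), 4L)
  expect_setequal(unique(c(kept$events$initiator, kept$events$receiver)),
                  c("a01", "a02"))
  expect_equal(kept$roster, roster9)

  lab3 <- lab
  lab3$flag[] <- "not_significant"
  none <- filter_events(log, lab3)
  expect_equal(nrow(none$events), 0L)
  expect_equal(none$roster, roster9)

  lab_other <- lab
  lab_other$pen_id <- "q"
  expect_error(filter_events(log, lab_other), "mismatched pen ids")
})
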