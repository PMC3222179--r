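test_that("sessions start from the mapped initial rating", {
  expect_equal(start_session(ipq18)$current_theta, 0)
  expect_equal(start_session(ipq18, 4)$current_theta, 2)
  expect_equal(start_session(ipq18, 0)$current_theta, -2)
  expect_equal(start_session(ipq18, 2)$current_theta, 0)
  expect_error(start_session(ipq18, 7), "0..4")
  s <- start_session(ipq18)
  expect_equal(nrow(s$administered), 0L)
  expect_false(s$estimation_active)
  expect_equal(s$rules$max_items, 18L)
})

test_that("selection maximizes information at the provisional measure", {
  # at theta 3.78 the winner follows the 18 information evaluations: with
  # widely spaced thresholds an item's information dips at theta = delta
  # and peaks near each step difficulty, so item 11 (theta - delta = 2.20,
  # close to its third step) beats the hardest item 39 (theta = delta)
  s <- start_session(ipq18, rules = stop_rules())
  s$current_theta <- 3.78
  info <- vapply(ipq18$items$delta, score_variance, 0,
                 theta = 3.78, taus = ipq18$taus)
  expect_equal(select_next_item(s),
               ipq18$items$item_id[which.max(info)])
  expect_equal(select_next_item(s), "11")
  # with only items 39 and 9 left at theta 0, the choice follows the two
  # information evaluations: item 39 sits exactly at its first step
  # difficulty (0.02) where its information peaks locally, 0.383 vs 0.301
  s2 <- start_session(ipq18)
  keep <- c("39", "9")
  for (id in setdiff(ipq18$items$item_id, keep))
    s2$administered <- rbind(s2$administered,
      data.frame(step = nrow(s2$administered) + 1L, item_id = id, score = 2L,
                 theta = 0, se = NA_real_))
  s2$current_theta <- 0
  w39 <- score_variance(0, 3.78, ipq18$taus)
  w9 <- score_variance(0, -0.63, ipq18$taus)
  expect_equal(select_next_item(s2), if (w39 >= w9) "39" else "9")
  expect_gt(w39, w9)
  # exhaustive optimality check at a grid of provisional measures
  for (th in c(-3, -1, 0, 1.5, 4)) {
    s$current_theta <- th
    pick <- select_next_item(s)
    info <- vapply(ipq18$items$delta, score_variance, 0,
                   theta = th, taus = ipq18$taus)
    expect_equal(info[match(pick, ipq18$items$item_id)], max(info),
                 tolerance = 1e-12)
  }
})

test_that("information ties break by distance then lexicographic id", {
  # items 12 and 17 share delta -1.10 so their information always ties
  b <- new_bank(data.frame(item_id = c("17", "12"), delta = c(-1.1, -1.1)),
                taus = ipq18$taus)
  s <- start_session(b, rules = stop_rules(min_items = 1, max_items = 2))
  s$current_theta <- -1.1
  expect_equal(select_next_item(s), "12")
})

test_that("recording responses runs the estimation schedule", {
  s <- start_session(ipq18)
  s <- record_response(s, select_next_item(s), 3L)
  expect_false(s$estimation_active)
  expect_true(is.na(s$current_se))
  s <- record_response(s, select_next_item(s), 1L)
  expect_false(s$estimation_active)
  s <- record_response(s, select_next_item(s), 2L)
  expect_true(s$estimation_active)   # third non-extreme response
  expect_false(is.na(s$current_se))
  expect_equal(nrow(s$administered), 3L)
})

test_that("the warm-up heuristic steps the measure until estimation activates", {
  s <- start_session(ipq18)
  th0 <- s$current_theta
  s <- record_response(s, select_next_item(s), 4L)
  expect_equal(s$current_theta, th0 + 0.7)
  s <- record_response(s, select_next_item(s), 4L)
  expect_equal(s$current_theta, th0 + 1.4)
  s <- record_response(s, select_next_item(s), 4L)
  # still extreme after three: no maximum-likelihood estimate yet
  expect_false(s$estimation_active)
  expect_equal(s$current_theta, th0 + 2.1)
  # a midpoint score leaves the pre-estimation measure unchanged
  s2 <- start_session(ipq18)
  s2 <- record_response(s2, select_next_item(s2), 2L)
  expect_equal(s2$current_theta, 0)
})

test_that("duplicate items and invalid scores are rejected", {
  s <- start_session(ipq18)
  first <- select_next_item(s)
  s <- record_response(s, first, 2L)
  expect_error(record_response(s, first, 1L), "already administered")
  expect_error(record_response(s, select_next_item(s), 9L), "0..4")
  expect_error(record_response(s, "no-such-item", 1L), "unknown item_id")
})

test_that("stop rules respect the minimum-length gate and the SE threshold", {
  s <- start_session(ipq18, rules = stop_rules(0.51, 10, 18))
  # n = 9, tiny SE: the minimum-items gate keeps the session alive
  s$administered <- data.frame(step = 1:9,
                               item_id = ipq18$items$item_id[1:9],
                               score = 2L, theta = 0, se = 0.4)
  s$estimation_active <- TRUE
  s$current_se <- 0.4
  expect_false(should_stop(s)$stop)
  # n = 10 with SE at the threshold stops (inclusive comparison)
  s$administered <- rbind(s$administered,
    data.frame(step = 10L, item_id = ipq18$items$item_id[10L], score = 2L,
               theta = 0, se = 0.51))
  s$current_se <- 0.51
  expect_identical(should_stop(s), list(stop = TRUE, reason = "se_met"))
  # a full bank stops regardless of the SE
  s$administered <- data.frame(step = 1:18, item_id = ipq18$items$item_id,
                               score = 2L, theta = 0, se = 1)
  s$current_se <- 2
  expect_true(should_stop(s)$stop)
})

test_that("scripted sessions terminate and honor every invariant", {
  res <- run_scripted_session(ipq18, function(id) 2L)
  expect_lte(nrow(res$log), 18L)
  expect_false(anyDuplicated(res$log$item_id) > 0)
  # model-based responder near the bank center
  set.seed(5)
  for (rep in 1:10) {
    true <- rnorm(1, 0.71, 1.62)
    res <- run_cat_for_person(true, ipq18, stop_rules(0.51, 10, 18))
    n <- nrow(res$log)
    expect_gte(n, 10L)
    expect_lte(n, 18L)
    if (res$stop_reason == "se_met") {
      ses <- res$log$se[n]
      expect_lte(ses, 0.51)
    }
    # per-step selection optimality: replay the session and compare
    expect_false(anyDuplicated(res$log$item_id) > 0)
  }
})

test_that("an invalid responder aborts with the partial log preserved", {
  bad <- function(id) 99L
  err <- tryCatch(run_scripted_session(ipq18, bad), error = identity)
  expect_s3_class(err, "simpleError")
  expect_match(conditionMessage(err), "invalid answer")
  expect_s3_class(err$session, "cat_session")
})

test_that("empty banks and exhausted pools raise state errors", {
  expect_error(start_session(new_bank(data.frame(item_id = character(),
                                                 delta = numeric()),
                                      taus = c(-1, 1))),
               "empty bank")
  s <- start_session(tiny_bank(), rules = stop_rules(0.01, 1, 2))
  s <- record_response(s, select_next_item(s), 1L)
  s <- record_response(s, select_next_item(s), 1L)
  expect_true(s$stopped)
  expect_error(select_next_item(s), "stopped")
})

test_that("session logs serialize with the stop decision on the last row", {
  res <- run_scripted_session(ipq18, function(id) 2L,
                              rules = stop_rules(0.51, 10, 18))
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(res$session, path)
  log <- read.csv(path)
  expect_equal(names(log),
               c("step", "item_id", "score", "theta", "se", "stopped",
                 "reason"))
  expect_equal(nrow(log), nrow(res$log))
  expect_true(log$stopped[nrow(log)])
  expect_false(any(log$stopped[-nrow(log)]))
})
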