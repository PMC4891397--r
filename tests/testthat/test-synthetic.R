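test_that("cohort parameters validate their ranges", {
  expect_error(cohort_params(p_forget = 1.5), "probabilities")
  expect_error(cohort_params(p_prune = -0.1), "probabilities")
  expect_error(cohort_params(floor_aversion = 0), "floor_aversion")
  expect_error(cohort_params(m_mem = -1), "m_mem")
  expect_error(cohort_params(n_players = 0), "n_players")
  expect_error(cohort_params(target_coverage = 0), "target_coverage")
  expect_error(cohort_params(reversal_profile = c(lobby = 0.5)),
               "unknown decision class")
})

test_that("with every imperfection off the player is the perfect memory agent", {
  p0 <- cohort_params(n_players = 1, m_mem = 7, p_forget = 0,
                      floor_aversion = 1, reversal_profile = c(staircase = 0),
                      p_prune = 0, target_coverage = 89, seed = 1)
  for (seed in c(3, 17, 4242)) {
    a <- generate_player(p0, palace, seed = seed)
    b <- run_agent(palace, agent_spec("memory", m = 7),
                   termination_rule("target_coverage", threshold = 89,
                                    cap = 30000),
                   seed = seed)
    expect_identical(a$room_id, b$room_id)
  }
  # and with zero memory, the unbiased random walker
  pr <- cohort_params(n_players = 1, m_mem = 0, p_forget = 0,
                      floor_aversion = 1, reversal_profile = c(staircase = 0),
                      p_prune = 0, target_coverage = 50, seed = 1)
  a <- generate_player(pr, palace, seed = 11)
  b <- run_agent(palace, agent_spec("random"),
                 termination_rule("target_coverage", threshold = 50,
                                  cap = 30000),
                 seed = 11)
  expect_identical(a$room_id, b$room_id)
})

test_that("players and cohorts reproduce under their seeds", {
  params <- cohort_params(n_players = 3, seed = 9)
  a <- generate_cohort(params, palace, quiet = TRUE)
  b <- generate_cohort(params, palace, quiet = TRUE)
  expect_identical(a, b)
  p1 <- generate_player(params, palace, seed = 5)
  p2 <- generate_player(params, palace, seed = 5)
  expect_identical(p1$room_id, p2$room_id)
})

test_that("default cohorts look like the intended study population", {
  params <- cohort_params(seed = 13)
  co <- generate_cohort(params, palace, quiet = TRUE)
  trajs <- split(co, co$player_id)
  expect_equal(length(trajs), 44)
  covs <- vapply(trajs, coverage, numeric(1), g = palace)
  expect_true(all(covs >= 89))
  hops <- vapply(trajs, nrow, numeric(1)) - 1
  # exploration runs last a few hundred hops, not tens or thousands
  expect_gt(mean(hops), 50)
  expect_lt(mean(hops), 1000)
  expect_identical(attr(co, "provenance"), "synthetic")
})

test_that("cohorts from different master seeds agree within sampling error", {
  mean_se <- function(seed) {
    co <- generate_cohort(cohort_params(seed = seed), palace, quiet = TRUE)
    hops <- vapply(split(co, co$player_id), nrow, numeric(1)) - 1
    c(mean(hops), sd(hops) / sqrt(length(hops)))
  }
  a <- mean_se(101)
  b <- mean_se(202)
  expect_false(identical(a, b))
  expect_lt(abs(a[1] - b[1]), 3 * sqrt(a[2]^2 + b[2]^2))
})

test_that("floor aversion suppresses staircase visits and bends the ratio maps", {
  landings <- palace$rooms$id[palace$rooms$category == "staircase_landing"]
  landing_share <- function(fa, seed) {
    co <- generate_cohort(cohort_params(floor_aversion = fa, seed = seed),
                          palace, quiet = TRUE)
    mean(co$room_id %in% landings)
  }
  # the same cohort seed spends fewer steps on staircases when averse
  expect_lt(landing_share(0.5, 5), landing_share(1, 5))

  co <- generate_cohort(cohort_params(seed = 23), palace, quiet = TRUE)
  prof <- dplyr::bind_rows(lapply(split(co, co$player_id), function(tr) {
    normalized_visits(build_movement_graph(tr, palace))
  })) %>%
    dplyr::group_by(room_id) %>%
    dplyr::summarise(alpha = sum(visits), .groups = "drop") %>%
    dplyr::mutate(alpha = alpha / sum(alpha))
  base <- stationary_profile(palace)
  y <- visit_ratio(prof, base)
  yf <- floor_normalized_visit_ratio(prof, base, palace)
  j <- dplyr::inner_join(y[, c("room_id", "y")],
                         yf[, c("room_id", "y")], by = "room_id",
                         suffix = c("", "_floor"))
  # total- and floor-normalized ratios disagree at staircase-adjacent rooms:
  # the between-floor allocation does not cancel there
  d <- abs(j$y - j$y_floor)[j$room_id %in% landings]
  expect_gt(max(d), 0.05)
  # and staircase landings are under-visited relative to the random walker
  expect_lt(mean(j$y[j$room_id %in% landings]), 1)
})

test_that("dead-end detection finds exactly the dorm-corridor motif", {
  br <- dead_end_branches(palace)
  expect_equal(nrow(br), 1)
  expect_equal(br$junction, "blockA_main")
  expect_equal(br$root, "dorm_corridor")
  expect_setequal(br$rooms[[1]], c("dorm_corridor", "D1", "D2"))
  expect_equal(nrow(dead_end_branches(path3_env())), 0)
})

test_that("generated imperfections are recoverable from the logs", {
  co <- generate_cohort(cohort_params(seed = 37), palace, quiet = TRUE)
  params <- attr(co, "params")

  rr <- reversal_rates(co, palace, exclude_recent = params$m_mem)
  h <- rr[rr$class == "room_two_door_hidden", ]
  ci <- stats::binom.test(h$n_reversals, h$n_traversals)$conf.int
  expect_true(ci[1] <= 0.40 && 0.40 <= ci[2])

  bp <- branch_revisit_profile(co, palace, "blockA_main",
                               c("dorm_corridor", "D1", "D2"))
  e <- bp$entries[bp$entries$prior_full_visit, ]
  expect_gt(nrow(e), 5)
  k <- sum(e$hops_to_exit == 1, na.rm = TRUE)
  ci <- stats::binom.test(k, nrow(e))$conf.int
  expect_true(ci[1] <= 0.80 && 0.80 <= ci[2])
})
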