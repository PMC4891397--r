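test_that("visit shares normalize and ratios divide out the baseline", {
  traj <- tibble::tibble(player_id = "p", room_id = c("A", "B", "A"),
                         t = 0:2, phase = "exploration")
  prof <- normalized_visits(build_movement_graph(traj, fig3))
  expect_equal(sum(prof$alpha), 1, tolerance = 1e-9)
  expect_equal(prof$alpha[prof$room_id == "A"], 2 / 3)

  single <- tibble::tibble(player_id = "p", room_id = "E", t = 0,
                           phase = "exploration")
  prof1 <- normalized_visits(build_movement_graph(single, fig3))
  expect_equal(prof1$alpha, 1)

  player <- tibble::tibble(room_id = c("A", "B"), alpha = c(0.1, 0.9))
  base <- tibble::tibble(room_id = c("A", "B"), alpha = c(0.05, 0.95))
  vr <- visit_ratio(player, base)
  expect_equal(vr$y[vr$room_id == "A"], 2)
  expect_equal(visit_ratio(player, player)$y, c(1, 1))
  # zero-baseline rooms are flagged, not scored
  base0 <- tibble::tibble(room_id = c("A", "B"), alpha = c(0, 1))
  vr0 <- visit_ratio(player, base0)
  expect_true(vr0$flagged[vr0$room_id == "A"])
  expect_true(is.na(vr0$y[vr0$room_id == "A"]))
})

test_that("the average random walker reaches the degree-proportional law", {
  # the baseline profile is an ensemble average: pooled visit shares of
  # several long walks (single walks fluctuate far more than iid counts
  # because revisits arrive in bursts)
  counts <- setNames(numeric(44), palace$rooms$id)
  for (i in 1:10) {
    traj <- run_agent(palace, agent_spec("random"),
                      termination_rule("fixed_hops", threshold = 1e5, cap = 1e5),
                      seed = roomwalk:::spawn_seed(1, i))
    tb <- table(traj$room_id)
    counts[names(tb)] <- counts[names(tb)] + tb
  }
  emp <- tibble::tibble(room_id = names(counts), alpha = counts / sum(counts))
  oracle <- stationary_profile(palace)
  j <- dplyr::inner_join(emp, oracle, by = "room_id",
                         suffix = c("_emp", "_th"))
  expect_equal(nrow(j), 44)
  rel <- abs(j$alpha_emp - j$alpha_th) / j$alpha_th
  expect_lt(max(rel), 0.05)
  # so the ensemble-level visit ratio against the stationary baseline is
  # flat near 1
  vr <- visit_ratio(emp, oracle)
  expect_true(all(vr$y > 0.95 & vr$y < 1.05))
})

test_that("floor normalization cancels between-floor allocation", {
  # single-floor graph: identical to the plain ratio
  player <- tibble::tibble(room_id = fig3$rooms$id, alpha = c(.1, .2, .3, .2, .2))
  base <- stationary_profile(fig3)
  fr <- floor_normalized_visit_ratio(player, base, fig3)
  vr <- visit_ratio(player, base)
  expect_equal(fr$y[order(fr$room_id)], vr$y[order(vr$room_id)])

  # uniform within floors but unequal across floors in both profiles:
  # floor factors cancel and every ratio is 1
  rooms <- palace$rooms
  wf <- c(`0` = 0.6, `1` = 0.3, `2` = 0.1)[as.character(rooms$floor)]
  nf <- table(rooms$floor)[as.character(rooms$floor)]
  player <- tibble::tibble(room_id = rooms$id, alpha = as.numeric(wf / nf))
  wf2 <- c(`0` = 0.2, `1` = 0.3, `2` = 0.5)[as.character(rooms$floor)]
  base <- tibble::tibble(room_id = rooms$id, alpha = as.numeric(wf2 / nf))
  fr <- floor_normalized_visit_ratio(player, base, palace)
  expect_equal(fr$y, rep(1, 44), tolerance = 1e-9)
})

test_that("rooms classify into the decision-point taxonomy", {
  cls <- suppressWarnings(classify_rooms(palace))
  get <- function(id) cls$class[cls$room_id == id]
  expect_equal(get("blockA_main"), "branching")   # the dorm-corridor junction
  expect_equal(get("AC_corridor"), "simple_corridor")
  expect_equal(get("T_Corner"), "simple_corner")
  expect_equal(get("S0a"), "staircase")
  expect_equal(get("DB2"), "room_two_door_hidden")
  expect_equal(get("G_R1"), "room_two_door_visible")
  expect_true(is.na(get("D1"))) # degree 1: no decision to make

  cls3 <- classify_rooms(fig3)
  expect_true(is.na(cls3$class[cls3$room_id == "A"]))
  expect_equal(cls3$class[cls3$room_id == "B"], "branching")

  # a two-door room without annotation warns and defaults to visible
  g <- env_graph(
    rooms = tibble::tibble(id = c("A", "R", "B"), name = id, floor = 0L,
                           block = NA_character_, x = 0:2, y = 0,
                           category = c("corridor", "room", "corridor")),
    edges = tibble::tibble(from = c("A", "R"), to = c("R", "B"),
                           link_type = "door"))
  expect_warning(cr <- classify_rooms(g), "without door-visibility")
  expect_equal(cr$class[cr$room_id == "R"], "room_two_door_visible")
})

test_that("reversal rates count turn-backs per class", {
  corpus <- tibble::tibble(player_id = "p", room_id = c("A", "B", "A"),
                           t = 0:2, phase = "exploration")
  rr <- reversal_rates(corpus, fig3)
  expect_equal(rr$class, "branching")
  expect_equal(rr$n_reversals, 1L)
  expect_equal(rr$rate, 1)

  # a strictly forward corridor walk has rate zero
  p3 <- path3_env()
  fw <- tibble::tibble(player_id = "p", room_id = c("A", "B", "C"),
                       t = 0:2, phase = "exploration")
  rr <- reversal_rates(fw, p3)
  expect_equal(rr$rate, 0)

  # triples never span a phase boundary
  two_phase <- tibble::tibble(player_id = "p", room_id = c("A", "B", "A"),
                              t = 0:2,
                              phase = c("exploration", "testing", "testing"))
  expect_equal(nrow(reversal_rates(two_phase, fig3)), 0)
})

test_that("radius of gyration is an rms distance with sane invariances", {
  two <- env_graph(
    rooms = tibble::tibble(id = c("A", "B"), name = id, floor = 0L,
                           block = NA_character_, x = c(0, 2), y = 0,
                           category = "room"),
    edges = tibble::tibble(from = "A", to = "B", link_type = "door"))
  single <- tibble::tibble(player_id = "p", room_id = "A", t = 0,
                           phase = "exploration")
  expect_equal(radius_of_gyration(single, two), 0)
  pair <- tibble::tibble(player_id = "p", room_id = c("A", "B"), t = 0:1,
                         phase = "exploration")
  expect_equal(radius_of_gyration(pair, two), 1)

  # translation invariance
  shift <- two
  shift$rooms$x <- shift$rooms$x + 100
  shift$rooms$y <- shift$rooms$y - 55
  expect_equal(radius_of_gyration(pair, shift), 1)

  # long-run value on the star matches the closed form from the stationary
  # shares and the fixture coordinates
  traj <- run_agent(fig3, agent_spec("random"),
                    termination_rule("fixed_hops", threshold = 2e5, cap = 2e5),
                    seed = 77)
  ix <- roomwalk:::env_index(fig3)
  alpha <- stationary_profile(fig3)$alpha
  ctr <- colSums(ix$coords * alpha)
  closed <- sqrt(sum(alpha * rowSums((ix$coords -
    matrix(ctr, 5, 3, byrow = TRUE))^2)))
  expect_equal(radius_of_gyration(traj, fig3), closed, tolerance = 0.02)
})

test_that("branch profiles trace entries and immediate exits", {
  branch <- c("dorm_corridor", "D1", "D2")
  # a corpus that never enters the branch has entry fraction zero
  stay <- tibble::tibble(player_id = "p",
                         room_id = c("S1A1", "blockA_main", "AC_corridor",
                                     "blockA_main", "S1A2"),
                         t = 0:4, phase = "exploration")
  bp <- branch_revisit_profile(stay, palace, "blockA_main", branch)
  expect_equal(nrow(bp$entries), 0)
  expect_true(all(bp$summary$entry_fraction == 0))

  # an in-and-straight-back excursion is a 1-hop immediate exit
  back <- tibble::tibble(player_id = "p",
                         room_id = c("blockA_main", "dorm_corridor", "D1",
                                     "dorm_corridor", "blockA_main",
                                     "dorm_corridor", "blockA_main"),
                         t = 0:6, phase = "exploration")
  bp <- branch_revisit_profile(back, palace, "blockA_main", branch)
  expect_equal(nrow(bp$entries), 2)
  expect_equal(bp$entries$hops_to_exit, c(3L, 1L))
  expect_false(bp$entries$prior_full_visit[1])
  # D2 was never seen, so the second entry is still not a full-visit entry
  expect_false(bp$entries$prior_full_visit[2])

  expect_error(branch_revisit_profile(stay, palace, "entrance", branch),
               "not adjacent")

  # memory agents re-enter the explored branch far less than random walkers
  entries_of <- function(agent, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- run_agent(palace, agent,
                      termination_rule("full_coverage", cap = 5000), seed = s)
      nrow(branch_revisit_profile(tibble::as_tibble(tr), palace,
                                  "blockA_main", branch)$entries)
    }, numeric(1)))
  }
  mem <- entries_of(agent_spec("memory", m = 44), 1:15)
  rnd <- entries_of(agent_spec("random"), 1:15)
  expect_lt(mem, rnd / 3)
})
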