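test_that("palace fixture satisfies every printed structural fact", {
  expect_equal(nrow(palace$rooms), 44)
  expect_equal(length(unique(palace$rooms$floor)), 3)
  expect_valid_env(palace)

  fl <- setNames(palace$rooms$floor, palace$rooms$id)
  st <- palace$edges[palace$edges$link_type == "staircase", ]
  # four staircases join the ground floor and floor 1
  expect_equal(sum(pmin(fl[st$from], fl[st$to]) == 0), 4)
  # exactly one staircase serves the top floor
  expect_equal(sum(fl[st$from] == 2 | fl[st$to] == 2), 1)
  # two of the rising staircases arrive in Block A, one in B, one in C
  bl <- setNames(palace$rooms$block, palace$rooms$id)
  up <- st[pmin(fl[st$from], fl[st$to]) == 0, ]
  upper_end <- ifelse(fl[up$from] == 1, up$from, up$to)
  expect_equal(sort(unname(bl[upper_end])), c("A", "A", "B", "C"))

  # the dorm corridor with rooms D1 and D2 hangs off the Block A main
  # corridor at one end only
  nb <- function(id) {
    c(palace$edges$to[palace$edges$from == id],
      palace$edges$from[palace$edges$to == id])
  }
  expect_setequal(nb("dorm_corridor"), c("blockA_main", "D1", "D2"))
  expect_equal(nb("D1"), "dorm_corridor")
  expect_equal(nb("D2"), "dorm_corridor")

  # on its own floor, Block B is reachable only through DB2 and The Lounge
  b_rooms <- palace$rooms$id[!is.na(palace$rooms$block) &
                               palace$rooms$block == "B"]
  on_floor_in <- palace$edges[palace$edges$link_type != "staircase" &
                                xor(palace$edges$from %in% b_rooms,
                                    palace$edges$to %in% b_rooms), ]
  outside <- ifelse(on_floor_in$from %in% b_rooms, on_floor_in$to,
                    on_floor_in$from)
  expect_setequal(outside, c("DB2", "the_lounge"))

  expect_equal(palace$start, "entrance")
  expect_equal(palace$rooms$floor[palace$rooms$id == "entrance"], 0L)
})

test_that("worked-example fixture has the stated star topology", {
  expect_equal(nrow(fig3$rooms), 5)
  expect_equal(nrow(fig3$edges), 4)
  deg <- igraph::degree(as_igraph(fig3))
  expect_equal(unname(deg[c("A", "C", "D", "E")]), rep(1, 4))
  expect_equal(unname(deg["B"]), 4)
  expect_true(igraph::is_connected(as_igraph(fig3)))
  expect_valid_env(fig3)
})

test_that("packaged fixture files load and round-trip byte-identically", {
  for (fx in c("fig3.json", "palace44.json")) {
    path <- system.file("extdata", fx, package = "roomwalk")
    g <- load_environment(path)
    out <- withr::local_tempfile(fileext = ".json")
    write_environment(g, out)
    expect_identical(readLines(out), readLines(path), label = fx)
  }
  g3 <- load_environment(system.file("extdata", "fig3.json", package = "roomwalk"))
  expect_equal(nrow(g3$rooms), 5)
  expect_equal(nrow(g3$edges), 4)
  gp <- load_environment(system.file("extdata", "palace44.json", package = "roomwalk"))
  expect_equal(nrow(gp$rooms), 44)
  expect_identical(as.data.frame(gp$rooms), as.data.frame(palace$rooms))
})

test_that("GraphML reader and writer preserve all attributes", {
  g3 <- load_environment(system.file("extdata", "fig3.graphml", package = "roomwalk"))
  expect_equal(nrow(g3$rooms), 5)
  out <- withr::local_tempfile(fileext = ".graphml")
  write_environment(palace, out)
  g2 <- load_environment(out)
  expect_identical(as.data.frame(g2$rooms), as.data.frame(palace$rooms))
  # the orientation of an undirected edge is not meaningful; compare the
  # canonical (sorted-endpoint) edge sets
  canon <- function(e) {
    k <- tibble::tibble(a = pmin(e$from, e$to), b = pmax(e$from, e$to),
                        link_type = e$link_type)
    k[order(k$a, k$b), ]
  }
  expect_equal(canon(g2$edges), canon(palace$edges), ignore_attr = TRUE)
  expect_identical(as.data.frame(g2$door_visibility),
                   as.data.frame(palace$door_visibility))
  expect_equal(g2$floor_height, palace$floor_height)
  expect_equal(g2$start, palace$start)
})

test_that("malformed environment files raise parse errors naming the element", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    floor_height = 4,
    rooms = data.frame(id = "A", floor = 0, x = 0, y = 0, category = "room"),
    edges = data.frame(from = "A", to = "Z", link_type = "door")),
    dataframe = "rows", auto_unbox = TRUE), f)
  expect_error(load_environment(f), "A--Z")

  writeLines(jsonlite::toJSON(list(
    floor_height = 4,
    rooms = data.frame(id = c("A", "B"), floor = 0, x = 0, y = 0,
                       category = c("room", "ballroom")),
    edges = data.frame(from = "A", to = "B", link_type = "door")),
    dataframe = "rows", auto_unbox = TRUE), f)
  expect_error(load_environment(f), "unknown category")

  writeLines(jsonlite::toJSON(list(
    floor_height = 4,
    rooms = data.frame(id = "A", floor = 0, category = "room"),
    edges = data.frame(from = character(), to = character(),
                       link_type = character())),
    dataframe = "rows", auto_unbox = TRUE), f)
  expect_error(load_environment(f), "missing attribute")
})

test_that("validation reports each violated invariant without raising", {
  rooms <- tibble::tibble(
    id = c("A", "B", "C", "D"), name = id, floor = c(0L, 1L, 0L, 0L),
    block = NA_character_, x = 0, y = 0, category = "room")
  # door edge spanning floors
  g <- env_graph(rooms[1:2, ],
                 tibble::tibble(from = "A", to = "B", link_type = "door"),
                 check = FALSE)
  rep <- validate_environment(g)
  expect_true(any(rep$rule == "cross_floor" & rep$element == "A--B"))

  # staircase edge on one floor
  g <- env_graph(rooms[c(1, 3), ],
                 tibble::tibble(from = "A", to = "C", link_type = "staircase"),
                 check = FALSE)
  expect_true(any(validate_environment(g)$rule == "staircase_floor"))

  # two disconnected components
  g <- env_graph(rooms[c(1, 3, 4), ],
                 tibble::tibble(from = "A", to = "C", link_type = "door"),
                 check = FALSE)
  expect_true(any(validate_environment(g)$rule == "connected"))

  expect_equal(nrow(validate_environment(palace)), 0)
})
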