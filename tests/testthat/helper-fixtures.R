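# Shared toy environments and corpora, built in code.

fig3 <- fig3_fixture()
palace <- palace44_fixture()

# linear three-room corridor A - B - C on one floor
path3_env <- function() {
  env_graph(
    rooms = tibble::tibble(
      id = c("A", "B", "C"), name = c("A", "B", "C"), floor = 0L,
      block = NA_character_, x = c(0, 2, 4), y = 0,
      category = c("room", "corridor", "room")),
    edges = tibble::tibble(from = c("A", "B"), to = c("B", "C"),
                           link_type = "door"),
    start = "A")
}

# the worked-example corpus: three players share the prefix A,B,C,B,D,B and
# then two continue to E, one returns to A
fig3_corpus <- function() {
  step <- function(pid, rooms) {
    tibble::tibble(player_id = pid, room_id = rooms,
                   t = seq_along(rooms) - 1, phase = "exploration")
  }
  dplyr::bind_rows(
    step("b", c("A", "B", "C", "B", "D", "B", "E")),
    step("c", c("A", "B", "C", "B", "D", "B", "E")),
    step("d", c("A", "B", "C", "B", "D", "B", "A")))
}

as_corpus <- function(trajectory) tibble::as_tibble(trajectory)

expect_valid_env <- function(g) {
  expect_equal(nrow(validate_environment(g)), 0)
}
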