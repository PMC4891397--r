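#' The five-node worked-example environment
#'
#' A single-floor toy layout: rooms C, D, and E hanging off corridor B, which
#' is reached from corridor A. It is the smallest environment on which the
#' contrast between a perfect-memory agent and an order-6 Markov agent can be
#' demonstrated, and it is used throughout the tests as an enumeration-friendly
#' arena.
#'
#' @return An [env_graph] with 5 nodes (A, B corridors; C, D, E rooms) and
#'   edges A--B, B--C, B--D, B--E, default start `"A"`.
#' @export
fig3_fixture <- function() {
  rooms <- tibble(
    id = c("A", "B", "C", "D", "E"),
    name = c("Corridor A", "Corridor B", "Room C", "Room D", "Room E"),
    floor = 0L,
    block = NA_character_,
    x = c(0, 4, 8, 8, 8),
    y = c(0, 0, 3, -3, 0),
    category = c("corridor", "corridor", "room", "room", "room"),
    corner = FALSE
  )
  edges <- tibble(
    from = c("A", "B", "B", "B"),
    to = c("B", "C", "D", "E"),
    link_type = c("corridor", "door", "door", "door")
  )
  env_graph(rooms, edges, floor_height = 4, start = "A")
}

#' The 44-room, three-floor palace environment
#'
#' A canonical approximation of the multi-floor game environment, frozen in
#' the package and constrained by every structural fact the study states:
#' 44 rooms over 3 floors; four staircases from the ground floor to the middle
#' floor (two arriving in Block A, one in Block B, one in Block C); exactly
#' one staircase serving the top floor; a dead-end dorm corridor with two
#' rooms (D1, D2) attached to the Block A main corridor at one end only; and
#' Block B reachable on its own floor only through the rooms DB2 and The
#' Lounge. The exact wall-level layout is not modelled; room names beyond the
#' structurally constrained ones are arbitrary labels.
#'
#' Door-visibility annotations mark the two-door rooms: the pass-through
#' rooms DB2 and The Lounge have a hidden far door (it leads onward at an
#' angle to the entrance), while G_R1, A_R1 and T_R5 have a visible one. One
#' degree-2 corridor on the top floor is annotated as a corner. The default
#' agent start is the ground-floor entrance.
#'
#' @return A validated [env_graph] with 44 rooms.
#' @export
palace44_fixture <- function() {
  r <- function(id, name, floor, block, x, y, category, corner = FALSE) {
    tibble(id = id, name = name, floor = as.integer(floor), block = block,
           x = x, y = y, category = category, corner = corner)
  }
  rooms <- bind_rows(
    # ground floor
    r("entrance", "Entrance Hall", 0, NA, 0, 0, "room"),
    r("corridor_G1", "West Gallery", 0, NA, 6, 0, "corridor"),
    r("corridor_G2", "East Gallery", 0, NA, 14, 0, "corridor"),
    r("G_R1", "Armoury", 0, NA, 6, 6, "room"),
    r("G_R2", "Vault", 0, NA, 6, 12, "room"),
    r("G_R3", "Kitchen", 0, NA, 3, -5, "room"),
    r("G_R4", "Pantry", 0, NA, 9, -5, "room"),
    r("G_R5", "Library", 0, NA, 12, 5, "room"),
    r("G_R6", "Study", 0, NA, 16, 5, "room"),
    r("G_R7", "Cellar Door", 0, NA, 14, -6, "room"),
    r("S0a", "West Stair (ground)", 0, NA, 4, 3, "staircase_landing"),
    r("S0b", "Hall Stair (ground)", 0, NA, 8, 3, "staircase_landing"),
    r("S0c", "Court Stair (ground)", 0, NA, 12, -3, "staircase_landing"),
    r("S0d", "East Stair (ground)", 0, NA, 18, 0, "staircase_landing"),
    # middle floor, blocks A / B / C
    r("S1A1", "West Stair (block A)", 1, "A", 4, 3, "staircase_landing"),
    r("S1A2", "Hall Stair (block A)", 1, "A", 8, 3, "staircase_landing"),
    r("S1T", "Tower Stair (lower)", 1, "A", 2, 0, "staircase_landing"),
    r("blockA_main", "Block A main corridor", 1, "A", 6, 0, "corridor"),
    r("dorm_corridor", "Dorm corridor", 1, "A", 6, -6, "corridor"),
    r("D1", "D1", 1, "A", 3, -9, "room"),
    r("D2", "D2", 1, "A", 9, -9, "room"),
    r("A_R1", "Drawing Room", 1, "A", 1, -3, "room"),
    r("A_R2", "Music Room", 1, "A", -3, -3, "room"),
    r("DB2", "DB2", 1, "A", 10, 4, "room"),
    r("blockB_corridor", "Block B corridor", 1, "B", 14, 8, "corridor"),
    r("S1B", "Court Stair (block B)", 1, "B", 12, 11, "staircase_landing"),
    r("B_R1", "Guest Suite", 1, "B", 17, 11, "room"),
    r("B_R2", "Servery", 1, "B", 17, 5, "room"),
    r("blockC_corridor", "Block C corridor", 1, "C", 20, 0, "corridor"),
    r("S1C", "East Stair (block C)", 1, "C", 24, 3, "staircase_landing"),
    r("C_R1", "Chapel", 1, "C", 22, -5, "room"),
    r("C_R2", "Salon", 1, "C", 18, -5, "room"),
    r("the_lounge", "The Lounge", 1, "C", 18, 4, "room"),
    r("AC_corridor", "A-C link corridor", 1, NA, 13, 0, "corridor"),
    # top floor
    r("S2T", "Tower Stair (upper)", 2, NA, 2, 0, "staircase_landing"),
    r("T_C1", "Tower corridor", 2, NA, 6, 0, "corridor"),
    r("T_Corner", "Tower corner", 2, NA, 10, 0, "corridor", corner = TRUE),
    r("T_C2", "Attic corridor", 2, NA, 10, 6, "corridor"),
    r("T_R1", "Observatory", 2, NA, 4, 4, "room"),
    r("T_R2", "Map Room", 2, NA, 6, -4, "room"),
    r("T_R3", "Solar", 2, NA, 14, 6, "room"),
    r("T_R4", "Gallery Loft", 2, NA, 10, 10, "room"),
    r("T_R5", "Attic Store", 2, NA, 6, 8, "room"),
    r("T_R6", "Roof Nook", 2, NA, 2, 8, "room")
  )
  e <- function(from, to, link_type) tibble(from = from, to = to, link_type = link_type)
  edges <- bind_rows(
    # ground floor
    e("entrance", "corridor_G1", "door"),
    e("corridor_G1", "corridor_G2", "corridor"),
    e("G_R1", "corridor_G1", "door"),
    e("G_R2", "G_R1", "door"),
    e("G_R3", "corridor_G1", "door"),
    e("G_R4", "corridor_G1", "door"),
    e("G_R5", "corridor_G2", "door"),
    e("G_R6", "corridor_G2", "door"),
    e("G_R7", "corridor_G2", "door"),
    e("S0a", "corridor_G1", "corridor"),
    e("S0b", "corridor_G1", "corridor"),
    e("S0c", "corridor_G2", "corridor"),
    e("S0d", "corridor_G2", "corridor"),
    # staircases (the only cross-floor links)
    e("S0a", "S1A1", "staircase"),
    e("S0b", "S1A2", "staircase"),
    e("S0c", "S1B", "staircase"),
    e("S0d", "S1C", "staircase"),
    e("S1T", "S2T", "staircase"),
    # middle floor
    e("S1A1", "blockA_main", "corridor"),
    e("S1A2", "blockA_main", "corridor"),
    e("S1T", "blockA_main", "corridor"),
    e("A_R1", "blockA_main", "door"),
    e("A_R2", "A_R1", "door"),
    e("DB2", "blockA_main", "door"),
    e("DB2", "blockB_corridor", "door"),
    e("dorm_corridor", "blockA_main", "corridor"),
    e("D1", "dorm_corridor", "door"),
    e("D2", "dorm_corridor", "door"),
    e("blockA_main", "AC_corridor", "corridor"),
    e("AC_corridor", "blockC_corridor", "corridor"),
    e("S1B", "blockB_corridor", "corridor"),
    e("B_R1", "blockB_corridor", "door"),
    e("B_R2", "blockB_corridor", "door"),
    e("the_lounge", "blockB_corridor", "door"),
    e("the_lounge", "blockC_corridor", "door"),
    e("S1C", "blockC_corridor", "corridor"),
    e("C_R1", "blockC_corridor", "door"),
    e("C_R2", "blockC_corridor", "door"),
    # top floor
    e("S2T", "T_C1", "corridor"),
    e("T_C1", "T_Corner", "corridor"),
    e("T_Corner", "T_C2", "corridor"),
    e("T_R1", "T_C1", "door"),
    e("T_R2", "T_C1", "door"),
    e("T_R3", "T_C2", "door"),
    e("T_R4", "T_C2", "door"),
    e("T_R5", "T_C2", "door"),
    e("T_R6", "T_R5", "door")
  )
  dv <- function(at, a, b, visibility) {
    tibble(at = at, from_edge = c(a, b), to_edge = c(b, a),
           visibility = visibility)
  }
  door_visibility <- bind_rows(
    dv("G_R1", "corridor_G1", "G_R2", "visible"),
    dv("A_R1", "blockA_main", "A_R2", "visible"),
    dv("DB2", "blockA_main", "blockB_corridor", "hidden"),
    dv("the_lounge", "blockB_corridor", "blockC_corridor", "hidden"),
    dv("T_R5", "T_C2", "T_R6", "visible")
  )
  env_graph(rooms, edges, floor_height = 4,
            door_visibility = door_visibility, start = "entrance")
}
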