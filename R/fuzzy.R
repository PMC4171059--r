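## Time-dependent fuzzy inference over four spatial flow cells: instantaneous
## triangular memberships from the maximum-flow location, temporal aggregation
## with a memory coefficient, winner-takes-all defuzzification into limb
## groups (upper: boxing/clapping/waving, lower: walking/jogging/running).

#' 2 x 2 cell grid over a frame region
#'
#' Partitions a region (the full frame, or a person bounding box) into four
#' disjoint covering cells: C1 top-left, C2 top-right, C3 bottom-left,
#' C4 bottom-right.
#'
#' @param shape frame shape `c(height, width)`.
#' @param bbox optional region `c(row0, row1, col0, col1)` (1-based,
#'   inclusive); defaults to the full frame.
#' @return An object of class `cell_grid` with per-cell row/column ranges and
#'   cell centres.
#' @export
cell_grid <- function(shape, bbox = NULL) {
  if (length(shape) != 2L || any(shape < 2L)) stopf("`shape` must be c(height, width), each >= 2")
  if (is.null(bbox)) bbox <- c(1L, shape[1], 1L, shape[2])
  if (bbox[1] < 1L || bbox[2] > shape[1] || bbox[3] < 1L || bbox[4] > shape[2] ||
      bbox[1] >= bbox[2] || bbox[3] >= bbox[4])
    stopf("invalid `bbox`")
  rs <- floor((bbox[1] + bbox[2]) / 2)     # last row of the top cells
  cs <- floor((bbox[3] + bbox[4]) / 2)     # last column of the left cells
  cells <- list(
    C1 = list(rows = c(bbox[1], rs),      cols = c(bbox[3], cs)),
    C2 = list(rows = c(bbox[1], rs),      cols = c(cs + 1L, bbox[4])),
    C3 = list(rows = c(rs + 1L, bbox[2]), cols = c(bbox[3], cs)),
    C4 = list(rows = c(rs + 1L, bbox[2]), cols = c(cs + 1L, bbox[4])))
  centers <- t(vapply(cells, function(cl)
    c(mean(cl$rows), mean(cl$cols)), numeric(2)))
  structure(list(shape = as.integer(shape), bbox = as.integer(bbox),
                 cells = cells, centers = centers),
            class = "cell_grid")
}

#' Person bounding box from a flow-energy map
#'
#' Thresholds the speed map at a fraction of its maximum and returns the
#' bounding box of the surviving pixels; falls back to the full frame when
#' nothing survives or the box would be degenerate.
#'
#' @param energy a speed map from [flow_energy()].
#' @param frac threshold as a fraction of the maximum (default 0.1).
#' @return `c(row0, row1, col0, col1)`, 1-based inclusive.
#' @export
person_bbox <- function(energy, frac = 0.1) {
  energy <- check_matrix(energy, "energy")
  full <- c(1L, nrow(energy), 1L, ncol(energy))
  mx <- max(energy)
  if (mx <= 0) return(full)
  idx <- which(energy >= frac * mx, arr.ind = TRUE)
  bb <- c(range(idx[, 1]), range(idx[, 2]))
  if (bb[1] >= bb[2] || bb[3] >= bb[4]) return(full)
  as.integer(bb)
}

#' Per-cell raw flow energies
#'
#' Sums the per-pixel flow speed over each of the four cells. The cell sums
#' conserve the total energy of the gridded region.
#'
#' @param flow a [flow_field()].
#' @param grid a [cell_grid()] fitting the flow shape.
#' @return Numeric 4-vector `(C1, C2, C3, C4)`.
#' @export
divide_flow <- function(flow, grid) {
  if (!inherits(flow, "flow_field")) stopf("`flow` must be a flow_field")
  if (!inherits(grid, "cell_grid")) stopf("`grid` must be a cell_grid")
  if (any(dim(flow$u) < grid$bbox[c(2, 4)]))
    stopf("grid does not fit the flow shape")
  e <- flow_energy(flow)
  vapply(grid$cells, function(cl)
    sum(e[cl$rows[1]:cl$rows[2], cl$cols[1]:cl$cols[2]]), numeric(1))
}

#' Instantaneous fuzzy memberships of a flow frame
#'
#' Triangular membership of the maximum-flow location against each cell
#' centre — the product of two axis-wise triangles, each peaking at 1 on the
#' cell centre and falling linearly to 0 at the opposite cell centre — scaled
#' by the cell's share of the total energy. All-zero energies give all-zero
#' memberships.
#'
#' @param cell_energies non-negative 4-vector from [divide_flow()].
#' @param peak_location `c(row, col)` of the maximum flow (1-based).
#' @param grid the [cell_grid()] the energies were computed on.
#' @return Memberships in `[0, 1]^4`.
#' @export
frame_membership <- function(cell_energies, peak_location, grid) {
  if (length(cell_energies) != 4L || any(cell_energies < 0))
    stopf("`cell_energies` must be a non-negative 4-vector")
  tot <- sum(cell_energies)
  if (tot <= 0) return(c(0, 0, 0, 0))
  opp <- c(4L, 3L, 2L, 1L)   # diagonal opposites
  mu <- numeric(4)
  for (i in 1:4) {
    ci <- grid$centers[i, ]; co <- grid$centers[opp[i], ]
    tr <- max(0, 1 - abs(peak_location[1] - ci[1]) / abs(co[1] - ci[1]))
    tc <- max(0, 1 - abs(peak_location[2] - ci[2]) / abs(co[2] - ci[2]))
    mu[i] <- tr * tc * (cell_energies[i] / tot)
  }
  pmin(pmax(mu, 0), 1)
}

#' Initialise the aggregated membership state
#'
#' Holds the aggregated memberships `mu` per cell, the frames-since-winner-
#' change counter `k`, the maximum effective memory length `N`, the memory
#' coefficient `eta` and the frame period `tau`.
#'
#' @param eta memory coefficient in `[0, 1]` (default 0.15).
#' @param N maximum memory length in frames (default 25, about 1 s at 25 fps).
#' @param tau frame period in seconds (default 1/25).
#' @return An object of class `membership_state`.
#' @export
membership_state <- function(eta = 0.15, N = 25L, tau = 1 / 25) {
  eta <- check_number(eta, "eta", min = 0)
  if (eta > 1) stopf("`eta` must be in [0, 1]")
  structure(list(mu = c(0, 0, 0, 0), k = 0L,
                 N = check_count(N, "N"), eta = eta,
                 tau = check_number(tau, "tau", min = 0, strict = TRUE),
                 winner = NA_integer_),
            class = "membership_state")
}

#' Temporal membership update
#'
#' The winning cell (largest instantaneous membership; ties to the lowest
#' index) is aggregated as `mu <- mu + eta_w * (1 - mu)`; non-winning cells
#' decay multiplicatively by `(1 - eta_w)`. A winner change resets the
#' counter `k` to 0; `k` is capped at `N`, beyond which the winner's
#' membership is no longer incremented. An all-zero instantaneous vector
#' skips the update (the counter still increments).
#'
#' @param state a [membership_state()].
#' @param eta_t instantaneous memberships in `[0, 1]^4` (from
#'   [frame_membership()], used as the frame's memory coefficients).
#' @return The updated state.
#' @export
update_membership <- function(state, eta_t) {
  if (!inherits(state, "membership_state")) stopf("`state` must be a membership_state")
  if (length(eta_t) != 4L || any(!is.finite(eta_t)) ||
      any(eta_t < 0) || any(eta_t > 1))
    stopf("`eta_t` must lie in [0, 1]^4")
  if (all(eta_t == 0)) {                 # degenerate frame: skip, age only
    state$k <- min(state$k + 1L, state$N)
    return(state)
  }
  w <- which.max(eta_t)                  # ties: lowest cell index
  if (is.na(state$winner) || w != state$winner) {
    state$winner <- w
    state$k <- 0L
  }
  memory_open <- state$k < state$N       # once k saturates, no more increments
  state$k <- min(state$k + 1L, state$N)
  ew <- eta_t[w]
  state$mu[-w] <- state$mu[-w] * (1 - ew)
  if (memory_open) state$mu[w] <- state$mu[w] + ew * (1 - state$mu[w])
  state$mu <- pmin(pmax(state$mu, 0), 1)
  state
}

#' Winner-takes-all limb-group defuzzification
#'
#' Compares the best aggregated membership of the two bottom cells against
#' the two top cells: flow dominated by the lower half indicates lower-limb
#' actions (walking, jogging, running), the upper half upper-limb actions
#' (boxing, clapping, waving). Confidence is the winning maximum divided by
#' the sum of the two maxima. All-zero memberships give group `"unknown"`
#' with confidence 0; an exact nonzero tie gives `"lower"` with confidence
#' 0.5 (reported via a message).
#'
#' @param state a [membership_state()].
#' @return A list with `group` (`"upper"`, `"lower"` or `"unknown"`) and
#'   `confidence` in `[0, 1]`.
#' @export
defuzzify <- function(state) {
  if (!inherits(state, "membership_state")) stopf("`state` must be a membership_state")
  top <- max(state$mu[1:2]); bottom <- max(state$mu[3:4])
  if (top == 0 && bottom == 0) return(list(group = "unknown", confidence = 0))
  if (bottom > top) return(list(group = "lower", confidence = bottom / (top + bottom)))
  if (top > bottom) return(list(group = "upper", confidence = top / (top + bottom)))
  message("defuzzify: exact membership tie; defaulting to lower limb group")
  list(group = "lower", confidence = 0.5)
}
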