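## Dorsal-stream front end: coarse-to-fine variational optical flow with
## robust data, optional symmetry, and smoothness terms.

#' Optical-flow estimation parameters
#'
#' @param rho weight of the symmetry term coupling forward and backward
#'   fields (>= 0; 0 disables the coupling, the default).
#' @param xi weight of the smoothness term (> 0).
#' @param pyramid_levels number of pyramid levels (downscale factor 0.5);
#'   levels that would shrink a side below 8 px are dropped.
#' @param warps_per_level warping (outer) iterations per level.
#' @param inner_iterations fixed-point reweighting iterations per warp.
#' @param epsilon Charbonnier robust-penalty constant.
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(rho = 0, xi = 0.02, pyramid_levels = 4L,
                        warps_per_level = 3L, inner_iterations = 10L,
                        epsilon = 1e-3) {
  structure(list(rho = check_number(rho, "rho", min = 0),
                 xi = check_number(xi, "xi", min = 0, strict = TRUE),
                 pyramid_levels = check_count(pyramid_levels, "pyramid_levels"),
                 warps_per_level = check_count(warps_per_level, "warps_per_level"),
                 inner_iterations = check_count(inner_iterations, "inner_iterations"),
                 epsilon = check_number(epsilon, "epsilon", min = 0, strict = TRUE)),
            class = "flow_params")
}

#' Construct a flow field
#'
#' @param u,v numeric matrices of horizontal (column) and vertical (row)
#'   velocities in pixels/frame; must share a shape and be finite.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(u, v) {
  u <- check_matrix(u, "u"); v <- check_matrix(v, "v")
  if (!identical(dim(u), dim(v))) stopf("`u` and `v` must share a shape")
  structure(list(u = u, v = v), class = "flow_field")
}

#' Estimate bidirectional optical flow between two frames
#'
#' Minimises a robust-penalised objective `E = E_data + rho * E_sym +
#' xi * E_smooth` (Charbonnier penalty on all terms) by coarse-to-fine
#' warping with inner fixed-point reweighting and Gauss-Seidel sweeps,
#' estimating forward (`frame_prev -> frame_next`) and backward fields
#' together. A warp update is only accepted if it does not increase the
#' objective at its pyramid level, so the per-level energy trace is
#' non-increasing. Layer visibility masks are fixed to the full frame
#' (single-layer estimation); no post-smoothing is applied to the fields.
#'
#' @param frame_prev,frame_next numeric matrices of the same shape, at least
#'   16 x 16.
#' @param params a [flow_params()] object.
#' @return A list with `forward` and `backward` [flow_field()]s and `trace`,
#'   a data frame of the objective value per (level, warp).
#' @export
estimate_flow <- function(frame_prev, frame_next, params = flow_params()) {
  a <- check_matrix(frame_prev, "frame_prev")
  b <- check_matrix(frame_next, "frame_next")
  if (!identical(dim(a), dim(b))) stopf("frames must share a shape")
  if (nrow(a) < 16L || ncol(a) < 16L) stopf("frames must be at least 16x16")
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    warning("constant frame(s): returning zero flow", call. = FALSE)
    z <- matrix(0, nrow(a), ncol(a))
    return(list(forward = flow_field(z, z), backward = flow_field(z, z),
                trace = data.frame(level = integer(), warp = integer(),
                                   energy = numeric())))
  }
  res <- cpp_estimate_flow(a, b, params$rho, params$xi,
                           params$pyramid_levels, params$warps_per_level,
                           params$inner_iterations, params$epsilon)
  list(forward = flow_field(res$u_fwd, res$v_fwd),
       backward = flow_field(res$u_bwd, res$v_bwd),
       trace = res$trace)
}

#' Per-pixel flow speed
#'
#' @param flow a [flow_field()].
#' @return Matrix of `sqrt(u^2 + v^2)` in pixels/frame.
#' @export
flow_energy <- function(flow) {
  if (!inherits(flow, "flow_field")) stopf("`flow` must be a flow_field")
  sqrt(flow$u^2 + flow$v^2)
}

#' Serialise a flow field to a text archive
#'
#' Paired 2-D numeric arrays with a small metadata header; values round-trip
#' bit-exactly.
#'
#' @param flow a [flow_field()].
#' @param path file path.
#' @export
write_flow <- function(flow, path) {
  write_archive(path, "flow_field",
                meta = list(shape = dim(flow$u)),
                arrays = list(u = flow$u, v = flow$v))
}

#' @rdname write_flow
#' @export
read_flow <- function(path) {
  a <- read_archive(path, "flow_field")
  flow_field(a$arrays$u, a$arrays$v)
}
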