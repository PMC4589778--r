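#' Paired lattice state
#'
#' A pair of L x L strategy grids, one per layer, with von Neumann
#' neighborhoods and periodic (toroidal) boundaries. Site `(i, j)` on one
#' layer is the interlayer partner of site `(i, j)` on the other. Grids are
#' integer matrices with 1 = cooperator, 0 = defector.
#'
#' @param sd,pd integer 0/1 matrices of identical square dimension (`L >= 3`).
#' @return An object of class `"idg_state"` with elements `L`, `sd`, `pd`.
#' @export
lattice_state <- function(sd, pd) {
  sd <- .as_grid(sd, "sd")
  pd <- .as_grid(pd, "pd")
  if (!identical(dim(sd), dim(pd)))
    stop("sd and pd grids must have identical dimensions")
  L <- nrow(sd)
  if (L != ncol(sd)) stop("grids must be square")
  if (L < 3) stop("L must be >= 3")
  structure(list(L = L, sd = sd, pd = pd), class = "idg_state")
}

.as_grid <- function(m, what) {
  if (!is.matrix(m)) stop(what, " must be a matrix")
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop(what, " grid must contain only 0 and 1")
  m
}

#' Von Neumann neighbors on the torus
#'
#' Coordinates are 0-based `(row, col)` engine coordinates. The four
#' neighbors are returned in the fixed order up, down, left, right, with
#' periodic wrap-around.
#'
#' @param site integer vector `c(row, col)`, `0 <= row, col < L`.
#' @param L lattice linear size.
#' @return A 4 x 2 integer matrix, one neighbor per row.
#' @examples
#' neighbors(c(0, 0), 4)  # wraps to rows/cols 3
#' @export
neighbors <- function(site, L) {
  if (length(site) != 2 || any(site < 0) || any(site >= L))
    stop("site must be c(row, col) with 0 <= row, col < L")
  r <- site[1]; c <- site[2]
  out <- rbind(
    c((r - 1) %% L, c),  # up
    c((r + 1) %% L, c),  # down
    c(r, (c - 1) %% L),  # left
    c(r, (c + 1) %% L)   # right
  )
  storage.mode(out) <- "integer"
  out
}

#' Random 50/50 initial state
#'
#' Each site on each layer is independently assigned cooperator or defector
#' with probability 1/2, the initial condition used throughout the model's
#' steady-state experiments.
#'
#' @param L lattice linear size (`>= 3`).
#' @param seed optional integer seed for R's RNG; identical seeds give
#'   identical states.
#' @return An `"idg_state"`.
#' @export
random_initial <- function(L, seed = NULL) {
  if (L < 3) stop("L must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  lattice_state(matrix(rbinom(L * L, 1L, 0.5), L),
                matrix(rbinom(L * L, 1L, 0.5), L))
}

#' Prepared block initial state
#'
#' A centered `block_side` x `block_side` square of cooperators at the same
#' position on both layers, defectors elsewhere. Used to visualize how a
#' compact cooperative domain survives, splits or expands.
#'
#' @param L lattice linear size.
#' @param block_side side of the cooperator block, `0 < block_side <= L`.
#' @return An `"idg_state"` with `synchronization_index()` equal to 1.
#' @export
block_initial <- function(L, block_side = floor(L / 2)) {
  if (L < 3) stop("L must be >= 3")
  if (block_side <= 0 || block_side > L)
    stop("block_side must satisfy 0 < block_side <= L")
  g <- matrix(0L, L, L)
  from <- floor((L - block_side) / 2) + 1
  idx <- from:(from + block_side - 1)
  g[idx, idx] <- 1L
  lattice_state(g, g)
}

#' @export
print.idg_state <- function(x, ...) {
  cat(sprintf("Interdependent lattice state, L = %d\n", x$L))
  cat(sprintf("  f_c(SD) = %.4f, f_c(PD) = %.4f, identical pairs = %.4f\n",
              mean(x$sd), mean(x$pd), mean(x$sd == x$pd)))
  invisible(x)
}

#' @export
plot.idg_state <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  pal <- c("firebrick", "steelblue")  # defectors red, cooperators blue
  for (ly in c("sd", "pd")) {
    g <- x[[ly]]
    graphics::image(t(g[x$L:1, , drop = FALSE]), col = pal,
                    breaks = c(-0.5, 0.5, 1.5), axes = FALSE,
                    main = toupper(ly), ...)
  }
  invisible(x)
}
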