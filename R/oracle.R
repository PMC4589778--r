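#' Exact distribution of one elementary update
#'
#' Enumerates every random draw of a single elementary update (layer, site,
#' branch, conformity noise, neighbor choice, Fermi adoption) on a small
#' state and returns the exact probability of each successor state. Because
#' one update changes at most one site, the successors are the unchanged
#' state plus every single-site flip; probabilities are computed in closed
#' form, with the Fermi adoption treated as a two-outcome branch of exact
#' probability `W`.
#'
#' Used as an independent oracle for the compiled engine (see
#' `tally_updates` in the test suite).
#'
#' @param state an `"idg_state"` with `L <= 4`.
#' @param params an [game_params()] object.
#' @return A numeric vector of length `2 L^2 + 1` summing to one. Element 1
#'   is the probability that the state is unchanged; element
#'   `1 + layer * L^2 + site + 1` (layer 0 = SD, 1 = PD; `site` the 0-based
#'   column-major index) is the probability that exactly that site flips.
#' @export
enumerate_single_update <- function(state, params = game_params()) {
  L <- state$L
  if (L > 4) stop("enumerate_single_update requires L <= 4")
  N <- L^2
  s <- params$s
  noise <- params$noise_prob
  p <- numeric(2 * N + 1)
  for (layer_i in 0:1) {
    layer <- c("SD", "PD")[layer_i + 1]
    g <- .grid_of(state, layer)
    for (site in 0:(N - 1)) {
      rc <- c(site %% L, site %/% L)
      sx <- g[rc[1] + 1, rc[2] + 1]
      group <- .partner_group(state, layer, rc)
      nC <- sum(group)
      maj <- as.numeric(nC >= 3)
      noise_pC <- switch(params$noise_mode,
                         uniform = 0.5,
                         abstain = as.numeric(sx == 1L),
                         member  = nC / 5,
                         set     = if (nC == 5) 1 else if (nC == 0) 0 else 0.5)
      pC_si <- noise * noise_pC + (1 - noise) * maj
      # imitation branch: each neighbor chosen w.p. 1/4; same strategy is a
      # no-op, otherwise adopt with the exact Fermi probability
      nb <- neighbors(rc, L)
      pC_im <- 0
      for (k in seq_len(4)) {
        sy <- g[nb[k, 1] + 1, nb[k, 2] + 1]
        if (sy == sx) {
          pC_im <- pC_im + 0.25 * (sx == 1L)
        } else {
          W <- fermi_probability(accumulate_payoff(state, layer, rc, params),
                                 accumulate_payoff(state, layer, nb[k, ],
                                                   params),
                                 params$K)
          pC_im <- pC_im + 0.25 * (W * (sy == 1L) + (1 - W) * (sx == 1L))
        }
      }
      pC <- s * pC_si + (1 - s) * pC_im
      p_flip <- if (sx == 1L) 1 - pC else pC
      p[1 + layer_i * N + site + 1] <- p_flip / (2 * N)
      p[1] <- p[1] + (1 - p_flip) / (2 * N)
    }
  }
  p
}
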