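#' Game and dynamics parameters
#'
#' Bundles the payoff constants of the two games and the parameters of the
#' update dynamics. The snowdrift (SD) and prisoner's dilemma (PD) layers share
#' the temptation `T = b`, the reward `R = 1` and the sucker's payoff `S = 0`;
#' only the punishment differs: `P_pd = 0.2` keeps the PD ranking
#' `T > R > P > S`, while `P_sd = -0.2` yields the SD ranking `T > R > S > P`.
#'
#' @param b temptation to defect, shared by both layers; must satisfy
#'   `1 < b <= 2` so that both payoff rankings hold.
#' @param s social influence strength in `[0, 1]`: the probability that an
#'   elementary update conforms to the interlayer partner group instead of
#'   imitating a lattice neighbor. `s = 0` decouples the two layers.
#' @param K uncertainty of the Fermi strategy-adoption rule (must be `> 0`).
#' @param P_pd,P_sd punishment payoffs of the PD and SD layers.
#' @param R reward for mutual cooperation (1 in the studied model).
#' @param S sucker's payoff, shared by both layers (0 in the studied model).
#' @param noise_prob probability that a social-influence update is a
#'   conformity-noise draw rather than strict majority learning, in `[0, 1]`.
#' @param noise_mode what a conformity-noise draw does:
#'   \describe{
#'     \item{`"set"`}{(default) pick uniformly among the *distinct* strategies
#'       present in the partner group; a unanimous group offers one choice.}
#'     \item{`"uniform"`}{pick C or D with probability 1/2 regardless of the
#'       group, so unanimous populations are never absorbing.}
#'     \item{`"member"`}{copy one uniformly chosen member of the group.}
#'     \item{`"abstain"`}{keep the current strategy.}
#'   }
#'   The modes agree whenever the group is mixed 3:2 under majority learning;
#'   they differ in whether noise can inject a strategy absent from the group.
#'   See the package vignette for why `"set"` is the default.
#'
#' @return An object of class `"idg_params"`.
#' @examples
#' p <- game_params(b = 1.1, s = 0.5)
#' p
#' @export
game_params <- function(b = 1.1, s = 0.5, K = 0.1, P_pd = 0.2, P_sd = -0.2,
                        R = 1, S = 0, noise_prob = 0.1,
                        noise_mode = c("set", "uniform", "member", "abstain")) {
  noise_mode <- match.arg(noise_mode)
  if (!is.numeric(b) || length(b) != 1 || b <= 1 || b > 2)
    stop("b must be a single number with 1 < b <= 2 (got ", b, ")")
  if (!is.numeric(s) || length(s) != 1 || s < 0 || s > 1)
    stop("s must lie in [0, 1] (got ", s, ")")
  if (!is.numeric(K) || length(K) != 1 || K <= 0)
    stop("K must be > 0 (got ", K, ")")
  if (!is.numeric(noise_prob) || noise_prob < 0 || noise_prob > 1)
    stop("noise_prob must lie in [0, 1] (got ", noise_prob, ")")
  # payoff rankings: PD needs T > R > P > S, SD needs T > R > S > P
  if (!(b > R && R > P_pd && P_pd > S))
    stop("PD payoff ranking b > R > P_pd > S violated")
  if (!(b > R && R > S && S > P_sd))
    stop("SD payoff ranking b > R > S > P_sd violated")
  structure(list(b = b, s = s, K = K, P_pd = P_pd, P_sd = P_sd, R = R, S = S,
                 noise_prob = noise_prob, noise_mode = noise_mode),
            class = "idg_params")
}

#' @export
print.idg_params <- function(x, ...) {
  cat("Interdependent-game parameters\n")
  cat(sprintf("  b = %g, s = %g, K = %g, noise = %g (%s)\n",
              x$b, x$s, x$K, x$noise_prob, x$noise_mode))
  cat(sprintf("  SD payoffs: T=%g R=%g S=%g P=%g\n", x$b, x$R, x$S, x$P_sd))
  cat(sprintf("  PD payoffs: T=%g R=%g S=%g P=%g\n", x$b, x$R, x$S, x$P_pd))
  invisible(x)
}

#' Payoff of a single pairwise game
#'
#' The focal player's payoff from one interaction, read off the 2x2 payoff
#' matrix of the requested layer: mutual cooperation pays `R`, cooperating
#' against a defector pays `S`, defecting against a cooperator pays the
#' temptation `b`, and mutual defection pays the layer's punishment
#' (`P_pd` or `P_sd`).
#'
#' @param my,opponent strategies, `"C"` or `"D"`.
#' @param layer `"SD"` or `"PD"`.
#' @param params an [game_params()] object.
#' @return A single payoff value.
#' @examples
#' payoff_single("D", "C", "PD", game_params(b = 1.1))  # temptation, 1.1
#' payoff_single("D", "D", "SD")                        # SD punishment, -0.2
#' @export
payoff_single <- function(my, opponent, layer, params = game_params()) {
  my <- match.arg(my, c("C", "D"))
  opponent <- match.arg(opponent, c("C", "D"))
  layer <- match.arg(layer, c("SD", "PD"))
  if (my == "C") {
    if (opponent == "C") params$R else params$S
  } else {
    if (opponent == "C") params$b
    else if (layer == "PD") params$P_pd else params$P_sd
  }
}
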