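#' Scalar features of the goal-based reduced SR
#'
#' In the goal-based reduced successor representation each state is
#' represented by a single scalar: the discounted future occupancy of the
#' goal state under the Non-Resistant policy, `x(S_k) = gamma^(n - k)`.  When
#' a punishment state `S_{n+1}` exists its feature is 0, because no backward
#' transition from it to the goal has ever been experienced.
#'
#' @param spec A [chain_spec()].
#' @return Numeric vector of length `n_states` (plus a trailing 0 when the
#'   chain has a punishment state).
#' @examples
#' reduced_features(chain_spec())
#' @export
reduced_features <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  x <- discount_to_goal(spec$gamma, spec$n_states)
  if (spec$has_punishment) x <- c(x, 0)
  x
}

#' Feature matrix of the genuine SR
#'
#' In the genuine (full) successor representation each state `S_k` is
#' represented by `n` features, the discounted future occupancies of every
#' state under the Non-Resistant policy:
#' `x_j(S_k) = gamma^(j - k)` for `j >= k` and 0 for `j < k`.
#'
#' @param spec A [chain_spec()] (punishment not supported for this learner).
#' @return An `n x n` matrix; row `k` is the SR of `S_k`.
#' @examples
#' genuine_features(chain_spec(n_states = 4))
#' @export
genuine_features <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  n <- spec$n_states
  # g[i + 1] = gamma^i via sequential products, so gamma * g[i] == g[i + 1]
  # exactly and Non-Resistant transitions generate RPEs of exactly 0.
  g <- discount_powers(spec$gamma, n)
  m <- matrix(0, n, n)
  for (k in seq_len(n)) m[k, k:n] <- g[seq_len(n - k + 1L)]
  m
}
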