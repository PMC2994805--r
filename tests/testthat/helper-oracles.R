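# Independent oracles used across test files.

# Exhaustive enumeration of the model prevalence over all 2^(x+1)
# susceptible/non-susceptible locus-state configurations: the HLA locus is
# in a susceptible (carrier) state with probability h, each non-HLA locus
# with probability h/r; affection applies Pt_i* by the HLA state.
enum_prevalence <- function(params, x = params$x) {
  stopifnot(x <= 12)
  states <- as.matrix(expand.grid(rep(list(0:1), x + 1)))
  p_state <- c(params$h, rep(params$f, x))
  prob <- apply(states, 1, function(s) prod(ifelse(s == 1, p_state, 1 - p_state)))
  pt <- ifelse(states[, 1] == 1, params$pt1_star, params$pt0_star)
  susceptible <- rowSums(states) >= params$n
  sum(prob * pt * susceptible)
}

# Default-constant model used by several tests.
toy_model <- function(pt_star = 1, ...) {
  ms_model(n = 1, r = 2, x = 2, pt_star = pt_star,
           composition = c(dominant = 1), ...)
}
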