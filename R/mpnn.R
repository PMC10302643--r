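#' @include AllClasses.R
NULL

.leaky <- function(x, slope) ifelse(x >= 0, x, slope * x)

#' Construct message-passing parameters
#'
#' Weights are drawn from a Glorot-style normal (sd proportional to
#' `1/sqrt(fan_in)`); there are no bias terms anywhere and the same weights
#' are reused at every iteration.
#'
#' @param dm message dimension (2-4).
#' @param iterations number of message-passing iterations (3-5).
#' @param leakySlope leaky ReLU negative slope, default 0.01.
#' @param init `"random"` or `"zero"`.
#' @param updateLeaky apply the leaky ReLU to the update output as well
#'   (default `FALSE`: linear update; messages are always activated).
#' @return an [MpnnParams-class].
#' @export
newMpnnParams <- function(dm = 3L, iterations = 4L, leakySlope = 0.01,
                          init = c("random", "zero"), updateLeaky = FALSE) {
  init <- match.arg(init)
  dm <- as.integer(dm); iterations <- as.integer(iterations)
  Wm <- matrix(if (init == "random") rnorm(dm * 3L, sd = 1 / sqrt(3)) else 0,
               dm, 3L)
  Wu <- if (init == "random") rnorm(1L + dm, sd = 1 / sqrt(1 + dm)) else
    numeric(1L + dm)
  new("MpnnParams", Wm = Wm, Wu = Wu, iterations = iterations,
      leakySlope = leakySlope, updateLeaky = updateLeaky)
}

# directed edge list (receiver, sender, order) over root + slots; the root is
# state index 1
.directedEdges <- function(graph) {
  E <- graph@edgeOrder
  up <- which(upper.tri(E) & E > 0, arr.ind = TRUE)
  if (!nrow(up))
    return(list(recv = integer(), send = integer(), e = numeric()))
  list(recv = c(up[, 1], up[, 2]),
       send = c(up[, 2], up[, 1]),
       e = c(E[up], E[up]))
}

.initialStates <- function(graph) c(P = 1, graph@presence)

#' One message-passing step
#'
#' For every state (the phosphorus root plus each template slot) sums the
#' activated linear messages over its neighbors:
#' `m_i = sum_j LeakyReLU(Wm %*% c(h_i, h_j, e_ij))`. States without incident
#' edges receive the zero message. Bonds are undirected: messages flow both
#' ways along every edge.
#'
#' @param states numeric vector of hidden states, length `totalSlots + 1`
#'   (root first), e.g. from [initialStates()].
#' @param graph an [AlignedGraph-class].
#' @param params an [MpnnParams-class].
#' @return numeric matrix `dm x (totalSlots + 1)` of messages.
#' @export
messageStep <- function(states, graph, params) {
  nst <- length(graph@presence) + 1L
  if (length(states) != nst)
    stop(sprintf("shape error: states length %d, graph needs %d",
                 length(states), nst))
  el <- .directedEdges(graph)
  dm <- nrow(params@Wm)
  m <- matrix(0, dm, nst)
  if (length(el$recv)) {
    X <- rbind(states[el$recv], states[el$send], el$e)
    A <- .leaky(params@Wm %*% X, params@leakySlope)
    for (d in seq_len(dm))
      m[d, ] <- vapply(seq_len(nst), function(i)
        sum(A[d, el$recv == i]), numeric(1))
  }
  m
}

#' Initial hidden states of an aligned graph
#'
#' The hidden state at iteration 0 is the Boolean presence vector, with the
#' always-present phosphorus root prepended.
#'
#' @param graph an [AlignedGraph-class].
#' @return numeric vector of length `totalSlots + 1`.
#' @export
initialStates <- function(graph) .initialStates(graph)

#' Run the message-passing network over an aligned graph
#'
#' Iterates `h_i <- LeakyReLU(Wu %*% c(h_i, m_i))` for the configured number
#' of iterations starting from the Boolean presence states, then concatenates
#' the final hidden states in slot order (the root state is propagated but not
#' emitted). Because every map is linear-then-LeakyReLU without bias, vacant
#' edgeless slots remain exactly zero throughout.
#'
#' @param graph an [AlignedGraph-class].
#' @param params an [MpnnParams-class].
#' @return the GNN output states: a numeric vector of length `totalSlots`.
#' @examples
#' tpl <- buildTemplate(list(buildTree(c("Me", "Me", "Me"), "PMe3")))
#' g <- encodeGraph(buildTree(c("Me", "Me", "Me"), "PMe3"), tpl)
#' runMpnn(g, newMpnnParams(dm = 2, iterations = 3, init = "zero"))
#' @export
runMpnn <- function(graph, params) {
  validObject(params)
  nst <- length(graph@presence) + 1L
  el <- .directedEdges(graph)
  dm <- nrow(params@Wm)
  h <- .initialStates(graph)
  nE <- length(el$recv)
  S <- NULL
  if (nE) {
    S <- matrix(0, nE, nst)
    S[cbind(seq_len(nE), el$recv)] <- 1
  }
  for (t in seq_len(params@iterations)) {
    if (nE) {
      X <- rbind(h[el$recv], h[el$send], el$e)
      A <- .leaky(params@Wm %*% X, params@leakySlope)
      m <- A %*% S                       # dm x nst aggregation by receiver
    } else m <- matrix(0, dm, nst)
    u <- drop(params@Wu %*% rbind(h, m))
    h <- if (params@updateLeaky) .leaky(u, params@leakySlope) else u
  }
  unname(h[-1L])
}
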