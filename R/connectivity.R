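#' Build the random excitatory connectivity matrix
#'
#' Connections are drawn independently with probability `p_conn` between
#' every ordered pair of distinct neurons; the weight of each realized
#' connection is uniform on `(0, wE]`. Autapses are excluded.
#'
#' @param n number of neurons (`>= 2`).
#' @param p_conn connection probability.
#' @param wE upper bound of the uniform weight draw.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return A list of class `aqif_connectivity` with elements `J` (an
#'   `n x n` sparse `dgCMatrix`, entry `J[i, j]` the weight of the synapse
#'   from neuron `j` onto neuron `i`) and `seed`.
#' @examples
#' con <- build_connectivity(512, seed = 1)
#' Matrix::nnzero(con$J) / (512 * 511)   # about 0.05
#' @export
build_connectivity <- function(n, p_conn = 0.05, wE = 4.50, seed = 1L) {
  if (length(n) != 1 || n < 2) stop("invalid argument: n must be >= 2")
  stopifnot(p_conn >= 0, p_conn <= 1, wE >= 0)
  n <- as.integer(n)
  set.seed(seed)
  # draw per ordered pair; column j holds outgoing synapses of neuron j
  idx <- which(stats::runif(as.double(n) * n) < p_conn)
  if (length(idx)) {
    i <- ((idx - 1) %% n) + 1
    j <- ((idx - 1) %/% n) + 1
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    w <- wE * stats::runif(length(i))
    if (wE == 0) w <- numeric(length(i)) # degenerate scale: all-zero matrix
    J <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  } else {
    J <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n))
  }
  J <- Matrix::drop0(J)
  structure(list(J = J, seed = seed), class = "aqif_connectivity")
}

#' Draw the tonic input vector
#'
#' Each neuron receives a constant drive `b0 + Exp(b1)`: a common baseline
#' plus an exponentially distributed spread with mean `b1`.
#'
#' @param n number of neurons.
#' @param b0 tonic input baseline (`>= 0`).
#' @param b1 tonic input spread (`>= 0`); `b1 = 0` gives every neuron
#'   exactly `b0`.
#' @param seed integer seed.
#' @return A list of class `aqif_tonic` with elements `b` (length-`n`
#'   numeric, all `>= b0`) and `seed`.
#' @export
draw_tonic_input <- function(n, b0, b1, seed = 1L) {
  if (b0 < 0 || b1 < 0) stop("invalid argument: b0 and b1 must be >= 0")
  stopifnot(n >= 1)
  set.seed(seed)
  b <- b0 + if (b1 > 0) stats::rexp(n, rate = 1 / b1) else numeric(n)
  structure(list(b = b, seed = seed), class = "aqif_tonic")
}
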