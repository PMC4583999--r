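# Expensive shared fixtures (full-size spiking runs), built once per test run
# and reused across test files.
.lvcomp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .lvcomp_cache))
    assign(key, force(expr), envir = .lvcomp_cache)
  get(key, envir = .lvcomp_cache)
}

# the reference EEI switching run: full size, w = 2.5, 20 s
eei_w25_run <- function() {
  cached("eei_w25", suppressWarnings(
    run_pipeline("EEI", w = 2.5, T = 20000, seed = 1)))
}

# single-neuron / tiny graphs for unit tests
lone_neuron_graph <- function(n = 1, edges = NULL) {
  W <- if (is.null(edges)) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, n))
  } else {
    Matrix::sparseMatrix(i = edges$i, j = edges$j, x = edges$x, dims = c(n, n))
  }
  structure(list(W = W, membership = factor(rep("E1", n)), spec = NULL,
                 seed = NA),
            class = "weighted_graph")
}
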