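#' Specify a three-population competition network
#'
#' Defines the block-structured network of three subnetworks in which two
#' populations of the same neuron type compete: either two excitatory
#' populations sharing one inhibitory pool (\code{"EEI"}) or two inhibitory
#' populations sharing one excitatory pool (\code{"EII"}). All synapses are
#' delta pulses; an inhibitory synapse is \code{g} times stronger than an
#' excitatory one, and synapses \emph{within} each competing population are
#' scaled by the bifurcation parameter \code{w} (\code{w >= 1} for EEI,
#' \code{0 <= w <= 1} for EII).
#'
#' @param scenario \code{"EEI"} or \code{"EII"}.
#' @param w within-population weight factor (dimensionless).
#' @param J EPSP amplitude in mV.
#' @param g IPSP/EPSP amplitude ratio.
#' @param p inhibitory-pathway connection multiplier (the fraction of
#'   presynaptic partners on inhibitory-related pathways is \code{p*eps}).
#' @param eps baseline connection fraction.
#' @param I_DC external DC current per neuron, pA.
#' @param t_d synaptic delay, ms.
#' @param N_E,N_I population sizes. For EEI, \code{N_E} is the size of
#'   \emph{each} competing excitatory population; for EII, \code{N_I} is the
#'   size of each competing inhibitory population. Defaults reproduce the
#'   full-size networks (EEI: 2x2000 E + 1000 I; EII: 4000 E + 2x500 I).
#' @return An object of class \code{network_spec}.
#' @export
network_spec <- function(scenario = c("EEI", "EII"), w,
                         J = 0.1, g = 6, p = 3, eps = 0.1,
                         I_DC = 270, t_d = 0.1,
                         N_E = NULL, N_I = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(N_E)) N_E <- if (scenario == "EEI") 2000L else 4000L
  if (is.null(N_I)) N_I <- if (scenario == "EEI") 1000L else 500L
  stopifnot(J > 0, g > 0, p * eps <= 1, N_E > 0, N_I > 0, t_d > 0, I_DC >= 0)
  if (scenario == "EEI" && w < 1)
    stop("EEI requires w >= 1 (within-population excitation at least as strong as across)")
  if (scenario == "EII" && (w < 0 || w > 1))
    stop("EII requires 0 <= w <= 1")
  structure(list(scenario = scenario, w = w, J = J, g = g, p = p, eps = eps,
                 I_DC = I_DC, t_d = t_d,
                 N_E = as.integer(N_E), N_I = as.integer(N_I)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  pops <- population_sizes(x)
  cat(sprintf("%s network spec: w = %g, J = %g mV, g = %g, p = %g, eps = %g\n",
              x$scenario, x$w, x$J, x$g, x$p, x$eps))
  cat("  populations:", paste(sprintf("%s (%d)", names(pops), pops),
                              collapse = ", "), "\n")
  cat(sprintf("  I_DC = %g pA, delay = %g ms\n", x$I_DC, x$t_d))
  invisible(x)
}

# population order: the two competing populations first, the shared one last
population_sizes <- function(spec) {
  if (spec$scenario == "EEI")
    c(E1 = spec$N_E, E2 = spec$N_E, I = spec$N_I)
  else
    c(I1 = spec$N_I, I2 = spec$N_I, E = spec$N_E)
}

.int_degree <- function(x, from, to) {
  if (abs(x - round(x)) > 1e-9)
    stop(sprintf("fractional degree %.3f in block %s -> %s: connection fraction times population size must be an integer",
                 x, from, to))
  as.integer(round(x))
}

#' Per-block degrees and weights of the competition network
#'
#' Expands a \code{\link{network_spec}} into the 3x3 table of blocks: for every
#' ordered pair of populations, the exact out-degree of each source neuron
#' into the target population, the exact in-degree of each target neuron, and
#' the signed synaptic weight (mV). Degrees implied by connection fractions
#' must be integral; a fractional degree is an error.
#'
#' @param spec a \code{\link{network_spec}}.
#' @return A data frame with one row per block: \code{from}, \code{to},
#'   \code{n_from}, \code{n_to}, \code{out_deg}, \code{in_deg}, \code{weight}.
#' @export
block_degrees <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- population_sizes(spec)
  pops <- names(sizes)
  J <- spec$J; g <- spec$g; w <- spec$w; p <- spec$p; eps <- spec$eps

  rows <- list()
  add <- function(from, to, in_deg, weight) {
    nf <- sizes[[from]]; nt <- sizes[[to]]
    ind <- .int_degree(in_deg, from, to)
    out <- .int_degree(ind * nt / nf, from, to)
    rows[[length(rows) + 1L]] <<- data.frame(
      from = from, to = to, n_from = nf, n_to = nt,
      out_deg = out, in_deg = ind, weight = weight,
      stringsAsFactors = FALSE)
  }

  if (spec$scenario == "EEI") {
    # E_k -> E_m: fraction eps, weight wJ within, J across
    for (from in c("E1", "E2")) for (to in c("E1", "E2"))
      add(from, to, eps * sizes[[to]], if (from == to) w * J else J)
    # E_k -> I: fraction p*eps of each excitatory population
    for (from in c("E1", "E2")) add(from, "I", p * eps * sizes[[from]], J)
    # I -> E_k and I -> I: fraction p*eps of the inhibitory population
    for (to in c("E1", "E2")) add("I", to, p * eps * sizes[["I"]], -g * J)
    add("I", "I", p * eps * sizes[["I"]], -g * J)
  } else {
    # I_k -> I_m: fraction p*eps, weight -wgJ within, -gJ across
    for (from in c("I1", "I2")) for (to in c("I1", "I2"))
      add(from, to, p * eps * sizes[[from]], if (from == to) -w * g * J else -g * J)
    # I_k -> E: each inhibitory neuron projects to p*eps of all E neurons,
    # so every E neuron receives p*eps*N_I inhibitory inputs per competing pool
    for (from in c("I1", "I2")) add(from, "E", p * eps * sizes[[from]], -g * J)
    # E -> I_k: each excitatory neuron projects to p*eps*N_I neurons in each
    # inhibitory population, i.e. every I neuron receives p*eps*N_E E inputs
    for (to in c("I1", "I2")) add("E", to, p * eps * sizes[["E"]], J)
    # E -> E: baseline fraction eps
    add("E", "E", eps * sizes[["E"]], J)
  }
  out <- do.call(rbind, rows)
  # order blocks deterministically: from, then to, in population order
  out <- out[order(match(out$from, pops), match(out$to, pops)), ]
  rownames(out) <- NULL
  class(out) <- c("block_degrees", class(out))
  out
}

#' Sample one 0/1 block with exact margins
#'
#' Draws a binary matrix in which every row sum equals \code{out_deg} and
#' every column sum equals \code{in_deg}, optionally with an empty diagonal
#' (no self-connections): a fixed-degree variant of the configuration model.
#' The block is initialized with a deterministic circulant pattern that meets
#' the margins exactly and then randomized by margin-preserving checkerboard
#' swaps (default 10 per edge), which approximates a uniform draw over all
#' margin-satisfying matrices without ever violating the margins.
#'
#' @param n_rows,n_cols block dimensions (rows are presynaptic).
#' @param out_deg,in_deg required row and column sums; must satisfy
#'   \code{n_rows*out_deg == n_cols*in_deg}.
#' @param forbid_diagonal if \code{TRUE}, the block must be square and the
#'   diagonal is kept empty.
#' @param seed optional integer seed.
#' @param swap_factor number of successful swaps per edge.
#' @return A sparse pattern matrix (\code{Matrix::sparseMatrix}) of 0/1.
#' @export
sample_block <- function(n_rows, n_cols, out_deg, in_deg,
                         forbid_diagonal = FALSE, seed = NULL,
                         swap_factor = 10) {
  if (n_rows * out_deg != n_cols * in_deg)
    stop("infeasible margins: n_rows*out_deg must equal n_cols*in_deg")
  if (!is.null(seed)) set.seed(seed)
  el <- cpp_sample_block(as.integer(n_rows), as.integer(n_cols),
                         as.integer(out_deg), as.integer(in_deg),
                         isTRUE(forbid_diagonal), swap_factor)
  Matrix::sparseMatrix(i = el$i, j = el$j, x = 1,
                       dims = c(n_rows, n_cols))
}

#' Assemble the full signed weight matrix
#'
#' Samples all nine blocks of the competition network with exact degrees and
#' assembles the N x N signed synaptic weight matrix (rows are presynaptic, so
#' excitatory rows are nonnegative and inhibitory rows nonpositive). Each
#' block gets a child seed derived deterministically from the master seed.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param seed master integer seed.
#' @param swap_factor successful checkerboard swaps per edge (see
#'   \code{\link{sample_block}}).
#' @return An object of class \code{weighted_graph}: list with the sparse
#'   weight matrix \code{W} (mV), the population \code{membership} factor, the
#'   \code{spec} and the \code{seed}.
#' @export
assemble_network <- function(spec, seed = 1L, swap_factor = 10) {
  stopifnot(inherits(spec, "network_spec"))
  bd <- block_degrees(spec)
  sizes <- population_sizes(spec)
  offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
  names(offs) <- names(sizes)
  N <- sum(sizes)

  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, nrow(bd))

  ii <- vector("list", nrow(bd)); jj <- ii; xx <- ii
  for (b in seq_len(nrow(bd))) {
    blk <- bd[b, ]
    set.seed(child_seeds[b])
    el <- cpp_sample_block(blk$n_from, blk$n_to, blk$out_deg, blk$in_deg,
                           blk$from == blk$to, swap_factor)
    ii[[b]] <- el$i + offs[[blk$from]]
    jj[[b]] <- el$j + offs[[blk$to]]
    xx[[b]] <- rep(blk$weight, length(el$i))
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(N, N))
  membership <- factor(rep(names(sizes), sizes), levels = names(sizes))
  structure(list(W = W, membership = membership, spec = spec, seed = seed),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %s, N = %d neurons, %d synapses, seed %d\n",
              x$spec$scenario, nrow(x$W), Matrix::nnzero(x$W), x$seed))
  invisible(x)
}

#' Write / read a network as plain text
#'
#' The graph is serialized as a sparse triplet table (0-based \code{row},
#' \code{col}, \code{weight} in mV) and a membership table (0-based
#' \code{neuron}, \code{population}), both tab-separated.
#'
#' @param graph a \code{weighted_graph}.
#' @param file base path; \code{<file>.edges.tsv} and \code{<file>.pops.tsv}
#'   are written.
#' @return \code{write_network} returns the file paths invisibly;
#'   \code{read_network} returns a \code{weighted_graph} (without spec/seed
#'   metadata beyond what the tables carry).
#' @export
write_network <- function(graph, file) {
  stopifnot(inherits(graph, "weighted_graph"))
  tr <- Matrix::summary(graph$W)
  edges <- data.frame(row = tr$i - 1L, col = tr$j - 1L, weight = tr$x)
  pops <- data.frame(neuron = seq_along(graph$membership) - 1L,
                     population = as.character(graph$membership))
  f1 <- paste0(file, ".edges.tsv"); f2 <- paste0(file, ".pops.tsv")
  utils::write.table(edges, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(pops, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(edges = f1, pops = f2))
}

#' @rdname write_network
#' @param file base path used by \code{write_network}.
#' @export
read_network <- function(file) {
  edges <- utils::read.table(paste0(file, ".edges.tsv"), header = TRUE, sep = "\t")
  pops <- utils::read.table(paste0(file, ".pops.tsv"), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  N <- nrow(pops)
  W <- Matrix::sparseMatrix(i = edges$row + 1L, j = edges$col + 1L,
                            x = edges$weight, dims = c(N, N))
  membership <- factor(pops$population, levels = unique(pops$population))
  structure(list(W = W, membership = membership, spec = NULL, seed = NA),
            class = "weighted_graph")
}
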