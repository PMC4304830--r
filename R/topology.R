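#' Construct a GRN topology
#'
#' A topology is a signed N x N adjacency matrix `M` in which entry `M[i, j]`
#' encodes the regulation of gene `i` by gene `j`: `+1` activation, `-1`
#' inhibition, `0` no interaction. The matrix is the genotype manipulated by
#' the genetic algorithm and the object whose topological robustness is
#' measured. Two topologies are equal iff their matrices are elementwise
#' equal; no isomorphism collapsing is performed.
#'
#' @param matrix integer matrix with entries in `{-1, 0, 1}`; `matrix[i, j]`
#'   is the regulation of gene `i` by gene `j`.
#' @param genes optional character vector of gene names (defaults to
#'   `G0, G1, ...`).
#' @return An object of class `grn_topology` with elements `matrix`,
#'   `n_genes` and `genes`.
#' @examples
#' rep3 <- grn_topology(rbind(c(0, 0, -1), c(-1, 0, 0), c(0, -1, 0)))
#' interaction_count(rep3)
#' @export
grn_topology <- function(matrix, genes = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m) || nrow(m) < 1) {
    stop("topology matrix must be square with at least one gene",
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(-1L, 0L, 1L))) {
    stop("topology entries must all be in {-1, 0, 1}", call. = FALSE)
  }
  n <- nrow(m)
  if (is.null(genes)) genes <- paste0("G", seq_len(n) - 1L)
  if (length(genes) != n) {
    stop("need exactly one gene name per row", call. = FALSE)
  }
  dimnames(m) <- list(genes, genes)
  structure(list(matrix = m, n_genes = n, genes = genes),
            class = "grn_topology")
}

#' @export
print.grn_topology <- function(x, ...) {
  cat(sprintf("GRN topology: %d genes, %d interactions (c = %.2f, K = %.2f)\n",
              x$n_genes, interaction_count(x),
              interaction_count(x) / x$n_genes^2,
              interaction_count(x) / x$n_genes))
  print(x$matrix)
  invisible(x)
}

#' Number of interactions in a topology
#'
#' @param topology a [grn_topology()].
#' @return Integer count `I` of nonzero matrix entries.
#' @export
interaction_count <- function(topology) {
  stopifnot(inherits(topology, "grn_topology"))
  sum(topology$matrix != 0L)
}

#' Topology complexity metrics
#'
#' Computes the interaction count `I`, the connectivity density
#' `c = I / N^2` and the mean number of regulators per gene `K = I / N`.
#' Values are returned unrounded; round to two decimals for presentation.
#'
#' @param topology a [grn_topology()].
#' @return A list with components `I`, `c` and `K`.
#' @export
complexity_metrics <- function(topology) {
  stopifnot(inherits(topology, "grn_topology"))
  I <- sum(topology$matrix != 0L)
  N <- topology$n_genes
  list(I = I, c = I / N^2, K = I / N)
}

#' Test two topologies for equality
#'
#' Equality is elementwise equality of the signed matrices (gene labels and
#' orderings matter; relabeled versions of the same wiring are different
#' topologies). Use [canonical_topology_key()] for permutation-invariant
#' comparison at the reporting level.
#'
#' @param x,y [grn_topology()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
topologies_equal <- function(x, y) {
  stopifnot(inherits(x, "grn_topology"), inherits(y, "grn_topology"))
  x$n_genes == y$n_genes && all(x$matrix == y$matrix)
}

#' Exact archive key for a topology
#'
#' Serializes the matrix entries row-major into a string; label-sensitive.
#'
#' @param topology a [grn_topology()].
#' @return A character scalar usable as a map key.
#' @export
topology_key <- function(topology) {
  stopifnot(inherits(topology, "grn_topology"))
  paste(as.integer(t(topology$matrix)), collapse = ",")
}

#' Permutation-invariant topology key
#'
#' Canonical form under gene relabeling: the lexicographically smallest
#' [topology_key()] over all simultaneous row/column permutations of the
#' matrix. Intended for reporting (e.g. asking whether independent
#' evolutionary runs converged on the same wiring); the evaluation archive
#' itself is label-sensitive.
#'
#' @param topology a [grn_topology()].
#' @return A character scalar.
#' @export
canonical_topology_key <- function(topology) {
  stopifnot(inherits(topology, "grn_topology"))
  n <- topology$n_genes
  perms <- .permutations(n)
  keys <- vapply(perms, function(p) {
    paste(as.integer(t(topology$matrix[p, p, drop = FALSE])), collapse = ",")
  }, character(1))
  min(keys)
}

.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .permutations(n - 1L)
    for (r in rest) {
      v <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, v[r])
    }
  }
  out
}

#' Reference topologies from the oscillation/bistability literature
#'
#' Returns the exact signed adjacency matrix for a named reference network:
#' \describe{
#'   \item{`repressilator`}{three-gene ring of cyclic repressions
#'     (A -| B, B -| C, C -| A).}
#'   \item{`toggle_switch`}{two genes, each with positive auto-regulation,
#'     mutually inhibiting the other (A -> A, B -> B, A -| B, B -| A); the
#'     canonical bistable motif.}
#'   \item{`delayed_negative_feedback_3`}{three-gene delayed negative
#'     feedback loop (A -> B, B -> C, C -| A), the classic
#'     oscillation-generating motif.}
#'   \item{`evolved_oscillator_4`}{four-gene oscillator made of two coupled
#'     negative feedback loops (A -> B, B -> D, D -| A, D -> C, C -| A).}
#'   \item{`amplified_negative_feedback_2`}{two-gene amplified negative
#'     feedback oscillator (A -> A, A -> B, B -| A).}
#' }
#'
#' @param name one of the identifiers above.
#' @return A [grn_topology()].
#' @export
library_topology <- function(name) {
  defs <- list(
    repressilator = list(
      genes = c("A", "B", "C"),
      edges = list(c("B", "A", -1), c("C", "B", -1), c("A", "C", -1))
    ),
    toggle_switch = list(
      genes = c("A", "B"),
      edges = list(c("A", "A", 1), c("B", "B", 1),
                   c("B", "A", -1), c("A", "B", -1))
    ),
    delayed_negative_feedback_3 = list(
      genes = c("A", "B", "C"),
      edges = list(c("B", "A", 1), c("C", "B", 1), c("A", "C", -1))
    ),
    evolved_oscillator_4 = list(
      genes = c("A", "B", "C", "D"),
      edges = list(c("B", "A", 1), c("D", "B", 1), c("A", "D", -1),
                   c("C", "D", 1), c("A", "C", -1))
    ),
    amplified_negative_feedback_2 = list(
      genes = c("A", "B"),
      edges = list(c("A", "A", 1), c("B", "A", 1), c("A", "B", -1))
    )
  )
  if (!name %in% names(defs)) {
    stop(sprintf("unknown topology '%s'; valid names: %s", name,
                 paste(names(defs), collapse = ", ")), call. = FALSE)
  }
  d <- defs[[name]]
  n <- length(d$genes)
  m <- matrix(0L, n, n, dimnames = list(d$genes, d$genes))
  for (e in d$edges) {
    # edge spec: (target, source, sign) -- source regulates target
    m[e[1], e[2]] <- as.integer(e[3])
  }
  grn_topology(m, genes = d$genes)
}

#' Read / write topology files
#'
#' The TSV form is a plain `N x N` integer matrix (no header): row `i` holds
#' the regulations INTO gene `i`. The JSON form is
#' `{"genes": [...], "matrix": [[...]]}`. Both round-trip bit-exactly.
#'
#' @param path file path.
#' @param topology a [grn_topology()].
#' @param genes optional gene names for the TSV reader.
#' @return `read_topology()` returns a [grn_topology()]; the writers return
#'   `path` invisibly.
#' @name topology_io
NULL

#' @rdname topology_io
#' @export
read_topology_tsv <- function(path, genes = NULL) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  grn_topology(m, genes = genes)
}

#' @rdname topology_io
#' @export
write_topology_tsv <- function(topology, path) {
  stopifnot(inherits(topology, "grn_topology"))
  utils::write.table(topology$matrix, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname topology_io
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  m <- as.matrix(obj$matrix)
  dimnames(m) <- NULL
  grn_topology(m, genes = obj$genes)
}

#' @rdname topology_io
#' @export
write_topology_json <- function(topology, path) {
  stopifnot(inherits(topology, "grn_topology"))
  obj <- list(genes = topology$genes,
              matrix = unname(topology$matrix))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Random topology
#'
#' Draws each of the `N^2` matrix entries independently and uniformly from
#' `{-1, 0, 1}`; the initializer used by [evolve_topology()].
#'
#' @param n_genes number of genes `N`.
#' @return A [grn_topology()].
#' @export
random_topology <- function(n_genes) {
  m <- matrix(sample(c(-1L, 0L, 1L), n_genes * n_genes, replace = TRUE),
              n_genes, n_genes)
  grn_topology(m)
}
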