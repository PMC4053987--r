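# R surface of the banded inside-outside dynamic program.
#
# Coordinates returned to R use gap indices: index i in 0..N is the boundary
# before base i+1, a two-dimensional entry (i, j) covers bases i+1..j and is
# stored banded at row i, column j-i (0..W).  Stem(i, j) assumes pair
# (i+1, j).  The maximal span W is clamped to the sequence length silently.

# Flatten parameters for the compiled code (last array index fastest).
.prep_params <- function(params, loop_cap = 30L) {
  flat <- function(a) as.vector(aperm(a, rev(seq_along(dim(a)))))
  sp <- params$special_hairpins
  codes <- integer(0)
  lens <- integer(0)
  if (length(sp)) {
    enc <- lapply(names(sp), function(s) .encode_seq(s))
    codes <- unlist(enc)
    lens <- vapply(enc, length, 1L)
  }
  list(
    rt = .rt(params),
    stack = as.vector(t(params$stack)),
    hairpin = unname(params$hairpin_length),
    bulge = unname(params$bulge_length),
    internal = unname(params$internal_length),
    mmh = flat(params$mismatch_hairpin),
    mmi = flat(params$mismatch_interior),
    int11 = flat(params$int11),
    int21 = flat(params$int21),
    int22 = if (is.null(params$int22)) numeric(0) else flat(params$int22),
    ninio = params$ninio, max_ninio = params$max_ninio,
    ml_close = params$ml_close, ml_branch = params$ml_branch,
    ml_unpaired = params$ml_unpaired,
    terminal_au = params$terminal_au, lxc = params$lxc,
    special_codes = codes, special_len = lens,
    special_val = unname(sp)
  )
}

.check_dp_args <- function(seq, params, max_span, loop_cap) {
  if (!inherits(params, "energy_parameters")) {
    stop("'params' must be an energy_parameters object")
  }
  if (!.is_count(max_span, 1L)) stop("'max_span' (W) must be an integer >= 1")
  if (!.is_count(loop_cap, 0L)) stop("'loop_cap' (C) must be a non-negative integer")
  x <- .as_codes(seq)
  if (length(x) < 1) stop("empty sequence")
  x
}

# Fast path: profile + log partition function, no tables kept.
.rfold_run <- function(codes, params, max_span, loop_cap = 30L) {
  cpp_rfold_profile(codes, .prep_params(params), as.integer(max_span),
                    as.integer(loop_cap))
}

#' Inside dynamic-programming tables
#'
#' Runs the banded inside algorithm over the seven grammar states and
#' returns the alpha tables (true, unscaled values; intended for short
#' sequences).  `alpha_outer[i + 1]` is the inside value of the boundary
#' after the first `i` bases, so `alpha_outer[N + 1]` is the partition
#' function.  Each two-dimensional state is a banded `(N+1) x (W+1)` matrix
#' whose entry `[i + 1, w + 1]` covers bases `i+1 .. i+w`.
#'
#' @param seq RNA sequence (string over ACGUN, or integer codes).
#' @param params an `energy_parameters` object.
#' @param max_span maximal base-pair span W (clamped to the sequence length).
#' @param loop_cap maximal total unpaired length C of interior/bulge loops.
#' @return an object of class `inside_tables`.
#' @seealso [rfold_outside()], [partition_function()], [structural_profile()]
#' @export
rfold_inside <- function(seq, params, max_span, loop_cap = 30) {
  x <- .check_dp_args(seq, params, max_span, loop_cap)
  res <- cpp_rfold_tables(x, .prep_params(params), as.integer(max_span),
                          as.integer(loop_cap))
  structure(
    list(alpha_outer = res$alpha_outer, alpha = res$alpha,
         N = length(x), W = res$W_eff, loop_cap = as.integer(loop_cap),
         logZ = res$logZ, ops = res$inside_ops),
    class = "inside_tables"
  )
}

#' Outside dynamic-programming tables
#'
#' Companion of [rfold_inside()]; `beta_outer[N + 1]` is 1 by construction.
#' If `inside` is supplied it is only used to check that the shapes match.
#'
#' @inheritParams rfold_inside
#' @param inside optional `inside_tables` from the same `(seq, params,
#'   max_span)`.
#' @return an object of class `outside_tables`.
#' @export
rfold_outside <- function(seq, params, max_span, inside = NULL,
                          loop_cap = 30) {
  x <- .check_dp_args(seq, params, max_span, loop_cap)
  if (!is.null(inside)) {
    stopifnot(inherits(inside, "inside_tables"))
    if (inside$N != length(x) || inside$W != .w_eff(max_span, length(x))) {
      stop("'inside' tables were computed for a different (seq, W)")
    }
  }
  res <- cpp_rfold_tables(x, .prep_params(params), as.integer(max_span),
                          as.integer(loop_cap))
  structure(
    list(beta_outer = res$beta_outer, beta = res$beta,
         N = length(x), W = res$W_eff, loop_cap = as.integer(loop_cap),
         ops = res$outside_ops),
    class = "outside_tables"
  )
}

#' Partition function
#'
#' The total Boltzmann weight of all admissible structures, read off the
#' inside tables as the outer value at the full-sequence boundary.  At
#' least 1, because the empty (pair-free) structure always contributes
#' weight 1.
#'
#' @param inside an `inside_tables` object.
#' @return the partition function Z, with the log value in attribute
#'   `"logZ"` (use that for long sequences).
#' @export
partition_function <- function(inside) {
  stopifnot(inherits(inside, "inside_tables"))
  structure(exp(inside$logZ), logZ = inside$logZ)
}

#' @export
print.inside_tables <- function(x, ...) {
  cat(sprintf("inside tables: N = %d, W = %d, C = %d, log Z = %.6g\n",
              x$N, x$W, x$loop_cap, x$logZ))
  invisible(x)
}

#' @export
print.outside_tables <- function(x, ...) {
  cat(sprintf("outside tables: N = %d, W = %d, C = %d\n", x$N, x$W,
              x$loop_cap))
  invisible(x)
}

# Operation counts of the two passes, for the complexity contract checks.
.rfold_op_counts <- function(seq, params, max_span, loop_cap = 30) {
  x <- .check_dp_args(seq, params, max_span, loop_cap)
  res <- .rfold_run(x, params, max_span, loop_cap)
  c(inside = res$inside_ops, outside = res$outside_ops)
}
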