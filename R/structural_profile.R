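# Structural profiles: the per-base context probabilities.

#' Compute the structural profile of an RNA sequence
#'
#' For every base position i the profile gives the six probabilities that,
#' under the Boltzmann ensemble of secondary structures (Turner
#' nearest-neighbour energies, maximal pair span `max_span`, interior-loop
#' size cap `loop_cap`), the base lies in a bulge loop (B), exterior loop
#' (E), hairpin loop (H), internal loop (I), multibranch loop (M) or stem
#' (S).  Each row sums to 1 up to floating-point error; rows are reported
#' as computed, without renormalisation.  The derived unstructured track
#' U = E + M is attached as a seventh column view (see
#' [unstructured_track()]).
#'
#' Sequences are normalised (uppercase, T to U); `N` and other ambiguity
#' codes are treated as unpairable bases that can still sit in any loop
#' context.
#'
#' @param x RNA/DNA sequence: a character string, or a `sequence_record`
#'   from [read_fasta()].
#' @param max_span maximal span W: bases further apart than this cannot
#'   pair.  Required; results depend on it, so no default is imposed.
#'   Values larger than the sequence length are clamped silently.
#' @param parameters energy parameters from [load_parameters()].
#' @param loop_cap maximal total unpaired length of interior/bulge loops
#'   (default 30, as in standard folding tools).
#' @param name sequence name used in printing and serialisation.
#' @return an object of class `structural_profile` with components
#'   `name`, `sequence`, `prob` (N x 6 matrix, columns B,E,H,I,M,S),
#'   `unstructured` (numeric vector, = E+M), `max_span`, `span_used`,
#'   `loop_cap`, `logZ`.
#' @examples
#' sp <- structural_profile("GGGCGAAAGCCC", max_span = 12)
#' sp
#' summary(sp)
#' @export
structural_profile <- function(x, max_span, parameters = load_parameters(),
                               loop_cap = 30, name = NULL) {
  if (inherits(x, "sequence_record")) {
    if (is.null(name)) name <- x$id
    x <- x$residues
  }
  if (!is.character(x) || length(x) != 1L) {
    stop("'x' must be a single sequence string or a sequence_record")
  }
  if (missing(max_span)) stop("'max_span' (W) is required")
  seq_norm <- .normalize_seq(x)
  codes <- .encode_seq(seq_norm)
  .check_dp_args(codes, parameters, max_span, loop_cap)
  res <- .rfold_run(codes, parameters, max_span, loop_cap)
  prob <- res$profile
  colnames(prob) <- .CONTEXTS
  structure(
    list(name = if (is.null(name)) "sequence" else name,
         sequence = as.character(seq_norm),
         prob = prob,
         unstructured = unname(prob[, "E"] + prob[, "M"]),
         max_span = as.integer(max_span),
         span_used = res$W_eff,
         loop_cap = as.integer(loop_cap),
         logZ = res$logZ),
    class = "structural_profile",
    ops = c(inside = res$inside_ops, outside = res$outside_ops)
  )
}

#' Unstructured track of a profile
#'
#' The unstructured context U collects the exterior and multibranch loop
#' contexts; unlike E and M individually, it is insensitive to the maximal
#' span W.
#'
#' @param profile a `structural_profile`.
#' @return numeric vector, `p(i,E) + p(i,M)` per position.
#' @export
unstructured_track <- function(profile) {
  stopifnot(inherits(profile, "structural_profile"))
  unname(profile$prob[, "E"] + profile$prob[, "M"])
}

#' @export
print.structural_profile <- function(x, ...) {
  n <- nrow(x$prob)
  cat(sprintf("structural profile of '%s' (%d nt, W = %d, C = %d)\n",
              x$name, n, x$span_used, x$loop_cap))
  cat(sprintf("  log Z = %.4f\n", x$logZ))
  k <- min(n, 8L)
  df <- as.data.frame(x)[seq_len(k), ]
  print(format(df, digits = 4), row.names = FALSE)
  if (n > k) cat("  ... (", n - k, " more positions)\n", sep = "")
  invisible(x)
}

#' @method summary structural_profile
#' @export
summary.structural_profile <- function(object, ...) {
  means <- colMeans(object$prob)
  out <- c(means, U = unname(means["E"] + means["M"]))
  class(out) <- "summary.structural_profile"
  attr(out, "name") <- object$name
  out
}

#' @export
print.summary.structural_profile <- function(x, ...) {
  cat(sprintf("mean context probabilities of '%s':\n", attr(x, "name")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' @method as.matrix structural_profile
#' @export
as.matrix.structural_profile <- function(x, ...) x$prob

#' @method as.data.frame structural_profile
#' @export
as.data.frame.structural_profile <- function(x, ...) {
  data.frame(
    position = seq_len(nrow(x$prob)),
    base = strsplit(x$sequence, "", fixed = TRUE)[[1]],
    x$prob,
    U = x$unstructured
  )
}

#' Plot a structural profile
#'
#' Stacked per-position context probabilities (they sum to 1, so the bands
#' fill the unit strip).
#'
#' @param x a `structural_profile`.
#' @param ... passed to [graphics::plot()].
#' @method plot structural_profile
#' @export
plot.structural_profile <- function(x, ...) {
  prob <- x$prob
  n <- nrow(prob)
  cum <- t(apply(prob, 1, cumsum))
  cols <- c(B = "#e78ac3", E = "#a6d854", H = "#8da0cb", I = "#66c2a5",
            M = "#1b9e77", S = "#fc8d62")
  graphics::plot(NULL, xlim = c(1, n), ylim = c(0, 1),
                 xlab = "position", ylab = "probability",
                 main = x$name, ...)
  lower <- rep(0, n)
  for (k in seq_len(ncol(prob))) {
    graphics::polygon(c(seq_len(n), rev(seq_len(n))),
                      c(cum[, k], rev(lower)),
                      col = cols[colnames(prob)[k]], border = NA)
    lower <- cum[, k]
  }
  graphics::legend("topright", legend = colnames(prob),
                   fill = cols[colnames(prob)], bty = "n", cex = 0.8)
  invisible(x)
}
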