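# Exact enumeration oracle for short sequences.
#
# Ground truth at desk scale: every pseudoknot-free secondary structure is
# enumerated, each base's context is classified from first principles
# (loop polygons and their hydrogen-bond counts), the structure's free
# energy is assembled loop by loop with the same attribution conventions as
# the energy model, and exact Boltzmann profiles follow by summation.  The
# oracle shares the energy tables but none of the dynamic-programming code.
#
# Span semantics match the banded grammar: under maximal span W, bases a
# and b can pair when b - a <= W_eff - 2 (W_eff = min(W, N)), the bound
# induced by the grammar's strict outer transition; nested pairs are
# automatically narrower.  Interior/bulge loops with more than `loop_cap`
# unpaired bases are not part of the ensemble.

.MAX_ENUM_N <- 16L

# All structures of codes x as partner vectors (0 = unpaired), via the
# standard "first position unpaired or paired to k" recursion, memoised on
# the region.
.enum_pairs <- function(x, max_sep) {
  n <- length(x)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4) return(list(integer(0)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1, j)
    kmax <- min(j, i + max_sep)
    k <- i + 4
    while (k <= kmax) {
      if (.pair_type(x[i], x[k]) > 0L) {
        inner <- rec(i + 1, k - 1)
        rest <- rec(k + 1, j)
        for (s1 in inner) {
          for (s2 in rest) {
            out[[length(out) + 1L]] <- c(i, k, s1, s2)
          }
        }
      }
      k <- k + 1L
    }
    memo[[key]] <- out
    out
  }
  # structures are flat integer vectors c(a1, b1, a2, b2, ...) of pairs
  rec(1L, n)
}

.pairs_to_partner <- function(pr, n) {
  partner <- integer(n)
  if (length(pr)) {
    a <- pr[c(TRUE, FALSE)]
    b <- pr[c(FALSE, TRUE)]
    partner[a] <- b
    partner[b] <- a
  }
  partner
}

.partner_to_db <- function(partner) {
  ch <- rep(".", length(partner))
  ch[partner > seq_along(partner)] <- "("
  ch[partner != 0 & partner < seq_along(partner)] <- ")"
  paste(ch, collapse = "")
}

.db_to_partner <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("(", ")", "."))) {
    stop("malformed dot-bracket string (characters outside '().')")
  }
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("malformed dot-bracket string (unbalanced)")
      a <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[a] <- i
      partner[i] <- a
    }
  }
  if (length(stack)) stop("malformed dot-bracket string (unbalanced)")
  partner
}

#' Enumerate all secondary structures of a short sequence
#'
#' Exhaustive, duplicate-free enumeration (including the empty structure)
#' of nested structures over the canonical pairs AU/UA/GC/CG/GU/UG with
#' hairpin loops of at least 3 unpaired bases.  Under a finite `max_span`
#' W, bases a and b may pair when `b - a <= min(W, N) - 2`, the admissible
#' set of the banded grammar used by [structural_profile()].  Guarded to
#' sequences of at most 16 bases (the count grows exponentially).
#'
#' @param seq RNA sequence (string or integer codes).
#' @param max_span maximal span W, or `Inf` for no constraint.
#' @return character vector of dot-bracket strings.
#' @export
enumerate_structures <- function(seq, max_span = Inf) {
  x <- .as_codes(seq)
  n <- length(x)
  if (n > .MAX_ENUM_N) {
    stop("enumeration is limited to sequences of at most ", .MAX_ENUM_N,
         " bases (got ", n, ")")
  }
  max_sep <- if (is.finite(max_span)) .w_eff(max_span, n) - 2L else n
  prs <- .enum_pairs(x, max_sep)
  vapply(prs, function(pr) .partner_to_db(.pairs_to_partner(pr, n)), "")
}

#' Count secondary structures by an independent recursion
#'
#' Counting analogue of [enumerate_structures()] (same admissibility
#' rules), computed by a memoised Nussinov-style recursion that never
#' builds the structures, so it can cross-check the enumerator.
#'
#' @inheritParams enumerate_structures
#' @return number of structures (the empty structure counts).
#' @export
count_structures <- function(seq, max_span = Inf) {
  x <- .as_codes(seq)
  n <- length(x)
  max_sep <- if (is.finite(max_span)) .w_eff(max_span, n) - 2L else n
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4) return(1)
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- rec(i + 1, j)
    kmax <- min(j, i + max_sep)
    k <- i + 4
    while (k <= kmax) {
      if (.pair_type(x[i], x[k]) > 0L) {
        total <- total + rec(i + 1, k - 1) * rec(k + 1, j)
      }
      k <- k + 1L
    }
    memo[[key]] <- total
    total
  }
  if (n < 5) return(1)
  rec(1L, n)
}

# Loop decomposition: for each pair, its direct child pairs; for each
# unpaired base, its innermost enclosing pair (0 = exterior).
.structure_loops <- function(partner) {
  n <- length(partner)
  enclosing <- integer(n) # innermost enclosing pair opening index, 0 = none
  children <- vector("list", n) # children[[a]] = opening indices under (a, b)
  ext_children <- integer(0)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (partner[i] > i) { # opening
      top <- if (length(stack)) stack[length(stack)] else 0L
      if (top == 0L) ext_children <- c(ext_children, i)
      else children[[top]] <- c(children[[top]], i)
      stack <- c(stack, i)
    } else if (partner[i] != 0L && partner[i] < i) { # closing
      stack <- stack[-length(stack)]
    } else {
      enclosing[i] <- if (length(stack)) stack[length(stack)] else 0L
    }
  }
  list(enclosing = enclosing, children = children,
       ext_children = ext_children)
}

#' Classify the structural context of every base
#'
#' Bases are vertices of loop polygons whose edges are backbone bonds and
#' hydrogen (pair) bonds.  A paired base is a stem (S).  An unpaired base
#' outside every polygon is exterior (E); in a polygon with one hydrogen
#' bond, hairpin (H); with two hydrogen bonds joined by a single backbone
#' edge on one side, bulge (B), otherwise internal (I); with more than two
#' hydrogen bonds, multibranch (M).  Every base receives exactly one label.
#'
#' @param structure dot-bracket string.
#' @return character vector of labels in {B,E,H,I,M,S}.
#' @export
classify_contexts <- function(structure) {
  partner <- .db_to_partner(structure)
  n <- length(partner)
  lab <- rep("E", n)
  lab[partner != 0L] <- "S"
  lp <- .structure_loops(partner)
  un <- which(partner == 0L & lp$enclosing > 0L)
  for (i in un) {
    a <- lp$enclosing[i]
    b <- partner[a]
    kids <- lp$children[[a]]
    nb <- length(kids)
    if (nb == 0L) {
      lab[i] <- "H"
    } else if (nb == 1L) {
      m <- kids[1] - a - 1L
      nn <- b - partner[kids[1]] - 1L
      lab[i] <- if (m > 0L && nn > 0L) "I" else "B"
    } else {
      lab[i] <- "M"
    }
  }
  lab
}

#' Free energy of a secondary structure
#'
#' Loop-by-loop free energy relative to the open chain, using the identical
#' attribution conventions as the energy model (see the package's energy
#' model documentation): hairpin, stack, bulge and interior terms per
#' closing pair, the affine multibranch model with terminal AU/GU penalties
#' per helix end facing the loop, and terminal penalties for helix ends
#' facing the exterior loop.  The empty structure has energy 0.
#'
#' @param seq RNA sequence (string or integer codes).
#' @param structure dot-bracket string.
#' @param params an `energy_parameters` object.
#' @return free energy difference in kcal/mol (may be `Inf` if the
#'   structure uses a forbidden loop, e.g. a hairpin of fewer than 3
#'   bases or a non-canonical pair).
#' @export
structure_energy <- function(seq, structure, params) {
  x <- .as_codes(seq)
  partner <- .db_to_partner(structure)
  if (length(partner) != length(x)) {
    stop("sequence and structure have different lengths")
  }
  lp <- .structure_loops(partner)
  e <- 0
  for (a in which(partner > seq_along(partner))) {
    b <- partner[a]
    kids <- lp$children[[a]]
    nb <- length(kids)
    if (nb == 0L) {
      e <- e + .energy_hairpin(x, a, b, params)
    } else if (nb == 1L) {
      p <- kids[1]
      q <- partner[p]
      if (p == a + 1L && q == b - 1L) {
        e <- e + .energy_stack(x, a, b, params)
      } else {
        e <- e + .energy_interior(x, a, b, p, q, params)
      }
    } else {
      unpaired <- (b - a - 1L) - sum(partner[kids] - kids + 1L)
      e <- e + params$ml_close + params$ml_branch +
        .terminal_au_energy(params, .pair_type(x[a], x[b])) +
        sum(vapply(kids, function(cc) {
          params$ml_branch +
            .terminal_au_energy(params, .pair_type(x[cc], x[partner[cc]]))
        }, 0)) +
        unpaired * params$ml_unpaired
    }
  }
  for (a in lp$ext_children) {
    e <- e + .terminal_au_energy(params, .pair_type(x[a], x[partner[a]]))
  }
  e
}

# Grammar admissibility beyond what the enumerator already enforces:
# interior/bulge loops (two-bond polygons) may hold at most `loop_cap`
# unpaired bases.
.cap_admissible <- function(partner, loop_cap) {
  lp <- .structure_loops(partner)
  for (a in which(partner > seq_along(partner))) {
    kids <- lp$children[[a]]
    if (length(kids) == 1L) {
      b <- partner[a]
      p <- kids[1]
      q <- partner[p]
      if ((p - a - 1L) + (b - q - 1L) > loop_cap) return(FALSE)
    }
  }
  TRUE
}

#' Exact structural profile by enumeration
#'
#' Computes the same quantity as [structural_profile()] by brute force:
#' enumerate all admissible structures, weight each by its Boltzmann
#' factor, and tally per (position, context).  Exact up to floating-point
#' summation; the backbone of the correctness tests.  Guarded to short
#' sequences.
#'
#' @inheritParams structural_profile
#' @return a `structural_profile` object (with attribute
#'   `"n_structures"`).
#' @export
exact_profile <- function(x, max_span, parameters = load_parameters(),
                          loop_cap = 30, name = NULL) {
  seq_norm <- .normalize_seq(x)
  codes <- .encode_seq(seq_norm)
  n <- length(codes)
  if (n > .MAX_ENUM_N) {
    stop("exact_profile is limited to sequences of at most ", .MAX_ENUM_N,
         " bases")
  }
  max_sep <- .w_eff(max_span, n) - 2L
  prs <- .enum_pairs(codes, max_sep)
  rt <- .rt(parameters)
  acc <- matrix(0, n, 6, dimnames = list(NULL, .CONTEXTS))
  z <- 0
  kept <- 0L
  for (pr in prs) {
    partner <- .pairs_to_partner(pr, n)
    if (!.cap_admissible(partner, loop_cap)) next
    db <- .partner_to_db(partner)
    e <- structure_energy(codes, db, parameters)
    if (!is.finite(e)) next
    w <- exp(-e / rt)
    lab <- classify_contexts(db)
    idx <- cbind(seq_len(n), match(lab, .CONTEXTS))
    acc[idx] <- acc[idx] + w
    z <- z + w
    kept <- kept + 1L
  }
  prob <- acc / z
  structure(
    list(name = if (is.null(name)) "sequence" else name,
         sequence = as.character(seq_norm),
         prob = prob,
         unstructured = unname(prob[, "E"] + prob[, "M"]),
         max_span = as.integer(max_span),
         span_used = .w_eff(max_span, n),
         loop_cap = as.integer(loop_cap),
         logZ = log(z)),
    class = "structural_profile",
    n_structures = kept
  )
}
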