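# Turner nearest-neighbour energy model: parameter file parsing and the
# Boltzmann weights of the grammar transitions.
#
# Energy attribution conventions (implemented identically here, in the
# enumeration oracle and in the compiled dynamic program):
#   * hairpin loops: length term (log-extrapolated beyond 30) plus terminal
#     mismatch for loops > 3; loops of exactly 3 get the terminal AU/GU
#     penalty instead of a mismatch; tabulated tri-/tetra-/hexaloops replace
#     the whole term.
#   * bulge of length 1: length term plus the stacking energy of the two
#     flanking pairs (the helix is treated as continuing); longer bulges get
#     the length term plus terminal AU/GU penalties on both closing pairs.
#   * internal loops: tabulated 1x1, 1x2/2x1 and 2x2 values where available;
#     otherwise length term + asymmetry penalty (capped) + one terminal
#     mismatch per closing pair.
#   * multibranch loops: affine model a + b*(branches) + c*(unpaired), the
#     closing helix counting as one branch; terminal AU/GU penalty per helix
#     end facing the loop.
#   * exterior loops: unpaired bases are free; each helix end facing the
#     exterior loop pays the terminal AU/GU penalty.

.REQUIRED_BLOCKS <- c(
  "stack", "hairpin_length", "bulge_length", "internal_length",
  "mismatch_hairpin", "mismatch_interior", "int11", "int21",
  "ninio", "ml_params", "terminal_au", "lxc"
)

#' Load Turner-style energy parameters
#'
#' Reads nearest-neighbour free-energy tables from one or more plain-text
#' parameter files, or the bundled Turner 2004 set.  Numbers are free
#' energies in kcal/mol at 37C; `INF` marks forbidden entries.  Blocks are
#' introduced by `# name` lines; `//` lines are comments.  Tables cover the
#' six canonical pairs in the order CG, GC, GU, UG, AU, UA and the bases in
#' the order A, C, G, U.
#'
#' @param source `"default"` for the bundled Turner 2004 tables, or a
#'   character vector of file paths.  When several files are given, later
#'   files add to / override earlier blocks (the bundled set keeps the large
#'   2x2 interior-loop table in a companion file this way).
#' @return An object of class `energy_parameters`: a list with components
#'   `stack` (6x6 matrix), `hairpin_length`, `bulge_length`,
#'   `internal_length` (length-31 vectors for loop sizes 0..30, with
#'   log-extrapolation coefficient `lxc` beyond 30), `mismatch_hairpin` and
#'   `mismatch_interior` (6x4x4 arrays), `int11` (6x6x4x4), `int21`
#'   (6x6x4x4x4), `int22` (6x6x4x4x4x4 or `NULL`), `special_hairpins`
#'   (named numeric: full loop sequence including the closing pair),
#'   `ninio`/`max_ninio` (asymmetry penalty per nucleotide and its cap),
#'   `ml_close`/`ml_branch`/`ml_unpaired` (affine multibranch coefficients),
#'   `terminal_au`, `lxc`, `temperature_K` and `gas_constant`
#'   (kcal mol^-1 K^-1).
#' @examples
#' par <- load_parameters()
#' par$temperature_K
#' boltzmann_weight(1, par)
#' @export
load_parameters <- function(source = "default") {
  if (identical(source, "default")) {
    source <- c(
      system.file("extdata", "turner2004.par", package = "rnaprofile"),
      system.file("extdata", "turner2004_int22.par", package = "rnaprofile")
    )
  }
  blocks <- list()
  for (path in source) {
    if (!file.exists(path)) stop("cannot read parameter file: ", path)
    blocks <- utils::modifyList(blocks, .parse_param_blocks(path))
  }
  missing <- setdiff(.REQUIRED_BLOCKS, names(blocks))
  if (length(missing)) {
    stop("parameter file(s) missing block(s): ", paste(missing, collapse = ", "))
  }
  .build_parameters(blocks)
}

# Split a parameter file into named token blocks.
.parse_param_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^##", ln) || grepl("^\\s*//", ln) || !nzchar(trimws(ln))) next
    hdr <- regmatches(ln, regexec("^# (\\S+)", ln))[[1]]
    if (length(hdr) == 2) {
      cur <- hdr[2]
      blocks[[cur]] <- character(0)
      next
    }
    if (is.null(cur)) stop("malformed parameter file (tokens before any block): ", path)
    blocks[[cur]] <- c(blocks[[cur]], strsplit(trimws(ln), "\\s+")[[1]])
  }
  blocks
}

.block_numeric <- function(blocks, name, n) {
  tok <- blocks[[name]]
  val <- suppressWarnings(as.numeric(ifelse(tok == "INF", Inf, tok)))
  if (anyNA(val)) stop("non-numeric entry in parameter block '", name, "'")
  if (!is.null(n) && length(val) != n) {
    stop("parameter block '", name, "' has ", length(val),
         " entries, expected ", n)
  }
  val
}

# Token order in files is row-major with the LAST index fastest; R arrays
# fill the first index fastest, hence the aperm dance.
.tokens_to_array <- function(v, dim) {
  aperm(array(v, dim = rev(dim)), rev(seq_along(dim)))
}

.build_parameters <- function(blocks) {
  p <- list()
  p$temperature_K <- if (!is.null(blocks$temperature_K)) {
    .block_numeric(blocks, "temperature_K", 1)
  } else 310.15
  if (!is.finite(p$temperature_K) || p$temperature_K <= 0) {
    stop("temperature_K must be a positive temperature in kelvin")
  }
  p$gas_constant <- 0.00198717 # kcal / (mol K)

  p$stack <- matrix(.block_numeric(blocks, "stack", 36), 6, 6, byrow = TRUE,
                    dimnames = list(.PAIRS, .PAIRS))
  for (nm in c("hairpin_length", "bulge_length", "internal_length")) {
    v <- .block_numeric(blocks, nm, 31)
    names(v) <- 0:30
    p[[nm]] <- v
  }
  if (any(is.finite(p$hairpin_length[1:3]))) {
    stop("hairpin_length must be INF for loop sizes 0..2")
  }
  for (nm in c("mismatch_hairpin", "mismatch_interior")) {
    p[[nm]] <- .tokens_to_array(.block_numeric(blocks, nm, 6 * 16), c(6, 4, 4))
    dimnames(p[[nm]]) <- list(.PAIRS, .BASES, .BASES)
  }
  p$int11 <- .tokens_to_array(.block_numeric(blocks, "int11", 36 * 16),
                              c(6, 6, 4, 4))
  p$int21 <- .tokens_to_array(.block_numeric(blocks, "int21", 36 * 64),
                              c(6, 6, 4, 4, 4))
  p$int22 <- if (!is.null(blocks$int22)) {
    .tokens_to_array(.block_numeric(blocks, "int22", 36 * 256),
                     c(6, 6, 4, 4, 4, 4))
  } else NULL

  nin <- .block_numeric(blocks, "ninio", 2)
  p$ninio <- nin[1]
  p$max_ninio <- nin[2]
  ml <- .block_numeric(blocks, "ml_params", 3)
  p$ml_close <- ml[1]
  p$ml_branch <- ml[2]
  p$ml_unpaired <- ml[3]
  p$terminal_au <- .block_numeric(blocks, "terminal_au", 1)
  p$lxc <- .block_numeric(blocks, "lxc", 1)

  p$special_hairpins <- numeric(0)
  if (!is.null(blocks$special_hairpins)) {
    tok <- blocks$special_hairpins
    if (length(tok) %% 2 != 0) stop("malformed 'special_hairpins' block")
    seqs <- tok[c(TRUE, FALSE)]
    vals <- suppressWarnings(as.numeric(tok[c(FALSE, TRUE)]))
    if (anyNA(vals)) stop("non-numeric energy in 'special_hairpins' block")
    if (!all(nchar(seqs) %in% c(5, 6, 8))) {
      stop("'special_hairpins' entries must be loops of size 3, 4 or 6 ",
           "written with their closing pair")
    }
    p$special_hairpins <- stats::setNames(vals, seqs)
  }
  structure(p, class = "energy_parameters")
}

#' Write energy parameters back to a single text file
#'
#' Inverse of [load_parameters()]: the written file parses back to an
#' identical object (round-trip identity holds entry for entry).
#'
#' @param params an `energy_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "energy_parameters"))
  fmt <- function(v) ifelse(is.infinite(v), "INF", format(v, digits = 15))
  rows <- function(v, ncol) {
    v <- fmt(v)
    apply(matrix(v, ncol = ncol, byrow = TRUE), 1, paste, collapse = " ")
  }
  flat <- function(a) as.vector(aperm(a, rev(seq_along(dim(a)))))
  out <- c(
    "## rnaprofile energy parameters 1.0",
    "# temperature_K", fmt(params$temperature_K),
    "# stack", rows(as.vector(t(params$stack)), 6),
    "# hairpin_length", rows(params$hairpin_length, 31),
    "# bulge_length", rows(params$bulge_length, 31),
    "# internal_length", rows(params$internal_length, 31),
    "# mismatch_hairpin", rows(flat(params$mismatch_hairpin), 4),
    "# mismatch_interior", rows(flat(params$mismatch_interior), 4),
    "# int11", rows(flat(params$int11), 4),
    "# int21", rows(flat(params$int21), 4)
  )
  if (!is.null(params$int22)) {
    out <- c(out, "# int22", rows(flat(params$int22), 4))
  }
  out <- c(out,
    "# ninio", paste(fmt(params$ninio), fmt(params$max_ninio)),
    "# ml_params",
    paste(fmt(params$ml_close), fmt(params$ml_branch), fmt(params$ml_unpaired)),
    "# terminal_au", fmt(params$terminal_au),
    "# lxc", fmt(params$lxc)
  )
  if (length(params$special_hairpins)) {
    out <- c(out, "# special_hairpins",
             paste(names(params$special_hairpins),
                   fmt(params$special_hairpins)))
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.energy_parameters <- function(x, ...) {
  cat("Turner-style nearest-neighbour energy parameters\n")
  cat(sprintf("  temperature: %.2f K (RT = %.4f kcal/mol)\n",
              x$temperature_K, x$gas_constant * x$temperature_K))
  cat(sprintf("  2x2 interior table: %s;  special hairpins: %d\n",
              if (is.null(x$int22)) "absent" else "present",
              length(x$special_hairpins)))
  invisible(x)
}

#' Zero-energy parameter set
#'
#' All free energies set to 0 kcal/mol (no special hairpins, no asymmetry
#' cap effects).  Every admissible structure then has Boltzmann weight 1, so
#' the partition function equals the number of admissible structures and
#' context probabilities are plain structure fractions.  Used by the
#' property tests; exported because it is generally useful for combinatorial
#' sanity checks.
#'
#' @return an `energy_parameters` object.
#' @export
flat_energy_parameters <- function() {
  p <- load_parameters()
  p$stack[] <- 0
  for (nm in c("hairpin_length", "bulge_length", "internal_length")) {
    v <- p[[nm]]
    v[is.finite(v)] <- 0
    p[[nm]] <- v
  }
  p$hairpin_length[4:31] <- 0 # sizes 3..30; 0..2 stay forbidden
  p$bulge_length[2:31] <- 0
  p$internal_length[3:31] <- 0
  p$mismatch_hairpin[] <- 0
  p$mismatch_interior[] <- 0
  p$int11[] <- 0
  p$int21[] <- 0
  if (!is.null(p$int22)) p$int22[] <- 0
  p$ninio <- 0
  p$max_ninio <- 0
  p$ml_close <- 0
  p$ml_branch <- 0
  p$ml_unpaired <- 0
  p$terminal_au <- 0
  p$lxc <- 0
  p$special_hairpins <- numeric(0)
  p
}

.rt <- function(params) params$gas_constant * params$temperature_K

#' Boltzmann weight of a free-energy difference
#'
#' @param delta_G free energy in kcal/mol (finite).
#' @param params an `energy_parameters` object supplying R and T.
#' @return `exp(-delta_G / (R * T))`.
#' @export
boltzmann_weight <- function(delta_G, params) {
  stopifnot(is.finite(delta_G))
  exp(-delta_G / .rt(params))
}

# ---- free-energy accessors (kcal/mol; Inf = forbidden) -------------------
# `x` is an integer-encoded sequence (N=0 A=1 C=2 G=3 U=4), indices 1-based.

.len_energy <- function(tab, L, lxc) {
  unname(if (L <= 30) tab[L + 1] else tab[31] + lxc * log(L / 30))
}

.terminal_au_energy <- function(params, type) {
  if (type >= 3) params$terminal_au else 0
}

.energy_hairpin <- function(x, i, j, params) {
  type <- .pair_type(x[i], x[j])
  L <- j - i - 1
  if (type == 0L || L < 3) return(Inf)
  if (L %in% c(3, 4, 6) && length(params$special_hairpins) &&
      all(x[i:j] > 0L)) {
    loop <- paste(.BASES[x[i:j]], collapse = "")
    hit <- params$special_hairpins[loop]
    if (!is.na(hit)) return(unname(hit))
  }
  e <- .len_energy(params$hairpin_length, L, params$lxc)
  if (L == 3) return(e + .terminal_au_energy(params, type))
  mm <- if (x[i + 1] > 0L && x[j - 1] > 0L) {
    params$mismatch_hairpin[type, x[i + 1], x[j - 1]]
  } else 0
  e + mm
}

.energy_stack <- function(x, i, j, params) {
  t1 <- .pair_type(x[i], x[j])
  t2 <- .pair_type(x[j - 1], x[i + 1]) # inner pair, reversed orientation
  if (t1 == 0L || t2 == 0L) return(Inf)
  params$stack[t1, t2]
}

# Interior/bulge loop closed by (i,j) with inner pair (p,q).
.energy_interior <- function(x, i, j, p, q, params) {
  t1 <- .pair_type(x[i], x[j])
  t2 <- .pair_type(x[q], x[p]) # reversed inner pair
  if (t1 == 0L || t2 == 0L) return(Inf)
  m <- p - i - 1
  n <- j - q - 1
  if (m < 0 || n < 0 || m + n == 0) return(Inf)
  if (m == 0 || n == 0) { # bulge
    L <- m + n
    e <- .len_energy(params$bulge_length, L, params$lxc)
    if (L == 1) {
      e + params$stack[t1, t2]
    } else {
      e + .terminal_au_energy(params, t1) + .terminal_au_energy(params, t2)
    }
  } else if (m == 1 && n == 1 && x[i + 1] > 0L && x[j - 1] > 0L) {
    params$int11[t1, t2, x[i + 1], x[j - 1]]
  } else if (m == 1 && n == 2 && all(x[c(i + 1, q + 1, j - 1)] > 0L)) {
    params$int21[t1, t2, x[i + 1], x[q + 1], x[j - 1]]
  } else if (m == 2 && n == 1 && all(x[c(q + 1, i + 1, p - 1)] > 0L)) {
    params$int21[t2, t1, x[q + 1], x[i + 1], x[p - 1]]
  } else if (m == 2 && n == 2 && !is.null(params$int22) &&
             all(x[c(i + 1, p - 1, q + 1, j - 1)] > 0L)) {
    params$int22[t1, t2, x[i + 1], x[p - 1], x[q + 1], x[j - 1]]
  } else {
    mm1 <- if (x[i + 1] > 0L && x[j - 1] > 0L) {
      params$mismatch_interior[t1, x[i + 1], x[j - 1]]
    } else 0
    mm2 <- if (x[q + 1] > 0L && x[p - 1] > 0L) {
      params$mismatch_interior[t2, x[q + 1], x[p - 1]]
    } else 0
    .len_energy(params$internal_length, m + n, params$lxc) +
      min(params$max_ninio, abs(m - n) * params$ninio) + mm1 + mm2
  }
}

.weight <- function(e, params) {
  if (!is.finite(e)) 0 else exp(-e / .rt(params))
}

.as_codes <- function(seq) {
  if (is.character(seq)) .encode_seq(.normalize_seq(seq)) else as.integer(seq)
}

#' Transition weights of the structure grammar
#'
#' Boltzmann weights (`exp(-dG/RT)`) of the individual grammar emissions;
#' structurally impossible emissions have weight exactly 0.  Sequence
#' positions are 1-based; `seq` may be a character string or an
#' integer-coded vector.
#'
#' `hairpin_weight(seq, i, j)` is the weight of closing a hairpin loop with
#' pair (i, j); `interior_weight(seq, i, j, p, q)` the weight of the
#' interior or bulge loop between closing pair (i, j) and inner pair
#' (p, q); `stack_weight(seq, i, j)` the weight of stacking pair (i, j) on
#' (i+1, j-1).  The multibranch weights implement the affine loop model
#' (closing, per-branch, per-unpaired-base), and
#' `external_branch_weight(seq, i, j)` is the terminal AU/GU penalty weight
#' of a helix end (i, j) facing the exterior (or a multibranch) loop.
#'
#' @param seq RNA sequence (string or integer codes).
#' @param i,j,p,q 1-based pair positions.
#' @param params an `energy_parameters` object.
#' @return a single non-negative weight.
#' @name transition_weights
NULL

#' @rdname transition_weights
#' @export
hairpin_weight <- function(seq, i, j, params) {
  x <- .as_codes(seq)
  if (i < 1 || j > length(x) || i >= j) stop("pair indices out of range")
  .weight(.energy_hairpin(x, i, j, params), params)
}

#' @rdname transition_weights
#' @export
interior_weight <- function(seq, i, j, p, q, params) {
  x <- .as_codes(seq)
  if (i < 1 || j > length(x)) stop("pair indices out of range")
  if (!(i < p && p <= q && q < j)) return(0)
  m <- p - i - 1
  n <- j - q - 1
  if (m + n == 0 || m + n > .loop_cap(params)) return(0)
  .weight(.energy_interior(x, i, j, p, q, params), params)
}

# the loop-size cap is a property of the DP, not of the tables; default 30.
# interior_weight uses it so callers can iterate freely.
.loop_cap <- function(params) {
  cap <- attr(params, "loop_cap")
  if (is.null(cap)) 30L else cap
}

#' @rdname transition_weights
#' @export
stack_weight <- function(seq, i, j, params) {
  x <- .as_codes(seq)
  if (i < 1 || j > length(x) || j - i < 3) return(0)
  .weight(.energy_stack(x, i, j, params), params)
}

#' @rdname transition_weights
#' @export
multiloop_close_weight <- function(params) {
  exp(-params$ml_close / .rt(params))
}

#' @rdname transition_weights
#' @export
multiloop_branch_weight <- function(params) {
  exp(-params$ml_branch / .rt(params))
}

#' @rdname transition_weights
#' @export
multiloop_unpaired_weight <- function(params) {
  exp(-params$ml_unpaired / .rt(params))
}

#' @rdname transition_weights
#' @export
external_branch_weight <- function(seq, i, j, params) {
  x <- .as_codes(seq)
  type <- .pair_type(x[i], x[j])
  if (type == 0L) return(0)
  .weight(.terminal_au_energy(params, type), params)
}
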