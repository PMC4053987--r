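# Synthetic data: random sequences with controlled GC, span/GC sweep
# experiments, the truncation-length validation, and CLIP fixtures with
# motifs planted in chosen structural contexts.
#
# All generators are pure functions of their arguments including the seed:
# the same call yields byte-identical output.

#' Random RNA sequences with fixed GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(U) =
#' (1-gc)/2.
#'
#' @param n number of sequences.
#' @param length sequence length (recycled across sequences).
#' @param gc GC content in [0, 1].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return named character vector (`seq1`, `seq2`, ...).
#' @export
random_sequences <- function(n, length, gc = 0.5, seed = NULL) {
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("'gc' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  length <- rep_len(length, n)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  out <- vapply(seq_len(n), function(i) {
    paste(sample(names(p), length[i], replace = TRUE, prob = p),
          collapse = "")
  }, "")
  names(out) <- paste0("seq", seq_len(n))
  out
}

.mean_profile_row <- function(seqs, max_span, parameters, loop_cap = 30) {
  tot <- matrix(0, 1, 6, dimnames = list(NULL, .CONTEXTS))
  nb <- 0
  for (s in seqs) {
    sp <- structural_profile(s, max_span = max_span, parameters = parameters,
                             loop_cap = loop_cap)
    tot <- tot + colSums(sp$prob)
    nb <- nb + nrow(sp$prob)
  }
  m <- tot / nb
  c(m[1, ], U = unname(m[1, "E"] + m[1, "M"]))
}

#' Mean structural profile as a function of the maximal span
#'
#' For each span W, the grand mean of p(i, context) over all nucleotides of
#' all sequences.  As W grows from small values, exterior-loop probability
#' falls (bases start pairing) and multibranch probability rises, while
#' their union U stays nearly constant.
#'
#' @param sequences character vector of RNA sequences.
#' @param w_values integer vector of spans to evaluate.
#' @param parameters energy parameters.
#' @param loop_cap interior-loop size cap.
#' @return data.frame with columns `W`, `B`, `E`, `H`, `I`, `M`, `S`, `U`.
#' @export
w_sweep <- function(sequences, w_values, parameters = load_parameters(),
                    loop_cap = 30) {
  stopifnot(length(sequences) >= 1)
  rows <- t(vapply(w_values, function(W) {
    .mean_profile_row(sequences, W, parameters, loop_cap)
  }, numeric(7)))
  data.frame(W = as.integer(w_values), rows)
}

#' Mean structural profile as a function of GC content
#'
#' Generates `n` random sequences per GC value (fresh, seeded, so the
#' experiment is reproducible) and reports grand-mean context
#' probabilities at fixed span.
#'
#' @param gc_values numeric vector of GC contents.
#' @param max_span span W used for all profiles.
#' @param n sequences per GC value.
#' @param length sequence length.
#' @param seed integer seed.
#' @inheritParams w_sweep
#' @return data.frame with columns `gc`, `B`, ..., `S`, `U`.
#' @export
gc_sweep <- function(gc_values, max_span, n = 50, length = 500, seed = 1,
                     parameters = load_parameters(), loop_cap = 30) {
  rows <- t(vapply(seq_along(gc_values), function(k) {
    seqs <- random_sequences(n, length, gc = gc_values[k], seed = seed + k)
    .mean_profile_row(seqs, max_span, parameters, loop_cap)
  }, numeric(7)))
  data.frame(gc = gc_values, rows)
}

#' Truncation-length validation
#'
#' How far away does sequence matter?  For random sequences of
#' `total_length` bases, the profile of the central `core` bases is
#' computed from the full sequence and from truncations keeping only `l`
#' flanking bases on each side; the two core profiles (all 6 contexts,
#' pooled over positions) are compared by Pearson correlation.
#'
#' @param n_seqs number of random sequences.
#' @param total_length full sequence length.
#' @param core length of the central segment whose profile is compared.
#' @param l_values flank lengths to evaluate.
#' @param max_span span W used for both profiles.
#' @param gc GC content of the random sequences.
#' @param seed integer seed.
#' @inheritParams w_sweep
#' @return data.frame with columns `seq`, `l`, `r` (one row per sequence
#'   and flank length).
#' @export
truncation_experiment <- function(n_seqs = 5, total_length = 10100,
                                  core = 100, l_values = c(250, 500, 1000,
                                                           2000, 2500),
                                  max_span = 100, gc = 0.5, seed = 1,
                                  parameters = load_parameters(),
                                  loop_cap = 30) {
  if (any(l_values < 0)) stop("'l_values' must be non-negative")
  if (core > total_length) stop("invalid geometry: core exceeds total_length")
  seqs <- random_sequences(n_seqs, total_length, gc = gc, seed = seed)
  start <- floor((total_length - core) / 2) + 1 # first core position
  out <- list()
  for (i in seq_len(n_seqs)) {
    full <- structural_profile(seqs[[i]], max_span = max_span,
                               parameters = parameters, loop_cap = loop_cap)
    core_full <- full$prob[start:(start + core - 1), ]
    for (l in l_values) {
      from <- max(1, start - l)
      to <- min(total_length, start + core - 1 + l)
      sub <- substr(seqs[[i]], from, to)
      tr <- structural_profile(sub, max_span = max_span,
                               parameters = parameters, loop_cap = loop_cap)
      idx <- (start - from + 1):(start - from + core)
      core_tr <- tr$prob[idx, ]
      out[[length(out) + 1L]] <- data.frame(
        seq = i, l = l,
        r = stats::cor(as.vector(core_full), as.vector(core_tr))
      )
    }
  }
  do.call(rbind, out)
}

# ---- CLIP fixture --------------------------------------------------------

.revcomp <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# A concrete (non-degenerate) instance of an IUPAC motif, reproducible
# given the RNG state.
.instantiate_motif <- function(motif) {
  sets <- .iupac_sets()
  ch <- strsplit(toupper(chartr("T", "U", motif)), "", fixed = TRUE)[[1]]
  bad <- !(ch %in% names(sets))
  if (any(bad)) stop("invalid IUPAC letter(s) in motif: ",
                     paste(unique(ch[bad]), collapse = ""))
  paste(vapply(ch, function(c) {
    s <- sets[[c]]
    if (length(s) == 1) s else sample(s, 1)
  }, ""), collapse = "")
}

# Build the sequence construct that embeds `site` (a concrete motif
# instance) in the requested structural context.  Returns the construct
# string and the 0-based offset of the site within it.
.plant_construct <- function(site, context, stem_length, loop_cap) {
  ml <- nchar(site)
  arm <- function(n) paste(sample(c("G", "C", "A", "U"), n, TRUE,
                                  prob = c(.4, .4, .1, .1)), collapse = "")
  if (context == "H") {
    loop <- if (ml >= 3) site else paste0(site, strrep("A", 3 - ml))
    p <- arm(stem_length)
    list(seq = paste0(p, loop, .revcomp(p)), offset = stem_length)
  } else if (context == "U") {
    pad <- function(n) paste(sample(c("A", "C"), n, TRUE, prob = c(.85, .15)),
                             collapse = "")
    list(seq = paste0(pad(15), site, pad(15)), offset = 15L)
  } else if (context == "S") {
    p1 <- arm(stem_length)
    p2 <- arm(stem_length)
    x <- paste0(p1, site, p2)
    list(seq = paste0(x, "GAAA", .revcomp(x)), offset = stem_length)
  } else if (context %in% c("I", "B")) {
    if (ml + (if (context == "I") 2L else 0L) > loop_cap) {
      stop("motif of length ", ml, " cannot be planted as a ", context,
           " loop under loop_cap = ", loop_cap)
    }
    p <- arm(stem_length)
    q <- arm(stem_length)
    spacer <- if (context == "I") "AA" else ""
    list(
      seq = paste0(p, site, q, "GAAA", .revcomp(q), spacer, .revcomp(p)),
      offset = stem_length
    )
  } else {
    stop("cannot plant motifs in context '", context,
         "' (supported: H, U, S, I, B)")
  }
}

#' Synthetic CLIP fixture with motifs planted in a known context
#'
#' Generates random background transcripts and embeds, in each, one
#' motif-anchored construct designed to put the motif into the requested
#' structural context (H: hairpin loop of a designed stem-loop; U:
#' A/C-rich unstructured stretch; S: one arm of a designed helix; I/B:
#' internal/bulge loop between two designed helices).  A matching peak
#' interval covers each planted site, and one decoy occurrence of the
#' motif is written into the background within +-1000 nt of the planted
#' site but outside any peak, feeding the unbound negative dataset.
#'
#' @param n_transcripts number of transcripts.
#' @param transcript_length background length per transcript.
#' @param motif IUPAC motif string; each planted site is a concrete,
#'   randomly chosen instance.
#' @param context planted context, one of `"H"`, `"U"`, `"S"`, `"I"`,
#'   `"B"`.
#' @param gc background GC content.
#' @param stem_length helix arm length of designed constructs.
#' @param decoy_offset distance (nt) from the planted site at which the
#'   decoy motif occurrence is written.
#' @param seed integer seed (fixture is reproducible).
#' @param loop_cap interior-loop cap used to check plant feasibility.
#' @return list with `transcripts` (named character vector), `peaks`
#'   (data.frame `transcript`, `start`, `end`; 0-based half-open),
#'   `truth` (data.frame with one row per planted site: `transcript`,
#'   `motif_start`, `motif_len`, `context`), and `motif`.
#' @export
clip_fixture <- function(n_transcripts = 30, transcript_length = 2000,
                         motif = "ACUK", context = "H", gc = 0.5,
                         stem_length = 10, decoy_offset = 300, seed = 1,
                         loop_cap = 30) {
  set.seed(seed)
  context <- match.arg(context, c("H", "U", "S", "I", "B"))
  txs <- random_sequences(n_transcripts, transcript_length, gc = gc)
  names(txs) <- paste0("tx", seq_len(n_transcripts))
  peaks <- list()
  truth <- list()
  for (i in seq_len(n_transcripts)) {
    site <- .instantiate_motif(motif)
    pc <- .plant_construct(site, context, stem_length, loop_cap)
    L <- nchar(pc$seq)
    mid <- floor(transcript_length / 2)
    at <- mid + sample(-50:50, 1) # 0-based construct start
    if (at + L > transcript_length || at - decoy_offset < 0) {
      stop("transcript_length too small for the construct and decoy offset")
    }
    tx <- txs[[i]]
    substr(tx, at + 1, at + L) <- pc$seq
    motif_start <- at + pc$offset
    # decoy motif occurrence outside the peak, within +-1000 nt
    dec_at <- motif_start + sample(c(-1, 1), 1) * decoy_offset
    substr(tx, dec_at + 1, dec_at + nchar(site)) <- .instantiate_motif(motif)
    txs[[i]] <- tx
    peaks[[i]] <- data.frame(transcript = names(txs)[i],
                             start = motif_start,
                             end = motif_start + nchar(site))
    truth[[i]] <- data.frame(transcript = names(txs)[i],
                             motif_start = motif_start,
                             motif_len = nchar(site),
                             context = context)
  }
  list(transcripts = txs, peaks = do.call(rbind, peaks),
       truth = do.call(rbind, truth), motif = motif)
}
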