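# CLIP-seq structural-specificity statistics.
#
# Workflow: motif-anchored binding sites inside CLIP peaks define the
# positive dataset (windows of +-flank nt around each site, one observation
# per peak, averaging within peaks).  Two negatives: unbound motif
# occurrences on the same transcripts near bound sites, and
# dinucleotide-preserving shuffles of the positive flanks.  Per relative
# position and context, a one-sided rank-sum test in each direction gives a
# signed P score (-log10 of the smaller one-sided p, negative when the
# positive dataset is the smaller side); the final score is the
# conservative combination over the two negatives, with Bonferroni
# significance levels.

.iupac_sets <- function() {
  list(A = "A", C = "C", G = "G", U = "U", T = "U",
       R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"),
       W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
       B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "U"))
}

.motif_regex <- function(motif) {
  sets <- .iupac_sets()
  ch <- strsplit(toupper(chartr("T", "U", motif)), "", fixed = TRUE)[[1]]
  bad <- !(ch %in% names(sets))
  if (any(bad)) stop("invalid IUPAC letter(s) in motif: ",
                     paste(unique(ch[bad]), collapse = ""))
  paste(vapply(ch, function(c) {
    s <- sets[[c]]
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

# 0-based start positions of all (overlapping) motif matches.
.motif_matches <- function(seq, motif) {
  rx <- paste0("(?=", .motif_regex(motif), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Read transcript-relative peak intervals (BED3)
#'
#' Three tab-separated columns: transcript id, start, end (0-based,
#' half-open), no header.  Extra columns are ignored.
#'
#' @param path BED file.
#' @return data.frame with columns `transcript`, `start`, `end`.
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("cannot read peaks file: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  df <- df[, 1:3]
  names(df) <- c("transcript", "start", "end")
  if (any(df$start < 0 | df$start >= df$end)) {
    stop("invalid peak interval(s): need 0 <= start < end")
  }
  df
}

#' Motif-anchored binding sites within peaks
#'
#' All matches of an IUPAC motif whose start lies within a peak.  Peaks
#' spanning just one or two bases are widened by 10 nt on each side before
#' matching.  Peaks with no match are dropped.
#'
#' @param transcripts named character vector (or list) of transcript
#'   sequences.
#' @param motif IUPAC motif string (e.g. `"ACUK"`, `"WGGA"`, `"UAY"`).
#' @param peaks data.frame `transcript`, `start`, `end` (0-based
#'   half-open, transcript coordinates), e.g. from [read_peaks()].
#' @param slack widening (nt) applied to peaks of length <= 2.
#' @return data.frame with one row per site: `transcript`, `start`
#'   (0-based), `length`, `peak` (index into `peaks`).
#' @export
find_motif_sites <- function(transcripts, motif, peaks, slack = 10L) {
  transcripts <- .as_transcripts(transcripts)
  ml <- nchar(motif)
  out <- list()
  for (k in seq_len(nrow(peaks))) {
    tx <- as.character(peaks$transcript[k])
    if (!tx %in% names(transcripts)) next
    s <- transcripts[[tx]]
    if (peaks$end[k] > nchar(s)) stop("peak ", k, " exceeds transcript ", tx)
    hits <- .motif_matches(s, motif)
    lo <- peaks$start[k]
    hi <- peaks$end[k] - 1L # last admissible match start
    if (peaks$end[k] - peaks$start[k] <= 2L) {
      lo <- lo - slack
      hi <- hi + slack
    }
    hits <- hits[hits >= lo & hits <= hi & hits + ml <= nchar(s)]
    if (length(hits)) {
      out[[length(out) + 1L]] <- data.frame(
        transcript = tx, start = hits, length = ml, peak = k
      )
    }
  }
  if (!length(out)) {
    return(data.frame(transcript = character(0), start = integer(0),
                      length = integer(0), peak = integer(0)))
  }
  do.call(rbind, out)
}

.as_transcripts <- function(transcripts) {
  if (inherits(transcripts, "sequence_record")) transcripts <- list(transcripts)
  if (is.list(transcripts) && length(transcripts) &&
      inherits(transcripts[[1]], "sequence_record")) {
    out <- lapply(transcripts, function(r) r$residues)
    names(out) <- vapply(transcripts, function(r) r$id, "")
    return(out)
  }
  if (is.character(transcripts)) transcripts <- as.list(transcripts)
  if (is.null(names(transcripts))) stop("transcripts must be named")
  transcripts
}

#' Sequence windows around binding sites
#'
#' Windows of `flank` nt on each side of every site, truncated at
#' transcript ends (truncation is recorded, not an error).  Windows keep
#' their site's peak id so that several sites in one peak can later be
#' averaged into a single observation.
#'
#' @param transcripts named transcript sequences.
#' @param sites data.frame as from [find_motif_sites()] (or with `peak`
#'   absent, in which case every site is its own observation group).
#' @param flank window half-width in nt.
#' @return list of window records: `seq`, `motif_at` (0-based offset of
#'   the motif within `seq`), `motif_len`, `group`, `truncated`.
#' @export
extract_positive_windows <- function(transcripts, sites, flank = 2000) {
  transcripts <- .as_transcripts(transcripts)
  out <- vector("list", nrow(sites))
  for (k in seq_len(nrow(sites))) {
    s <- transcripts[[as.character(sites$transcript[k])]]
    n <- nchar(s)
    a <- sites$start[k] # 0-based motif start
    from <- max(0L, a - as.integer(flank)) # 0-based window start
    to <- min(n, a + sites$length[k] + as.integer(flank)) # half-open end
    out[[k]] <- list(
      seq = substr(s, from + 1L, to),
      motif_at = a - from,
      motif_len = sites$length[k],
      group = if ("peak" %in% names(sites)) sites$peak[k] else k,
      truncated = (from > a - flank) || (to < a + sites$length[k] + flank)
    )
  }
  out
}

#' Unbound motif sites near bound sites
#'
#' Motif occurrences that are on the same transcript as a bound site and
#' (under the default rule) within `radius` nt of some bound site, but are
#' not themselves bound: not inside any peak and not in `bound_sites`.
#' The `"beyond"` rule instead keeps occurrences at least `radius` nt away
#' from every bound site (sensitivity analysis for the ambiguous reading
#' of the distance rule).
#'
#' @inheritParams find_motif_sites
#' @param bound_sites data.frame from [find_motif_sites()].
#' @param radius distance rule parameter in nt.
#' @param rule `"within"` (default) or `"beyond"`.
#' @return data.frame like `bound_sites` (with `peak = NA`); each row is
#'   its own observation group.
#' @export
build_unbound_dataset <- function(transcripts, motif, bound_sites, peaks,
                                  radius = 1000, rule = c("within",
                                                          "beyond")) {
  rule <- match.arg(rule)
  transcripts <- .as_transcripts(transcripts)
  ml <- nchar(motif)
  out <- list()
  for (tx in unique(as.character(bound_sites$transcript))) {
    s <- transcripts[[tx]]
    bound <- bound_sites$start[bound_sites$transcript == tx]
    pk <- peaks[as.character(peaks$transcript) == tx, , drop = FALSE]
    hits <- .motif_matches(s, motif)
    hits <- hits[hits + ml <= nchar(s)]
    for (h in hits) {
      if (h %in% bound) next
      in_peak <- nrow(pk) && any(h >= pk$start & h < pk$end)
      if (in_peak) next
      d <- min(abs(h - bound))
      keep <- if (rule == "within") d <= radius else d >= radius
      if (keep) {
        out[[length(out) + 1L]] <- data.frame(
          transcript = tx, start = h, length = ml, peak = NA_integer_
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript = character(0), start = integer(0),
                      length = integer(0), peak = integer(0)))
  }
  res <- do.call(rbind, out)
  res$peak <- NA_integer_
  res
}

#' Dinucleotide-preserving shuffle
#'
#' Altschul-Erickson Euler-path shuffle: the output is a uniformly chosen
#' random sequence with exactly the same multiset of overlapping
#' dinucleotides as the input (hence also the same base composition and the
#' same first and last characters).  Sequences of length <= 3 or with a
#' forced arrangement are returned unchanged.  Uses R's RNG; seed upstream
#' for reproducibility.
#'
#' @param seq a character string.
#' @return shuffled string.
#' @export
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n <= 3L) return(seq)
  letters_ <- unique(ch)
  if (length(letters_) == 1L) return(seq)
  # edge list of the de Bruijn multigraph
  from <- ch[-n]
  to <- ch[-1]
  verts <- unique(ch)
  last <- ch[n]
  edges <- split(to, factor(from, levels = verts))
  for (attempt in 1:1000) {
    # choose a candidate "last edge" for every vertex except the final one
    last_edge <- list()
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      outs <- edges[[v]]
      if (!length(outs)) next
      last_edge[[v]] <- outs[sample.int(length(outs), 1)]
    }
    # the chosen last edges must form an arborescence into `last`:
    # from every vertex with out-edges, following last edges reaches `last`
    for (v in names(last_edge)) {
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.null(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  if (!ok) return(seq) # no arborescence found; keep input
  # order each vertex's remaining edges randomly, append the last edge
  ordered <- list()
  for (v in verts) {
    outs <- edges[[v]]
    if (!length(outs)) { ordered[[v]] <- character(0); next }
    if (v == last || is.null(last_edge[[v]])) {
      ordered[[v]] <- outs[sample.int(length(outs))]
    } else {
      le <- last_edge[[v]]
      i <- match(le, outs)
      rest <- outs[-i]
      if (length(rest) > 1) rest <- rest[sample.int(length(rest))]
      ordered[[v]] <- c(rest, le)
    }
  }
  # walk the Euler path
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Shuffled negatives from positive windows
#'
#' Each window's upstream and downstream flanks are dinucleotide-shuffled
#' independently; the motif (plus `keep` nt on each side for the partially
#' shuffled datasets) is untouched.
#'
#' @param windows window records from [extract_positive_windows()].
#' @param keep 0 for the fully shuffled dataset; 5 or 10 keep the
#'   motif +- keep nt core intact.
#' @return window records with shuffled sequences.
#' @export
build_shuffled_dataset <- function(windows, keep = 0) {
  lapply(windows, function(w) {
    n <- nchar(w$seq)
    a <- max(0L, w$motif_at - as.integer(keep)) # 0-based core start
    b <- min(n, w$motif_at + w$motif_len + as.integer(keep)) # half-open end
    up <- if (a > 0) dinuc_shuffle(substr(w$seq, 1, a)) else ""
    down <- if (b < n) dinuc_shuffle(substr(w$seq, b + 1, n)) else ""
    w$seq <- paste0(up, substr(w$seq, a + 1, b), down)
    w
  })
}

#' @rdname build_shuffled_dataset
#' @export
build_partial_shuffled_dataset <- function(windows, keep = 5) {
  build_shuffled_dataset(windows, keep = keep)
}

#' Structural-profile dataset over a reporting window
#'
#' Computes the structural profile of every window sequence and collects,
#' per observation, the context probabilities at positions
#' `-window .. motif_len + window - 1` relative to the motif start.
#' Windows sharing an observation group (= peak) are averaged into a
#' single observation.  Contexts reported: B, E, H, I, M, S and the
#' derived U = E + M.
#'
#' @param windows window records ([extract_positive_windows()] /
#'   [build_shuffled_dataset()]).
#' @param label dataset label.
#' @param max_span maximal span W for the profiles (the CLIP analyses use
#'   200 by default).
#' @param window reporting half-width around the motif (positions beyond
#'   the sequence are NA).
#' @param parameters energy parameters.
#' @param loop_cap interior-loop cap.
#' @return object of class `profile_dataset`: list with `label`, `arr`
#'   (observations x positions x 7 contexts), `rel_pos`, `motif_len`,
#'   `n_windows`.
#' @export
profile_dataset <- function(windows, label = "dataset", max_span = 200,
                            window = 20, parameters = load_parameters(),
                            loop_cap = 30) {
  stopifnot(length(windows) >= 1)
  ml <- windows[[1]]$motif_len
  rel <- seq.int(-window, ml + window - 1L)
  ctx <- c(.CONTEXTS, "U")
  per_win <- array(NA_real_, c(length(windows), length(rel), length(ctx)))
  for (k in seq_along(windows)) {
    w <- windows[[k]]
    sp <- structural_profile(w$seq, max_span = max_span,
                             parameters = parameters, loop_cap = loop_cap)
    pos <- w$motif_at + rel + 1L # 1-based positions in the window
    ok <- pos >= 1 & pos <= nrow(sp$prob)
    per_win[k, ok, 1:6] <- sp$prob[pos[ok], ]
    per_win[k, ok, 7] <- sp$unstructured[pos[ok]]
  }
  groups <- vapply(windows, function(w) as.integer(w$group), 1L)
  ug <- unique(groups)
  arr <- array(NA_real_, c(length(ug), length(rel), length(ctx)),
               dimnames = list(NULL, as.character(rel), ctx))
  for (g in seq_along(ug)) {
    rows <- which(groups == ug[g])
    arr[g, , ] <- apply(per_win[rows, , , drop = FALSE], c(2, 3), mean)
  }
  structure(
    list(label = label, arr = arr, rel_pos = rel, motif_len = ml,
         n_windows = length(windows)),
    class = "profile_dataset"
  )
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat(sprintf(
    "profile dataset '%s': %d observations (%d windows), positions %d..%d\n",
    x$label, dim(x$arr)[1], x$n_windows, min(x$rel_pos), max(x$rel_pos)))
  invisible(x)
}

#' One-sided Wilcoxon-Mann-Whitney p-value
#'
#' Thin wrapper over [stats::wilcox.test()]: exact enumeration when both
#' samples have fewer than 50 values and no ties, otherwise the normal
#' approximation with tie and continuity corrections.  Samples of fewer
#' than 2 values give p = 1 with a warning.
#'
#' @param a,b numeric samples.
#' @param direction `"greater"` tests the hypothesis that `a` is
#'   stochastically larger than `b`; `"less"` the reverse.
#' @return the one-sided p-value.
#' @export
wmw_one_sided <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    warning("sample with fewer than 2 values; returning p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = direction, exact = NULL,
                       correct = TRUE)$p.value
  )
}

# Signed score from two samples; p-values floored at 1e-300.
.pscore_samples <- function(pos, neg) {
  p_g <- wmw_one_sided(pos, neg, "greater")
  p_l <- wmw_one_sided(pos, neg, "less")
  p <- max(min(p_g, p_l), 1e-300)
  s <- -log10(p)
  if (p_l < p_g) -s else s # ties break toward the positive sign
}

#' Signed P score at one position and context
#'
#' `-log10` of the smaller of the two one-sided rank-sum p-values
#' comparing the positive and negative observations, with negative sign
#' when the "positive smaller" hypothesis wins (ties break toward the
#' positive sign).  A large positive score means the context probability
#' is significantly larger in the positive dataset.
#'
#' @param positive,negative `profile_dataset` objects on identical
#'   reporting windows.
#' @param position relative position (0 = motif start).
#' @param context one of B, E, H, I, M, S, U.
#' @return signed score.
#' @export
pscore <- function(positive, negative, position, context) {
  stopifnot(inherits(positive, "profile_dataset"),
            inherits(negative, "profile_dataset"))
  i <- match(position, positive$rel_pos)
  if (is.na(i)) stop("position ", position, " outside the reporting window")
  j <- match(context, dimnames(positive$arr)[[3]])
  if (is.na(j)) stop("unknown context: ", context)
  .pscore_samples(positive$arr[, i, j], negative$arr[, i, j])
}

#' Conservative combination of scores against two negatives
#'
#' Same sign: the score of smaller magnitude (conservative in both
#' directions).  Opposite signs: 0.  Vectorised.
#'
#' @param score_vs_unbound,score_vs_shuffled signed scores.
#' @return combined scores.
#' @export
combine_negatives <- function(score_vs_unbound, score_vs_shuffled) {
  s1 <- score_vs_unbound
  s2 <- score_vs_shuffled
  out <- ifelse(s1 * s2 < 0, 0,
                ifelse(abs(s1) <= abs(s2), s1, s2))
  out[is.na(s1) | is.na(s2)] <- NA_real_
  out
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests in the family (reporting positions times
#'   contexts tested).
#' @return corrected per-test level `alpha / n_tests`.
#' @export
bonferroni_level <- function(alpha = 0.05, n_tests) {
  if (!.is_count(n_tests, 1L)) stop("'n_tests' must be a positive integer")
  alpha / n_tests
}

#' Position-wise P-score track
#'
#' The full CLIP statistic: per relative position and context, signed
#' scores against each negative dataset and their conservative
#' combination, with Bonferroni significance at level `alpha` over
#' (positions x contexts) tests.  By default the unstructured context U
#' replaces E and M (their union is insensitive to the maximal span).
#'
#' @param positive `profile_dataset` of the bound sites.
#' @param negatives named list of one or two negative `profile_dataset`s
#'   (e.g. `list(unbound = ..., shuffled = ...)`).
#' @param alpha family-wise error rate for the Bonferroni correction.
#' @param contexts contexts tested.
#' @return object of class `pscore_track`: a data.frame with columns
#'   `rel_position`, `context`, one score column per negative, `score`
#'   (combined) and `significant`; attributes `alpha`, `level`,
#'   `n_tests`, `threshold` (score magnitude needed for significance).
#' @export
pscore_track <- function(positive, negatives, alpha = 0.05,
                         contexts = c("B", "H", "I", "S", "U")) {
  if (inherits(negatives, "profile_dataset")) negatives <- list(negatives)
  stopifnot(length(negatives) >= 1)
  if (is.null(names(negatives)) || any(!nzchar(names(negatives)))) {
    names(negatives) <- paste0("neg", seq_along(negatives))
  }
  rel <- positive$rel_pos
  n_tests <- length(rel) * length(contexts)
  level <- bonferroni_level(alpha, n_tests)
  thr <- -log10(level)
  grid <- expand.grid(rel_position = rel, context = contexts,
                      stringsAsFactors = FALSE)
  scores <- matrix(NA_real_, nrow(grid), length(negatives),
                   dimnames = list(NULL, names(negatives)))
  for (k in seq_along(negatives)) {
    neg <- negatives[[k]]
    stopifnot(identical(neg$rel_pos, rel))
    for (r in seq_len(nrow(grid))) {
      i <- match(grid$rel_position[r], rel)
      j <- match(grid$context[r], dimnames(positive$arr)[[3]])
      a <- positive$arr[, i, j]
      b <- neg$arr[, i, j]
      a <- a[is.finite(a)]
      b <- b[is.finite(b)]
      scores[r, k] <- if (length(a) >= 2 && length(b) >= 2) {
        .pscore_samples(a, b)
      } else NA_real_
    }
  }
  combined <- if (ncol(scores) >= 2) {
    combine_negatives(scores[, 1], scores[, 2])
  } else scores[, 1]
  out <- cbind(grid, as.data.frame(scores))
  names(out)[3:(2 + length(negatives))] <-
    paste0("score_", names(negatives))
  out$score <- combined
  out$significant <- !is.na(combined) & abs(combined) > thr
  structure(out, class = c("pscore_track", "data.frame"),
            alpha = alpha, level = level, n_tests = n_tests,
            threshold = thr)
}

#' Significance mask of a P-score track
#'
#' @param track a `pscore_track`.
#' @return logical vector: |score| exceeds the Bonferroni threshold.
#' @export
significant <- function(track) {
  stopifnot(inherits(track, "pscore_track"))
  track$significant
}

#' Span-sensitivity ratio of the peak score
#'
#' Ratio of a context's highest score over all positions between tracks
#' computed at two spans (conventionally W = 400 over W = 30).  Missing
#' (NA) when the denominator track's best score is not positive.
#'
#' @param track_w400,track_w30 `pscore_track`s over identical positions.
#' @param context context label.
#' @return the ratio, or NA.
#' @export
w_sensitivity <- function(track_w400, track_w30, context) {
  top <- function(tr) {
    v <- tr$score[tr$context == context]
    if (!length(v) || all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }
  a <- top(track_w400)
  b <- top(track_w30)
  if (is.na(b) || b <= 0) return(NA_real_)
  a / b
}

#' Plot a P-score track
#'
#' Score lines per context with dashed Bonferroni levels; position 0 is
#' the motif start.
#'
#' @param x a `pscore_track`.
#' @param ... passed to [graphics::matplot()].
#' @method plot pscore_track
#' @export
plot.pscore_track <- function(x, ...) {
  ctx <- unique(x$context)
  rel <- sort(unique(x$rel_position))
  m <- sapply(ctx, function(cc) {
    x$score[x$context == cc][order(x$rel_position[x$context == cc])]
  })
  thr <- attr(x, "threshold")
  graphics::matplot(rel, m, type = "l", lty = 1, lwd = 2,
                    xlab = "position relative to motif start",
                    ylab = "P score", ...)
  graphics::abline(h = c(-thr, thr), lty = 3)
  graphics::abline(v = 0, col = "grey")
  graphics::legend("topright", legend = ctx, lty = 1, lwd = 2,
                   col = seq_along(ctx), bty = "n", cex = 0.8)
  invisible(x)
}

#' End-to-end CLIP structural-specificity analysis
#'
#' From transcripts, peaks and a motif to the combined P-score track:
#' find bound sites, build positive windows, unbound and (optionally
#' partially) shuffled negatives, compute profile datasets and the track.
#'
#' @inheritParams find_motif_sites
#' @param flank window half-width around each site (nt).
#' @param max_span span W for the profiles.
#' @param window reporting half-width around the motif.
#' @param keep 0 for fully shuffled flanks; 5/10 keep a core intact.
#' @param alpha Bonferroni family-wise level.
#' @param radius unbound-site distance rule (nt).
#' @param unbound_rule `"within"` or `"beyond"` (see
#'   [build_unbound_dataset()]).
#' @param seed seed for the shuffles.
#' @param parameters energy parameters.
#' @param loop_cap interior-loop cap.
#' @return list with `track` (`pscore_track`), `datasets` (the three
#'   `profile_dataset`s), `sites` (bound sites).
#' @export
run_clip_pipeline <- function(transcripts, peaks, motif, flank = 2000,
                              max_span = 200, window = 20, keep = 0,
                              alpha = 0.05, radius = 1000,
                              unbound_rule = "within", seed = 1,
                              parameters = load_parameters(),
                              loop_cap = 30) {
  transcripts <- .as_transcripts(transcripts)
  sites <- find_motif_sites(transcripts, motif, peaks)
  if (!nrow(sites)) stop("no motif-matched sites within the peaks")
  pos_win <- extract_positive_windows(transcripts, sites, flank = flank)
  unb <- build_unbound_dataset(transcripts, motif, sites, peaks,
                               radius = radius, rule = unbound_rule)
  if (!nrow(unb)) stop("no unbound motif sites found")
  unb$peak <- seq_len(nrow(unb)) + max(sites$peak) # own observation groups
  unb_win <- extract_positive_windows(transcripts, unb, flank = flank)
  set.seed(seed)
  shuf_win <- build_shuffled_dataset(pos_win, keep = keep)
  ds_pos <- profile_dataset(pos_win, "positive", max_span, window,
                            parameters, loop_cap)
  ds_unb <- profile_dataset(unb_win, "unbound", max_span, window,
                            parameters, loop_cap)
  ds_shf <- profile_dataset(shuf_win,
                            if (keep > 0) sprintf("partial+-%d", keep)
                            else "shuffled",
                            max_span, window, parameters, loop_cap)
  track <- pscore_track(ds_pos, list(unbound = ds_unb, shuffled = ds_shf),
                        alpha = alpha)
  list(track = track, datasets = list(positive = ds_pos, unbound = ds_unb,
                                      shuffled = ds_shf),
       sites = sites)
}
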