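# Shared test helpers.  Fixtures are built in code; nothing is read from
# disk except files the tests write themselves.

# Bundled parameters, loaded once per test run.
.par_env <- new.env()
test_params <- function() {
  if (is.null(.par_env$par)) .par_env$par <- load_parameters()
  .par_env$par
}

rand_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

same_dinucs <- function(a, b) {
  ta <- dinuc_counts(a)
  tb <- dinuc_counts(b)
  identical(sort(names(ta)), sort(names(tb))) &&
    all(ta[sort(names(ta))] == tb[sort(names(ta))])
}

# A window record as consumed by profile_dataset().
make_window <- function(seq, motif_at, motif_len, group,
                        truncated = FALSE) {
  list(seq = seq, motif_at = as.integer(motif_at),
       motif_len = as.integer(motif_len), group = group,
       truncated = truncated)
}

# Windows with a bare motif instance planted mid-sequence in i.i.d.
# background: the "no structural signal" generator used for null
# calibration (positive and negative samples are exchangeable).
null_windows <- function(k, len = 300, motif = "ACUG") {
  at <- as.integer(len / 2) - 2L
  lapply(seq_len(k), function(i) {
    s <- rand_seq(len)
    substr(s, at + 1, at + nchar(motif)) <- motif
    make_window(s, at, nchar(motif), group = i)
  })
}

# Minimal profile_dataset wrapper around an obs x pos x context array,
# for unit tests of the score functions.
make_dataset <- function(arr, rel_pos, motif_len = 4L, label = "test") {
  dimnames(arr) <- list(NULL, as.character(rel_pos),
                        c("B", "E", "H", "I", "M", "S", "U"))
  structure(list(label = label, arr = arr, rel_pos = rel_pos,
                 motif_len = motif_len, n_windows = dim(arr)[1]),
            class = "profile_dataset")
}

# Pair list (2-column matrix, a < b) of a dot-bracket string.
db_pairs <- function(db) {
  partner <- rnaprofile:::.db_to_partner(db)
  a <- which(partner > seq_along(partner))
  cbind(a, partner[a])
}
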