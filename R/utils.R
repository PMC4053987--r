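# Internal helpers shared across modules.

# Canonical pair order used by every energy table: CG GC GU UG AU UA.
.PAIRS <- c("CG", "GC", "GU", "UG", "AU", "UA")
.BASES <- c("A", "C", "G", "U")

# Context column order is fixed alphabetically everywhere.
.CONTEXTS <- c("B", "E", "H", "I", "M", "S")

# Pair-type lookup over base codes N=0 A=1 C=2 G=3 U=4;
# .PT[a+1, b+1] is the type of pair (a, b), 0 = not pairable.
.PT <- matrix(0L, 5, 5)
.PT[1 + 1, 4 + 1] <- 5L # A-U
.PT[4 + 1, 1 + 1] <- 6L # U-A
.PT[2 + 1, 3 + 1] <- 1L # C-G
.PT[3 + 1, 2 + 1] <- 2L # G-C
.PT[3 + 1, 4 + 1] <- 3L # G-U
.PT[4 + 1, 3 + 1] <- 4L # U-G

# Normalise residues: uppercase, T->U, anything outside ACGUN -> N.
# Returns a character scalar; attr "n_mapped" counts bases coerced to N.
.normalize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% c("A", "C", "G", "U", "N"))
  if (any(bad)) ch[bad] <- "N"
  out <- paste(ch, collapse = "")
  attr(out, "n_mapped") <- sum(bad)
  out
}

# Encode a normalised sequence to integer codes N=0 A=1 C=2 G=3 U=4.
.encode_seq <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  code <- match(ch, c("N", "A", "C", "G", "U")) - 1L
  if (anyNA(code)) {
    stop("sequence contains characters outside {A,C,G,U,N} after normalization")
  }
  code
}

.pair_type <- function(a, b) .PT[a + 1L, b + 1L]

# Effective maximal span: W is clamped to the sequence length silently.
.w_eff <- function(W, N) min(as.integer(W), as.integer(N))

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}
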