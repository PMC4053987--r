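# FASTA input and profile serialisation.

#' Read sequences from a FASTA file
#'
#' Records are normalised for profile computation: residues are uppercased,
#' T becomes U, and characters outside ACGUN are mapped to N (a single
#' warning reports how many).  Record ids are the first whitespace-delimited
#' token of the header; duplicate ids are deterministically suffixed
#' (`_2`, `_3`, ...) with a warning.  Line wrapping, CRLF endings and
#' trailing blank lines are tolerated.
#'
#' @param path FASTA file.
#' @return list of `sequence_record` objects (fields `id`, `description`,
#'   `residues`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- duplicated(ids)
  if (any(dup)) {
    for (i in which(dup)) {
      k <- 2L
      while (paste0(ids[i], "_", k) %in% ids) k <- k + 1L
      ids[i] <- paste0(ids[i], "_", k)
    }
    warning("duplicate FASTA ids made unique by suffixing")
  }
  n_mapped <- 0L
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    res <- as.character(set[[i]])
    if (!nzchar(res)) stop("FASTA record '", ids[i], "' has an empty sequence")
    norm <- .normalize_seq(res)
    n_mapped <- n_mapped + attr(norm, "n_mapped")
    out[[i]] <- structure(
      list(id = ids[i], description = desc[i],
           residues = as.character(norm)),
      class = "sequence_record"
    )
  }
  if (n_mapped > 0L) {
    warning(n_mapped, " residue(s) outside {A,C,G,T,U,N} were mapped to N")
  }
  names(out) <- ids
  out
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf(">%s%s (%d nt)\n", x$id,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              nchar(x$residues)))
  invisible(x)
}

# Simple FASTA writer used by the CLI and fixture generators.
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  nms <- names(seqs)
  if (is.null(nms)) nms <- paste0("seq", seq_along(seqs))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", nms[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a structural profile to disk
#'
#' Two layouts: `"tsv"` is a header line
#' `position base B E H I M S U` followed by one row per base with
#' probabilities at 6 decimals; `"capr"` mimics the original tool's layout
#' (best-effort compatible): a `>name` line, then one line per context in
#' the order Bulge, Exterior, Hairpin, Internal, Multibranch, Stem, each
#' holding the per-position probabilities.
#'
#' @param profile a `structural_profile`.
#' @param path output file; in `"tsv"` mode an existing file is
#'   overwritten, in `"capr"` mode use `append = TRUE` to accumulate
#'   records.
#' @param format `"tsv"` or `"capr"`.
#' @param append append to `path` instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("tsv", "capr"),
                          append = FALSE) {
  stopifnot(inherits(profile, "structural_profile"))
  format <- match.arg(format)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(c("position", "base", .CONTEXTS, "U"), collapse = "\t"),
               con)
    base <- strsplit(profile$sequence, "", fixed = TRUE)[[1]]
    rows <- cbind(as.character(seq_along(base)), base,
                  matrix(sprintf("%.6f", cbind(profile$prob,
                                               profile$unstructured)),
                         nrow = length(base)))
    writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  } else {
    labels <- c("Bulge", "Exterior", "Hairpin", "Internal", "Multibranch",
                "Stem")
    writeLines(paste0(">", profile$name), con)
    for (k in seq_along(labels)) {
      writeLines(paste(labels[k],
                       paste(sprintf("%.6f", profile$prob[, k]),
                             collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a profile written in "tsv" format
#'
#' Round-trip companion of [write_profile()] (tsv layout only).
#'
#' @param path tsv file written by [write_profile()].
#' @param name sequence name to attach.
#' @return a `structural_profile` (with `max_span`, `loop_cap` and `logZ`
#'   unset, as the file does not carry them).
#' @export
read_profile <- function(path, name = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "character", rep("numeric", 7)))
  need <- c("position", "base", .CONTEXTS, "U")
  if (!identical(names(df), need)) {
    stop("not a profile tsv file (expected columns: ",
         paste(need, collapse = " "), ")")
  }
  prob <- as.matrix(df[, .CONTEXTS])
  dimnames(prob) <- list(NULL, .CONTEXTS)
  structure(
    list(name = if (is.null(name)) "sequence" else name,
         sequence = paste(df$base, collapse = ""),
         prob = prob,
         unstructured = df$U,
         max_span = NA_integer_, span_used = NA_integer_,
         loop_cap = NA_integer_, logZ = NA_real_),
    class = "structural_profile"
  )
}
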