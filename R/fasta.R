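# FASTA input/output. Reading goes through Biostrings; writing is done here
# because the package records plasmid topology in the header line
# ("topology=circular"), a documented dialect FASTA itself does not define,
# and wraps sequence lines at 70 columns.

#' Read a single-record FASTA file
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return Named character scalar: the uppercased sequence, named by the
#'   record id (first whitespace-delimited token of the header).
#' @export
read_fasta_seq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L) {
    stop("expected a single FASTA record in ", path, ", found ", length(set),
         call. = FALSE)
  }
  seq <- toupper(as.character(set[[1]]))
  id <- strsplit(names(set)[[1]], "\\s+")[[1]][1]
  stats::setNames(seq, id)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param topology Optional character vector (recycled) of `"linear"` or
#'   `"circular"`; circular records get a `topology=circular` token appended
#'   to the header.
#' @param width Line width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, topology = "linear", width = 70L) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  topology <- rep_len(topology, length(seqs))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    hdr <- names(seqs)[[i]]
    if (identical(topology[[i]], "circular")) hdr <- paste(hdr, "topology=circular")
    writeLines(paste0(">", hdr), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Write an annotated plasmid as a minimal GenBank flat file
#'
#' Emits a LOCUS line, `misc_feature` entries for every feature label, and the
#' ORIGIN sequence block. Intended for plasmid-map viewers; not a complete
#' GenBank implementation.
#'
#' @param x An [annotated_seq] object.
#' @param name Record name.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(x, name, path) {
  stopifnot(inherits(x, "annotated_seq"))
  n <- nchar(x$seq)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                     substr(name, 1, 16), n,
                     if (x$topology == "circular") "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  if (nrow(x$features) > 0) {
    for (i in seq_len(nrow(x$features))) {
      loc <- sprintf("%d..%d", x$features$start[[i]] + 1L, x$features$end[[i]])
      if (identical(x$features$strand[[i]], "-")) loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     misc_feature    %s", loc), con)
      writeLines(sprintf("                     /label=\"%s\"", x$features$label[[i]]), con)
    }
  }
  writeLines("ORIGIN", con)
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(x$seq, s, min(s + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(1L, nchar(chunk), by = 10L) + 9L, nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}
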