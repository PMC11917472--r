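# Exhaustive restriction-site scanning on both strands, for linear and
# circular sequences, with IUPAC degeneracy expanded. Implemented as a
# zero-width-lookahead regex scan so overlapping occurrences are all found;
# tests cross-check against an independent naive per-position scanner and
# against Biostrings::matchPattern.

# compile an IUPAC pattern to a regex with character classes
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  cls <- IUPAC_EXPAND[chars]
  if (anyNA(cls)) {
    stop("pattern contains non-IUPAC character(s): ",
         paste(unique(chars[is.na(cls)]), collapse = ", "), call. = FALSE)
  }
  paste(ifelse(nchar(cls) == 1L, cls, paste0("[", cls, "]")), collapse = "")
}

# 0-based start positions of all (overlapping) matches of an IUPAC pattern
scan_pattern <- function(seq, pattern) {
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Find restriction sites on both strands
#'
#' Scans a sequence for every occurrence of each enzyme's recognition pattern
#' and of its reverse complement, expanding IUPAC degeneracy. Palindromic
#' patterns are reported once per physical site (on the + strand). For
#' circular topology, matches spanning the origin are found as well and
#' positions are reported modulo the sequence length.
#'
#' @param seq DNA string (A/C/G/T).
#' @param enzymes Tibble of enzymes as returned by [parse_enzyme_list()] (a
#'   subset of rows is fine).
#' @param topology `"linear"` (default) or `"circular"`.
#' @return Tibble with one row per hit: `enzyme`, `start` (0-based position
#'   of the recognition match on the forward strand), `strand` (`+`/`-`),
#'   `cut` (top-strand cut coordinate), sorted by `start` within enzyme.
#' @export
find_sites <- function(seq, enzymes, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  seq <- as_dna(seq, "sequence")
  n <- nchar(seq)
  enz_v <- start_v <- strand_v <- cut_v <- list()
  for (i in seq_len(nrow(enzymes))) {
    recog <- enzymes$recognition[[i]]
    off <- enzymes$cut_offset[[i]]
    m <- nchar(recog)
    target <- if (topology == "circular" && m > 1L && n > 1L) {
      paste0(seq, substr(seq, 1L, min(m - 1L, n)))
    } else {
      seq
    }
    fwd <- scan_pattern(target, recog)
    fwd <- fwd[fwd < n]                       # starts inside [0, n)
    start <- fwd
    strand <- rep("+", length(fwd))
    cut <- fwd + off
    rcpat <- dna_revcomp(recog)
    if (!identical(rcpat, recog)) {           # non-palindromic: scan - strand
      rev <- scan_pattern(target, rcpat)
      rev <- rev[rev < n]
      start <- c(start, rev)
      strand <- c(strand, rep("-", length(rev)))
      cut <- c(cut, rev + (m - off))
    }
    if (length(start) == 0L) next
    if (topology == "circular") cut <- cut %% n
    # degenerate patterns can match both strands at one physical site
    keep <- !duplicated(start)
    ord <- order(start[keep])
    enz_v[[length(enz_v) + 1L]] <- rep(enzymes$name[[i]], sum(keep))
    start_v[[length(start_v) + 1L]] <- start[keep][ord]
    strand_v[[length(strand_v) + 1L]] <- strand[keep][ord]
    cut_v[[length(cut_v) + 1L]] <- cut[keep][ord]
  }
  tibble::new_tibble(list(
    enzyme = as.character(unlist(enz_v)),
    start = as.integer(unlist(start_v)),
    strand = as.character(unlist(strand_v)),
    cut = as.integer(unlist(cut_v))),
    nrow = length(unlist(start_v)))
}

#' Count restriction sites / test uniqueness
#'
#' @inheritParams find_sites
#' @return `count_sites()`: nonnegative integer per enzyme row (named by
#'   enzyme when more than one). `is_unique()`: logical, `TRUE` iff exactly
#'   one site.
#' @export
count_sites <- function(seq, enzymes, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  hits <- find_sites(seq, enzymes, topology)
  counts <- vapply(enzymes$name, function(nm) sum(hits$enzyme == nm), integer(1))
  if (length(counts) == 1L) unname(counts) else counts
}

#' @rdname count_sites
#' @export
is_unique <- function(seq, enzymes, topology = c("linear", "circular")) {
  count_sites(seq, enzymes, match.arg(topology)) == 1L
}

# fast path used pervasively by the engine: counts for a single enzyme row
count_one <- function(seq, recog, topology = "linear") {
  n <- nchar(seq)
  m <- nchar(recog)
  target <- if (topology == "circular" && m > 1L && n > 1L) {
    paste0(seq, substr(seq, 1L, min(m - 1L, n)))
  } else seq
  fwd <- scan_pattern(target, recog)
  fwd <- fwd[fwd < n]
  rc <- dna_revcomp(recog)
  if (identical(rc, recog)) return(length(fwd))
  rev <- scan_pattern(target, rc)
  rev <- rev[rev < n]
  length(unique(c(fwd, rev)))
}
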