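# Low-level sequence primitives shared by every module. Sequences are plain
# uppercase character scalars; all user-facing coordinates in the package are
# 0-based, half-open (coordinate 0 = first base of the 5' flank).

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

# complement table over the full IUPAC alphabet (R<->Y, K<->M, B<->V, D<->H)
IUPAC_FROM <- "ACGTRYSWKMBVDHN"
IUPAC_TO   <- "TGCAYRSWMKVBHDN"

# degeneracy expansion used to compile recognition patterns to regex classes
IUPAC_EXPAND <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of DNA sequences
#'
#' Vectorised Watson-Crick reverse complement. IUPAC ambiguity codes are
#' supported (needed for scanning degenerate enzyme recognition patterns on
#' the bottom strand); plain genomic sequences must be A/C/G/T only, which is
#' enforced upstream at ingest.
#'
#' @param x Character vector of DNA sequences (any case; uppercased first).
#' @return Character vector of reverse complements.
#' @examples
#' dna_revcomp("GGTCTC")  # "GAGACC"
#' dna_revcomp("GAATTC")  # palindromic: unchanged
#' @export
dna_revcomp <- function(x) {
  x <- toupper(x)
  bad <- grepl(paste0("[^", IUPAC_FROM, "]"), x)
  if (any(bad)) {
    stop("dna_revcomp(): sequence contains characters outside the IUPAC DNA alphabet: ",
         paste(unique(unlist(strsplit(gsub(paste0("[", IUPAC_FROM, "]"), "", x[bad]), ""))),
               collapse = ", "), call. = FALSE)
  }
  comp <- chartr(IUPAC_FROM, IUPAC_TO, x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# uppercase + strict ACGT check for genomic (locus/backbone) sequences
as_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single nonempty string", call. = FALSE)
  }
  x <- toupper(x)
  if (grepl("U", x, fixed = TRUE)) {
    stop(what, " contains 'U': RNA input is not accepted, supply DNA", call. = FALSE)
  }
  if (grepl("[^ACGT]", x)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", x), "")[[1]])
    stop(what, " may contain only A/C/G/T (ambiguity codes are allowed only in ",
         "enzyme recognition patterns); found: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

# 0-based half-open substring: subseq0(s, 2, 5) == bases 3..5 (1-based)
subseq0 <- function(s, start, end) {
  if (start > end) stop("subseq0(): start > end", call. = FALSE)
  if (start == end) return("")
  substr(s, start + 1L, end)
}

# split a coding sequence into codons (drops a trailing partial codon)
codons_of <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# positions (0-based, codon index) of in-frame stop codons
inframe_stops <- function(s) which(codons_of(s) %in% STOP_CODONS) - 1L

# round half away from zero to an integer base-pair count
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Annotated sequence container
#'
#' A light S3 wrapper around a DNA string plus a feature table, used for
#' assembled inserts and plasmids.
#'
#' @param seq DNA string (A/C/G/T).
#' @param features Tibble with columns `label`, `start`, `end` (0-based,
#'   half-open), `strand`.
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `annotated_seq`.
#' @export
annotated_seq <- function(seq, features = empty_features(), topology = "linear") {
  stopifnot(topology %in% c("linear", "circular"))
  n <- nchar(seq)
  if (nrow(features) > 0) {
    if (any(features$start < 0 | features$end > n | features$start >= features$end)) {
      stop("annotated_seq(): feature interval outside sequence bounds", call. = FALSE)
    }
    if (anyDuplicated(features$label)) {
      stop("annotated_seq(): duplicate feature label", call. = FALSE)
    }
  }
  structure(list(seq = seq, features = features, topology = topology),
            class = "annotated_seq")
}

empty_features <- function() {
  tibble::tibble(label = character(), start = integer(), end = integer(),
                 strand = character())
}

feature_row <- function(label, start, end, strand = "+") {
  tibble::tibble(label = label, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

# locate a named feature, returning list(start, end) or NULL
get_feature <- function(x, label) {
  f <- x$features[x$features$label == label, ]
  if (nrow(f) == 0) return(NULL)
  list(start = f$start[[1]], end = f$end[[1]], strand = f$strand[[1]])
}

#' @export
print.annotated_seq <- function(x, ...) {
  cat(sprintf("<annotated_seq> %s, %d bp, %d feature(s)\n",
              x$topology, nchar(x$seq), nrow(x$features)))
  if (nrow(x$features) > 0) print(x$features, n = nrow(x$features))
  invisible(x)
}
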