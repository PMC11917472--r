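# Gene-locus parsing and biological sanity validation. The input convention
# follows the standard per-gene download layout: flank_len bases of 5'
# flanking region, the ORF, then flank_len bases of 3' flanking region.

#' Partition a raw gene-of-interest sequence into flanks and ORF
#'
#' The raw sequence must be laid out as `flank_len` bp of 5' flanking region,
#' the ORF, and `flank_len` bp of 3' flanking region (1,000 bp flanks by
#' default, the layout served per gene by yeastgenome.org).
#'
#' @param raw DNA string (A/C/G/T, any case).
#' @param flank_len Flank length in bp on each side (default 1000).
#' @param name Gene name carried on the locus (default "GOI").
#' @return A `gene_locus` object with components `name`, `upstream`, `orf`,
#'   `downstream`, `flank_len`.
#' @examples
#' loc <- parse_goi(strrep("A", 25), flank_len = 10)
#' nchar(loc$orf)  # 5
#' @export
parse_goi <- function(raw, flank_len = 1000L, name = "GOI") {
  raw <- as_dna(raw, "GOI sequence")
  flank_len <- as.integer(flank_len)
  if (flank_len < 1L) stop("flank_len must be >= 1", call. = FALSE)
  n <- nchar(raw)
  if (n <= 2L * flank_len) {
    stop("GOI sequence too short (", n, " bp): need more than 2*flank_len = ",
         2L * flank_len, " bp (at least ", 2L * flank_len + 3L,
         " bp for a nonempty ORF)", call. = FALSE)
  }
  structure(
    list(name = name,
         upstream = subseq0(raw, 0L, flank_len),
         orf = subseq0(raw, flank_len, n - flank_len),
         downstream = subseq0(raw, n - flank_len, n),
         flank_len = flank_len),
    class = "gene_locus"
  )
}

#' Read a gene locus from a single-record FASTA file
#'
#' @param path FASTA path (exactly one record; the record id becomes the gene
#'   name).
#' @inheritParams parse_goi
#' @return A `gene_locus` object.
#' @export
read_goi <- function(path, flank_len = 1000L) {
  s <- read_fasta_seq(path)
  parse_goi(s[[1]], flank_len = flank_len, name = names(s)[[1]])
}

locus_seq <- function(locus) {
  paste0(locus$upstream, locus$orf, locus$downstream)
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s: %d bp 5'FR + %d bp ORF + %d bp 3'FR\n",
              x$name, nchar(x$upstream), nchar(x$orf), nchar(x$downstream)))
  invisible(x)
}

#' Biological sanity checks on a parsed locus
#'
#' Two classes of checks: (1) start codon, stop codon and frame of the ORF;
#' (2) user-supplied intervals of overlapping ORFs intersecting either flank.
#' Findings are warnings that alert the user; they never abort a design run.
#'
#' @param locus A `gene_locus`.
#' @param overlaps Optional list of 2-element integer vectors (or a 2-column
#'   matrix), each a 0-based half-open interval in locus coordinates marking
#'   a region occupied by another ORF.
#' @return Tibble of findings with columns `code`, `message`, `start`, `end`;
#'   zero rows means the locus is clean (see attribute `is_clean`).
#' @export
validate_locus <- function(locus, overlaps = NULL) {
  stopifnot(inherits(locus, "gene_locus"))
  F <- locus$flank_len
  L <- nchar(locus$orf)
  out <- empty_validation()

  if (substr(locus$orf, 1, 3) != "ATG") {
    out <- dplyr::bind_rows(out, finding(
      "START_CODON_MISSING",
      sprintf("ORF does not begin with ATG (found %s)", substr(locus$orf, 1, 3)),
      F, F + 3L))
  }
  if (L >= 3L && !(substr(locus$orf, L - 2L, L) %in% STOP_CODONS)) {
    out <- dplyr::bind_rows(out, finding(
      "STOP_CODON_MISSING",
      sprintf("ORF does not end with a stop codon (found %s)",
              substr(locus$orf, L - 2L, L)),
      F + L - 3L, F + L))
  }
  if (L %% 3L != 0L) {
    out <- dplyr::bind_rows(out, finding(
      "ORF_FRAME",
      sprintf("ORF length %d is not a multiple of 3", L), F, F + L))
  }

  if (!is.null(overlaps)) {
    if (is.matrix(overlaps)) overlaps <- asplit(overlaps, 1)
    total <- 2L * F + L
    for (iv in overlaps) {
      if (length(iv) != 2L || anyNA(iv) || iv[2] <= iv[1] ||
          iv[1] < 0 || iv[2] > total) {
        stop("malformed overlap interval [", paste(iv, collapse = ", "),
             "): need 0 <= start < end <= ", total, call. = FALSE)
      }
      hits_up <- iv[1] < F                       # intersects 5' flank
      hits_dn <- iv[2] > F + L                   # intersects 3' flank
      if (hits_up || hits_dn) {
        where <- paste(c(if (hits_up) "5' flank", if (hits_dn) "3' flank"),
                       collapse = " and ")
        out <- dplyr::bind_rows(out, finding(
          "ORF_OVERLAP",
          sprintf("overlapping ORF interval [%d, %d) intersects the %s",
                  iv[1], iv[2], where),
          as.integer(iv[1]), as.integer(iv[2])))
      }
    }
  }

  attr(out, "is_clean") <- nrow(out) == 0L
  out
}

empty_validation <- function() {
  tibble::tibble(code = character(), message = character(),
                 start = integer(), end = integer())
}

finding <- function(code, message, start, end) {
  tibble::tibble(code = code, message = message,
                 start = as.integer(start), end = as.integer(end))
}

#' @rdname validate_locus
#' @param report A validation report tibble from [validate_locus()].
#' @export
is_clean <- function(report) isTRUE(attr(report, "is_clean")) || nrow(report) == 0L
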