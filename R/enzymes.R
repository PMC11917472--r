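# Restriction-enzyme list handling. The plain-text format is one enzyme per
# line, "Name<whitespace>RECOG^NITION", where the caret marks the top-strand
# cut position inside the recognition pattern ("G^AATTC"). File order is
# meaningful: it is the user's preference order and the tie-break order used
# throughout the design engine.

#' Parse a restriction-enzyme list
#'
#' @param text Character vector of lines, or a single string with embedded
#'   newlines. Lines starting with `#` are comments; blank lines are skipped.
#' @return Tibble with columns `name`, `recognition` (caret removed, IUPAC
#'   codes allowed), `cut_offset` (0-based position of the caret). Enzymes
#'   without a caret get `cut_offset = floor(len/2)` with a notice.
#' @examples
#' parse_enzyme_list("EcoRI G^AATTC")
#' @export
parse_enzyme_list <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("enzyme list is empty", call. = FALSE)

  rows <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2L) {
      stop("malformed enzyme line (need 'Name PATTERN'): '", ln, "'", call. = FALSE)
    }
    name <- parts[[1]]
    pat <- toupper(parts[[2]])
    ncaret <- lengths(regmatches(pat, gregexpr("^", pat, fixed = TRUE)))
    if (ncaret > 1L) {
      stop("enzyme ", name, ": recognition pattern has ", ncaret,
           " carets, at most one is allowed", call. = FALSE)
    }
    if (ncaret == 1L) {
      cut_offset <- as.integer(regexpr("^", pat, fixed = TRUE)) - 1L
      recog <- sub("^", "", pat, fixed = TRUE)
    } else {
      recog <- pat
      cut_offset <- nchar(recog) %/% 2L
      rlang::inform(paste0("enzyme ", name, ": no caret in pattern; assuming ",
                           "a central cut at offset ", cut_offset))
    }
    if (grepl(paste0("[^", IUPAC_FROM, "]"), recog)) {
      stop("enzyme ", name, ": illegal character in recognition pattern '",
           recog, "'", call. = FALSE)
    }
    if (nchar(recog) < 4L) {
      stop("enzyme ", name, ": recognition pattern must be at least 4 bp",
           call. = FALSE)
    }
    tibble::tibble(name = name, recognition = recog,
                   cut_offset = as.integer(cut_offset))
  })
  enz <- dplyr::bind_rows(rows)
  dup <- enz$name[duplicated(enz$name)]
  if (length(dup) > 0L) {
    stop("duplicate enzyme name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  enz
}

#' Read a restriction-enzyme list file
#'
#' @param path Path to a plain-text enzyme list (see [parse_enzyme_list()]).
#' @return Tibble of enzymes in file order.
#' @export
read_enzymes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_enzyme_list(readLines(path, warn = FALSE))
}

#' Suggested restriction-enzyme list
#'
#' A curated list of common unambiguous 6-cutters suitable both for
#' linearization-site search and for tag-flanking sites, shipped with the
#' package (`inst/extdata/enzymes_suggested.txt`). Customize freely; order is
#' preference order.
#'
#' @return Tibble of enzymes.
#' @export
suggested_enzymes <- function() {
  read_enzymes(system.file("extdata", "enzymes_suggested.txt",
                           package = "pipodesign", mustWork = TRUE))
}

# subset usable for tag-flanking sites: exactly 6 bp, no degenerate codes
tag_flank_subset <- function(enzymes) {
  ok <- nchar(enzymes$recognition) == 6L &
    !grepl("[^ACGT]", enzymes$recognition)
  enzymes[ok, , drop = FALSE]
}
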