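# Deterministic synthetic-fixture generator: loci, backbones and tag genes
# with planted, controlled restriction-site geometry on a scrubbed random
# background, so every operation and invariant is testable offline. Background
# GC is ~0.40 to resemble yeast intergenic sequence (cosmetic only); ORF and
# tag-gene backgrounds are drawn codon-wise from the 61 sense codons so the
# reading frame is stop-free by construction and stays so under scrubbing.

BASES <- c("A", "C", "G", "T")
BASE_PROBS <- c(0.30, 0.20, 0.20, 0.30)    # GC ~ 0.40

ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

# run `expr` under a locally seeded RNG without disturbing the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

random_bases <- function(n) sample(BASES, n, replace = TRUE, prob = BASE_PROBS)

#' Specification of a synthetic gene-locus fixture
#'
#' @param seed Integer RNG seed; identical specs generate identical loci.
#' @param orf_len ORF length in bp (multiple of 3, >= 6; includes start and
#'   stop codons).
#' @param flank_len Flank length in bp.
#' @param plants Tibble with columns `enzyme`, `region` (`FR5`/`ORF`/`FR3`)
#'   and `offset`: the desired region-local cut coordinate measured from the
#'   region's reference edge (FR3 and ORF: distance from the left/5' edge;
#'   FR5: distance from its right, ORF-facing edge, i.e. the junction
#'   distance).
#' @param forbidden Enzyme tibble whose sites are scrubbed from the whole
#'   locus outside the planted windows. Plant enzymes are always scrubbed
#'   elsewhere so each planted site is unique in its region.
#' @param enzymes Enzyme tibble resolving the names in `plants`.
#' @param name Gene name.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, orf_len = 300L, flank_len = 1000L,
                         plants = NULL, forbidden = NULL, enzymes = NULL,
                         name = "SYNGENE") {
  orf_len <- as.integer(orf_len)
  if (orf_len < 6L || orf_len %% 3L != 0L) {
    stop("orf_len must be a multiple of 3 and at least 6", call. = FALSE)
  }
  if (is.null(plants)) {
    plants <- tibble::tibble(enzyme = character(), region = character(),
                             offset = integer())
  }
  structure(list(seed = as.integer(seed), orf_len = orf_len,
                 flank_len = as.integer(flank_len), plants = plants,
                 forbidden = forbidden, enzymes = enzymes, name = name),
            class = "fixture_spec")
}

#' Generate a synthetic gene locus with planted restriction sites
#'
#' @param spec A [fixture_spec()].
#' @return A `gene_locus` whose planted sites are unique in their regions and
#'   whose background is free of all forbidden enzymes' sites; the ORF starts
#'   with ATG, ends with TAA, and is free of internal in-frame stops.
#' @export
make_goi <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  F <- spec$flank_len
  L <- spec$orf_len
  total <- 2L * F + L
  enzymes <- spec$enzymes
  plants <- spec$plants
  if (nrow(plants) > 0 && is.null(enzymes)) {
    stop("fixture_spec with plants needs an enzyme table", call. = FALSE)
  }

  with_local_seed(spec$seed, {
    v <- c(random_bases(F),
           unlist(strsplit(c("ATG", sample(SENSE_CODONS, (L - 6L) / 3L,
                                           replace = TRUE), "TAA"), "")),
           random_bases(F))
    locked <- rep(FALSE, total)
    locked[(F + 1L):(F + 3L)] <- TRUE              # ATG
    locked[(F + L - 2L):(F + L)] <- TRUE           # stop

    # plant requested sites (site_start chosen so the cut lands at offset)
    for (i in seq_len(nrow(plants))) {
      e <- enzymes[enzymes$name == plants$enzyme[[i]], , drop = FALSE]
      if (nrow(e) != 1L) {
        stop("plant enzyme not in enzyme table: ", plants$enzyme[[i]],
             call. = FALSE)
      }
      m <- nchar(e$recognition)
      reg <- plants$region[[i]]
      off <- plants$offset[[i]]
      cut_local <- switch(reg, FR5 = F - off, ORF = off, FR3 = off,
                          stop("unknown plant region ", reg, call. = FALSE))
      reg_start <- switch(reg, FR5 = 0L, ORF = F, FR3 = F + L)
      reg_len <- switch(reg, FR5 = F, ORF = L, FR3 = F)
      site_local <- cut_local - e$cut_offset
      if (site_local < 0L || site_local + m > reg_len) {
        stop("infeasible plant: ", plants$enzyme[[i]], " at ", reg, " offset ",
             off, " (site would leave the region)", call. = FALSE)
      }
      idx <- reg_start + site_local + seq_len(m)
      if (any(locked[idx])) {
        stop("infeasible plant: overlaps a locked window", call. = FALSE)
      }
      v[idx] <- strsplit(e$recognition, "")[[1]]
      locked[idx] <- TRUE
    }

    scrub_list <- unique(dplyr::bind_rows(
      spec$forbidden,
      if (nrow(plants) > 0) enzymes[enzymes$name %in% plants$enzyme, ]))
    orf_range <- c(F, F + L)   # 0-based half-open, for codon-aware repair
    v <- scrub_sequence(v, locked, scrub_list, orf_range = orf_range,
                        topology = "linear")

    raw <- paste(v, collapse = "")
    structure(list(name = spec$name,
                   upstream = subseq0(raw, 0L, F),
                   orf = subseq0(raw, F, F + L),
                   downstream = subseq0(raw, F + L, total),
                   flank_len = F),
              class = "gene_locus")
  })
}

# Re-roll unlocked bases until no scrub-list site survives outside locked
# windows and (when orf_range is given) the ORF has no internal in-frame
# stop. Deterministic given the RNG state; errors if it cannot converge.
scrub_sequence <- function(v, locked, scrub, orf_range = NULL,
                           topology = "linear", stop_trim = 3L) {
  n <- length(v)
  for (iter in seq_len(400L)) {
    s <- paste(v, collapse = "")
    dirty <- integer(0)
    if (!is.null(scrub) && nrow(scrub) > 0) {
      hits <- find_sites(s, scrub, topology)
      if (nrow(hits) > 0) {
        m_by <- nchar(scrub$recognition)[match(hits$enzyme, scrub$name)]
        for (h in seq_len(nrow(hits))) {
          idx <- (hits$start[[h]] + seq_len(m_by[[h]]) - 1L) %% n + 1L
          if (!all(locked[idx])) dirty <- c(dirty, idx[!locked[idx]])
        }
      }
    }
    if (!is.null(orf_range)) {
      orf <- paste(v[(orf_range[1] + 1L):orf_range[2]], collapse = "")
      core <- substr(orf, 1L, nchar(orf) - stop_trim)
      for (ci in inframe_stops(core)) {
        idx <- orf_range[1] + 3L * ci + 1:3
        if (all(locked[idx])) {
          stop("fixture infeasible: a planted window forces an in-frame stop",
               call. = FALSE)
        }
        dirty <- c(dirty, idx[!locked[idx]])
      }
    }
    if (length(dirty) == 0L) return(v)
    dirty <- unique(dirty)
    v[dirty] <- random_bases(length(dirty))
  }
  stop("fixture generation did not converge while scrubbing sites",
       call. = FALSE)
}

#' Generate a synthetic circular backbone with a planted MCS
#'
#' @param seed Integer RNG seed.
#' @param enzymes Enzyme tibble; all of these are scrubbed from the backbone
#'   background (circular scan) except the planted MCS sites.
#' @param mcs_enzymes Character vector of enzyme names planted, in order, as
#'   unique sites inside the MCS.
#' @param length Backbone length in bp before planting.
#' @param marker_len Length of the inert placeholder block annotated as the
#'   selection/counterselection marker (marker identity never enters the
#'   design arithmetic).
#' @return A [backbone()] object with a `MARKER` feature and planted MCS.
#' @export
make_backbone <- function(seed, enzymes, mcs_enzymes, length = 3000L,
                          marker_len = 400L) {
  length <- as.integer(length)
  rows <- enzymes[match(mcs_enzymes, enzymes$name), , drop = FALSE]
  if (anyNA(rows$name)) stop("mcs_enzymes not all present in enzyme table",
                             call. = FALSE)
  spacer <- 4L
  mcs_need <- sum(nchar(rows$recognition)) + spacer * (nrow(rows) - 1L)
  mcs0 <- as.integer(floor(length * 0.6))
  if (mcs0 + mcs_need + 10L > length || marker_len + 150L > mcs0) {
    stop("backbone too short for the requested MCS/marker layout", call. = FALSE)
  }
  with_local_seed(seed, {
    v <- random_bases(length)
    locked <- rep(FALSE, length)
    pos <- mcs0
    for (i in seq_len(nrow(rows))) {
      m <- nchar(rows$recognition[[i]])
      idx <- pos + seq_len(m)
      v[idx] <- strsplit(rows$recognition[[i]], "")[[1]]
      locked[idx] <- TRUE
      pos <- pos + m + spacer
    }
    mcs_end <- pos - spacer
    v <- scrub_sequence(v, locked, enzymes, topology = "circular")
    backbone(paste(v, collapse = ""),
             mcs = c(mcs0 - 5L, min(mcs_end + 5L, length)),
             features = feature_row("MARKER", 100L, 100L + marker_len),
             name = sprintf("synthetic_backbone_seed%d", seed))
  })
}

#' Generate a synthetic tag (fluorescent-protein) gene
#'
#' Codon-wise random open reading frame starting with ATG, free of internal
#' in-frame stops and of all given enzymes' sites; no terminal stop codon
#' (the design engine adds or strips one per task).
#'
#' @param seed Integer RNG seed.
#' @param enzymes Enzyme tibble to scrub from the gene.
#' @param n_codons Number of codons including the start (default 80).
#' @return DNA string.
#' @export
make_fpg <- function(seed, enzymes, n_codons = 80L) {
  n_codons <- as.integer(n_codons)
  stopifnot(n_codons >= 2L)
  with_local_seed(seed, {
    v <- unlist(strsplit(c("ATG", sample(SENSE_CODONS, n_codons - 1L,
                                         replace = TRUE)), ""))
    locked <- rep(FALSE, length(v))
    locked[1:3] <- TRUE
    v <- scrub_sequence(v, locked, enzymes, orf_range = c(0L, length(v)),
                        topology = "linear", stop_trim = 0L)
    paste(v, collapse = "")
  })
}
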