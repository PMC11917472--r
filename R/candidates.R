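# Candidate linearization cut sites. For each edit task two locus regions are
# involved; the region hosting the cut supplies the pop-in homology, the other
# supplies the pop-out homology, and both role assignments are enumerated.

REGIONS <- c("FR5", "ORF", "FR3")

#' Region role assignments for an edit task
#'
#' @param task One of `"delete"`, `"tag_n"`, `"tag_c"`.
#' @return Tibble with columns `pop_in` and `pop_out`; both role assignments
#'   are returned, the depicted/default assignment first (cut in the 3' flank
#'   for deletion and C-tagging, cut in the 5' flank for N-tagging).
#' @export
eligible_region_pairs <- function(task) {
  task <- check_task(task)
  switch(task,
    delete = tibble::tibble(pop_in = c("FR3", "FR5"), pop_out = c("FR5", "FR3")),
    tag_n  = tibble::tibble(pop_in = c("FR5", "ORF"), pop_out = c("ORF", "FR5")),
    tag_c  = tibble::tibble(pop_in = c("FR3", "ORF"), pop_out = c("ORF", "FR3"))
  )
}

# the usable stretch of a region for a given task, as a string, plus the side
# of the junction it faces. For the ORF under tag_c the usable interval ends
# at the stop-codon boundary: the native stop is removed from the insert, so
# neither a cut site nor homology beyond that boundary would survive.
region_info <- function(locus, region, task) {
  L <- nchar(locus$orf)
  if (region == "FR5") {
    list(seq = locus$upstream, junction = "right", genomic_offset = 0L)
  } else if (region == "FR3") {
    list(seq = locus$downstream, junction = "left",
         genomic_offset = locus$flank_len + L)
  } else if (region == "ORF") {
    core <- orf_core(locus)
    if (task == "tag_c") {
      list(seq = core, junction = "right", genomic_offset = locus$flank_len)
    } else if (task == "tag_n") {
      list(seq = locus$orf, junction = "left", genomic_offset = locus$flank_len)
    } else {
      stop("ORF is not an eligible region for task '", task, "'", call. = FALSE)
    }
  } else {
    stop("unknown region '", region, "'", call. = FALSE)
  }
}

# the ORF with its native stop codon trimmed (only when it actually ends in
# one; anomalous ORFs already draw a validation warning)
orf_core <- function(locus) {
  L <- nchar(locus$orf)
  if (L >= 3L && substr(locus$orf, L - 2L, L) %in% STOP_CODONS) {
    substr(locus$orf, 1L, L - 3L)
  } else {
    locus$orf
  }
}

#' Enumerate candidate linearization cut sites
#'
#' For each eligible pop-in region and each enzyme, every recognition-site hit
#' lying wholly inside the region's usable interval becomes a candidate.
#' Inadmissibility is data, not an error: candidates failing a constraint are
#' flagged with a coded reason.
#'
#' @param locus A `gene_locus`.
#' @param task Edit task.
#' @param params A `pipo_params` object.
#' @return Tibble with one row per candidate: `pop_in_region`,
#'   `pop_out_region`, `enzyme`, `strand`, `site_start` (region-local,
#'   0-based), `cut_pos` (region-local top-strand cut coordinate),
#'   `d_junction`, `d_distal`, `admissible`, `reason`. `d_junction` is the
#'   distance from the cut to the region edge facing the insert junction;
#'   `d_junction + d_distal` equals the usable region length.
#' @export
enumerate_candidates <- function(locus, task, params) {
  task <- check_task(task)
  stopifnot(inherits(locus, "gene_locus"), inherits(params, "pipo_params"))
  mh <- params$min_homology
  pairs <- eligible_region_pairs(task)

  rows <- list()
  for (p in seq_len(nrow(pairs))) {
    reg <- pairs$pop_in[[p]]
    info <- region_info(locus, reg, task)
    rlen <- nchar(info$seq)
    hits <- find_sites(info$seq, params$enzymes, "linear")
    if (nrow(hits) == 0L) next
    n_by_enzyme <- table(hits$enzyme)
    cut <- hits$cut
    dj <- if (info$junction == "right") rlen - cut else cut
    dd <- rlen - dj
    reason <- rep(NA_character_, nrow(hits))
    reason[dd < mh] <- "MIN_HOMOLOGY_DISTAL"
    reason[dj < mh] <- "MIN_HOMOLOGY_JUNCTION"
    reason[as.integer(n_by_enzyme[hits$enzyme]) != 1L] <- "NOT_UNIQUE_IN_REGION"
    # preserve enzyme file order, then position
    ord <- order(match(hits$enzyme, params$enzymes$name), hits$start)
    rows[[length(rows) + 1L]] <- tibble::new_tibble(list(
      pop_in_region = rep(reg, nrow(hits)),
      pop_out_region = rep(pairs$pop_out[[p]], nrow(hits)),
      enzyme = hits$enzyme[ord], strand = hits$strand[ord],
      site_start = hits$start[ord], cut_pos = cut[ord],
      d_junction = as.integer(dj[ord]), d_distal = as.integer(dd[ord]),
      admissible = is.na(reason[ord]), reason = reason[ord]),
      nrow = nrow(hits))
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      pop_in_region = character(), pop_out_region = character(),
      enzyme = character(), strand = character(), site_start = integer(),
      cut_pos = integer(), d_junction = integer(), d_distal = integer(),
      admissible = logical(), reason = character()))
  }
  dplyr::bind_rows(rows)
}
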