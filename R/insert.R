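# Insert assembly for the three edit geometries, the in-frame stop-codon
# check for tag-flanking sites, and the greedy tag-flank enzyme selection.
#
# Layouts (genomic 5'->3' order; each 6 bp site contributes 2 codons, the
# linker and tag gene are multiples of 3, so the fusion reading frame from
# fusion start to fusion stop is preserved):
#   delete: [5'FR part][3'FR part]
#   tag_c : [ORF part, native stop removed][S1][linker][S2][FPG, stop ensured][S3][3'FR part]
#   tag_n : [5'FR part][S1][FPG, start ensured / stop stripped][S2][linker][S3][ORF part from native ATG]
# In tag_n, S1 lies 5' of the fusion start codon (untranslated); in tag_c, S3
# lies 3' of the fusion stop. Both are exempt from the stop-codon check.

#' Check that a tag-flanking site introduces no in-frame stop codon
#'
#' @param site The candidate 6 bp recognition sequence.
#' @param frame_offset Position of the site's first base within its codon
#'   (0, 1 or 2). At offset 0 the site contributes exactly 2 codons.
#' @param left,right Fixed neighboring bases (context) used to evaluate
#'   codons straddling the site boundary at nonzero offsets. Codons that
#'   cannot be completed from the given context are not checked.
#' @return `TRUE` iff no codon overlapping the site, read in the fusion
#'   frame, is TAA/TAG/TGA.
#' @examples
#' check_no_stop_inframe("GGATCC")  # GGA, TCC -> TRUE
#' check_no_stop_inframe("TAATGA")  # TAA -> FALSE
#' @export
check_no_stop_inframe <- function(site, frame_offset = 0L, left = "", right = "") {
  if (nchar(site) != 6L) {
    stop("check_no_stop_inframe(): site must be exactly 6 bp, got ",
         nchar(site), call. = FALSE)
  }
  f <- as.integer(frame_offset) %% 3L
  full <- paste0(left, site, right)
  nl <- nchar(left)
  nf <- nchar(full)
  s0 <- (nl - f) %% 3L                        # first codon start in frame
  if (s0 > nf - 3L) return(TRUE)
  starts <- seq.int(s0, nf - 3L, by = 3L)
  starts <- starts[starts < nl + 6L & starts + 3L > nl]   # overlap the site
  if (length(starts) == 0L) return(TRUE)
  cods <- substring(full, starts + 1L, starts + 3L)
  !any(cods %in% STOP_CODONS)
}

# Per-slot constraints for the three tag-flanking sites of a tagging task:
# whether the stop-codon check applies, the site's frame offset in the edited
# locus, and the fixed context on either side. Uses the full genomic ORF (not
# the arm) because the reading frame of the edited locus is what matters.
tag_slot_specs <- function(locus, task, params) {
  lk <- params$linker
  last2 <- function(s) substr(s, max(1L, nchar(s) - 1L), nchar(s))
  first2 <- function(s) substr(s, 1L, min(2L, nchar(s)))
  if (task == "tag_c") {
    core <- orf_core(locus)
    fpg <- normalize_fpg(params$fpg, task)
    f1 <- nchar(core) %% 3L
    f2 <- (nchar(core) + 6L + nchar(lk)) %% 3L
    list(
      list(checked = TRUE, frame = f1, left = last2(core), right = first2(lk)),
      list(checked = TRUE, frame = f2, left = last2(lk), right = first2(fpg)),
      list(checked = FALSE, frame = 0L, left = "", right = "")   # after fusion stop
    )
  } else if (task == "tag_n") {
    fpg <- normalize_fpg(params$fpg, task)
    f2 <- nchar(fpg) %% 3L
    f3 <- (nchar(fpg) + 6L + nchar(lk)) %% 3L
    list(
      list(checked = FALSE, frame = 0L, left = "", right = ""),  # 5' of fusion start
      list(checked = TRUE, frame = f2, left = last2(fpg), right = first2(lk)),
      list(checked = TRUE, frame = f3, left = last2(lk), right = first2(locus$orf))
    )
  } else {
    stop("tag_slot_specs(): no tag sites for task '", task, "'", call. = FALSE)
  }
}

#' Greedy selection of the three tag-flanking enzymes
#'
#' Assigns distinct enzymes, in file (preference) order, to the three
#' tag-flanking site slots so that each inserted 6 bp site introduces no
#' in-frame stop codon where translated, is absent from the vector backbone
#' and from the draft insert, and is not the linearization enzyme. Uniqueness
#' on the final assembled circular plasmid is re-verified after assembly.
#'
#' @param draft_parts Character vector of the insert parts without tag sites
#'   (arms, linker, tag gene).
#' @param backbone_seq Circular backbone sequence.
#' @param params A `pipo_params` object.
#' @param linearization_enzyme Name of the candidate's linearization enzyme.
#' @param slots Slot constraint list from the design engine (internal).
#' @param bb_counts Optional precomputed named vector of backbone site counts
#'   per tag enzyme (performance; computed when absent).
#' @param exclude Enzyme names never to consider (used by the design engine to
#'   retry after a junction-created duplicate of an assigned site).
#' @return Character vector of 3 enzyme names, or `NULL` if no assignment
#'   exists (rejection reason `TAG_SITES_UNAVAILABLE`).
#' @export
select_tag_flank_enzymes <- function(draft_parts, backbone_seq, params,
                                     linearization_enzyme, slots,
                                     bb_counts = NULL, exclude = character(0)) {
  tags <- params$tag_flank_enzymes
  tags <- tags[!tags$name %in% exclude, , drop = FALSE]
  if (nrow(tags) == 0L) return(NULL)
  if (is.null(bb_counts)) {
    bb_counts <- vapply(tags$recognition,
                        function(r) count_one(backbone_seq, r, "circular"),
                        integer(1))
    names(bb_counts) <- tags$name
  }
  draft <- paste(draft_parts, collapse = "")
  chosen <- character(0)
  for (slot in slots) {
    found <- NA_character_
    for (i in seq_len(nrow(tags))) {
      nm <- tags$name[[i]]
      if (nm %in% chosen || identical(nm, linearization_enzyme)) next
      site <- tags$recognition[[i]]
      if (slot$checked &&
          !check_no_stop_inframe(site, slot$frame, slot$left, slot$right)) next
      if (bb_counts[[nm]] > 0L) next
      if (count_one(draft, site, "linear") > 0L) next
      found <- nm
      break
    }
    if (is.na(found)) return(NULL)
    chosen <- c(chosen, found)
  }
  chosen
}

#' Assemble the synthesizable insert for a cut candidate
#'
#' @param locus A `gene_locus`.
#' @param task Edit task.
#' @param arms Arm list from [build_arms()].
#' @param cand The candidate row the arms were built for.
#' @param params A `pipo_params` object.
#' @param tag_sites For tagging tasks, character vector of 3 enzyme names
#'   (slots 1-3) from [select_tag_flank_enzymes()]; ignored for deletions.
#' @return An [annotated_seq] (linear) with features `POP_IN_ARM`,
#'   `POP_OUT_ARM`, `LINEARIZATION_SITE` and, for tagging, `LINKER`, `FPG`,
#'   `TAG_SITE_1..3`; attribute `cut_in_insert` holds the linearization cut
#'   coordinate within the insert.
#' @export
assemble_insert <- function(locus, task, arms, cand, params, tag_sites = NULL) {
  task <- check_task(task)
  check_task_params(task, params)
  part_for <- function(region) {
    if (region == cand$pop_in_region) arms$pop_in else arms$pop_out
  }
  arm_label <- function(region) {
    if (region == cand$pop_in_region) "POP_IN_ARM" else "POP_OUT_ARM"
  }
  site_seq <- function(nm) {
    tags <- params$tag_flank_enzymes
    tags$recognition[[match(nm, tags$name)]]
  }

  pieces <- if (task == "delete") {
    list(list(part_for("FR5"), arm_label("FR5")),
         list(part_for("FR3"), arm_label("FR3")))
  } else if (task == "tag_c") {
    stopifnot(length(tag_sites) == 3L)
    list(list(part_for("ORF"), arm_label("ORF")),
         list(site_seq(tag_sites[[1]]), "TAG_SITE_1"),
         list(params$linker, "LINKER"),
         list(site_seq(tag_sites[[2]]), "TAG_SITE_2"),
         list(normalize_fpg(params$fpg, task), "FPG"),
         list(site_seq(tag_sites[[3]]), "TAG_SITE_3"),
         list(part_for("FR3"), arm_label("FR3")))
  } else {
    stopifnot(length(tag_sites) == 3L)
    list(list(part_for("FR5"), arm_label("FR5")),
         list(site_seq(tag_sites[[1]]), "TAG_SITE_1"),
         list(normalize_fpg(params$fpg, task), "FPG"),
         list(site_seq(tag_sites[[2]]), "TAG_SITE_2"),
         list(params$linker, "LINKER"),
         list(site_seq(tag_sites[[3]]), "TAG_SITE_3"),
         list(part_for("ORF"), arm_label("ORF")))
  }

  seqs <- vapply(pieces, `[[`, character(1), 1)
  labels <- vapply(pieces, `[[`, character(1), 2)
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs)
  feats <- tibble::tibble(label = labels, start = as.integer(starts),
                          end = as.integer(ends), strand = "+")

  # linearization site and cut, in insert coordinates
  pin_idx <- which(labels == "POP_IN_ARM")
  pin_off <- starts[[pin_idx]]
  enz_row <- params$enzymes[params$enzymes$name == cand$enzyme, , drop = FALSE]
  feats <- dplyr::bind_rows(feats, feature_row(
    "LINEARIZATION_SITE",
    pin_off + arms$arm_site_offset,
    pin_off + arms$arm_site_offset + nchar(enz_row$recognition[[1]]),
    cand$strand))

  out <- annotated_seq(paste(seqs, collapse = ""), feats, "linear")
  attr(out, "cut_in_insert") <- as.integer(pin_off + arms$arm_cut_offset)
  out
}
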