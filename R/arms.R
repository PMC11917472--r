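# Homology-arm sizing. The pop-in arm runs from the insert junction through
# the cut site plus exactly min_homology bp beyond it, so that both sides of
# the cut carry at least min_homology of genomic identity. The pop-out arm is
# taken flush against the junction of the pop-out region, extending away from
# it, at the target length round(r_homo * pop_in_len); when the region holds
# fewer bases the whole usable region is taken and the arm is flagged
# truncated.

#' Build homology arms for an admissible cut candidate
#'
#' @param locus A `gene_locus`.
#' @param task Edit task.
#' @param cand One candidate row from [enumerate_candidates()] (a one-row
#'   data frame or a named list).
#' @param params A `pipo_params` object.
#' @return List with components `pop_in`, `pop_out` (sequences), `pop_in_len`,
#'   `pop_out_len`, `achieved_ratio`, `truncated`, and bookkeeping fields
#'   `arm_cut_offset` (cut position within the pop-in arm) and
#'   `arm_site_offset` (recognition-site start within the pop-in arm).
#' @export
build_arms <- function(locus, task, cand, params) {
  task <- check_task(task)
  if (!isTRUE(cand$admissible)) {
    stop("build_arms(): candidate is inadmissible (", cand$reason, ")",
         call. = FALSE)
  }
  mh <- params$min_homology
  dj <- cand$d_junction

  pin_info <- region_info(locus, cand$pop_in_region, task)
  pin_len <- dj + mh
  rlen <- nchar(pin_info$seq)
  if (pin_info$junction == "left") {
    # arm covers region-local [0, dj + mh)
    pop_in <- subseq0(pin_info$seq, 0L, pin_len)
    arm_cut_offset <- dj
    arm_site_offset <- cand$site_start
  } else {
    # arm covers region-local [rlen - dj - mh, rlen)
    pop_in <- subseq0(pin_info$seq, rlen - pin_len, rlen)
    arm_cut_offset <- mh
    arm_site_offset <- cand$site_start - (rlen - pin_len)
  }

  pout_info <- region_info(locus, cand$pop_out_region, task)
  avail <- nchar(pout_info$seq)
  target <- as.integer(round_half_away(params$r_homo * pin_len))
  pout_len <- min(target, avail)
  truncated <- target > avail
  pop_out <- if (pout_info$junction == "left") {
    subseq0(pout_info$seq, 0L, pout_len)
  } else {
    subseq0(pout_info$seq, avail - pout_len, avail)
  }

  list(pop_in = pop_in, pop_out = pop_out,
       pop_in_len = as.integer(pin_len), pop_out_len = as.integer(pout_len),
       achieved_ratio = pout_len / pin_len, truncated = truncated,
       arm_cut_offset = as.integer(arm_cut_offset),
       arm_site_offset = as.integer(arm_site_offset),
       warnings = if (truncated) "POP_OUT_TRUNCATED" else character(0))
}
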