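# Design parameters. Defaults follow the tool's standard operating point:
# 70 bp minimum homology on each side of the linearization cut, pop-out to
# pop-in homology ratio r_homo = 2 (ratios >= 2 empirically bias the pop-out
# step toward the intended edit), 1,000 bp flanks.

#' Design parameters for PIPO plasmid design
#'
#' @param enzymes Tibble of candidate linearization/subcloning enzymes in
#'   preference order (see [parse_enzyme_list()]).
#' @param min_homology Minimum homology in bp required on each side of the
#'   linearization cut site (default 70).
#' @param r_homo Target ratio of pop-out to pop-in homology length
#'   (default 2; dimensionless, > 0).
#' @param flank_len Length in bp of each flanking region in the locus input
#'   (default 1000).
#' @param linker In-frame linker DNA for tagging tasks (length a multiple of
#'   3). Default: a (Gly-Gly-Ser)x2 linker.
#' @param fpg Fluorescent-protein-gene (tag) DNA for tagging tasks; `NULL`
#'   for deletions.
#' @param tag_flank_enzymes Tibble of enzymes eligible for the three
#'   tag-flanking sites; restricted to unambiguous 6 bp recognition patterns
#'   (rows violating this are dropped with a notice). Defaults to the 6 bp
#'   subset of `enzymes`.
#' @return A list of class `pipo_params`.
#' @export
design_params <- function(enzymes,
                          min_homology = 70L,
                          r_homo = 2,
                          flank_len = 1000L,
                          linker = "GGTGGTTCTGGTGGTTCT",
                          fpg = NULL,
                          tag_flank_enzymes = NULL) {
  stopifnot(is.data.frame(enzymes), nrow(enzymes) >= 1L)
  min_homology <- as.integer(min_homology)
  if (min_homology < 1L) stop("min_homology must be >= 1", call. = FALSE)
  if (!is.numeric(r_homo) || r_homo <= 0) stop("r_homo must be > 0", call. = FALSE)
  flank_len <- as.integer(flank_len)
  if (!is.null(linker)) linker <- as_dna(linker, "linker")
  if (!is.null(fpg)) {
    fpg <- as_dna(fpg, "fpg")
  }
  if (is.null(tag_flank_enzymes)) tag_flank_enzymes <- enzymes
  keep <- tag_flank_subset(tag_flank_enzymes)
  if (nrow(keep) < nrow(tag_flank_enzymes)) {
    rlang::inform(paste0(nrow(tag_flank_enzymes) - nrow(keep), " enzyme(s) ",
                         "dropped from the tag-flanking list (recognition must ",
                         "be an unambiguous 6 bp pattern)"))
  }
  structure(list(min_homology = min_homology, r_homo = r_homo,
                 flank_len = flank_len, linker = linker, fpg = fpg,
                 enzymes = enzymes, tag_flank_enzymes = keep),
            class = "pipo_params")
}

EDIT_TASKS <- c("delete", "tag_n", "tag_c")

check_task <- function(task) {
  task <- match.arg(task, EDIT_TASKS)
  task
}

# validations that depend on the task
check_task_params <- function(task, params) {
  if (task %in% c("tag_n", "tag_c")) {
    if (is.null(params$fpg)) {
      stop("task '", task, "' requires a fluorescent-protein-gene sequence (fpg)",
           call. = FALSE)
    }
    if (is.null(params$linker)) {
      stop("task '", task, "' requires a linker sequence", call. = FALSE)
    }
    if (nchar(params$linker) %% 3L != 0L) {
      stop("linker length (", nchar(params$linker),
           ") must be a multiple of 3 for tagging tasks", call. = FALSE)
    }
    if (nchar(normalize_fpg(params$fpg, task)) %% 3L != 0L) {
      stop("fpg length must be a multiple of 3 (after start/stop ",
           "normalization) to preserve the fusion reading frame", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# task-dependent start/stop normalization of the tag gene:
#  tag_c: fusion stop lives at the FPG end -> ensure a terminal stop (append
#         TAA when absent)
#  tag_n: FPG is the fusion N-terminus -> ensure a leading ATG, strip a
#         terminal stop if present
normalize_fpg <- function(fpg, task) {
  n <- nchar(fpg)
  if (task == "tag_c") {
    if (n < 3L || !(substr(fpg, n - 2L, n) %in% STOP_CODONS)) {
      fpg <- paste0(fpg, "TAA")
    }
    fpg
  } else if (task == "tag_n") {
    if (n >= 3L && substr(fpg, n - 2L, n) %in% STOP_CODONS) {
      fpg <- substr(fpg, 1L, n - 3L)
    }
    if (substr(fpg, 1L, 3L) != "ATG") fpg <- paste0("ATG", fpg)
    fpg
  } else {
    stop("normalize_fpg(): no tag gene for task '", task, "'", call. = FALSE)
  }
}
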