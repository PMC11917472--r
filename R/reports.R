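# Report writers and the file-based single-design driver the CLI wraps.
# Outputs are deterministic: identical inputs produce byte-identical files.

#' Write design reports and output sequences
#'
#' Writes a per-candidate TSV (columns: gene, task, enzyme, pop_in_region,
#' cut_pos, d_junction, pop_in_len, pop_out_len, achieved_ratio, truncated,
#' tag_sites, mcs_left, mcs_right, insert_len, status, reason, optimal), a
#' JSON report mirroring the TSV plus sequences, the optimal plasmid as a
#' single-record circular FASTA, the optimal insert as a second FASTA, and
#' optionally a GenBank plasmid map.
#'
#' @param design A `pipo_design`.
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("tsv", "json")`.
#' @param genbank Also write a GenBank map of the optimal plasmid?
#' @param prefix File-name prefix; default `<gene>_<task>`.
#' @return Invisibly, a character vector of the files written.
#' @export
write_design_reports <- function(design, dir, formats = c("tsv", "json"),
                                 genbank = FALSE, prefix = NULL) {
  stopifnot(inherits(design, "pipo_design"))
  formats <- match.arg(formats, c("tsv", "json"), several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- paste0(design$locus$name, "_", design$task)
  written <- character(0)

  report <- dplyr::select(tidy(design), "gene", "task", "enzyme",
                          "pop_in_region", "cut_pos", "d_junction",
                          "pop_in_len", "pop_out_len", "achieved_ratio",
                          "truncated", "tag_sites", "mcs_left", "mcs_right",
                          "insert_len", "status", "reason", "optimal")

  if ("tsv" %in% formats) {
    p <- file.path(dir, paste0(prefix, "_candidates.tsv"))
    readr::write_tsv(report, p, na = "")
    written <- c(written, p)
  }
  if ("json" %in% formats) {
    cd <- design$candidates
    with_seqs <- report
    with_seqs$insert_seq <- vapply(cd$insert, function(x)
      if (is.null(x)) NA_character_ else x$seq, character(1))
    with_seqs$plasmid_seq <- vapply(cd$plasmid, function(x)
      if (is.null(x)) NA_character_ else x$seq, character(1))
    p <- file.path(dir, paste0(prefix, "_candidates.json"))
    jsonlite::write_json(with_seqs, p, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p)
  }

  opt <- optimal_candidate(design)
  if (nrow(opt) == 1L) {
    plasmid <- opt$plasmid[[1]]
    insert <- opt$insert[[1]]
    nm <- sprintf("%s %s optimal enzyme=%s insert=%dbp",
                  design$locus$name, design$task, opt$enzyme[[1]],
                  opt$insert_len[[1]])
    p1 <- file.path(dir, paste0(prefix, "_plasmid.fasta"))
    write_fasta(stats::setNames(plasmid$seq, nm), p1, topology = "circular")
    p2 <- file.path(dir, paste0(prefix, "_insert.fasta"))
    write_fasta(stats::setNames(insert$seq,
                                sprintf("%s %s insert", design$locus$name,
                                        design$task)), p2)
    written <- c(written, p1, p2)
    if (genbank) {
      p3 <- file.path(dir, paste0(prefix, "_plasmid.gb"))
      write_genbank(plasmid, paste0(prefix, "_plasmid"), p3)
      written <- c(written, p3)
    }
  }
  invisible(written)
}

#' Run one design from input files or objects and write reports
#'
#' The programmatic equivalent of the command-line `design` subcommand.
#'
#' @param goi A `gene_locus`, or a path to a single-record locus FASTA.
#' @param task Edit task (`delete`, `tag_n`, `tag_c`).
#' @param bb A [backbone()] object, or a path to a backbone FASTA (then `mcs`
#'   is required).
#' @param enzymes Enzyme tibble or path to an enzyme list file.
#' @param out_dir Output directory for reports.
#' @param mcs MCS interval (0-based half-open) when `bb` is a path/string.
#' @param linker,fpg Linker / tag-gene sequence or FASTA path (tagging only).
#' @param min_homology,r_homo,flank_len See [design_params()].
#' @param formats,genbank See [write_design_reports()].
#' @param overlaps Optional overlap intervals for [validate_locus()].
#' @return The `pipo_design`, invisibly, with attribute `exit_status`
#'   (0 = at least one valid design, 3 = none).
#' @export
run_design <- function(goi, task, bb, enzymes, out_dir,
                       mcs = NULL, linker = NULL, fpg = NULL,
                       min_homology = 70L, r_homo = 2, flank_len = 1000L,
                       formats = c("tsv", "json"), genbank = FALSE,
                       overlaps = NULL) {
  locus <- if (inherits(goi, "gene_locus")) goi else read_goi(goi, flank_len)
  if (!inherits(bb, "pipo_backbone")) {
    seqs <- if (file.exists(bb)) read_fasta_seq(bb) else stats::setNames(bb, "backbone")
    bb <- backbone(seqs[[1]], mcs, name = names(seqs)[[1]])
  }
  if (is.data.frame(enzymes)) enz <- enzymes else enz <- read_enzymes(enzymes)
  read_if_path <- function(x) {
    if (is.null(x)) return(NULL)
    if (file.exists(x)) read_fasta_seq(x)[[1]] else x
  }
  args <- list(enzymes = enz, min_homology = min_homology, r_homo = r_homo,
               flank_len = flank_len, fpg = read_if_path(fpg))
  lk <- read_if_path(linker)
  if (!is.null(lk)) args$linker <- lk
  params <- do.call(design_params, args)

  report <- validate_locus(locus, overlaps)
  if (nrow(report) > 0) {
    for (i in seq_len(nrow(report))) {
      rlang::inform(paste0("locus check [", report$code[[i]], "]: ",
                           report$message[[i]]))
    }
  }

  design <- pipo_design(locus, task, bb, params)
  write_design_reports(design, out_dir, formats = formats, genbank = genbank)
  for (i in which(!is.na(design$candidates$reason))) {
    rlang::inform(sprintf("cut site disregarded: %s in %s at %d [%s]",
                          design$candidates$enzyme[[i]],
                          design$candidates$pop_in_region[[i]],
                          design$candidates$cut_pos[[i]],
                          design$candidates$reason[[i]]))
  }
  attr(design, "exit_status") <- if (any(design$candidates$status == "valid")) 0L else 3L
  invisible(design)
}
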